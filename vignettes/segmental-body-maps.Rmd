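---
title: "Segmental body-map analysis of digital symptom drawings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmental body-map analysis of digital symptom drawings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segmapr)
```

## The problem

Acute disease of an internal organ is often accompanied by *referred
segmental signs*: hyperalgesia of the skin (Head zones), deep hyperalgesia
(Mackenzie zones), increased skin and muscle resistance, defense, and signs
of sympathetic activation such as vasomotor changes, piloerection,
asymmetric hyperhidrosis or unilateral mydriasis. These signs appear in
somatic tissue that shares its segmental (spinal or trigeminal) innervation
with the diseased organ, and — by the Hansen–Schliack *side rule* —
predominantly on the body side hosting that organ: heart and stomach on the
left, liver and gallbladder on the right. Spontaneous visceral pain, by
contrast, is a poorly localized, largely midline sensation. Quantifying
where signs and pain sit on the body, per spinal segment and per body half,
is therefore of direct interest for differential diagnosis.

When findings are captured as digital drawings on a body template, this
becomes an image-analysis problem: drawings must be rasterized, superimposed
and binarized per patient, intersected with a segmental atlas of the body
surface, and summarized as coverage, lateralization and frequency
statistics. `segmapr` implements that pipeline end to end, together with a
synthetic cohort generator that encodes the assumed generative structure so
every statistic can be validated against known ground truth.

## The segmental atlas

All statistics are computed against a **schematic** front/back body
template in which every body pixel carries exactly one of 33 segment labels
— trigeminal V1–V3, cervical C2–C8, thoracic T1–T12, lumbar L1–L5, sacral
S1–S5 and coccygeal Cog1 — and one *subject-side* label (left/right).
The template is parametric: a head block of five equal bands (V1–V3,
C2–C3) on a narrow centered column, a trunk block of 28 equal bands
(C4–S5 plus Cog1) spanning 60% of the template width, and lateral limb
rectangles that inherit the trunk band label of their row, restricted to
C5–T1 (arms) and L2–S2 (legs), following standard dermatome order. Cog1 is
dorsal and exists on the back view only; the sacral S3–S5 bands are on both
views by default and can be restricted to the back
(`build_schematic_atlas(..., sacral_front = FALSE)`).

Three conventions matter downstream:

* **Sides are the subject's.** On the front view the subject's right half is
  on the image left; on the back view it is on the image right. The atlas
  stores per-pixel side labels explicitly, so no view-mirroring convention
  can corrupt lateralization statistics.
* **Pixel-center sampling with half-open bands.** A pixel belongs to the
  band containing its center, bands are `[y0, y1)`, so the label maps
  partition the body exactly and identical calls are bit-identical.
* **Odd column counts.** Pixel centers exactly on the template midline
  (x = 0.5) cannot be assigned a side; that single column is excluded from
  the body mask, keeping the left/right partition and the mirror symmetry
  of the atlas exact. Even column counts avoid the issue entirely.

The minimum grid is 66 × 20: below that some band has no pixel row (the
constructor names the first segment that fails). The anatomy is deliberately
schematic — axis-aligned bands, no body contour — because every downstream
statistic depends only on the label maps, not on artwork.

## From drawings to statistics

Drawings are closed polygons in normalized template coordinates,
rasterized by the even-odd rule sampled at pixel centers and clipped to the
body mask. Open strokes are closed automatically when their endpoints meet
within one pixel and otherwise buffered by a one-pixel brush; zero-area
polygons contribute nothing and raise a warning. Per patient, all
distributed signs are **superimposed and binarized** (pixel-wise OR): the
number of signs at a pixel is deliberately discarded, only bodily location
is kept. Spontaneous pain is processed identically but always separately
from the other signs.

`segment_coverage()` divides, for each segment, the number of set pixels by
the segment's pixel total, pooling front and back views into one
denominator. Segments reaching **5% coverage** (the default threshold)
enter the result; the rule exists to exclude segments grazed by drawing
imperfections. For included segments the left and right halves are reported
relative to their own half totals. Two genuinely open design choices are
resolved as follows:

* The threshold applies to the **full segment first**; half-segment
  percentages are reported for surviving segments. The alternative — a
  segment qualifies when either *half* reaches 5% of the half — is
  available as `half_rule = TRUE` (it is never stricter than the default
  rule).
* The comparison uses a `1e-9` absolute epsilon below the threshold so that
  exact integer boundaries (e.g. 10 set pixels of a 200-pixel segment at
  5%) are included regardless of floating-point representation; no
  realizable pixel ratio lies within the epsilon of the threshold without
  equaling it.

`mean_map()` averages per-patient binary maps within an organ group, giving
at each pixel the fraction of patients affected there; `n` times the map is
integer-valued by construction. `mean_signs_per_half_segment()` counts, per
patient, each distributed sign that passes the segment threshold and
touches a half, and averages the counts. `lateralization_summary()` counts
side-labelled findings per body half — front and back treated as one
surface — and reports the ipsilateral percentage under the side rule
(heart, stomach → left; liver/gallbladder → right; rounded to the nearest
integer). The paired organs (lungs, kidneys/ureters) mix left, right and
bilateral affections, so no ipsilateral side is defined and the percentage
is `NA`. Throughout, percentages with zero denominators are `NA`, never 0,
and printed percentages use one decimal with ties rounded half away from
zero.

Cohort selection (`select_single_organ()`) retains patients with a
single-organ diagnosis in one of the five analyzable groups, drops records
flagged as lost, and removes organ groups with fewer than 4 patients
(configurable); it is idempotent.

## The synthetic cohort generator

No patient-level dataset accompanies the analysis this package implements,
so validation rests on a generator whose defaults *are* the assumed study
conditions:

* **Organ spans** (with span maxima that attract drawings): heart T1–T8,
  maximum T3–T5; stomach T2–T12, maximum T6–T9; liver/gallbladder C3–C5
  plus T6–T11 (the shoulder presentation), maximum T6–T9; kidneys/ureters
  T6–L2, maximum T9–L1; lungs V2–L2 with no clear maximum.
* **Side rule**: for unpaired organs each drawing run and each lateralized
  finding falls ipsilaterally with probability 0.85 (between the observed
  ~83% for heart and 100% for liver/gallbladder, configurable per organ).
  Paired organs sample an affected side uniformly, bilateral with
  probability 0.3 to reflect the frequency of bilateral lung disease.
* **Prevalences**: cohort-wide marginals (superficial hyperalgesia 0.418,
  muscle resistance 0.355, mydriasis 0.336, …, spontaneous pain 0.773;
  symptoms nausea 0.409 down to urinary retention 0). Per-organ prevalences
  are not separately modelled — every organ profile carries the same
  marginal, a documented modelling convenience, because only cohort-wide
  sign frequencies are available.
* **Organ mix** 62 : 20 : 8 : 12 : 8 over heart, lungs, stomach,
  liver/gallbladder and kidneys/ureters (the single-organ case distribution
  implied by the reported per-organ mydriasis rates of a 110-patient
  cohort).
* **Geometry**: a present sign draws 1–3 contiguous runs of one to three
  half segments within the organ span (start biased 3 : 1 towards the span
  maximum); each run covers a fraction of the half-segment surface drawn
  from a normal distribution (mean 0.5, SD 0.15, truncated to
  [0.05, 1]) at a uniform horizontal anchor. Spontaneous pain is drawn as a
  midline-straddling rectangle within the organ's pain span (e.g. heart
  T2–T5, stomach T5–T9), making its left/right pixel mass exactly symmetric
  before jitter. Vertex-level Gaussian jitter (SD 0.005 in normalized
  units, about half a pixel at the default 132 × 40 grid) emulates drawing
  imperfections.
* **Demographics**: age ~ N(57.3, 17.2) truncated to 18–99, 40.9% female.

All randomness flows from one seed through deterministic per-patient
substreams; identical seeds give bit-identical cohorts, and the emitted
ground truth (organ, affected side, per-sign target runs, finding sides,
symptoms) is checked against the records in the test suite.

What the generator does *not* emulate: *per-organ* sign profiles,
co-occurrence between signs, multi-organ disease, anatomically realistic
drawing shapes, or examiner-specific bias. A passing recovery test
therefore shows that the pipeline measures what the generative model puts
in — not that real drawings obey the model.

## Validation and problem sizes

The test suite validates the pipeline at three levels, with sizes chosen to
keep each property statistically decisive:

* worked-example arithmetic on published marginal counts (cohorts of
  110/81/18/5 patients reconstructed from the printed numerators and
  denominators);
* exact oracle equivalence: coverage versus scalar per-pixel counting on
  100 random masks, rasterization versus a scalar point-in-polygon test,
  superimposition versus the pixel-wise maximum;
* parameter recovery at a fixed seed: prevalences and the ipsilateral
  mydriasis proportion within 3 binomial standard errors at n = 5000;
  exact span recovery per organ at n = 200 with zero jitter and run
  coverage fractions of at least 0.3; pain left/right mass ratio within
  [0.8, 1.25] and all-signs ipsilateral-to-contralateral mass ratio above 2
  at n = 200.

## Known limitations

* **Band quantization bounds coverage precision.** A polygon edge cutting
  through the middle of a band is resolved to about half a pixel row; at
  the default grid a trunk band is ~4 pixel rows tall, so coverage of a
  partially covered segment is quantized in steps of several percentage
  points. Refining the grid changes such coverages by up to the same
  amount; coverage of fully covered or untouched segments is exact at any
  resolution. Use taller grids when sub-band precision matters.
* The schematic template has no limb-specific dermatome geometry beyond the
  band inheritance described above, and no body contour; absolute pixel
  areas are not anatomical surface areas.
* Binarization discards sign multiplicity at a pixel by design; analyses
  needing per-sign intensity must work from the per-sign maps.
* The generator's shared marginal prevalences make organ groups differ only
  in span, side and mix — convenient for recovery testing, unrealistic for
  classifier development.
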