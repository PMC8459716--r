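#' Per-segment coverage of a binary body map, with inclusion threshold
#'
#' For every segment the coverage is the percentage of the segment's pixels
#' (front and back views pooled into one denominator) that are set in the
#' map. Segments reaching at least `threshold` coverage pass the inclusion
#' rule; for those, coverage of the left and right half segments is reported
#' as well. The default 5% rule excludes segments with marginal coverage,
#' e.g. from drawing imperfections.
#'
#' @param map A `body_map`, or a `mean_body_map` (then any pixel touched by
#'   at least one patient counts as set).
#' @param atlas The `segment_atlas` the map lives on.
#' @param threshold Inclusion threshold as a fraction in `[0, 1]`
#'   (default 0.05).
#' @param half_rule Apply the threshold to the half segments instead: a
#'   segment is included when either half reaches `threshold` coverage of
#'   that half's pixels (default `FALSE`: the rule applies to the full
#'   segment).
#' @return data.frame with columns `segment`, `side` (`both`, plus `left` /
#'   `right` rows for passing segments), `pixels_set`, `pixels_total`,
#'   `coverage` (percent) and `passed_threshold`.
#' @export
segment_coverage <- function(map, atlas, threshold = 0.05,
                             half_rule = FALSE) {
  stopifnot(is_segment_atlas(atlas))
  if (inherits(map, "mean_body_map"))
    map <- body_map(map$front > 0, map$back > 0)
  if (!is_body_map(map)) stop("segment_coverage: not a body_map")
  if (!all(dim(map$front) == c(atlas$rows, atlas$cols)))
    stop("segment_coverage: map and atlas grids differ", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("segment_coverage: threshold must be a single value in [0, 1]",
         call. = FALSE)

  labs <- atlas$labels
  nseg <- length(labs)
  tot <- set <- matrix(0L, nseg, 2L, dimnames = list(labs, c("left", "right")))
  for (v in body_views()) {
    seg <- atlas$seg[[v]]; side <- atlas$side[[v]]; m <- map[[v]]
    keep <- seg > 0L
    fs <- factor(labs[seg[keep]], levels = labs)
    fh <- factor(c("left", "right")[side[keep]], levels = c("left", "right"))
    tot <- tot + table(fs, fh)
    set <- set + tapply(m[keep], list(fs, fh), sum, default = 0L)
  }
  seg_tot <- rowSums(tot); seg_set <- rowSums(set)
  coverage <- ifelse(seg_tot > 0, 100 * seg_set / seg_tot, NA_real_)
  passed <- if (half_rule) {
    half_frac <- set / pmax(tot, 1L)
    seg_tot > 0 & apply(half_frac >= (threshold - 1e-9) & tot > 0, 1, any)
  } else {
    !is.na(coverage) & (seg_set / pmax(seg_tot, 1L)) >= (threshold - 1e-9)
  }

  out <- data.frame(segment = labs, side = "both", pixels_set = seg_set,
                    pixels_total = seg_tot, coverage = coverage,
                    passed_threshold = passed, stringsAsFactors = FALSE)
  halves <- lapply(labs[passed], function(s) {
    data.frame(segment = s, side = c("left", "right"),
               pixels_set = set[s, ], pixels_total = tot[s, ],
               coverage = ifelse(tot[s, ] > 0, 100 * set[s, ] / tot[s, ],
                                 NA_real_),
               passed_threshold = TRUE, stringsAsFactors = FALSE)
  })
  out <- rbind(out, do.call(rbind, halves))
  rownames(out) <- NULL
  out
}

#' Segments passing the inclusion rule
#'
#' @inheritParams segment_coverage
#' @return Character vector of segment labels, in cranio-caudal order.
#' @export
passing_segments <- function(map, atlas, threshold = 0.05,
                             half_rule = FALSE) {
  cov <- segment_coverage(map, atlas, threshold, half_rule)
  cov$segment[cov$side == "both" & cov$passed_threshold]
}

#' Mean body map of an organ group
#'
#' Pixel-wise mean of the patients' binarized maps: the value at a pixel is
#' the fraction of the organ's patients in whom at least one of the selected
#' findings covered that body point. With `what = "all_signs"` each patient
#' contributes the superimposed, binarized union of all distributed signs
#' (spontaneous pain excluded); with `what = "pain"` only the spontaneous
#' pain drawing; any single sign token selects that sign alone.
#'
#' @param x A `cohort`.
#' @param organ Organ group label.
#' @param what `"all_signs"`, `"pain"`, or one token of
#'   [distributed_signs()].
#' @param atlas A `segment_atlas`.
#' @return A `mean_body_map`: list with per-view fraction grids `front` /
#'   `back`, patient count `n`, `organ` and `what`.
#' @export
mean_map <- function(x, organ, what, atlas) {
  validate_cohort(x)
  stopifnot(is_segment_atlas(atlas))
  signs <- switch(what,
    all_signs = setdiff(distributed_signs(), "spontaneous_pain"),
    pain = "spontaneous_pain",
    {
      if (!what %in% distributed_signs())
        stop("mean_map: unknown selection '", what, "'", call. = FALSE)
      what
    })
  patients <- Filter(function(p) p$organ == organ, x$patients)
  if (!length(patients))
    stop("mean_map: no patients with organ '", organ, "'", call. = FALSE)
  acc_f <- acc_b <- matrix(0, atlas$rows, atlas$cols)
  for (p in patients) {
    m <- patient_sign_map(p, atlas, signs)
    acc_f <- acc_f + m$front
    acc_b <- acc_b + m$back
  }
  n <- length(patients)
  structure(list(front = acc_f / n, back = acc_b / n, n = n,
                 organ = organ, what = what), class = "mean_body_map")
}

#' @export
print.mean_body_map <- function(x, ...) {
  cat("<mean_body_map> organ=", x$organ, " what=", x$what, " n=", x$n,
      "; max fraction=", round(max(x$front, x$back), 3), "\n", sep = "")
  invisible(x)
}

#' Left/right pixel mass of a map
#'
#' Sums map values over the subject-left and subject-right body halves,
#' pooling front and back views. Used to quantify lateralization of mean
#' maps (e.g. midline symmetry of spontaneous pain).
#'
#' @param map A `body_map` or `mean_body_map`.
#' @param atlas A `segment_atlas`.
#' @return Named numeric vector `c(left =, right =)`.
#' @export
map_side_mass <- function(map, atlas) {
  stopifnot(is_segment_atlas(atlas))
  mass <- c(left = 0, right = 0)
  for (v in body_views()) {
    side <- atlas$side[[v]]
    m <- map[[v]]
    mass["left"] <- mass["left"] + sum(m[side == 1L])
    mass["right"] <- mass["right"] + sum(m[side == 2L])
  }
  mass
}

#' Mean number of segmental signs per half segment
#'
#' For each patient, a distributed sign contributes one count to a half
#' segment when the sign's own map passes the segment inclusion threshold
#' (full segment, front+back pooled) and has at least one pixel in that
#' half. The table reports the mean count over the organ's patients, i.e.
#' the expected number of distinct signs affecting each half segment.
#'
#' @param x A `cohort`.
#' @param organ Organ group label.
#' @param atlas A `segment_atlas`.
#' @param threshold Segment inclusion threshold (default 0.05).
#' @return data.frame with columns `segment`, `side`, `mean_signs`.
#' @export
mean_signs_per_half_segment <- function(x, organ, atlas, threshold = 0.05) {
  validate_cohort(x)
  patients <- Filter(function(p) p$organ == organ, x$patients)
  if (!length(patients))
    stop("mean_signs_per_half_segment: no patients with organ '", organ, "'",
         call. = FALSE)
  labs <- atlas$labels
  acc <- matrix(0, length(labs), 2L, dimnames = list(labs, c("left", "right")))
  signs <- setdiff(distributed_signs(), "spontaneous_pain")
  for (p in patients) {
    present <- unique(vapply(p$drawings, `[[`, character(1), "sign"))
    for (s in intersect(present, signs)) {
      m <- patient_sign_map(p, atlas, s)
      cov <- segment_coverage(m, atlas, threshold)
      hit <- cov[cov$side != "both" & cov$pixels_set > 0, ]
      if (nrow(hit))
        acc[cbind(hit$segment, hit$side)] <-
          acc[cbind(hit$segment, hit$side)] + 1
    }
  }
  acc <- acc / length(patients)
  data.frame(segment = rep(labs, 2L),
             side = rep(c("left", "right"), each = length(labs)),
             mean_signs = c(acc[, "left"], acc[, "right"]),
             stringsAsFactors = FALSE)
}

#' Lateralization summary of side-labelled findings
#'
#' Counts, for one organ group, how many patients carry each lateralized
#' finding on the left and on the right, and expresses the ipsilateral
#' proportion under the side rule (heart and stomach: left; liver and
#' gallbladder: right). For the paired organs (lungs, kidneys/ureters) no
#' ipsilateral side is defined and the percentage is `NA`: their cohorts mix
#' left, right and bilateral affections.
#'
#' @param x A `cohort`.
#' @param organ One of [analyzable_organs()].
#' @return data.frame with columns `organ`, `finding`, `n_left`, `n_right`,
#'   `ipsilateral_side`, `percent_ipsilateral` (rounded to the nearest
#'   integer, half away from zero; `NA` when no side is defined or no
#'   finding was observed).
#' @export
lateralization_summary <- function(x, organ) {
  validate_cohort(x)
  if (!organ %in% analyzable_organs())
    stop("lateralization_summary: organ must be one of the analyzable groups",
         call. = FALSE)
  patients <- Filter(function(p) p$organ == organ, x$patients)
  ipsi <- ipsilateral_side_of(organ)
  rows <- lapply(lateralized_findings(), function(f) {
    nl <- sum(vapply(patients, function(p)
      any(vapply(p$lateralized, function(lf)
        lf$finding == f && lf$side == "left", logical(1))), logical(1)))
    nr <- sum(vapply(patients, function(p)
      any(vapply(p$lateralized, function(lf)
        lf$finding == f && lf$side == "right", logical(1))), logical(1)))
    pct <- if (is.na(ipsi) || nl + nr == 0) NA_real_ else
      round_away(100 * (if (ipsi == "left") nl else nr) / (nl + nr))
    data.frame(organ = organ, finding = f, n_left = nl, n_right = nr,
               ipsilateral_side = ipsi, percent_ipsilateral = pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Frequency table of signs and symptoms
#'
#' Number and percentage of patients showing each segmental sign (distributed
#' signs by drawing, lateralized findings by side label; glossy eye and wide
#' eyelid separation are also reported as one combined sign, as examined) and
#' each segmental symptom, plus the aggregate rows *at least 1 segmental
#' sign*, *at least 1 segmental symptom* and *spontaneous pain*. Percentages
#' are of the whole cohort, one decimal, half rounded away from zero.
#'
#' @param x A non-empty `cohort`.
#' @return data.frame with columns `finding`, `group` (`sign`, `symptom`,
#'   `aggregate`), `n`, `percent`.
#' @export
frequency_table <- function(x) {
  validate_cohort(x)
  n <- length(x$patients)
  if (n == 0L) stop("frequency_table: empty cohort", call. = FALSE)

  has_drawing <- function(p, s)
    any(vapply(p$drawings, function(d) d$sign == s, logical(1)))
  has_lat <- function(p, f)
    any(vapply(p$lateralized, function(lf) lf$finding == f, logical(1)))

  count <- function(pred) sum(vapply(x$patients, pred, logical(1)))
  row <- function(finding, group, k)
    data.frame(finding = finding, group = group, n = k,
               percent = round_away(100 * k / n, 1), stringsAsFactors = FALSE)

  dist_signs <- setdiff(distributed_signs(), "spontaneous_pain")
  rows <- list()
  for (s in dist_signs)
    rows[[length(rows) + 1L]] <- row(s, "sign", count(function(p)
      has_drawing(p, s)))
  for (f in lateralized_findings())
    rows[[length(rows) + 1L]] <- row(f, "sign", count(function(p)
      has_lat(p, f)))
  rows[[length(rows) + 1L]] <- row("glossy_eye_wide_eyelid", "sign",
    count(function(p) has_lat(p, "glossy_eye") ||
                      has_lat(p, "eyelid_separation")))
  for (s in segmental_symptoms())
    rows[[length(rows) + 1L]] <- row(s, "symptom", count(function(p)
      s %in% p$symptoms))
  any_sign <- count(function(p)
    any(vapply(p$drawings, function(d)
      d$sign != "spontaneous_pain", logical(1))) || length(p$lateralized) > 0)
  any_sym <- count(function(p) length(p$symptoms) > 0)
  pain <- count(function(p) has_drawing(p, "spontaneous_pain"))
  rows[[length(rows) + 1L]] <- row("at_least_1_segmental_sign", "aggregate",
                                   any_sign)
  rows[[length(rows) + 1L]] <- row("at_least_1_segmental_symptom",
                                   "aggregate", any_sym)
  rows[[length(rows) + 1L]] <- row("spontaneous_pain", "aggregate", pain)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
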