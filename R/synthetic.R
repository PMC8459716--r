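#' Default generative specification for synthetic cohorts
#'
#' Encodes the study conditions the analysis assumes: organ-specific segment
#' spans with a span maximum (heart signs centred on T3-T5; stomach T2-T12
#' with maximum T6-T9; liver/gallbladder thoracic plus the C3-C5 shoulder
#' zone, right-sided; kidneys/ureters T6-L2; lungs widespread V2-L2), the
#' side rule for unpaired organs (heart and stomach left, liver/gallbladder
#' right; default ipsilateral probability 0.85), midline spontaneous pain,
#' and cohort-wide sign/symptom prevalences. Per-organ prevalences are not
#' separately modelled: every organ uses the cohort-wide marginal, a
#' documented modelling convenience.
#'
#' @param n Cohort size (default 110).
#' @param seed Default generation seed.
#' @return A `synthetic_spec` list; see fields in the source and the methods
#'   vignette.
#' @export
default_spec <- function(n = 110L, seed = 1L) {
  sign_prev <- c(
    superficial_hyperalgesia = 0.418, muscle_resistance = 0.355,
    defense = 0.118, deep_hyperalgesia = 0.118,
    superficial_skin_resistance = 0.109, vasomotor_changes = 0.091,
    allodynia = 0.018, piloerection = 0.009,
    asymmetric_hyperhidrosis = 0.009, zoster = 0,
    passive_movement_resistance = 0)
  lat_prev <- c(
    mydriasis = 0.336, tense_facial_muscles = 0.100, glossy_eye = 0.073,
    eyelid_separation = 0, asymmetric_posture = 0.064,
    reduced_respiration = 0.027)
  symptom_prev <- c(
    nausea = 0.409, vomiting = 0.164, diarrhea = 0.091, meteorism = 0.073,
    constipation = 0.045, urinary_retention = 0)

  seg <- segment_labels()
  span <- function(from, to) seg[match(from, seg):match(to, seg)]
  profile <- function(organ, span, span_max, ipsi_side, pain_span,
                      ipsi_prob = 0.85) {
    list(organ = organ, span = span, span_max = span_max,
         ipsi_side = ipsi_side, ipsi_prob = ipsi_prob,
         sign_prev = sign_prev, lat_prev = lat_prev,
         symptom_prev = symptom_prev, pain_prev = 0.773,
         pain_span = pain_span, pain_midline = TRUE)
  }
  organs <- list(
    heart = profile("heart", span("T1", "T8"), span("T3", "T5"),
                    "left", span("T2", "T5")),
    lungs = profile("lungs", span("V2", "L2"), span("V2", "L2"),
                    "both", span("T5", "T9")),
    stomach = profile("stomach", span("T2", "T12"), span("T6", "T9"),
                      "left", span("T5", "T9")),
    liver_gallbladder = profile("liver_gallbladder",
                                c(span("C3", "C5"), span("T6", "T11")),
                                span("T6", "T9"), "right", span("T5", "T9")),
    kidneys_ureters = profile("kidneys_ureters", span("T6", "L2"),
                              span("T9", "L1"), "both", span("T9", "L2")))

  spec <- structure(list(
    organs = organs,
    # organ mix from the single-organ case distribution implied by the
    # reported per-organ mydriasis rates (62/20/8/12/8 of 110)
    mix = c(heart = 62, lungs = 20, stomach = 8, liver_gallbladder = 12,
            kidneys_ureters = 8) / 110,
    n = as.integer(n), seed = as.integer(seed),
    coverage_mean = 0.5, coverage_sd = 0.15, coverage_range = c(0.05, 1),
    jitter = 0.005, bilateral_prob = 0.3,
    age_mean = 57.3, age_sd = 17.2, female_prob = 0.409),
    class = "synthetic_spec")
  validate_spec(spec)
  spec
}

#' @rdname default_spec
#' @param spec A `synthetic_spec`.
#' @export
validate_spec <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stop("not a synthetic_spec", call. = FALSE)
  if (abs(sum(spec$mix) - 1) > 1e-8)
    stop("synthetic_spec: organ mix must sum to 1", call. = FALSE)
  if (spec$n < 1L) stop("synthetic_spec: cohort size must be >= 1",
                        call. = FALSE)
  for (pr in spec$organs) {
    probs <- c(pr$sign_prev, pr$lat_prev, pr$symptom_prev, pr$pain_prev,
               pr$ipsi_prob)
    if (any(probs < 0 | probs > 1))
      stop("synthetic_spec: probabilities for organ '", pr$organ,
           "' outside [0, 1]", call. = FALSE)
    if (!all(pr$span_max %in% pr$span))
      stop("synthetic_spec: span maximum of organ '", pr$organ,
           "' is not a subset of its span", call. = FALSE)
    if (!all(c(pr$span, pr$pain_span) %in% segment_labels()))
      stop("synthetic_spec: unknown segment in span of organ '", pr$organ,
           "'", call. = FALSE)
  }
  if (spec$jitter < 0 || spec$coverage_range[1] <= 0 ||
      spec$coverage_range[2] > 1 ||
      spec$coverage_range[1] > spec$coverage_range[2])
    stop("synthetic_spec: invalid coverage/jitter settings", call. = FALSE)
  invisible(spec)
}

# jittered, clamped rectangle polygon
.rect_poly <- function(x0, x1, y0, y1, jitter) {
  m <- matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2L, byrow = TRUE)
  if (jitter > 0) m <- m + stats::rnorm(length(m), 0, jitter)
  pmin(pmax(m, 0), 1)
}

.sample_fraction <- function(spec) {
  min(max(stats::rnorm(1, spec$coverage_mean, spec$coverage_sd),
          spec$coverage_range[1]), spec$coverage_range[2])
}

# a contiguous run of 1-3 segments within the profile's span, biased
# towards the span maximum
.sample_run <- function(span, span_max) {
  w <- ifelse(span %in% span_max, 3, 1)
  start <- sample.int(length(span), 1L, prob = w)
  len <- sample.int(3L, 1L)
  span[start:min(start + len - 1L, length(span))]
}

.sample_side <- function(affected, ipsi_prob) {
  if (affected == "both") return(sample(body_sides(), 1L))
  if (stats::runif(1) < ipsi_prob) affected else
    setdiff(body_sides(), affected)
}

#' Generate a synthetic cohort with retained ground truth
#'
#' Samples patients from the generative model in `spec`: an organ from the
#' mix; for paired organs an affected side (bilateral with probability
#' `bilateral_prob`); each distributed sign independently present with its
#' prevalence and drawn as rectangles covering a sampled fraction of 1-3
#' contiguous half segments within the organ's span, placed on the
#' ipsilateral half with the side-rule probability; spontaneous pain as a
#' midline-straddling rectangle within the organ's pain span; lateralized
#' findings with a side sampled by the same rule; symptoms as Bernoulli
#' flags. All randomness flows from `seed` through deterministic per-patient
#' substreams, so identical calls are bit-identical.
#'
#' @param spec A `synthetic_spec`, e.g. [default_spec()].
#' @param n,seed Optional overrides of `spec$n` / `spec$seed`.
#' @return List with elements `cohort` (a [cohort()]) and `truth` (per
#'   patient: organ, affected side, per-sign target runs, lateralized
#'   findings, symptoms, pain run).
#' @export
generate_cohort <- function(spec = default_spec(), n = NULL, seed = NULL) {
  validate_spec(spec)
  n <- as.integer(n %||% spec$n)
  seed <- as.integer(seed %||% spec$seed)
  set.seed(seed)
  pseeds <- sample.int(.Machine$integer.max - 1L, n)

  patients <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(pseeds[i])
    organ <- sample(names(spec$mix), 1L, prob = spec$mix)
    pr <- spec$organs[[organ]]
    affected <- if (pr$ipsi_side %in% body_sides()) pr$ipsi_side else
      if (stats::runif(1) < spec$bilateral_prob) "both" else
        sample(body_sides(), 1L)

    symptoms <- names(pr$symptom_prev)[
      stats::runif(length(pr$symptom_prev)) < pr$symptom_prev]

    lateralized <- list()
    lat_truth <- list()
    for (f in names(pr$lat_prev)) {
      if (stats::runif(1) < pr$lat_prev[[f]]) {
        side <- .sample_side(affected, pr$ipsi_prob)
        lateralized[[length(lateralized) + 1L]] <-
          list(finding = f, side = side)
        lat_truth[[f]] <- side
      }
    }

    polys <- list()  # per sign per view accumulation
    sign_truth <- list()
    add_poly <- function(sign, view, poly) {
      key <- paste(sign, view, sep = "|")
      polys[[key]] <<- c(polys[[key]], list(poly))
    }
    for (s in names(pr$sign_prev)) {
      if (stats::runif(1) >= pr$sign_prev[[s]]) next
      n_runs <- sample.int(3L, 1L)
      runs <- list()
      for (k in seq_len(n_runs)) {
        run <- .sample_run(pr$span, pr$span_max)
        side <- .sample_side(affected, pr$ipsi_prob)
        view <- sample(body_views(), 1L)
        f <- .sample_fraction(spec)
        u <- stats::runif(1)
        for (segname in run) {
          rect <- segment_rect(segname, side, view)
          w <- f * (rect[2] - rect[1])
          x0 <- rect[1] + u * (rect[2] - rect[1] - w)
          add_poly(s, view, .rect_poly(x0, x0 + w, rect[3], rect[4],
                                       spec$jitter))
        }
        runs[[k]] <- list(segments = run, side = side, view = view,
                          fraction = f)
      }
      sign_truth[[s]] <- runs
    }

    pain_truth <- NULL
    if (stats::runif(1) < pr$pain_prev) {
      run <- .sample_run(pr$pain_span, pr$pain_span)
      view <- sample(body_views(), 1L)
      f <- .sample_fraction(spec)
      for (segname in run) {
        rect <- segment_rect(segname, "both", view)
        hw <- f * (rect[2] - rect[1]) / 2
        add_poly("spontaneous_pain", view,
                 .rect_poly(0.5 - hw, 0.5 + hw, rect[3], rect[4],
                            spec$jitter))
      }
      pain_truth <- list(segments = run, view = view, fraction = f)
    }

    drawings <- lapply(names(polys), function(key) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      drawing_record(parts[1], parts[2], polys[[key]])
    })

    age <- round(min(max(stats::rnorm(1, spec$age_mean, spec$age_sd), 18), 99))
    sex <- if (stats::runif(1) < spec$female_prob) "female" else "male"
    id <- sprintf("P%04d", i)
    patients[[i]] <- patient_record(id, organ, drawings, lateralized,
                                    symptoms, age = age, sex = sex)
    truth[[i]] <- list(id = id, organ = organ, affected_side = affected,
                       signs = sign_truth, lateralized = lat_truth,
                       symptoms = symptoms, pain = pain_truth)
  }
  list(cohort = cohort(patients, meta = list(source = "synthetic",
                                             seed = seed, n = n)),
       truth = truth)
}
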