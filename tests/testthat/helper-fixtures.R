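# Shared fixtures and independent brute-force oracles.

# memoized atlases (building is cheap but used everywhere)
.fixture_env <- new.env(parent = emptyenv())
test_atlas <- function(rows = 132, cols = 40) {
  key <- paste0("a", rows, "x", cols)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- build_schematic_atlas(rows, cols)
  .fixture_env[[key]]
}

rect_poly <- function(x0, x1, y0, y1) {
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
}

# polygon that covers exactly the pixels of `segment` on `view` (both halves):
# bounding box of the segment's pixel centers, padded by less than one pixel
segment_cover_poly <- function(atlas, segment, view) {
  code <- match(segment, atlas$labels)
  hit <- which(atlas$seg[[view]] == code, arr.ind = TRUE)
  stopifnot(nrow(hit) > 0)
  cy <- (hit[, 1] - 0.5) / atlas$rows
  cx <- (hit[, 2] - 0.5) / atlas$cols
  rect_poly(min(cx) - 0.4 / atlas$cols, max(cx) + 0.4 / atlas$cols,
            min(cy) - 0.4 / atlas$rows, max(cy) + 0.4 / atlas$rows)
}

# oracle: scalar, per-pixel even-odd crossing test
bf_rasterize <- function(poly, rows, cols) {
  out <- matrix(0L, rows, cols)
  n <- nrow(poly)
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      x <- (cc - 0.5) / cols; y <- (r - 0.5) / rows
      inside <- FALSE
      j <- n
      for (i in seq_len(n)) {
        yi <- poly[i, 2]; yj <- poly[j, 2]
        if ((yi > y) != (yj > y)) {
          xint <- poly[j, 1] + (y - yj) * (poly[i, 1] - poly[j, 1]) / (yi - yj)
          if (x < xint) inside <- !inside
        }
        j <- i
      }
      if (inside) out[r, cc] <- 1L
      }
  }
  out
}

# oracle: per-pixel scalar counting of segment coverage (front+back pooled)
bf_segment_counts <- function(map, atlas) {
  labs <- atlas$labels
  tot <- set <- stats::setNames(numeric(length(labs)), labs)
  for (v in c("front", "back")) {
    seg <- atlas$seg[[v]]; m <- map[[v]]
    for (r in seq_len(nrow(seg))) for (cc in seq_len(ncol(seg))) {
      k <- seg[r, cc]
      if (k > 0L) {
        tot[k] <- tot[k] + 1
        if (m[r, cc] == 1L) set[k] <- set[k] + 1
      }
    }
  }
  list(set = set, tot = tot)
}

random_body_mask <- function(atlas, p = 0.2) {
  f <- matrix(stats::rbinom(atlas$rows * atlas$cols, 1, p),
              atlas$rows, atlas$cols) * body_mask(atlas, "front")
  b <- matrix(stats::rbinom(atlas$rows * atlas$cols, 1, p),
              atlas$rows, atlas$cols) * body_mask(atlas, "back")
  body_map(f, b)
}

simple_patient <- function(id, organ, drawings = list(), lateralized = list(),
                           symptoms = character(), ...) {
  patient_record(id, organ, drawings, lateralized, symptoms, ...)
}

# small drawing fully inside the trunk zone
trunk_drawing <- function(sign = "superficial_hyperalgesia", view = "front",
                          x0 = 0.3, x1 = 0.45, y0 = 0.4, y1 = 0.5) {
  drawing_record(sign, view, rect_poly(x0, x1, y0, y1))
}

# cohort reproducing the printed marginal counts of the study sample:
# n = 110; 85 spontaneous pain; 81 with >= 1 segmental sign of which 46
# superficial hyperalgesia and 39 muscle resistance; 37 mydriasis;
# 52 with >= 1 segmental symptom.
printed_counts_cohort <- function(n = 110, n_pain = 85, n_sign = 81,
                                  n_suphyp = 46, n_muscle = 39,
                                  n_mydriasis = 37, n_symptom = 52) {
  patients <- lapply(seq_len(n), function(i) {
    drawings <- list()
    if (i <= n_pain)
      drawings <- c(drawings, list(trunk_drawing("spontaneous_pain")))
    if (i <= n_suphyp)
      drawings <- c(drawings, list(trunk_drawing("superficial_hyperalgesia")))
    if (i <= n_muscle)
      drawings <- c(drawings, list(trunk_drawing("muscle_resistance")))
    if (i > n_suphyp && i <= n_sign && i > n_muscle)
      drawings <- c(drawings, list(trunk_drawing("vasomotor_changes")))
    lateralized <- if (i <= n_mydriasis)
      list(list(finding = "mydriasis", side = "left")) else list()
    symptoms <- if (i <= n_symptom) "nausea" else character()
    patient_record(sprintf("wp%03d", i), "heart", drawings, lateralized,
                   symptoms)
  })
  cohort(patients, meta = list(source = "printed-counts"))
}

# heart cohort with a given mydriasis split
mydriasis_cohort <- function(organ, n_ipsi_side, sides) {
  stopifnot(length(n_ipsi_side) == length(sides))
  idx <- 0
  patients <- list()
  for (k in seq_along(sides)) {
    for (i in seq_len(n_ipsi_side[k])) {
      idx <- idx + 1
      patients[[idx]] <- patient_record(
        sprintf("%s%03d", organ, idx), organ,
        lateralized = list(list(finding = "mydriasis", side = sides[k])))
    }
  }
  cohort(patients)
}
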