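#' Segment labels in cranio-caudal order
#'
#' The segmental scheme used throughout: three trigeminal divisions (V1-V3),
#' cervical C2-C8, thoracic T1-T12, lumbar L1-L5, sacral S1-S5 and the
#' coccygeal segment Cog1 -- 33 segments in total. The returned order is the
#' cranio-caudal order and is also the integer coding used in atlas grids.
#'
#' @return Character vector of length 33.
#' @export
segment_labels <- function() {
  c("V1", "V2", "V3", paste0("C", 2:8), paste0("T", 1:12),
    paste0("L", 1:5), paste0("S", 1:5), "Cog1")
}

# ---- parametric layout -----------------------------------------------------
# The schematic body template is defined in normalized [0,1] x [0,1]
# coordinates (x across columns, y down rows) and rasterized at pixel centers.
# Head region: y in [0, .15), five equal bands V1, V2, V3, C2, C3 on a
# narrow centered column. Trunk region: y in [.15, 1), 28 equal bands
# C4..S5 plus Cog1 (the Cog1 band is populated on the back view only).
# Arms and legs are lateral rectangles that inherit the trunk band label of
# their row, restricted to C5-T1 (arms) and L2-S2 (legs).
.head_bands <- c("V1", "V2", "V3", "C2", "C3")
.trunk_bands <- c(paste0("C", 4:8), paste0("T", 1:12), paste0("L", 1:5),
                  paste0("S", 1:5), "Cog1")
.arm_bands <- c("C5", "C6", "C7", "C8", "T1")
.leg_bands <- c("L2", "L3", "L4", "L5", "S1", "S2")

.layout <- list(
  head_y = c(0, 0.15),
  trunk_y = c(0.15, 1),
  head_x = c(0.35, 0.65),
  trunk_x = c(0.20, 0.80),
  limb_x_left = c(0.05, 0.20),   # image-left limb column
  limb_x_right = c(0.80, 0.95))  # image-right limb column

#' Normalized band and zone geometry of the schematic template
#'
#' Returns, for every segment, the normalized y-range of its horizontal band
#' and the zone (`head` or `trunk`) holding its main body surface. Useful for
#' constructing drawings that target specific segments.
#'
#' @return A data.frame with columns `segment`, `zone`, `y0`, `y1`,
#'   `on_arms`, `on_legs`, `back_only`.
#' @export
atlas_layout <- function() {
  hb <- .head_bands
  tb <- .trunk_bands
  hy <- seq(.layout$head_y[1], .layout$head_y[2], length.out = length(hb) + 1)
  ty <- seq(.layout$trunk_y[1], .layout$trunk_y[2], length.out = length(tb) + 1)
  data.frame(
    segment = c(hb, tb),
    zone = c(rep("head", length(hb)), rep("trunk", length(tb))),
    y0 = c(hy[-length(hy)], ty[-length(ty)]),
    y1 = c(hy[-1], ty[-1]),
    on_arms = c(hb, tb) %in% .arm_bands,
    on_legs = c(hb, tb) %in% .leg_bands,
    back_only = c(hb, tb) == "Cog1",
    stringsAsFactors = FALSE)
}

#' Normalized rectangle of a segment's torso/head surface
#'
#' Gives the axis-aligned rectangle, in normalized template coordinates, that
#' a drawing should cover to mark a segment (or one of its halves) on a given
#' view. Sides are the *subject's* anatomical sides: on the front view the
#' subject's right half appears on the image left, on the back view on the
#' image right.
#'
#' @param segment A segment label (see [segment_labels()]).
#' @param side `"left"`, `"right"` (subject side) or `"both"`.
#' @param view `"front"` or `"back"`.
#' @return Numeric vector `c(x0, x1, y0, y1)`.
#' @export
segment_rect <- function(segment, side = "both", view = "front") {
  lay <- atlas_layout()
  row <- lay[lay$segment == segment, ]
  if (nrow(row) != 1L) stop("unknown segment: ", segment)
  if (row$back_only && view == "front")
    stop("segment ", segment, " exists on the back view only")
  zx <- if (row$zone == "head") .layout$head_x else .layout$trunk_x
  xr <- if (side == "both") zx else {
    image_left <- (view == "front" && side == "right") ||
      (view == "back" && side == "left")
    if (image_left) c(zx[1], 0.5) else c(0.5, zx[2])
  }
  c(xr[1], xr[2], row$y0, row$y1)
}

# pixel-center coordinates along an axis with n cells
.centers <- function(n) (seq_len(n) - 0.5) / n

# raw label/side grids for one view, before size validation
.build_view <- function(rows, cols, view, sacral_front) {
  labs <- segment_labels()
  lay <- atlas_layout()
  px <- .centers(cols)
  py <- .centers(rows)

  # band index per row (0 = none)
  band_of_row <- integer(rows)
  for (k in seq_len(nrow(lay))) {
    hit <- py >= lay$y0[k] & py < lay$y1[k]
    band_of_row[hit] <- k
  }

  in_head_x <- px >= .layout$head_x[1] & px < .layout$head_x[2]
  in_trunk_x <- px >= .layout$trunk_x[1] & px < .layout$trunk_x[2]
  in_limb_x <- (px >= .layout$limb_x_left[1] & px < .layout$limb_x_left[2]) |
    (px >= .layout$limb_x_right[1] & px < .layout$limb_x_right[2])
  on_midline <- abs(px - 0.5) < 1e-12  # odd column counts: excluded from body

  seg <- matrix(0L, rows, cols)
  for (r in seq_len(rows)) {
    k <- band_of_row[r]
    if (k == 0L) next
    segname <- lay$segment[k]
    if (lay$back_only[k] && view == "front") next
    if (!sacral_front && view == "front" && segname %in% c("S3", "S4", "S5"))
      next
    code <- match(segname, labs)
    if (lay$zone[k] == "head") {
      cols_hit <- in_head_x
    } else {
      cols_hit <- in_trunk_x
      if (lay$on_arms[k] || lay$on_legs[k]) cols_hit <- cols_hit | in_limb_x
    }
    seg[r, cols_hit & !on_midline] <- code
  }

  # subject-side labels: 1 = left, 2 = right
  image_left <- px < 0.5
  side_row <- if (view == "front") ifelse(image_left, 2L, 1L) else
    ifelse(image_left, 1L, 2L)
  side <- matrix(rep(side_row, each = rows), rows, cols)
  side[seg == 0L] <- 0L
  list(seg = seg, side = side)
}

#' Build the schematic segmental body atlas
#'
#' Constructs a deterministic front/back body template on a `rows` x `cols`
#' pixel grid in which every body pixel carries exactly one segment label and
#' one subject-side label. The template is schematic (axis-aligned dermatome
#' bands with lateral limb rectangles): all downstream statistics depend only
#' on the label maps, not on anatomical artwork.
#'
#' @param rows,cols Grid dimensions per view; `rows >= 66`, `cols >= 20` so
#'   that every segment band is at least one pixel tall and the left/right
#'   halves are resolvable.
#' @param sacral_front Include the sacral S3-S5 bands on the front view
#'   (default `TRUE`). The coccygeal segment is always back-only.
#' @return A `segment_atlas` object: list with `rows`, `cols`, integer label
#'   matrices `seg$front`/`seg$back` (0 = background, codes index
#'   [segment_labels()]), side matrices `side$front`/`side$back`
#'   (0 none, 1 left, 2 right -- subject side), and `labels`.
#' @export
build_schematic_atlas <- function(rows, cols, sacral_front = TRUE) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(length(rows) == 1L, length(cols) == 1L, rows > 0L, cols > 0L)
  views <- lapply(c(front = "front", back = "back"), function(v)
    .build_view(rows, cols, v, sacral_front))
  atlas <- structure(list(
    rows = rows, cols = cols,
    seg = list(front = views$front$seg, back = views$back$seg),
    side = list(front = views$front$side, back = views$back$side),
    labels = segment_labels(),
    sacral_front = sacral_front), class = "segment_atlas")

  counts <- segment_pixel_counts(atlas)
  tot <- tapply(counts$pixels, counts$segment, sum)
  if (any(tot == 0) || rows < 66L || cols < 20L) {
    bad <- names(tot)[tot == 0]
    worst <- if (length(bad)) bad[1] else names(tot)[which.min(tot)]
    stop("atlas sizing error: grid ", rows, "x", cols,
         " cannot resolve segment '", worst,
         "'; need rows >= 66 and cols >= 20", call. = FALSE)
  }
  # every segment must have both halves populated
  half <- tapply(counts$pixels, list(counts$segment, counts$side), sum)
  empty_half <- rownames(half)[apply(half, 1, function(p) any(p == 0))]
  if (length(empty_half))
    stop("atlas sizing error: segment '", empty_half[1],
         "' has an empty body half; need cols >= 20", call. = FALSE)
  atlas
}

#' @export
print.segment_atlas <- function(x, ...) {
  npix <- vapply(x$seg, function(m) sum(m > 0L), integer(1))
  cat("<segment_atlas> ", x$rows, "x", x$cols, " per view; ",
      length(x$labels), " segments; body pixels front=", npix[["front"]],
      " back=", npix[["back"]], "\n", sep = "")
  invisible(x)
}

is_segment_atlas <- function(x) inherits(x, "segment_atlas")

#' Body mask of one atlas view
#'
#' @param atlas A `segment_atlas`.
#' @param view `"front"` or `"back"`.
#' @return Integer 0/1 matrix.
#' @export
body_mask <- function(atlas, view = "front") {
  stopifnot(is_segment_atlas(x = atlas))
  (atlas$seg[[view]] > 0L) + 0L
}

#' Pixel counts per segment, side and view
#'
#' Tabulates the atlas label maps into a table with one row per
#' (segment, side, view) combination, including zero counts. Counts sum to
#' the body-mask pixel total of each view.
#'
#' @param atlas A `segment_atlas`.
#' @return data.frame with columns `segment`, `side`, `view`, `pixels`.
#' @export
segment_pixel_counts <- function(atlas) {
  stopifnot(is_segment_atlas(atlas))
  labs <- atlas$labels
  out <- lapply(body_views(), function(v) {
    seg <- atlas$seg[[v]]; side <- atlas$side[[v]]
    keep <- seg > 0L
    tab <- table(factor(labs[seg[keep]], levels = labs),
                 factor(c("left", "right")[side[keep]],
                        levels = c("left", "right")))
    data.frame(segment = rep(labs, 2L),
               side = rep(c("left", "right"), each = length(labs)),
               view = v,
               pixels = c(tab[, "left"], tab[, "right"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Serialize an atlas as a NIfTI label volume with a JSON code table
#'
#' Writes the two views as a `rows x cols x 2` unsigned 8-bit volume
#' (slice 1 front, slice 2 back) with an identity affine, plus a JSON sidecar
#' mapping integer codes to segment labels.
#'
#' @param atlas A `segment_atlas`.
#' @param path Output `.nii` / `.nii.gz` path. The sidecar is written next to
#'   it with extension `.json`.
#' @return Invisibly, the sidecar path.
#' @export
write_atlas_nifti <- function(atlas, path) {
  stopifnot(is_segment_atlas(atlas))
  vol <- array(0L, dim = c(atlas$rows, atlas$cols, 2L))
  vol[, , 1L] <- atlas$seg$front
  vol[, , 2L] <- atlas$seg$back
  RNifti::writeNifti(RNifti::asNifti(vol), path, datatype = "uint8")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  codes <- as.list(stats::setNames(seq_along(atlas$labels), atlas$labels))
  jsonlite::write_json(list(background = 0L, codes = codes,
                            slices = list(front = 1L, back = 2L)),
                       sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}

#' Write a colour-coded PNG preview of the atlas
#'
#' Front and back views side by side, one colour per segment; intended as a
#' quick visual check of the band layout.
#'
#' @param atlas A `segment_atlas`.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
atlas_preview_png <- function(atlas, path) {
  stopifnot(is_segment_atlas(atlas))
  pal <- grDevices::hcl.colors(length(atlas$labels), "Spectral")
  rgbm <- grDevices::col2rgb(pal) / 255
  canvas <- cbind(atlas$seg$front, 0L, atlas$seg$back)
  img <- array(1, dim = c(nrow(canvas), ncol(canvas), 3L))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[canvas > 0L] <- rgbm[ch, canvas[canvas > 0L]]
    img[, , ch] <- plane
  }
  png::writePNG(img, path)
  invisible(path)
}
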