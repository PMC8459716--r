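#' Binary body maps
#'
#' A `body_map` is a pair of integer 0/1 grids on the atlas dimensions, one
#' per view, always zero outside the atlas body mask. A value of 1 means the
#' mapped finding covers that point of the body.
#'
#' @param front,back Integer/logical matrices of equal dimension.
#' @param provenance Optional list (patient id, sign set, ...).
#' @return A `body_map` object.
#' @export
body_map <- function(front, back, provenance = list()) {
  stopifnot(all(dim(front) == dim(back)))
  front <- (front != 0) + 0L
  back <- (back != 0) + 0L
  structure(list(front = front, back = back, provenance = provenance),
            class = "body_map")
}

is_body_map <- function(x) inherits(x, "body_map")

#' @export
print.body_map <- function(x, ...) {
  cat("<body_map> ", nrow(x$front), "x", ncol(x$front),
      "; set pixels front=", sum(x$front), " back=", sum(x$back), "\n",
      sep = "")
  invisible(x)
}

empty_body_map <- function(atlas, provenance = list()) {
  z <- matrix(0L, atlas$rows, atlas$cols)
  body_map(z, z, provenance)
}

# Even-odd (parity) point-in-polygon test at pixel centers, vectorized over
# pixels. poly is an n x 2 matrix of (x, y) vertices in normalized
# coordinates; px, py are pixel-center coordinate vectors of equal length.
.points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside
}

.polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Pixels within `radius` (normalized units) of any segment of an open
# polyline; used for stroke drawings that do not close on themselves.
.buffer_polyline <- function(px, py, pts, radius) {
  hit <- rep(FALSE, length(px))
  for (i in seq_len(nrow(pts) - 1L)) {
    ax <- pts[i, 1]; ay <- pts[i, 2]
    bx <- pts[i + 1L, 1]; by <- pts[i + 1L, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    d2 <- (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
    hit <- hit | d2 <= radius^2
  }
  hit
}

#' Rasterize one drawing onto the atlas grid
#'
#' Fills the drawing's polygons by the even-odd rule, sampling at pixel
#' centers, on the drawing's view; the result is intersected with the atlas
#' body mask and the other view is all zero. Open strokes are closed
#' automatically when their endpoints coincide within one pixel, otherwise
#' they are buffered by `brush` pixels.
#'
#' @param d A [drawing_record()].
#' @param atlas A `segment_atlas`.
#' @param brush Brush radius in pixels for open strokes (default 1).
#' @return A `body_map`.
#' @export
rasterize_drawing <- function(d, atlas, brush = 1) {
  stopifnot(inherits(d, "drawing_record"), is_segment_atlas(atlas))
  rows <- atlas$rows; cols <- atlas$cols
  px <- rep((seq_len(cols) - 0.5) / cols, each = rows)
  py <- rep((seq_len(rows) - 0.5) / rows, times = cols)
  pixel_diag <- sqrt((1 / rows)^2 + (1 / cols)^2)

  inside <- rep(FALSE, rows * cols)
  for (poly in d$polygons) {
    closed <- isTRUE(attr(poly, "closed")) || is.null(attr(poly, "closed"))
    if (!closed) {
      ends_meet <- sqrt(sum((poly[1, ] - poly[nrow(poly), ])^2)) <= pixel_diag
      if (!ends_meet) {
        inside <- inside |
          .buffer_polyline(px, py, poly, brush * pixel_diag / sqrt(2))
        next
      }
    }
    if (.polygon_area(poly) == 0) {
      warning("degenerate zero-area polygon in drawing '", d$sign,
              "'; contributes no pixels", call. = FALSE)
      next
    }
    inside <- inside | .points_in_polygon(px, py, poly)
  }

  grid <- matrix(as.integer(inside), rows, cols)
  grid <- grid * body_mask(atlas, d$view)
  zero <- matrix(0L, rows, cols)
  if (d$view == "front") body_map(grid, zero, list(sign = d$sign))
  else body_map(zero, grid, list(sign = d$sign))
}

#' Superimpose and binarize a set of body maps
#'
#' Pixel-wise logical OR of the maps: the result marks every body point where
#' at least one of the input findings was present. Sign multiplicity is
#' deliberately discarded -- only bodily location is kept. The operation is
#' idempotent, commutative and associative.
#'
#' @param maps List of `body_map`s on the same grid.
#' @param provenance Optional provenance list for the result.
#' @return A `body_map`.
#' @export
superimpose_binarize <- function(maps, provenance = list()) {
  stopifnot(length(maps) >= 1L, all(vapply(maps, is_body_map, logical(1))))
  d0 <- dim(maps[[1]]$front)
  ok <- vapply(maps, function(m) all(dim(m$front) == d0), logical(1))
  if (!all(ok)) stop("superimpose_binarize: maps are on different grids")
  f <- Reduce(`|`, lapply(maps, `[[`, "front"))
  b <- Reduce(`|`, lapply(maps, `[[`, "back"))
  body_map(f + 0L, b + 0L, provenance)
}

#' Superimposed, binarized map of one patient's drawings
#'
#' Rasterizes every drawing of the patient whose sign token is in `signs`
#' and superimposes them into one binary map; the empty map when no drawing
#' matches.
#'
#' @param patient A [patient_record()].
#' @param atlas A `segment_atlas`.
#' @param signs Character vector of sign tokens to include.
#' @return A `body_map`.
#' @export
patient_sign_map <- function(patient, atlas, signs) {
  sel <- Filter(function(d) d$sign %in% signs, patient$drawings)
  if (!length(sel)) return(empty_body_map(atlas, list(id = patient$id)))
  maps <- lapply(sel, rasterize_drawing, atlas = atlas)
  superimpose_binarize(maps, provenance = list(id = patient$id, signs = signs))
}
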