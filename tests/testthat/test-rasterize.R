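test_that("a rectangle over segment T5 rasterizes to exactly T5's pixels", {
  atlas <- test_atlas()
  poly <- segment_cover_poly(atlas, "T5", "front")
  d <- drawing_record("superficial_hyperalgesia", "front", poly)
  m <- rasterize_drawing(d, atlas)
  code <- match("T5", atlas$labels)
  expect_identical(m$front, (atlas$seg$front == code) + 0L)
  expect_equal(sum(m$back), 0)
  # agrees with the scalar point-in-polygon oracle (inside the body mask)
  bf <- bf_rasterize(poly, atlas$rows, atlas$cols) * body_mask(atlas, "front")
  expect_identical(m$front, bf)
})

test_that("rasterization agrees with the per-pixel oracle on random polygons", {
  atlas <- test_atlas(66, 20)
  set.seed(71)
  for (k in 1:8) {
    nv <- sample(3:6, 1)
    poly <- cbind(runif(nv), runif(nv))
    d <- drawing_record("muscle_resistance", "back", poly)
    m <- suppressWarnings(rasterize_drawing(d, atlas))
    bf <- bf_rasterize(poly, atlas$rows, atlas$cols) * body_mask(atlas, "back")
    expect_identical(m$back, bf)
    expect_equal(sum(m$front), 0)
  }
})

test_that("clipping: outside polygons are empty, the full square is the body", {
  atlas <- test_atlas()
  off <- drawing_record("zoster", "front", rect_poly(0.0, 0.04, 0.0, 0.04))
  m_off <- rasterize_drawing(off, atlas)
  expect_equal(sum(m_off$front) + sum(m_off$back), 0)
  full <- drawing_record("zoster", "front", rect_poly(0, 1, 0, 1))
  m_full <- rasterize_drawing(full, atlas)
  expect_identical(m_full$front, body_mask(atlas, "front"))
})

test_that("degenerate polygons yield an empty mask with a warning", {
  atlas <- test_atlas()
  degen <- matrix(c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3), ncol = 2, byrow = TRUE)
  expect_warning(m <- rasterize_drawing(
    drawing_record("defense", "front", degen), atlas), "degenerate")
  expect_equal(sum(m$front), 0)
})

test_that("open strokes are buffered; closed-loop strokes are filled", {
  atlas <- test_atlas()
  stroke <- rect_poly(0.25, 0.45, 0.3, 0.4)[1:3, ]
  attr(stroke, "closed") <- FALSE
  m <- rasterize_drawing(drawing_record("vasomotor_changes", "front", stroke),
                         atlas)
  expect_gt(sum(m$front), 0)
  # thin: far fewer pixels than the filled bounding rectangle
  filled <- rasterize_drawing(drawing_record("vasomotor_changes", "front",
                                             rect_poly(0.25, 0.45, 0.3, 0.4)),
                              atlas)
  expect_lt(sum(m$front), sum(filled$front))
  # a stroke whose ends meet within a pixel is treated as a closed polygon
  loop <- rbind(rect_poly(0.25, 0.45, 0.3, 0.4),
                c(0.25, 0.3 + 1e-4))
  attr(loop, "closed") <- FALSE
  m_loop <- rasterize_drawing(drawing_record("vasomotor_changes", "front",
                                             loop), atlas)
  expect_identical(m_loop$front, filled$front)
})

test_that("superimposition is an idempotent, commutative OR with identity", {
  atlas <- test_atlas(66, 20)
  set.seed(72)
  m <- random_body_mask(atlas)
  e <- body_map(matrix(0L, 66, 20), matrix(0L, 66, 20))
  expect_identical(superimpose_binarize(list(m, m))$front, m$front)
  expect_identical(superimpose_binarize(list(m, e))$front, m$front)
  for (k in 1:20) {
    tri <- list(random_body_mask(atlas), random_body_mask(atlas),
                random_body_mask(atlas))
    s123 <- superimpose_binarize(tri)
    s321 <- superimpose_binarize(rev(tri))
    expect_identical(s123$front, s321$front)
    expect_identical(s123$back, s321$back)
    # equivalent to the pixel-wise maximum
    expect_identical(s123$front,
                     pmax(tri[[1]]$front, tri[[2]]$front, tri[[3]]$front))
    # OR-monotonicity: adding a map never clears a pixel
    expect_true(all(s123$front >= tri[[1]]$front))
  }
  small <- body_map(matrix(0L, 10, 10), matrix(0L, 10, 10))
  expect_error(superimpose_binarize(list(m, small)), "different grids")
})

test_that("coverage fractions are stable under atlas refinement", {
  a1 <- test_atlas(132, 40)
  a2 <- test_atlas(264, 80)
  # convex trapezoid spanning the T3..T8 bands exactly; the slanted sides
  # exercise column quantization (a horizontal edge cutting mid-band is
  # limited by the band height, not the rasterizer -- see vignette)
  lay <- atlas_layout()
  y0 <- lay$y0[lay$segment == "T3"]
  y1 <- lay$y1[lay$segment == "T8"]
  poly <- matrix(c(0.27, y0, 0.61, y0, 0.55, y1, 0.30, y1),
                 ncol = 2, byrow = TRUE)
  cov <- function(atlas) {
    d <- drawing_record("muscle_resistance", "front", poly)
    tab <- segment_coverage(rasterize_drawing(d, atlas), atlas)
    tab <- tab[tab$side == "both", ]
    stats::setNames(tab$coverage, tab$segment)
  }
  c1 <- cov(a1); c2 <- cov(a2)
  expect_true(all(abs(c1 - c2) < 2))
})
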