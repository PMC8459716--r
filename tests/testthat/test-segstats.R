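test_that("coverage of the empty map is zero and of the body mask is 100%", {
  atlas <- test_atlas()
  empty <- body_map(matrix(0L, atlas$rows, atlas$cols),
                    matrix(0L, atlas$rows, atlas$cols))
  cov0 <- segment_coverage(empty, atlas)
  expect_true(all(cov0$coverage == 0))
  expect_false(any(cov0$passed_threshold))

  full <- body_map(body_mask(atlas, "front"), body_mask(atlas, "back"))
  cov1 <- segment_coverage(full, atlas)
  both <- cov1[cov1$side == "both", ]
  expect_true(all(both$coverage == 100))
  expect_true(all(both$passed_threshold))
})

test_that("the 5% rule is exact at the 10-of-200-pixel boundary", {
  atlas <- test_atlas(165, 34)   # T5 has exactly 200 pixels pooled
  counts <- segment_pixel_counts(atlas)
  expect_equal(sum(counts$pixels[counts$segment == "T5"]), 200)
  code <- match("T5", atlas$labels)
  idx <- which(atlas$seg$front == code)
  mk <- function(k) {
    f <- matrix(0L, atlas$rows, atlas$cols)
    f[idx[seq_len(k)]] <- 1L
    body_map(f, matrix(0L, atlas$rows, atlas$cols))
  }
  cov10 <- segment_coverage(mk(10), atlas)
  t5 <- cov10[cov10$segment == "T5" & cov10$side == "both", ]
  expect_equal(t5$coverage, 5)
  expect_true(t5$passed_threshold)
  cov9 <- segment_coverage(mk(9), atlas)
  expect_false(cov9$passed_threshold[cov9$segment == "T5" &
                                     cov9$side == "both"])
})

test_that("the half-segment variant of the inclusion rule is available", {
  atlas <- test_atlas(165, 34)   # T5: 200 pixels pooled, 100 per half
  code <- match("T5", atlas$labels)
  idx <- which(atlas$seg$front == code & atlas$side$front == 1L)
  f <- matrix(0L, atlas$rows, atlas$cols)
  f[idx[1:6]] <- 1L   # 3% of the segment but 6% of its left half
  m <- body_map(f, matrix(0L, atlas$rows, atlas$cols))
  counts <- segment_pixel_counts(atlas)
  expect_equal(sum(counts$pixels[counts$segment == "T5" &
                                 counts$side == "left"]), 100)
  expect_false("T5" %in% passing_segments(m, atlas, 0.05))
  expect_true("T5" %in% passing_segments(m, atlas, 0.05, half_rule = TRUE))
  # the half rule is never stricter than the full-segment rule
  set.seed(12)
  r <- random_body_mask(atlas, 0.06)
  expect_true(all(passing_segments(r, atlas, 0.05) %in%
                  passing_segments(r, atlas, 0.05, half_rule = TRUE)))
})

test_that("coverage equals brute-force pixel counting on random masks", {
  atlas <- test_atlas(66, 20)
  set.seed(4711)
  for (k in 1:10) {
    m <- random_body_mask(atlas, p = runif(1, 0.05, 0.6))
    cov <- segment_coverage(m, atlas)
    both <- cov[cov$side == "both", ]
    bf <- bf_segment_counts(m, atlas)
    expect_equal(both$pixels_set, unname(bf$set[both$segment]))
    expect_equal(both$pixels_total, unname(bf$tot[both$segment]))
    expect_equal(both$coverage, unname(100 * bf$set / bf$tot)[
      match(both$segment, names(bf$set))])
  }
})

test_that("half-segment rows appear only for passing segments and sum up", {
  atlas <- test_atlas()
  set.seed(8)
  m <- random_body_mask(atlas, 0.3)
  cov <- segment_coverage(m, atlas)
  passed <- cov$segment[cov$side == "both" & cov$passed_threshold]
  expect_setequal(unique(cov$segment[cov$side != "both"]), passed)
  for (s in passed) {
    rows <- cov[cov$segment == s, ]
    expect_equal(rows$pixels_set[rows$side == "both"],
                 sum(rows$pixels_set[rows$side != "both"]))
    expect_equal(rows$pixels_total[rows$side == "both"],
                 sum(rows$pixels_total[rows$side != "both"]))
  }
})

test_that("raising the threshold never adds segments to the included set", {
  atlas <- test_atlas()
  set.seed(9)
  m <- random_body_mask(atlas, 0.08)
  prev <- NULL
  for (th in c(0.01, 0.05, 0.1, 0.25, 0.8)) {
    cur <- passing_segments(m, atlas, th)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_error(segment_coverage(m, atlas, threshold = 1.2), "threshold")
  expect_error(segment_coverage(m, atlas, threshold = -0.1), "threshold")
})

test_that("mean maps average per-patient binarized maps", {
  atlas <- test_atlas()
  p1 <- simple_patient("m1", "heart",
                       list(trunk_drawing(x0 = 0.25, x1 = 0.35)))
  p2 <- simple_patient("m2", "heart",
                       list(trunk_drawing(x0 = 0.55, x1 = 0.65)))
  one <- mean_map(cohort(list(p1)), "heart", "all_signs", atlas)
  m1 <- patient_sign_map(p1, atlas, "superficial_hyperalgesia")
  expect_equal(one$front, m1$front + 0)
  expect_equal(one$n, 1)

  two <- mean_map(cohort(list(p1, p2)), "heart", "all_signs", atlas)
  m2 <- patient_sign_map(p2, atlas, "superficial_hyperalgesia")
  expect_equal(sum(m1$front * m2$front), 0)  # disjoint by construction
  union <- (m1$front + m2$front) > 0
  expect_true(all(two$front[union] == 0.5))
  expect_true(all(two$front[!union] == 0))

  expect_error(mean_map(cohort(list(p1)), "lungs", "all_signs", atlas),
               "no patients")
})

test_that("mean maps match accumulate-and-divide on a simulated cohort", {
  atlas <- test_atlas(66, 20)
  spec <- default_spec()
  spec$mix <- c(heart = 1, lungs = 0, stomach = 0, liver_gallbladder = 0,
                kidneys_ureters = 0)
  g <- generate_cohort(spec, n = 10, seed = 21)
  mm <- mean_map(g$cohort, "heart", "all_signs", atlas)
  signs <- setdiff(distributed_signs(), "spontaneous_pain")
  acc <- matrix(0, atlas$rows, atlas$cols)
  for (p in g$cohort$patients)
    acc <- acc + patient_sign_map(p, atlas, signs)$front
  expect_equal(mm$front, acc / 10)
  # conservation: n * mean has integer values in [0, n]
  v <- mm$front * mm$n
  expect_true(all(abs(v - round(v)) < 1e-9))
  expect_true(all(v >= 0 & v <= mm$n))
})

test_that("mean signs per half segment count thresholded sign touches", {
  atlas <- test_atlas()
  poly <- segment_cover_poly(atlas, "T5", "front")
  back <- segment_cover_poly(atlas, "T5", "back")
  p <- simple_patient("h1", "heart", list(
    drawing_record("superficial_hyperalgesia", "front", poly),
    drawing_record("superficial_hyperalgesia", "back", back)))
  tab <- mean_signs_per_half_segment(cohort(list(p)), "heart", atlas)
  expect_equal(tab$mean_signs[tab$segment == "T5"], c(1, 1))
  expect_true(all(tab$mean_signs[tab$segment != "T5"] == 0))

  none <- simple_patient("h2", "heart")
  tab0 <- mean_signs_per_half_segment(cohort(list(none)), "heart", atlas)
  expect_true(all(tab0$mean_signs == 0))
})

test_that("mean signs per half segment match an explicit recount", {
  atlas <- test_atlas(66, 20)
  spec <- default_spec()
  spec$mix <- c(heart = 0, lungs = 0, stomach = 1, liver_gallbladder = 0,
                kidneys_ureters = 0)
  g <- generate_cohort(spec, n = 8, seed = 33)
  tab <- mean_signs_per_half_segment(g$cohort, "stomach", atlas)
  # oracle: explicit loop over patients x signs
  acc <- matrix(0, 33, 2, dimnames = list(segment_labels(),
                                          c("left", "right")))
  for (p in g$cohort$patients) {
    for (s in unique(vapply(p$drawings, `[[`, "", "sign"))) {
      if (s == "spontaneous_pain") next
      m <- patient_sign_map(p, atlas, s)
      cov <- segment_coverage(m, atlas, 0.05)
      for (seg in cov$segment[cov$side == "both" & cov$passed_threshold])
        for (sd in c("left", "right")) {
          r <- cov[cov$segment == seg & cov$side == sd, ]
          if (nrow(r) && r$pixels_set > 0) acc[seg, sd] <- acc[seg, sd] + 1
        }
    }
  }
  acc <- acc / length(g$cohort$patients)
  expect_equal(tab$mean_signs, unname(c(acc[, "left"], acc[, "right"])))
})

test_that("lateralization summaries reproduce the side-rule arithmetic", {
  heart <- mydriasis_cohort("heart", c(15, 3), c("left", "right"))
  lat <- lateralization_summary(heart, "heart")
  myd <- lat[lat$finding == "mydriasis", ]
  expect_equal(myd$n_left, 15)
  expect_equal(myd$n_right, 3)
  expect_equal(myd$ipsilateral_side, "left")
  expect_equal(myd$percent_ipsilateral, 83)

  liver <- mydriasis_cohort("liver_gallbladder", 5, "right")
  lat2 <- lateralization_summary(liver, "liver_gallbladder")
  myd2 <- lat2[lat2$finding == "mydriasis", ]
  expect_equal(myd2$percent_ipsilateral, 100)
  # findings never observed have an NA percentage, not 0
  expect_true(is.na(lat2$percent_ipsilateral[lat2$finding == "glossy_eye"]))
  # paired organs carry no ipsilateral side
  lungs <- mydriasis_cohort("lungs", c(4, 4), c("left", "right"))
  lat3 <- lateralization_summary(lungs, "lungs")
  expect_true(all(is.na(lat3$percent_ipsilateral)))
  expect_error(lateralization_summary(heart, "other"), "analyzable")
})

test_that("lateralized counts are conserved against the raw records", {
  g <- generate_cohort(default_spec(), n = 80, seed = 17)
  for (org in c("heart", "liver_gallbladder")) {
    lat <- lateralization_summary(g$cohort, org)
    for (f in lateralized_findings()) {
      n_raw <- sum(vapply(g$cohort$patients, function(p)
        p$organ == org && any(vapply(p$lateralized, function(lf)
          lf$finding == f, logical(1))), logical(1)))
      row <- lat[lat$finding == f, ]
      expect_equal(row$n_left + row$n_right, n_raw)
    }
  }
})

test_that("frequency tables use cohort percentages with half-up rounding", {
  x <- printed_counts_cohort()
  tab <- frequency_table(x)
  val <- function(f) tab$percent[tab$finding == f]
  expect_equal(val("superficial_hyperalgesia"), 41.8)
  expect_equal(val("muscle_resistance"), 35.5)
  expect_equal(val("mydriasis"), 33.6)
  expect_equal(val("at_least_1_segmental_sign"), 73.6)
  expect_equal(val("at_least_1_segmental_symptom"), 47.3)
  expect_equal(val("spontaneous_pain"), 77.3)
  expect_equal(tab$n[tab$finding == "zoster"], 0)
  expect_equal(val("zoster"), 0)
  # percentages recompute from counts, ties rounded half away from zero
  expect_equal(tab$percent, segmapr:::round_away(100 * tab$n / 110, 1))
  tie <- cohort(lapply(1:16, function(i)
    patient_record(paste0("t", i), "heart",
                   symptoms = if (i <= 5) "nausea" else character())))
  ttab <- frequency_table(tie)
  expect_equal(ttab$percent[ttab$finding == "nausea"], 31.3)  # 31.25 up
})
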