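test_that("curve construction normalizes to the first frame", {
  cu <- build_curve(c(1000, 800, 600), frame_interval_h = 0.25)
  expect_equal(cu$normalized_area, c(1, 0.8, 0.6))
  expect_equal(cu$time_h, c(0, 0.25, 0.5))
  expect_true(all(build_curve(rep(500, 5))$normalized_area == 1))
  expect_error(build_curve(c(0, 10, 20)), "zero")
})

test_that("area_at does nearest-sample lookup on the 15-min grid", {
  geom <- acquisition_geometry(duration = 6)
  y <- simulate_kinetics(kinetics_model(0.4, 1), geom)$normalized_area
  cu <- build_curve(y * 2000, frame_interval_h = 0.25)
  expect_identical(area_at(cu, 0), 1)
  expect_equal(area_at(cu, 2), 0.4 + 0.6 * exp(-2), tolerance = 1e-12)
  expect_identical(area_at(cu, 6), y[length(y)] / y[1])
  expect_warning(area_at(cu, 2.1), "off the sampling grid")
  expect_error(area_at(cu, 7), "outside")
})

test_that("trapezoidal AUC matches rectangles and the closed form", {
  const24 <- build_curve(rep(1, 97), frame_interval_h = 0.25)
  expect_identical(compute_auc(const24, 24), 24)
  const6 <- build_curve(rep(1, 25), frame_interval_h = 0.25)
  expect_identical(compute_auc(const6, 6), 6)
  m <- kinetics_model(0.4, 1)
  geom <- acquisition_geometry(duration = 24)
  cu <- build_curve(simulate_kinetics(m, geom)$normalized_area * 1e4,
                    frame_interval_h = 0.25)
  expect_equal(compute_auc(cu, 24), kinetics_auc(m, 24), tolerance = 5e-3)
  expect_error(compute_auc(const6, 12), "exceeds")
})

test_that("AUC bounds and monotonicity hold for random admissible curves", {
  set.seed(31)
  for (i in 1:20) {
    y <- c(1, sort(runif(24, 0.2, 1), decreasing = TRUE))
    cu <- build_curve(y * 1000, frame_interval_h = 0.25)
    auc <- compute_auc(cu, 6)
    expect_gt(auc, 0); expect_lte(auc, 6)
    # pointwise-lower curve has lower AUC and area-2h
    y2 <- y * c(1, rep(0.9, 24))
    cu2 <- build_curve(y2 * 1000, frame_interval_h = 0.25)
    expect_lt(compute_auc(cu2, 6), auc)
    expect_lte(area_at(cu2, 2), area_at(cu, 2))
  }
})

test_that("end-of-movie circularity averages retained aggregates", {
  fake <- list(objects = data.frame(circularity = c(0.6, 0.8)))
  expect_equal(end_circularity(fake), 0.7)
  none <- list(objects = data.frame(circularity = numeric()))
  expect_warning(v <- end_circularity(none), "undefined")
  expect_true(is.na(v))
})

test_that("condition summaries aggregate replicates correctly", {
  geom <- acquisition_geometry(duration = 24)
  y <- simulate_kinetics(kinetics_model(0.5, 1), geom)$normalized_area
  cu <- build_curve(y * 1000, 0.25, well_id = "w1")
  s1 <- summarize_condition(list(cu), window_h = 24, label = "solo")
  expect_identical(s1$n_replicates, 1L)
  expect_identical(unname(s1$auc["sd"]), 0)   # single-replicate convention
  expect_equal(unname(s1$auc["mean"]), compute_auc(cu, 24))

  cu2 <- build_curve(rep(1000, 97), 0.25, well_id = "w2")  # constant curve
  s2 <- summarize_condition(list(cu, cu2), window_h = 24)
  expect_equal(unname(s2$auc["mean"]), mean(c(compute_auc(cu, 24), 24)))
  expect_equal(unname(s2$auc["sd"]), sd(c(compute_auc(cu, 24), 24)))

  bad <- build_curve(rep(1000, 10), 0.5)
  expect_error(summarize_condition(list(cu, bad), window_h = 4), "mixed")

  # 30 synthetic replicates of one model: mean AUC within 2% of closed form
  reps <- simulate_condition(kinetics_model(0.45, 1.2),
                             acquisition_geometry(duration = 24),
                             n_replicates = 30, seed = 8)
  s3 <- summarize_condition(reps, window_h = 24)
  expect_equal(unname(s3$auc["mean"]), kinetics_auc(kinetics_model(0.45, 1.2), 24),
               tolerance = 0.02)
})

test_that("Mann-Whitney comparison agrees with exhaustive enumeration", {
  mk <- function(v, lab) {
    curves <- lapply(seq_along(v), function(i)
      build_curve(rep(1000, 25) * c(1, rep(v[i], 24)), 0.25,
                  well_id = sprintf("%s%d", lab, i)))
    summarize_condition(curves, window_h = 6, label = lab)
  }
  # {1,2,3} vs {10,11,12} scaled into (0,1]: U extreme, p = 0.1 by enumeration
  a <- mk(c(0.1, 0.2, 0.3), "a"); b <- mk(c(0.7, 0.8, 0.9), "b")
  res <- compare_conditions(a, b, "auc")
  expect_true(res$u %in% c(0, 9))
  expect_equal(res$p_value, 0.1, tolerance = 1e-9)
  expect_equal(res$p_value, mw_exact_oracle(a$replicates$auc, b$replicates$auc),
               tolerance = 1e-9)
  # random small groups: exact agreement with the enumeration oracle
  set.seed(33)
  for (i in 1:5) {
    va <- runif(sample(3:8, 1), 0.2, 1)
    vb <- runif(sample(3:8, 1), 0.2, 1)
    res <- compare_conditions(mk(va, "a"), mk(vb, "b"), "auc")
    expect_equal(res$p_value, mw_exact_oracle(mk(va, "a")$replicates$auc,
                                              mk(vb, "b")$replicates$auc),
                 tolerance = 1e-9)
  }
  # identical replicate sets: no effect
  expect_gte(suppressWarnings(compare_conditions(a, a, "auc"))$p_value, 0.99)
  expect_error(compare_conditions(a, b, "banana"))
})
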