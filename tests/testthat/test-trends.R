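test_that("mean MI_norm over a mask reduces to the expected cell averages", {
  m <- fake_map(0.2, 0.1, mi_norm = 1:9)
  mask1 <- rep(FALSE, 9); mask1[3] <- TRUE
  expect_equal(mean_minorm_in_mask(m, mask1), 3)
  mask2 <- rep(FALSE, 9); mask2[c(1, 3)] <- TRUE
  expect_equal(mean_minorm_in_mask(m, mask2), 2)
  expect_equal(mean_minorm_in_mask(m, rep(TRUE, 9)), mean(1:9))
  # data-frame mask keyed by (channel, lf, hf)
  df <- m$cells[3, c("channel", "lf_hz", "hf_hz")]
  expect_equal(mean_minorm_in_mask(m, df), 3)
  expect_error(mean_minorm_in_mask(m, rep(FALSE, 9)), "empty mask")
})

test_that("the age correlation behaves like Pearson's r", {
  ages <- c(3, 6, 9, 12, 18, 24, 36)
  out <- pearson_age_correlation(2 + 0.1 * ages, ages)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_lt(out$p, 1e-6)
  expect_error(pearson_age_correlation(rep(1, 7), ages), "constant")
  expect_error(pearson_age_correlation(1:2, c(3, 6)), "at least 3")
})

test_that("phase-max proportions normalize within the masked region", {
  m <- fake_map(0.2, 0.1, phase_max = c(90, 90, 90, -110, -110, 70, 70, 70, 70),
                channel = "Cz")
  pr <- phase_max_proportions(m, rep(TRUE, 9))
  expect_equal(sum(pr), 1)
  expect_equal(unname(pr[as.character(90)]), 3 / 9)
  expect_equal(unname(pr[as.character(-110)]), 2 / 9)
  # all masked cells share one bin
  one <- phase_max_proportions(m, c(TRUE, TRUE, TRUE, rep(FALSE, 6)))
  expect_equal(unname(one[as.character(90)]), 1)
  expect_error(phase_max_proportions(m, rep(TRUE, 9), region = "O1"),
               "in region")
})

test_that("per-bin age trends use Bonferroni over 18 tests", {
  set.seed(55)
  ages <- rep(c(3, 6, 9, 12, 18, 24, 36), 4)
  props <- matrix(1 / 18, length(ages), 18)
  props[, 10] <- 0.02 + 0.002 * ages          # strong increasing trend
  props[, 2] <- 0.2 - 0.002 * ages            # strong decreasing trend
  props <- props + matrix(runif(length(ages) * 18, 0, 1e-4), length(ages))
  tr <- phase_trend(props, ages)
  expect_s3_class(tr, "phase_trend")
  expect_identical(nrow(tr), 18L)
  expect_true(tr$significant[10] && tr$r[10] > 0)
  expect_true(tr$significant[2] && tr$r[2] < 0)
  expect_true(all(tr$p[tr$significant] < 0.05 / 18))

  # constant bins are untestable, not significant
  props[, 5] <- 0.3
  tr2 <- phase_trend(props, ages)
  expect_false(tr2$testable[5])
  expect_false(tr2$significant[5])
})

test_that("the circular mean handles wrap-around and degenerate inputs", {
  expect_equal(as.numeric(circular_mean_phase(c(10, 30))), 20,
               tolerance = 1e-10)
  expect_equal(abs(as.numeric(circular_mean_phase(c(170, -170)))), 180,
               tolerance = 1e-10)
  expect_error(circular_mean_phase(c(90, -90)), "antipodal")
  expect_error(circular_mean_phase(numeric(0)), "at least one")
  # rotation equivariance (mod 360)
  set.seed(8)
  x <- runif(25, -180, 180) * 0.3          # concentrated sample
  for (shift in c(30, 100, 250)) {
    a <- as.numeric(circular_mean_phase(x)) + shift
    b <- as.numeric(circular_mean_phase(x + shift))
    expect_lt(ang_diff(a, b), 1e-8)
  }
  # matches the independent oracle
  expect_equal(as.numeric(circular_mean_phase(x)), circ_mean_oracle(x),
               tolerance = 1e-10)
})

test_that("group trends recover the structure of a synthetic cohort", {
  spec <- build_filterbank(250, lf_centers = 8, hf_centers = 64)
  coh <- simulate_cohort(8, channel_labels = c("Fz", "Pz"), duration_s = 60,
                         base_depth = 0.2, depth_slope_per_month = 0.6 / 33,
                         seed = 61)
  maps <- lapply(coh, function(r)
    pac_map(segment_recording(r), spec, seed = 67))
  cl <- pac_cluster(maps, seed = 71)
  tr <- pac_trends(cl)
  expect_gt(tr$mi_age$r, 0)
  expect_lt(tr$mi_age$p, 0.05)
  expect_lte(ang_diff(as.numeric(tr$circular_means$anterior), -110), 20)
  expect_lte(ang_diff(as.numeric(tr$circular_means$posterior), 70), 20)
  expect_true(all(abs(rowSums(tr$proportions$overall) - 1) < 1e-12))
})
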