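test_that("phase binning reproduces analytic bin means", {
  # constant amplitude: every bin equals the constant
  ph <- seq(-179.5, 179.5, by = 1)
  d <- bin_amplitude_by_phase(ph, rep(3, length(ph)))
  expect_equal(unname(d$mean_amp), rep(3, 18))

  # amp = 1 + cos(phase - 90) with uniform phase: bin mean equals the
  # average of the modulator over the bin (analytic integration oracle)
  ph <- seq(-180, 179.9, by = 0.1)
  amp <- 1 + cos((ph - 90) * pi / 180)
  d <- bin_amplitude_by_phase(ph, amp)
  edges <- pac_bin_edges() * pi / 180
  analytic <- vapply(seq_len(18), function(b) {
    integrate(function(x) 1 + cos(x - pi / 2), edges[b], edges[b + 1])$value /
      (edges[b + 1] - edges[b])
  }, numeric(1))
  expect_equal(unname(d$mean_amp), analytic, tolerance = 1e-3)
  expect_identical(d$bin_centers[which.max(d$mean_amp)], 90)

  # degenerate input: all phase in one bin leaves 17 bins missing
  d1 <- bin_amplitude_by_phase(rep(5, 10), rnorm(10)^2)
  expect_identical(sum(is.na(d1$mean_amp)), 17L)
  expect_error(bin_amplitude_by_phase(numeric(0), numeric(0)), "empty")
})

test_that("averaging distributions is a per-bin mean over non-missing segments", {
  ph <- seq(-179.5, 179.5, by = 1)
  d1 <- bin_amplitude_by_phase(ph, rep(1, 360))
  d3 <- bin_amplitude_by_phase(ph, rep(3, 360))
  avg <- average_distributions(list(d1, d3))
  expect_equal(unname(avg$mean_amp), rep(2, 18))
  expect_identical(average_distributions(list(d1))$mean_amp, d1$mean_amp)

  # a bin missing in one segment falls back to the other segment's value
  part <- bin_amplitude_by_phase(rep(5, 10), rep(9, 10))
  mix <- average_distributions(list(d1, part))
  expect_equal(unname(mix$mean_amp[1]), 1)       # only d1 contributes
  expect_equal(unname(mix$mean_amp[10]), 5)      # bin [0,20): mean of 1 and 9

  only_part <- bin_amplitude_by_phase(rep(5, 10), rep(9, 10))
  expect_error(average_distributions(list(only_part, part)), "every segment")
})

test_that("averaging over 30 segments shrinks the bin SD about sqrt(30)-fold", {
  ph <- seq(-179.5, 179.5, by = 1)
  one_seg <- function() bin_amplitude_by_phase(ph, rexp(360))$mean_amp[1]
  avg_30 <- function() {
    d <- lapply(1:30, function(i) bin_amplitude_by_phase(ph, rexp(360)))
    average_distributions(d)$mean_amp[1]
  }
  set.seed(31)
  s1 <- sd(replicate(300, one_seg()))
  s30 <- sd(replicate(300, avg_30()))
  expect_gt(s1 / s30, sqrt(30) * 0.7)
  expect_lt(s1 / s30, sqrt(30) * 1.4)
})

test_that("the modulation index matches its entropy definition", {
  ph <- seq(-179.5, 179.5, by = 1)
  uni <- bin_amplitude_by_phase(ph, rep(1, 360))
  expect_equal(modulation_index(uni), 0, tolerance = 1e-15)

  # hand-checkable distribution: one bin 2/19, seventeen bins 1/19
  d <- uni
  d$mean_amp <- c(2, rep(1, 17))
  p <- d$mean_amp / sum(d$mean_amp)
  expected <- (log(18) + sum(p * log(p))) / log(18)  # (log N - H)/log N
  expect_equal(modulation_index(d), expected, tolerance = 1e-12)
  expect_lt(abs(modulation_index(d) - 6.5e-3), 1e-4)

  # all mass in one bin -> 1 (use a tiny-positive floor of 0 elsewhere)
  d$mean_amp <- c(7, rep(0, 17))
  expect_equal(modulation_index(d), 1, tolerance = 1e-15)

  # scale invariance
  d$mean_amp <- rexp(18) + 0.1
  mi1 <- modulation_index(d)
  d2 <- d; d2$mean_amp <- d$mean_amp * 37.5
  expect_equal(modulation_index(d2), mi1, tolerance = 1e-12)

  # strictly increasing as mass concentrates (uniform -> point mass family)
  lam <- seq(0, 1, by = 0.1)
  mis <- vapply(lam, function(l) {
    dd <- uni
    dd$mean_amp <- (1 - l) * rep(1 / 18, 18) + l * c(1, rep(0, 17))
    modulation_index(dd)
  }, numeric(1))
  expect_true(all(diff(mis) > 0))

  bad <- uni; bad$mean_amp <- rep(0, 18)
  expect_error(modulation_index(bad), "zero total amplitude")
  part <- bin_amplitude_by_phase(rep(5, 4), rep(1, 4))
  expect_error(modulation_index(part), "present")
})

test_that("phase max picks the right bin center and flags ties", {
  ph <- seq(-179.5, 179.5, by = 1)
  amp <- 1 + cos((ph - 90) * pi / 180)
  pm <- phase_max(bin_amplitude_by_phase(ph, amp))
  expect_identical(as.numeric(pm), 90)
  expect_false(attr(pm, "tie"))

  uni <- bin_amplitude_by_phase(ph, rep(1, 360))
  pm_u <- phase_max(uni)
  expect_identical(as.numeric(pm_u), -170)
  expect_true(attr(pm_u, "tie"))

  # end-to-end: simulated -90 preference recovers -90
  rec <- simulate_coupled_signal(8, 64, -90, 0.8, duration_s = 10,
                                 noise_scale = 0)
  pa <- extract_phase_amp(segment_recording(rec), 1, 8, 64, single_pair_spec())
  d <- average_distributions(lapply(seq_len(ncol(pa$amp)), function(s)
    bin_amplitude_by_phase(pa$phase_deg[, s], pa$amp[, s])))
  expect_identical(as.numeric(phase_max(d)), -90)
})

test_that("surrogates destroy coupling but keep the procedure's scale", {
  rec <- simulate_coupled_signal(8, 64, 90, 1, duration_s = 30,
                                 noise_scale = 0)
  pa <- extract_phase_amp(segment_recording(rec), 1, 8, 64, single_pair_spec())
  d <- average_distributions(lapply(seq_len(ncol(pa$amp)), function(s)
    bin_amplitude_by_phase(pa$phase_deg[, s], pa$amp[, s])))
  mi_raw <- modulation_index(d)
  surr <- surrogate_mi(pa$phase_deg, pa$amp, 250, seed = 17)
  expect_length(surr, 200)
  expect_lt(max(surr), mi_raw)
  expect_identical(surr, surrogate_mi(pa$phase_deg, pa$amp, 250, seed = 17))
  expect_error(surrogate_mi(pa$phase_deg, pa$amp, 250,
                            shift_range_s = c(0, 3)),
               "shift_range_s")
})

test_that("MI normalization is an exact z-score with sample SD", {
  surr <- c(rep(0.1, 100), rep(0.3, 100))
  nz <- normalize_mi(0.4, surr)
  expect_equal(nz$surr_mean, 0.2)
  expect_equal(nz$surr_sd, sd(surr))
  expect_equal(nz$mi_norm, (0.4 - 0.2) / sd(surr))
  expect_equal(normalize_mi(mean(surr), surr)$mi_norm, 0)
  # translation invariance
  nz2 <- normalize_mi(0.4 + 5, surr + 5)
  expect_equal(nz2$mi_norm, nz$mi_norm, tolerance = 1e-12)
  expect_error(normalize_mi(0.4, rep(0.2, 10)), "zero surrogate SD")
  expect_error(normalize_mi(0.4, 0.2), "at least 2")
})

test_that("pac_map detects injected coupling and covers only valid pairs", {
  rec <- simulate_coupled_signal(8, 64, 90, 0.8, duration_s = 60, seed = 23)
  seg <- segment_recording(rec)
  pm <- pac_map(seg, single_pair_spec(), seed = 29)
  expect_identical(nrow(pm$cells), 1L)
  expect_gt(pm$cells$mi_norm, 1.96)
  expect_identical(pm$cells$phase_max_deg, 90)
  expect_equal(pm$cells$mi_norm,
               (pm$cells$mi_raw - pm$cells$surr_mean) / pm$cells$surr_sd)

  # reproducibility of the full map for a fixed seed
  pm2 <- pac_map(seg, single_pair_spec(), seed = 29)
  expect_identical(pm$cells, pm2$cells)

  # invalid pairs get no cell
  spec2 <- build_filterbank(250, lf_centers = c(8, 20),
                            hf_centers = c(40, 64))
  pm3 <- pac_map(seg, spec2, n_surr = 20, seed = 1)
  expect_identical(nrow(pm3$cells), sum(spec2$valid_pair_mask))
  keys <- paste(pm3$cells$lf_hz, pm3$cells$hf_hz)
  expect_false(any(keys == "20 40"))
})
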