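test_that("the default bank matches the standard comodulogram grid", {
  spec <- build_filterbank(250)
  expect_identical(spec$lf_centers, seq(2, 20, by = 2))
  expect_identical(spec$hf_centers, seq(40, 100, by = 4))
  expect_identical(dim(spec$valid_pair_mask), c(10L, 16L))
  expect_error(build_filterbank(150), "Nyquist")
  single <- build_filterbank(250, lf_centers = 8, hf_centers = 64)
  expect_true(valid_pair(8, 64, single))
})

test_that("an in-band tone passes with flat envelope and exact phase slope", {
  fs <- 250
  t <- (0:1499) / fs
  z <- complex_bandpass(cos(2 * pi * 8 * t), 8, 2, fs)
  mid <- 300:1200
  env <- Mod(z)[mid]
  expect_lt(max(abs(env - mean(env))) / mean(env), 0.05)
  ph <- Arg(z)[mid]
  slope <- mean(diff(ph) %% (2 * pi)) * fs / (2 * pi)   # cycles per second
  expect_lt(abs(slope - 8) / 8, 0.01)
})

test_that("the filter is zero-phase: output phase matches input phase", {
  fs <- 250
  t <- (0:999) / fs
  x <- cos(2 * pi * 8 * t)
  z <- complex_bandpass(x, 8, 2, fs)
  true_deg <- ((8 * 360 * t + 180) %% 360) - 180
  out_deg <- Arg(z) * 180 / pi
  err <- abs(((out_deg - true_deg + 180) %% 360) - 180)
  expect_lt(max(err[200:800]), 1)
})

test_that("out-of-band tones are strongly attenuated", {
  fs <- 250
  t <- (0:999) / fs
  x <- cos(2 * pi * 30 * t)
  z <- complex_bandpass(x, 8, 2, fs)
  expect_lt(sqrt(mean(Mod(z)^2)) / sqrt(mean(x^2)), 0.05)
})

test_that("filtering is linear", {
  set.seed(21)
  a <- rnorm(600)
  b <- rnorm(600)
  za <- complex_bandpass(a, 8, 2, 250)
  zb <- complex_bandpass(b, 8, 2, 250)
  zab <- complex_bandpass(a + 2 * b, 8, 2, 250)
  expect_equal(zab, za + 2 * zb, tolerance = 1e-10)
})

test_that("pair validity follows the computed filter supports", {
  spec <- build_filterbank(250)
  expect_true(valid_pair(2, 64, spec))
  # independent route: measure each filter's magnitude response from its
  # impulse response through the public filtering function
  fgrid <- seq(0, 125, by = 0.05)
  support_of <- function(center, bw) {
    imp <- c(rep(0, 500), 1, rep(0, 500))
    h <- complex_bandpass(imp, center, bw, 250)
    # response at f: |sum_k h[k] e^{-i 2 pi f k}|; use real branch + quadrature
    k <- seq_along(imp) - 501
    resp <- vapply(fgrid, function(f)
      Mod(sum(h * exp(-2i * pi * f * k / 250))), numeric(1))
    range(fgrid[resp >= 0.05 * max(resp)])
  }
  s20 <- support_of(20, 2)
  s40 <- support_of(40, 20)
  expect_identical(unname(valid_pair(20, 40, spec)), s20[2] < s40[1])
  # identical centers and bandwidths always overlap
  same <- build_filterbank(250, lf_centers = 50, lf_bandwidth = 20,
                           hf_centers = 50, hf_bandwidth = 20)
  expect_false(valid_pair(50, 50, same))
  expect_error(valid_pair(3, 64, spec), "not in the filter bank")
})

test_that("lowering the support threshold never validates an invalid pair", {
  masks <- lapply(c(0.05, 0.02, 0.01), function(thr)
    build_filterbank(250, support_threshold = thr)$valid_pair_mask)
  expect_true(all(masks[[2]][!masks[[1]]] == FALSE))
  expect_true(all(masks[[3]][!masks[[2]]] == FALSE))
})

test_that("extract_phase_amp returns aligned, calibrated series", {
  spec <- single_pair_spec()
  # no modulation: amplitude nearly constant
  rec0 <- simulate_coupled_signal(8, 64, 0, 0, duration_s = 8, noise_scale = 0)
  pa0 <- extract_phase_amp(segment_recording(rec0), 1, 8, 64, spec)
  expect_identical(dim(pa0$phase_deg), dim(pa0$amp))
  expect_true(all(pa0$phase_deg >= -180 & pa0$phase_deg < 180))
  expect_lt(sd(pa0$amp) / mean(pa0$amp), 0.10)

  # full modulation at 90 degrees: top-decile amplitudes cluster at 90
  rec1 <- simulate_coupled_signal(8, 64, 90, 1, duration_s = 8,
                                  noise_scale = 0)
  pa1 <- extract_phase_amp(segment_recording(rec1), 1, 8, 64, spec)
  top <- pa1$phase_deg[pa1$amp >= quantile(pa1$amp, 0.9)]
  expect_lte(ang_diff(circ_mean_oracle(top), 90), 20)

  # phase of an LF sinusoid over whole cycles is uniform across bins
  counts <- table(cut(pa0$phase_deg, breaks = seq(-180, 180, by = 20)))
  expect_lt(max(counts) / min(counts), 1.3)

  expect_error(extract_phase_amp(segment_recording(rec0), 1, 20, 40,
                                 build_filterbank(250)),
               "excluded")
  expect_error(extract_phase_amp(segment_recording(rec0), "Oz", 8, 64, spec),
               "unknown channel")
})

test_that("short segments and Nyquist-violating bands are rejected", {
  expect_error(complex_bandpass(rnorm(100), 8, 2, 250), "too short")
  expect_error(complex_bandpass(rnorm(1000), 120, 20, 250), "Nyquist")
})
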