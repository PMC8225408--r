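# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Welch power spectral density: mean periodogram over `k` non-overlapping
# Hann-windowed blocks. Returns freq (Hz) and power.
welch_psd <- function(x, fs, k = 8) {
  n <- length(x)
  blk <- n %/% k
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(blk - 1)) / (blk - 1))
  acc <- 0
  for (i in seq_len(k)) {
    seg <- x[((i - 1) * blk + 1):(i * blk)] * w
    acc <- acc + Mod(fft(seg))^2
  }
  half <- blk %/% 2
  list(freq = (1:half) * fs / blk, power = (acc / k)[2:(half + 1)])
}

# Least-squares log-log slope of PSD over [f_lo, f_hi].
psd_slope <- function(x, fs, f_lo = 1, f_hi = 100) {
  p <- welch_psd(x, fs)
  keep <- p$freq >= f_lo & p$freq <= f_hi
  unname(coef(lm(log(p$power[keep]) ~ log(p$freq[keep])))[2])
}

# Brute-force connected-component labelling by repeated neighbour expansion
# (no search structure shared with the package's flood fill).
brute_label <- function(mask) {
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    nxt <- nxt + 1L
    lab[i, j] <- nxt
    repeat {
      changed <- FALSE
      for (jj in seq_len(nc)) for (ii in seq_len(nr)) {
        if (!mask[ii, jj] || lab[ii, jj] > 0L) next
        nbrs <- c(
          if (ii > 1) lab[ii - 1, jj] else 0L,
          if (ii < nr) lab[ii + 1, jj] else 0L,
          if (jj > 1) lab[ii, jj - 1] else 0L,
          if (jj < nc) lab[ii, jj + 1] else 0L
        )
        if (any(nbrs == nxt)) {
          lab[ii, jj] <- nxt
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  lab
}

# Are two labelings identical up to a permutation of labels?
same_partition <- function(a, b) {
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  on <- which(a > 0L)
  if (length(on) == 0L) return(TRUE)
  ka <- as.integer(factor(a[on], levels = unique(a[on])))
  kb <- as.integer(factor(b[on], levels = unique(b[on])))
  identical(ka, kb)
}

# Independent circular mean (sum of unit vectors, atan2), degrees.
circ_mean_oracle <- function(deg) {
  s <- sum(sin(deg * pi / 180)); c <- sum(cos(deg * pi / 180))
  atan2(s, c) * 180 / pi
}

# Smallest absolute angular difference in degrees.
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  min(d, 360 - d)
}

# Single-pair filter bank used by many tests.
single_pair_spec <- function(fs = 250, lf = 8, hf = 64) {
  build_filterbank(fs, lf_centers = lf, hf_centers = hf)
}

# Minimal fake pac_map for group-level tests: one channel, an lf x hf grid of
# given mi_raw / surr_mean values.
fake_map <- function(mi_raw, surr_mean, mi_norm = mi_raw, phase_max = 90,
                     channel = "Cz", lf = c(6, 8, 10), hf = c(56, 64, 72),
                     subject_id = "S1", age = 12, spec = NULL) {
  if (is.null(spec)) spec <- build_filterbank(250, lf_centers = lf,
                                              hf_centers = hf)
  grid <- expand.grid(lf_hz = lf, hf_hz = hf)
  n <- nrow(grid) * length(channel)
  cells <- data.frame(
    channel = rep(channel, each = nrow(grid)),
    lf_hz = rep(grid$lf_hz, length(channel)),
    hf_hz = rep(grid$hf_hz, length(channel)),
    mi_raw = rep_len(mi_raw, n), surr_mean = rep_len(surr_mean, n),
    surr_sd = 1, mi_norm = rep_len(mi_norm, n),
    phase_max_deg = rep_len(phase_max, n), tie = FALSE,
    stringsAsFactors = FALSE
  )
  structure(
    list(cells = cells, subject_id = subject_id, age_months = age,
         fs_hz = 250, spec = spec, n_surr = 200, n_segments = 30),
    class = "pac_map"
  )
}
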