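# Phase-amplitude distributions, the Kullback-Leibler modulation index with
# time-shift surrogate normalization, phase max, and the per-recording PAC
# map over channels x valid frequency pairs.

new_phase_amp_dist <- function(mean_amp, n_per_bin, n_segments_averaged = 1L) {
  structure(
    list(
      bin_edges = pac_bin_edges(),
      bin_centers = pac_bin_centers(),
      mean_amp = mean_amp,
      n_per_bin = n_per_bin,
      n_segments_averaged = n_segments_averaged
    ),
    class = "phase_amp_dist"
  )
}

#' @export
print.phase_amp_dist <- function(x, ...) {
  cat(sprintf(
    "<phase_amp_dist> 18 x 20-degree bins, %d segment(s) averaged, %d empty bin(s)\n",
    x$n_segments_averaged, sum(is.na(x$mean_amp))
  ))
  invisible(x)
}

#' Bin high-frequency amplitude by low-frequency phase
#'
#' Assigns every sample to one of 18 20-degree phase bins spanning
#' \[-180, 180) degrees and computes the mean high-frequency amplitude within
#' each bin. Bins containing no samples are recorded as missing (`NA`) and
#' resolved when distributions are averaged across segments.
#'
#' @param phase_deg Low-frequency phase series, degrees.
#' @param amp High-frequency amplitude series, same length.
#'
#' @return An object of class `phase_amp_dist` with `bin_edges`,
#'   `bin_centers`, `mean_amp` (length 18, `NA` for empty bins) and
#'   `n_per_bin`.
#' @export
#' @examples
#' ph <- seq(-180, 179, by = 1)
#' d <- bin_amplitude_by_phase(ph, 1 + cos((ph - 90) * pi / 180))
#' d$bin_centers[which.max(d$mean_amp)]
bin_amplitude_by_phase <- function(phase_deg, amp) {
  if (length(phase_deg) != length(amp)) {
    stop("`phase_deg` and `amp` must have equal length")
  }
  if (length(phase_deg) == 0L) stop("empty input: no samples to bin")
  idx <- phase_bin_index(phase_deg)
  counts <- tabulate(idx, nbins = 18L)
  sums <- numeric(18L)
  agg <- rowsum(amp, idx)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  mean_amp <- ifelse(counts > 0L, sums / counts, NA_real_)
  new_phase_amp_dist(mean_amp, counts)
}

#' Average phase-amplitude distributions across segments
#'
#' Per-bin arithmetic mean over segments in which the bin is non-missing;
#' this is the participant-level distribution from which the raw modulation
#' index is computed.
#'
#' @param dists List of `phase_amp_dist` objects with identical binning.
#'
#' @return A `phase_amp_dist`; errors if any bin is missing in every segment.
#' @export
average_distributions <- function(dists) {
  if (length(dists) < 1L) stop("need at least one distribution")
  stopifnot(all(vapply(dists, inherits, logical(1), "phase_amp_dist")))
  m <- vapply(dists, function(d) d$mean_amp, numeric(18L))
  m <- matrix(m, nrow = 18L)
  n_ok <- rowSums(!is.na(m))
  if (any(n_ok == 0L)) {
    stop("phase bin empty in every segment; cannot average")
  }
  avg <- rowMeans(m, na.rm = TRUE)
  new_phase_amp_dist(avg, n_ok, n_segments_averaged = length(dists))
}

# MI of one or more binned mean-amplitude columns (18 x k matrix); internal
# vectorized core shared by modulation_index() and surrogate_mi().
mi_from_bins <- function(m) {
  tot <- colSums(m)
  p <- sweep(m, 2L, tot, "/")
  terms <- p * log(18 * p)
  terms[p == 0] <- 0
  colSums(terms) / log(18)
}

#' Kullback-Leibler modulation index
#'
#' The raw modulation index of a phase-amplitude distribution: the
#' Kullback-Leibler divergence of the normalized mean-amplitude distribution
#' `P(b)` from the uniform distribution over the 18 phase bins, divided by
#' `log(18)` so that the index lies in \[0, 1] (0 for a uniform distribution,
#' 1 when all amplitude concentrates in a single bin). Equivalently
#' `MI = (log N - H(P)) / log N` with `N = 18` and Shannon entropy `H`;
#' `0 * log 0` is taken as 0.
#'
#' @param dist A `phase_amp_dist` with all bins present.
#'
#' @return Numeric scalar in \[0, 1].
#' @export
#' @examples
#' d <- bin_amplitude_by_phase(seq(-180, 179), rep(1, 360))
#' modulation_index(d)  # uniform -> 0
modulation_index <- function(dist) {
  stopifnot(inherits(dist, "phase_amp_dist"))
  if (anyNA(dist$mean_amp)) {
    stop("all 18 phase bins must be present to compute the modulation index")
  }
  if (sum(dist$mean_amp) <= 0) stop("zero total amplitude")
  as.numeric(mi_from_bins(matrix(dist$mean_amp, ncol = 1L)))
}

#' Phase of maximal high-frequency amplitude (phase max)
#'
#' The center of the phase bin in which the mean high-frequency amplitude is
#' largest — the coupling's preferred phase. Ties are broken toward the
#' smallest bin center and flagged via the `"tie"` attribute.
#'
#' @param dist A `phase_amp_dist` with all bins present.
#'
#' @return Bin center in degrees (one of -170, -150, ..., 170), with a
#'   logical attribute `"tie"`.
#' @export
phase_max <- function(dist) {
  stopifnot(inherits(dist, "phase_amp_dist"))
  if (anyNA(dist$mean_amp)) {
    stop("all 18 phase bins must be present to compute phase max")
  }
  mx <- max(dist$mean_amp)
  at <- which(dist$mean_amp == mx)
  out <- dist$bin_centers[at[1L]]
  attr(out, "tie") <- length(at) > 1L
  out
}

#' Surrogate modulation indices by circular time shift
#'
#' Generates the surrogate MI distribution used to normalize the raw
#' modulation index: for each surrogate, every segment's amplitude series is
#' circularly shifted relative to its phase series by an independent uniform
#' draw from `shift_range_s` (default 0.1-1.9 s, i.e. 25-475 samples at
#' 250 Hz for 2-s segments), and the binning, cross-segment averaging and MI
#' computation are repeated exactly as in the real pipeline. Shifting
#' destroys genuine phase-amplitude dependence while preserving each
#' segment's amplitude distribution.
#'
#' @param phase_deg,amp Samples-by-segments matrices (or vectors for a single
#'   segment) of aligned phase and amplitude.
#' @param fs_hz Sampling rate, Hz.
#' @param n_surr Number of surrogates (default 200).
#' @param shift_range_s Length-2 numeric, allowed shift range in seconds;
#'   must lie strictly inside one segment length.
#' @param edge_trim Number of samples at each segment edge excluded from the
#'   binning (the filter's edge-transient region); the circular shift is
#'   still taken over the full segment. Default 0.
#' @param seed Optional seed for the shift draws.
#'
#' @return Numeric vector of `n_surr` surrogate MI values.
#' @export
surrogate_mi <- function(phase_deg, amp, fs_hz, n_surr = 200,
                         shift_range_s = c(0.1, 1.9), edge_trim = 0,
                         seed = NULL) {
  if (is.vector(phase_deg)) phase_deg <- matrix(phase_deg, ncol = 1L)
  if (is.vector(amp)) amp <- matrix(amp, ncol = 1L)
  stopifnot(identical(dim(phase_deg), dim(amp)), n_surr >= 1)
  l <- nrow(phase_deg)
  n_seg <- ncol(phase_deg)
  seg_len_s <- l / fs_hz
  if (length(shift_range_s) != 2L || shift_range_s[1] <= 0 ||
      shift_range_s[2] <= shift_range_s[1] ||
      shift_range_s[2] >= seg_len_s) {
    stop("`shift_range_s` must satisfy 0 < lo < hi < segment length (",
         seg_len_s, " s)")
  }
  lo <- max(1L, as.integer(round(shift_range_s[1] * fs_hz)))
  hi <- min(l - 1L, as.integer(round(shift_range_s[2] * fs_hz)))
  edge_trim <- as.integer(edge_trim)
  if (edge_trim < 0 || 2L * edge_trim >= l) {
    stop("`edge_trim` must be non-negative and leave a non-empty interior")
  }
  kept <- (edge_trim + 1L):(l - edge_trim)
  with_seed(seed, {
    shifts <- matrix(
      sample(lo:hi, n_seg * n_surr, replace = TRUE), n_seg, n_surr
    )
    sum_means <- matrix(0, 18L, n_surr)
    n_ok <- matrix(0L, 18L, n_surr)
    for (s in seq_len(n_seg)) {
      idx <- phase_bin_index(phase_deg[, s])
      counts <- tabulate(idx[kept], nbins = 18L)
      # per-bin amplitude sums for ALL circular shifts at once, as the
      # circular cross-correlation of each bin's indicator with the
      # amplitude series (row k+1 holds the sums for a shift of k samples);
      # indicator rows outside the kept interior stay zero, so edge-transient
      # phase samples never enter the bins while shifts remain full-circle
      b <- matrix(0, l, 18L)
      b[cbind(kept, idx[kept])] <- 1
      cc <- Re(stats::mvfft(Conj(stats::mvfft(b)) * stats::fft(amp[, s]),
                            inverse = TRUE)) / l
      means <- t(cc[shifts[s, ] + 1L, , drop = FALSE]) / counts
      ok <- counts > 0L
      sum_means[ok, ] <- sum_means[ok, ] + means[ok, , drop = FALSE]
      n_ok[ok, ] <- n_ok[ok, ] + 1L
    }
    if (any(n_ok == 0L)) stop("phase bin empty in every segment")
    as.numeric(mi_from_bins(sum_means / n_ok))
  })
}

#' Normalize the modulation index against its surrogate distribution
#'
#' The normalized modulation index is the z score of the raw MI with respect
#' to the surrogate MI distribution:
#' `mi_norm = (mi_raw - mean(surr)) / sd(surr)` (sample SD, n-1).
#'
#' @param mi_raw Raw modulation index.
#' @param surr Numeric vector of surrogate MI values (length >= 2, nonzero
#'   SD).
#'
#' @return List with `surr_mean`, `surr_sd`, `mi_norm`.
#' @export
normalize_mi <- function(mi_raw, surr) {
  if (length(surr) < 2L) stop("need at least 2 surrogate values")
  s <- stats::sd(surr)
  if (!is.finite(s) || s == 0) stop("zero surrogate SD; cannot normalize")
  m <- mean(surr)
  list(surr_mean = m, surr_sd = s, mi_norm = (mi_raw - m) / s)
}

#' Compute the PAC map of one recording
#'
#' The per-recording "fit": for every channel and every valid low/high
#' frequency pair of the filter bank, extracts phase and amplitude, bins
#' amplitude by phase within each segment, averages the distributions across
#' segments, and computes the raw modulation index, its surrogate mean/SD and
#' z score (`mi_norm`), and the phase-max bin center.
#'
#' Within each segment, samples inside the low-frequency filter's
#' edge-transient region (one half kernel length at each end, where the
#' zero-phase output depends on reflection padding) are excluded from the
#' phase binning, for the real distribution and the surrogates alike.
#' Because segments hold a whole number of oscillation cycles, edge
#' distortions repeat coherently across segments and would otherwise inflate
#' the averaged distribution's apparent nonuniformity relative to the
#' time-shifted surrogates.
#'
#' @param seg A `segmented_eeg` (typically 30 selected 2-s segments).
#' @param spec A [build_filterbank()] result; defaults to the standard bank
#'   at the recording's sampling rate.
#' @param n_surr Number of time-shift surrogates per cell (default 200).
#' @param shift_range_s Surrogate shift range in seconds.
#' @param seed Optional seed; a fixed seed makes the whole map reproducible.
#'
#' @return An object of class `pac_map`: a list with `cells` (data frame with
#'   columns `channel`, `lf_hz`, `hf_hz`, `mi_raw`, `surr_mean`, `surr_sd`,
#'   `mi_norm`, `phase_max_deg`, `tie`), subject metadata, the filter bank
#'   `spec`, `n_surr` and `n_segments`. Cells exist only for valid pairs.
#' @export
#' @examples
#' \donttest{
#' rec <- simulate_coupled_signal(8, 64, 90, 0.8, duration_s = 60, seed = 1)
#' seg <- segment_recording(rec)
#' spec <- build_filterbank(250, lf_centers = 8, hf_centers = 64)
#' pm <- pac_map(seg, spec, seed = 1)
#' pm$cells
#' }
pac_map <- function(seg, spec = NULL, n_surr = 200,
                    shift_range_s = c(0.1, 1.9), seed = NULL) {
  stopifnot(inherits(seg, "segmented_eeg"))
  if (is.null(spec)) spec <- build_filterbank(seg$fs_hz)
  stopifnot(inherits(spec, "filterbank_spec"))
  n_seg <- dim(seg$segments)[3]
  l <- dim(seg$segments)[2]
  chans <- seg$channel_labels
  trim <- edge_trim_samples(spec$lf_bandwidth, seg$fs_hz, l)
  kept <- (trim + 1L):(l - trim)

  with_seed(seed, {
    rows <- list()
    for (ch in chans) {
      x <- matrix(seg$segments[match(ch, chans), , ], nrow = l)
      # filter once per center, reuse across pairs
      lf_sig <- lapply(spec$lf_centers, function(c0)
        complex_bandpass(x, c0, spec$lf_bandwidth, seg$fs_hz))
      hf_sig <- lapply(spec$hf_centers, function(c0)
        complex_bandpass(x, c0, spec$hf_bandwidth, seg$fs_hz))
      for (i in seq_along(spec$lf_centers)) {
        zl <- lf_sig[[i]]
        if (is.vector(zl)) zl <- matrix(zl, ncol = 1L)
        phase <- Arg(zl) * 180 / pi
        phase[phase >= 180] <- -180
        for (j in seq_along(spec$hf_centers)) {
          if (!spec$valid_pair_mask[i, j]) next
          zh <- hf_sig[[j]]
          if (is.vector(zh)) zh <- matrix(zh, ncol = 1L)
          amp <- Mod(zh)
          dists <- lapply(seq_len(n_seg), function(s)
            bin_amplitude_by_phase(phase[kept, s], amp[kept, s]))
          d <- average_distributions(dists)
          mi <- modulation_index(d)
          pm <- phase_max(d)
          surr <- surrogate_mi(phase, amp, seg$fs_hz, n_surr = n_surr,
                               shift_range_s = shift_range_s,
                               edge_trim = trim, seed = NULL)
          nz <- normalize_mi(mi, surr)
          rows[[length(rows) + 1L]] <- data.frame(
            channel = ch,
            lf_hz = spec$lf_centers[i], hf_hz = spec$hf_centers[j],
            mi_raw = mi, surr_mean = nz$surr_mean, surr_sd = nz$surr_sd,
            mi_norm = nz$mi_norm,
            phase_max_deg = as.numeric(pm), tie = attr(pm, "tie"),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    cells <- do.call(rbind, rows)
    rownames(cells) <- NULL
    structure(
      list(
        cells = cells,
        subject_id = seg$subject_id, age_months = seg$age_months,
        fs_hz = seg$fs_hz, spec = spec,
        n_surr = n_surr, n_segments = n_seg
      ),
      class = "pac_map"
    )
  })
}

#' @export
print.pac_map <- function(x, ...) {
  cat(sprintf(
    "<pac_map> %s (age %s mo): %d channel(s) x %d valid pair(s), %d segment(s), %d surrogates\n",
    x$subject_id %||% "?",
    if (is.na(x$age_months)) "?" else format(x$age_months),
    length(unique(x$cells$channel)),
    nrow(x$cells) / length(unique(x$cells$channel)),
    x$n_segments, x$n_surr
  ))
  invisible(x)
}

#' @export
summary.pac_map <- function(object, ...) {
  cells <- object$cells
  out <- data.frame(
    channel = unique(cells$channel),
    mean_mi_norm = tapply(cells$mi_norm, cells$channel, mean)[unique(cells$channel)],
    max_mi_norm = tapply(cells$mi_norm, cells$channel, max)[unique(cells$channel)],
    row.names = NULL
  )
  cat(sprintf("PAC map for %s: %d cells\n", object$subject_id %||% "?",
              nrow(cells)))
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
as.data.frame.pac_map <- function(x, ...) {
  cbind(
    subject_id = x$subject_id, age_months = x$age_months, x$cells,
    stringsAsFactors = FALSE
  )
}

#' Plot a PAC map as comodulograms
#'
#' Draws one comodulogram (low-frequency by high-frequency grid of `mi_norm`)
#' per channel; invalid pairs are blank.
#'
#' @param x A `pac_map`.
#' @param channels Channels to plot (default all).
#' @param ... Passed to [graphics::image()].
#' @export
plot.pac_map <- function(x, channels = NULL, ...) {
  spec <- x$spec
  chans <- channels %||% unique(x$cells$channel)
  nc <- length(chans)
  op <- graphics::par(mfrow = grDevices::n2mfrow(nc),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (ch in chans) {
    z <- matrix(NA_real_, length(spec$lf_centers), length(spec$hf_centers))
    cc <- x$cells[x$cells$channel == ch, ]
    z[cbind(match(cc$lf_hz, spec$lf_centers),
            match(cc$hf_hz, spec$hf_centers))] <- cc$mi_norm
    graphics::image(spec$lf_centers, spec$hf_centers, z,
                    xlab = "LF phase frequency (Hz)",
                    ylab = "HF amplitude frequency (Hz)",
                    main = ch, ...)
  }
  invisible(x)
}
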