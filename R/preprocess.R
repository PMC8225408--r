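#' Segment a recording into fixed-length windows
#'
#' Cuts a continuous recording into non-overlapping consecutive windows of
#' `segment_len_s` seconds (default 2 s, the window length used for PAC
#' analysis). A trailing partial window is discarded, never padded, because
#' the downstream filters require full windows.
#'
#' @param rec An [recording()].
#' @param segment_len_s Window length in seconds.
#'
#' @return An object of class `segmented_eeg`: a list with `segments`
#'   (channels x samples x segments array), `fs_hz`, `channel_labels`,
#'   `segment_len_s`, and subject metadata.
#' @export
#' @examples
#' rec <- simulate_coupled_signal(8, 64, 90, 0.8, duration_s = 6, seed = 1)
#' seg <- segment_recording(rec)
#' dim(seg$segments)
segment_recording <- function(rec, segment_len_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- segment_len_s * rec$fs_hz
  if (abs(len - round(len)) > 1e-8) {
    stop("`segment_len_s * fs_hz` must be an integer number of samples")
  }
  len <- as.integer(round(len))
  ns <- ncol(rec$data)
  n_seg <- ns %/% len
  if (n_seg < 1L) {
    stop("recording shorter than one segment (", segment_len_s, " s)")
  }
  seg <- array(
    rec$data[, seq_len(n_seg * len), drop = FALSE],
    dim = c(nrow(rec$data), len, n_seg),
    dimnames = list(rec$channel_labels, NULL, NULL)
  )
  structure(
    list(
      segments = seg,
      fs_hz = rec$fs_hz,
      channel_labels = rec$channel_labels,
      segment_len_s = segment_len_s,
      subject_id = rec$subject_id,
      age_months = rec$age_months
    ),
    class = "segmented_eeg"
  )
}

#' @export
print.segmented_eeg <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf(
    "<segmented_eeg> %s: %d segment(s) of %g s, %d channel(s) @ %g Hz\n",
    x$subject_id %||% "?", d[3], x$segment_len_s, d[1], x$fs_hz
  ))
  invisible(x)
}

# Subset a segmented_eeg by segment index, preserving metadata.
subset_segments <- function(seg, keep) {
  seg$segments <- seg$segments[, , keep, drop = FALSE]
  seg
}

# Mean negative log-density of `x` under a Gaussian-kernel density estimate of
# `ref` (evaluated by interpolation on a fixed grid): the improbability score.
neg_log_density_score <- function(x, ref) {
  if (stats::sd(ref) == 0) return(0)
  d <- stats::density(ref, n = 512L)
  f <- stats::approx(d$x, d$y, xout = x, rule = 2L)$y
  -mean(log(pmax(f, 1e-300)))
}

# z-score a vector; constant input maps to all-zero scores.
zscore0 <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Joint-probability segment rejection
#'
#' Flags artifact segments by how improbable each electrode's activity is
#' along two dimensions: (i) relative to that electrode's activity pooled
#' across all other segments, and (ii) relative to the activity of all
#' electrodes within the same segment. The improbability score is the mean
#' negative log-likelihood of the segment's samples under a Gaussian kernel
#' density estimate of the reference distribution. Each score is z-scored
#' across segments per electrode, and a segment is rejected when any
#' electrode's score on either dimension lies more than `sd_threshold`
#' standard deviations from that score's mean. The pass is applied once.
#'
#' @param seg A `segmented_eeg` with at least 2 segments.
#' @param sd_threshold Rejection threshold in SD units (default 3;
#'   `Inf` disables rejection).
#'
#' @return The surviving `segmented_eeg`, with a `rejection_log` attribute:
#'   a data frame with columns `subject_id`, `segment_index`, `dimension`
#'   (`"across_segments"` / `"within_segment"`), `max_abs_z`, `rejected`.
#' @export
joint_probability_reject <- function(seg, sd_threshold = 3) {
  stopifnot(inherits(seg, "segmented_eeg"))
  a <- seg$segments
  n_ch <- dim(a)[1]
  n_seg <- dim(a)[3]
  if (n_seg < 2L) stop("need at least 2 segments to estimate a distribution")

  # Dimension 1: electrode's segment vs that electrode across all segments.
  score1 <- matrix(0, n_ch, n_seg)
  for (e in seq_len(n_ch)) {
    pooled <- as.vector(a[e, , ])
    for (s in seq_len(n_seg)) {
      score1[e, s] <- neg_log_density_score(a[e, , s], pooled)
    }
  }
  z1 <- t(apply(score1, 1L, zscore0))

  # Dimension 2: electrode's segment vs all electrodes in the same segment;
  # scores are z-scored across segments so the rejection unit is the segment.
  score2 <- matrix(0, n_ch, n_seg)
  for (s in seq_len(n_seg)) {
    pooled <- as.vector(a[, , s])
    for (e in seq_len(n_ch)) {
      score2[e, s] <- neg_log_density_score(a[e, , s], pooled)
    }
  }
  z2 <- t(apply(score2, 1L, zscore0))
  if (n_ch == 1L) z2[] <- 0   # single electrode: within-segment dimension void

  max1 <- apply(abs(z1), 2L, max)
  max2 <- apply(abs(z2), 2L, max)
  rejected <- (max1 > sd_threshold) | (max2 > sd_threshold)

  log <- data.frame(
    subject_id = rep(seg$subject_id %||% NA_character_, 2L * n_seg),
    segment_index = rep(seq_len(n_seg), 2L),
    dimension = rep(c("across_segments", "within_segment"), each = n_seg),
    max_abs_z = c(max1, max2),
    rejected = rep(rejected, 2L),
    stringsAsFactors = FALSE
  )
  out <- subset_segments(seg, !rejected)
  attr(out, "rejection_log") <- log
  out
}

#' Randomly select segments for analysis
#'
#' Samples exactly `n` segments (default 30, i.e. 60 s of 2-s windows)
#' uniformly without replacement, preserving temporal order. A recording with
#' fewer than `n` surviving segments is not analyzable and raises an
#' insufficient-data error (condition class `pacdev_insufficient_data`).
#'
#' @param seg A `segmented_eeg`.
#' @param n Number of segments to keep.
#' @param seed Optional seed; the selected set is reproducible for a fixed
#'   seed.
#'
#' @return A `segmented_eeg` with exactly `n` segments.
#' @export
select_segments <- function(seg, n = 30, seed = NULL) {
  stopifnot(inherits(seg, "segmented_eeg"))
  n_seg <- dim(seg$segments)[3]
  if (n_seg < n) {
    stop(insufficient_data_error(sprintf(
      "insufficient data: %d segment(s) available, %d required; recording not analyzable",
      n_seg, n
    )))
  }
  if (n_seg == n) return(seg)
  keep <- with_seed(seed, sort(sample.int(n_seg, n)))
  subset_segments(seg, keep)
}
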