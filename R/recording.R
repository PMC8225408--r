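#' EEG recording container
#'
#' A minimal in-memory representation of one subject's multichannel EEG:
#' a channels-by-samples numeric matrix plus sampling rate, 10-20 channel
#' labels and subject metadata. All analysis entry points accept this class.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs_hz Sampling rate in Hz.
#' @param channel_labels Character vector of channel names, one per row of
#'   `data`. Defaults to `rownames(data)`.
#' @param subject_id Subject identifier (any scalar; kept as metadata).
#' @param age_months Age at recording, in months.
#'
#' @return An object of class `eeg_recording`: a list with elements `data`,
#'   `fs_hz`, `channel_labels`, `subject_id`, `age_months`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(500), 1), fs_hz = 250, channel_labels = "Cz")
#' rec
recording <- function(data, fs_hz, channel_labels = rownames(data),
                      subject_id = NA_character_, age_months = NA_real_) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), is.numeric(data), nrow(data) >= 1L)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    stop("`fs_hz` must be a single positive number")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` must have one entry per channel (row) of `data`")
  }
  if (anyNA(data)) stop("`data` contains missing values")
  rownames(data) <- channel_labels
  structure(
    list(
      data = data,
      fs_hz = as.numeric(fs_hz),
      channel_labels = as.character(channel_labels),
      subject_id = subject_id,
      age_months = as.numeric(age_months)
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$data) / x$fs_hz
  cat(sprintf(
    "<eeg_recording> %s: %d channel(s) x %d samples (%.1f s @ %g Hz)\n",
    x$subject_id %||% "?", nrow(x$data), ncol(x$data), dur, x$fs_hz
  ))
  if (!is.na(x$age_months)) cat(sprintf("  age: %g months\n", x$age_months))
  cat(sprintf("  channels: %s\n", paste(x$channel_labels, collapse = ", ")))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)
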