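# File formats: tabular (TSV) recordings, a minimal EDF reader/writer for
# continuous uniform-rate multichannel data, manifests, and result tables.

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         edf = "edf",
         tsv = , txt = , tab = "tsv",
         stop("cannot infer recording format from extension: .", ext))
}

#' Read a recording from disk
#'
#' Supports two formats: plain TSV (one column per channel, header row of
#' channel labels, one sample per line) and EDF (16-bit continuous European
#' Data Format, all channels at one sampling rate). For TSV the sampling rate
#' is not stored in the file and must be supplied (typically from the
#' manifest). Recordings whose Nyquist frequency is below the highest filter
#' band edge of the standard bank are rejected; rates other than 250 Hz are
#' accepted with a warning and never implicitly resampled.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"edf"`.
#' @param fs_hz Sampling rate in Hz (required for TSV; ignored for EDF,
#'   which stores it).
#' @param subject_id,age_months Metadata attached to the recording.
#'
#' @return An [recording()].
#' @export
read_recording <- function(path, format = c("auto", "tsv", "edf"),
                           fs_hz = NULL, subject_id = NA_character_,
                           age_months = NA_real_) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    if (is.null(fs_hz)) stop("`fs_hz` is required for TSV recordings")
    first <- readLines(path, n = 1L)
    labels <- strsplit(first, "\t", fixed = TRUE)[[1L]]
    if (!anyNA(suppressWarnings(as.numeric(labels)))) {
      stop("TSV recording must have a header row of channel labels")
    }
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE)
    rec <- recording(t(as.matrix(tab)), fs_hz = fs_hz,
                     channel_labels = colnames(tab),
                     subject_id = subject_id, age_months = age_months)
  } else {
    rec <- read_edf(path)
    rec$subject_id <- subject_id
    rec$age_months <- age_months
  }
  max_edge <- 100 + 20 / 2   # highest band edge of the standard filter bank
  if (rec$fs_hz / 2 < max_edge) {
    stop("sampling rate too low: Nyquist ", rec$fs_hz / 2,
         " Hz is below the highest filter band edge (", max_edge, " Hz)")
  }
  if (rec$fs_hz != 250) {
    warning("sampling rate is ", rec$fs_hz,
            " Hz; the standard pipeline rate is 250 Hz. No resampling is applied.")
  }
  rec
}

#' Write a recording to disk
#'
#' @param rec An [recording()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"tsv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "tsv", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "tsv") {
    tab <- as.data.frame(t(rec$data))
    colnames(tab) <- rec$channel_labels
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

# ---- minimal EDF (European Data Format) support -----------------------------
# Continuous recordings only, all channels sharing one sampling rate, 16-bit
# samples. Record duration is chosen so samples-per-record is integral.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$data)
  fs <- rec$fs_hz
  n_samp <- ncol(rec$data)
  rec_dur <- 1
  spr <- fs * rec_dur
  if (abs(spr - round(spr)) > 1e-9) stop("fs_hz must give integral samples per 1-s record")
  spr <- as.integer(round(spr))
  n_rec <- n_samp %/% spr
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)")
  if (n_rec * spr != n_samp) {
    warning("trailing ", n_samp - n_rec * spr,
            " sample(s) do not fill an EDF record and are dropped on write")
  }
  x <- rec$data[, seq_len(n_rec * spr), drop = FALSE]
  pmin_ <- apply(x, 1L, min)
  pmax_ <- apply(x, 1L, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8L),
    pad_field("X X X X", 80L),          # patient id
    pad_field("Startdate X X X X", 80L),
    pad_field("01.01.00", 8L), pad_field("00.00.00", 8L),
    pad_field(256L + ns * 256L, 8L),
    pad_field("", 44L),
    pad_field(n_rec, 8L),
    pad_field(format(rec_dur), 8L),
    pad_field(ns, 4L)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    list(rec$channel_labels, 16L),
    list(rep("", ns), 80L),             # transducer
    list(rep("uV", ns), 8L),
    list(formatC(pmin_, digits = 6, format = "g"), 8L),
    list(formatC(pmax_, digits = 6, format = "g"), 8L),
    list(rep(dmin, ns), 8L),
    list(rep(dmax, ns), 8L),
    list(rep("", ns), 80L),             # prefiltering
    list(rep(spr, ns), 8L),
    list(rep("", ns), 32L)
  )
  for (f in fields) {
    writeChar(paste(vapply(f[[1L]], pad_field, character(1), f[[2L]]),
                    collapse = ""), con, eos = NULL)
  }
  # physical values re-read use the written (truncated) header fields, so
  # quantize against the parsed values for an honest round trip
  pmin_w <- as.numeric(pad_field(formatC(pmin_, digits = 6, format = "g"), 8L))
  pmax_w <- as.numeric(pad_field(formatC(pmax_, digits = 6, format = "g"), 8L))
  gain <- (pmax_w - pmin_w) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      seg <- x[ch, ((r - 1L) * spr + 1L):(r * spr)]
      dig <- as.integer(round((seg - pmin_w[ch]) / gain[ch]) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8L)                       # version
  rd(80L); rd(80L); rd(8L); rd(8L)
  as.integer(rd(8L))           # header bytes (ignored)
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  get_fields <- function(width) {
    vapply(seq_len(ns), function(i) trimws(rd(width)), character(1))
  }
  labels <- get_fields(16L)
  get_fields(80L); get_fields(8L)
  pmin_ <- as.numeric(get_fields(8L))
  pmax_ <- as.numeric(get_fields(8L))
  dmin <- as.numeric(get_fields(8L))
  dmax <- as.numeric(get_fields(8L))
  get_fields(80L)
  spr <- as.integer(get_fields(8L))
  get_fields(32L)
  if (length(unique(spr)) != 1L) {
    stop("EDF files with per-channel sampling rates are not supported")
  }
  fs <- spr[1L] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  out <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[1L], size = 2L, signed = TRUE,
                     endian = "little")
      out[ch, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <-
        pmin_[ch] + (dig - dmin[ch]) * gain[ch]
    }
  }
  recording(out, fs_hz = fs, channel_labels = labels)
}

# ---- manifests and result tables -------------------------------------------

#' Read or write a cohort manifest
#'
#' A manifest is a TSV with columns `subject_id`, `age_months`, `path` (and
#' optionally more, e.g. `net_type`). Each (subject_id, path) pair must be
#' unique; ages outside the standard collection time points
#' (3, 6, 9, 12, 18, 24, 36 months) are allowed with a warning.
#'
#' @param path Manifest file path.
#' @param base_dir Directory against which relative recording paths are
#'   resolved (default: the manifest's directory).
#' @return Data frame with a `path` column of resolved file paths.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validate_manifest(tab, base_dir)
}

#' @rdname read_manifest
#' @param manifest Data frame to validate/write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(tab, base_dir = NULL) {
  need <- c("subject_id", "age_months", "path")
  if (!all(need %in% names(tab))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab[, c("subject_id", "path")])) {
    stop("manifest rows must be unique in (subject_id, path)")
  }
  if (!is.null(base_dir)) {
    rel <- !file.exists(tab$path)
    tab$path[rel] <- file.path(base_dir, tab$path[rel])
  }
  if (!all(file.exists(tab$path))) {
    stop("manifest points to missing file(s): ",
         paste(tab$path[!file.exists(tab$path)], collapse = ", "))
  }
  if (!all(tab$age_months %in% cohort_ages())) {
    warning("manifest contains ages outside the standard collection points ",
            "{3, 6, 9, 12, 18, 24, 36} months")
  }
  if (any(tab$age_months <= 0)) stop("ages must be positive")
  tab
}

# Write a cohort of recordings + manifest to a directory (TSV per subject).
#' Write a simulated cohort to disk
#'
#' Writes each recording as a TSV (one column per channel) plus a manifest
#' TSV (`subject_id`, `age_months`, `path`).
#'
#' @param cohort List of recordings (e.g. from [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    fn <- paste0(rec$subject_id, ".tsv")
    write_recording(rec, file.path(dir, fn), format = "tsv")
    data.frame(subject_id = rec$subject_id, age_months = rec$age_months,
               path = fn, stringsAsFactors = FALSE)
  })
  mpath <- file.path(dir, "manifest.tsv")
  write_manifest(do.call(rbind, rows), mpath)
  invisible(mpath)
}

# Result-table writers: plain TSVs mirroring the in-memory classes.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_pac_map_tsv <- function(map, path) {
  write_tsv(as.data.frame(map), path)
}

write_cluster_tsvs <- function(clusters, cluster_path, mask_path) {
  write_tsv(clusters$clusters, cluster_path)
  cells <- clusters$group$cells
  write_tsv(
    data.frame(
      channel = cells$channel, lf_hz = cells$lf_hz, hf_hz = cells$hf_hz,
      cluster_id = clusters$labels, pac_plus = clusters$pac_plus
    ),
    mask_path
  )
}

write_trend_tsvs <- function(trends, trend_path, mi_age_path) {
  rows <- do.call(rbind, lapply(names(trends$trends), function(nm) {
    cbind(region = nm, as.data.frame(trends$trends[[nm]]))
  }))
  write_tsv(rows, trend_path)
  write_tsv(
    data.frame(r = trends$mi_age$r, p = trends$mi_age$p, n = trends$mi_age$n),
    mi_age_path
  )
}
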