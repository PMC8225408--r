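#' Pink (1/f) noise
#'
#' Generates a Gaussian random series whose power spectral density is
#' proportional to 1/f, the standard background model for scalp EEG. The
#' series is synthesized in the frequency domain (white Gaussian spectrum
#' shaped by f^(-1/2), Hermitian-symmetrized, inverse FFT) and rescaled so its
#' sample standard deviation equals `scale`.
#'
#' @param n_samples Number of samples to generate (>= 0).
#' @param fs_hz Sampling rate in Hz (sets the frequency axis only; the 1/f
#'   shape is rate-invariant).
#' @param scale Target sample standard deviation of the output.
#' @param seed Optional integer seed; for a fixed seed the output is
#'   bit-reproducible and the caller's RNG stream is left untouched.
#'
#' @return Numeric vector of length `n_samples` (length 0 if `n_samples = 0`).
#' @export
#' @examples
#' x <- pink_noise(1024, fs_hz = 250, seed = 1)
#' sd(x)
pink_noise <- function(n_samples, fs_hz = 250, scale = 1, seed = NULL) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 0 ||
      n_samples != round(n_samples)) {
    stop("`n_samples` must be a single non-negative integer")
  }
  n <- as.integer(n_samples)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(0)
  with_seed(seed, {
    # One-sided spectrum: frequencies k*fs/n for k = 1..floor(n/2).
    half <- (n - 1L) %/% 2L                 # strictly positive, non-Nyquist bins
    f <- (1:half) * fs_hz / n
    amp <- 1 / sqrt(f)
    pos <- complex(
      real = stats::rnorm(half) * amp,
      imaginary = stats::rnorm(half) * amp
    )
    spec <- complex(length.out = n)
    spec[2:(half + 1L)] <- pos
    spec[n:(n - half + 1L)] <- Conj(pos)
    if (n %% 2L == 0L) {                    # real Nyquist bin
      fn <- (n / 2) * fs_hz / n
      spec[n / 2 + 1L] <- complex(real = stats::rnorm(1) / sqrt(fn))
    }
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    s <- stats::sd(x)
    if (s > 0) x <- x / s
    x * scale
  })
}

#' Simulate a phase-amplitude coupled signal
#'
#' Builds a single-channel test signal in which the amplitude of a
#' high-frequency oscillation is modulated by the phase of a low-frequency
#' oscillation:
#' \deqn{x(t) = \cos(\phi(t)) + a_{hf}\,[1 + m \cos(\phi(t) - \phi_0)]
#'   \cos(2\pi f_{hf} t) + \eta(t)}
#' with \eqn{\phi(t) = 2\pi f_{lf} t} and pink-noise background \eqn{\eta}.
#' Under the cosine phase convention (phase 0 degrees at the low-frequency
#' peak, increasing with time), the high-frequency envelope is maximal exactly
#' where the low-frequency phase equals `phase_pref_deg`.
#'
#' @param lf_hz Low-frequency carrier, Hz.
#' @param hf_hz High-frequency carrier, Hz; must satisfy
#'   `0 < lf_hz < hf_hz < fs_hz/2`.
#' @param phase_pref_deg Low-frequency phase (degrees) at which the
#'   high-frequency amplitude peaks; wrapped to \[-180, 180).
#' @param coupling_depth Modulation depth `m` in \[0, 1]; 0 means no coupling.
#' @param duration_s Duration in seconds; `duration_s * fs_hz` must be a whole
#'   number of samples.
#' @param fs_hz Sampling rate in Hz.
#' @param amp_ratio High-frequency carrier amplitude relative to the
#'   low-frequency amplitude (default 0.5).
#' @param noise_scale Standard deviation of the added pink noise relative to
#'   the unit low-frequency amplitude (default 1; 0 disables noise).
#' @param seed Optional seed for the pink-noise draw.
#' @param subject_id,age_months Metadata carried on the returned recording.
#' @param channel_label Channel name for the single simulated channel.
#'
#' @return An [recording()] with one channel.
#' @export
#' @examples
#' rec <- simulate_coupled_signal(8, 64, 90, 0.8, duration_s = 2, seed = 1)
simulate_coupled_signal <- function(lf_hz, hf_hz, phase_pref_deg,
                                    coupling_depth, duration_s, fs_hz = 250,
                                    amp_ratio = 0.5, noise_scale = 1,
                                    seed = NULL, subject_id = NA_character_,
                                    age_months = NA_real_,
                                    channel_label = "Cz") {
  if (!(lf_hz > 0 && lf_hz < hf_hz && hf_hz < fs_hz / 2)) {
    stop("require 0 < lf_hz < hf_hz < fs_hz/2 (Nyquist violation)")
  }
  if (coupling_depth < 0 || coupling_depth > 1) {
    stop("`coupling_depth` must be in [0, 1]")
  }
  n <- duration_s * fs_hz
  if (n <= 0 || abs(n - round(n)) > 1e-8) {
    stop("`duration_s * fs_hz` must be a positive integer number of samples")
  }
  n <- as.integer(round(n))
  pref <- wrap_deg(phase_pref_deg) * pi / 180
  t <- (0:(n - 1L)) / fs_hz
  ph <- 2 * pi * lf_hz * t
  env <- 1 + coupling_depth * cos(ph - pref)
  x <- cos(ph) + amp_ratio * env * cos(2 * pi * hf_hz * t)
  if (noise_scale > 0) {
    x <- x + pink_noise(n, fs_hz = fs_hz, scale = noise_scale, seed = seed)
  }
  recording(matrix(x, nrow = 1L), fs_hz = fs_hz,
            channel_labels = channel_label,
            subject_id = subject_id, age_months = age_months)
}

# Ages (months) at which cohort recordings are collected.
cohort_ages <- function() c(3, 6, 9, 12, 18, 24, 36)

#' Simulate a multi-subject cohort with regional phase preference
#'
#' Generates one multichannel recording per subject with the group-level
#' structure the downstream statistics are designed to detect: anterior
#' channels carry coupling with a phase preference near -110 degrees,
#' posterior channels near +70 degrees, and coupling depth increases linearly
#' with age (`base_depth` at 3 months, slope `depth_slope_per_month`). Ages
#' are assigned round-robin over the seven collection time points
#' (3, 6, 9, 12, 18, 24, 36 months) unless given explicitly.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param ages_months Optional vector of ages, each from
#'   {3, 6, 9, 12, 18, 24, 36}; recycled/validated against `n_subjects`.
#' @param anterior_pref_deg,posterior_pref_deg Regional phase preferences in
#'   degrees (defaults -110 and +70).
#' @param base_depth Coupling depth at 3 months.
#' @param depth_slope_per_month Linear increase of coupling depth per month of
#'   age; the depth at every cohort age must stay in \[0, 1].
#' @param channel_labels 10-20 channel names; each must belong to the anterior
#'   or posterior set of `regions`.
#' @param lf_hz,hf_hz Frequency pair carrying the simulated coupling.
#' @param duration_s Recording duration per subject, seconds.
#' @param fs_hz Sampling rate, Hz.
#' @param amp_ratio,noise_scale Passed to [simulate_coupled_signal()].
#' @param regions Named list with `anterior` and `posterior` channel sets
#'   (default [pac_regions()]).
#' @param seed Optional seed; the whole cohort is reproducible for a fixed
#'   seed.
#'
#' @return List of [recording()] objects (one per subject) with an
#'   `ages_months` attribute.
#' @export
#' @examples
#' coh <- simulate_cohort(4, channel_labels = c("Fz", "Pz"),
#'                        duration_s = 4, seed = 1)
simulate_cohort <- function(n_subjects, ages_months = NULL,
                            anterior_pref_deg = -110, posterior_pref_deg = 70,
                            base_depth = 0.2,
                            depth_slope_per_month = 0.6 / 33,
                            channel_labels = unlist(pac_regions(),
                                                    use.names = FALSE),
                            lf_hz = 8, hf_hz = 64, duration_s = 64,
                            fs_hz = 250, amp_ratio = 0.5, noise_scale = 1,
                            regions = pac_regions(), seed = NULL) {
  if (n_subjects < 2) stop("`n_subjects` must be at least 2")
  allowed <- cohort_ages()
  if (is.null(ages_months)) {
    ages_months <- allowed[((seq_len(n_subjects) - 1L) %% length(allowed)) + 1L]
  }
  if (length(ages_months) != n_subjects) {
    stop("`ages_months` must have length `n_subjects`")
  }
  if (!all(ages_months %in% allowed)) {
    stop("all ages must be drawn from {", paste(allowed, collapse = ", "), "}")
  }
  depths <- base_depth + depth_slope_per_month * (ages_months - min(allowed))
  if (any(depths < 0 | depths > 1)) {
    stop("coupling depth out of [0, 1] at some cohort age; ",
         "adjust `base_depth` / `depth_slope_per_month`")
  }
  is_ant <- channel_labels %in% regions$anterior
  is_post <- channel_labels %in% regions$posterior
  if (!all(is_ant | is_post)) {
    stop("channel(s) not in any region: ",
         paste(channel_labels[!(is_ant | is_post)], collapse = ", "))
  }
  prefs <- ifelse(is_ant, anterior_pref_deg, posterior_pref_deg)

  with_seed(seed, {
    recs <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      chans <- lapply(seq_along(channel_labels), function(ci) {
        simulate_coupled_signal(
          lf_hz, hf_hz, prefs[ci], depths[i], duration_s, fs_hz,
          amp_ratio = amp_ratio, noise_scale = noise_scale, seed = NULL
        )$data[1L, ]
      })
      recs[[i]] <- recording(
        do.call(rbind, chans), fs_hz = fs_hz,
        channel_labels = channel_labels,
        subject_id = sprintf("S%02d", i), age_months = ages_months[i]
      )
    }
    attr(recs, "ages_months") <- ages_months
    recs
  })
}
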