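# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Heartbeat morphology as a sum of Gaussian bumps
#'
#' A beat is modelled as five Gaussian deflections (P, Q, R, S, T) placed
#' relative to the R-wave peak. The defaults give a plausible normal sinus
#' beat; `abnormal_morphology()` widens the QRS complex and inverts the T
#' wave, a premature-ventricular-contraction-like shape, so that the two
#' classes are separable by waveform alone.
#'
#' @param wave Wave labels.
#' @param amplitude Peak amplitude in mV (signed).
#' @param center Bump center in seconds relative to the R peak.
#' @param width Gaussian standard deviation in seconds (> 0).
#' @return Tibble with columns `wave`, `amplitude`, `center`, `width`.
#' @export
beat_morphology <- function(wave = c("P", "Q", "R", "S", "T"),
                            amplitude = c(0.15, -0.10, 1.20, -0.25, 0.35),
                            center = c(-0.20, -0.035, 0.00, 0.035, 0.25),
                            width = c(0.025, 0.010, 0.014, 0.012, 0.045)) {
  m <- tibble(wave = wave, amplitude = amplitude, center = center, width = width)
  if (any(m$width <= 0)) ecg_abort("morphology widths must be > 0", "ecgkit_invalid_config")
  r <- which(m$wave == "R")
  if (length(r) != 1L || any(abs(m$amplitude[-r]) >= abs(m$amplitude[r]))) {
    ecg_abort("R amplitude must be strictly largest in absolute value", "ecgkit_invalid_config")
  }
  m
}

#' @rdname beat_morphology
#' @export
abnormal_morphology <- function() {
  beat_morphology(
    amplitude = c(0.05, -0.20, 1.00, -0.40, -0.40),
    center    = c(-0.22, -0.06, 0.00, 0.06, 0.30),
    width     = c(0.025, 0.030, 0.040, 0.035, 0.060)
  )
}

#' Simulation configuration for synthetic annotated ECG
#'
#' Defaults emulate an MIT-BIH-style recording: 360 Hz sampling,
#' quasi-periodic beats with P-QRS-T morphology and per-beat annotations
#' (`"N"` normal, `"V"` abnormal).
#'
#' @param duration Record length in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param heart_rate Mean heart rate in beats per minute.
#' @param rr_cv Coefficient of variation of the RR interval; intervals are
#'   i.i.d. Gaussian truncated at three standard deviations.
#' @param fraction_abnormal Probability that a beat is abnormal, in `[0, 1]`.
#' @param normal,abnormal Beat morphologies (see [beat_morphology()]).
#' @param seed RNG seed fixing beat times, classes and shapes.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 60, sampling_rate = 360, heart_rate = 72,
                       rr_cv = 0.05, fraction_abnormal = 0,
                       normal = beat_morphology(),
                       abnormal = abnormal_morphology(),
                       seed = 1L) {
  if (duration <= 0) ecg_abort("duration must be > 0", "ecgkit_invalid_config")
  if (fraction_abnormal < 0 || fraction_abnormal > 1) {
    ecg_abort("fraction_abnormal must lie in [0, 1]", "ecgkit_invalid_config")
  }
  structure(
    list(duration = duration, sampling_rate = sampling_rate,
         heart_rate = heart_rate, rr_cv = rr_cv,
         fraction_abnormal = fraction_abnormal,
         normal = normal, abnormal = abnormal, seed = as.integer(seed)),
    class = "sim_config"
  )
}

morphology_extent <- function(m) max(abs(m$center) + 3 * m$width)

#' Generate a clean annotated synthetic ECG record
#'
#' Produces a single-channel record of `round(duration * sampling_rate)`
#' samples with one annotation per beat, placed at the R-wave sample:
#' symbol `"N"` for normal beats, `"V"` for abnormal ones (drawn
#' independently with probability `fraction_abnormal`).
#'
#' @param config A [sim_config()].
#' @return An [ecg_record()] with one channel.
#' @export
generate_clean_ecg <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  mean_rr <- 60 / config$heart_rate
  extent <- max(morphology_extent(config$normal), morphology_extent(config$abnormal))
  # adjacent beats overlap by 2*extent - RR; refuse when that exceeds RR/2
  if (extent > 0.75 * mean_rr) {
    ecg_abort(sprintf(
      "heart rate %g bpm too high: beat morphology spans %.3f s, overlapping neighbours by more than half the mean RR interval (%.3f s)",
      config$heart_rate, extent, mean_rr
    ), "ecgkit_beat_overlap")
  }
  with_seed(config$seed, {
    sd_rr <- config$rr_cv * mean_rr
    # draw generously many RR intervals, truncate at +/- 3 SD
    n_draw <- ceiling(config$duration / mean_rr) + 10L
    rr <- rnorm(n_draw, mean_rr, sd_rr)
    rr <- pmin(pmax(rr, mean_rr - 3 * sd_rr), mean_rr + 3 * sd_rr)
    # beats at the record edges keep truncated waveforms, as in a real
    # recording that starts and ends mid-rhythm
    centers <- mean_rr / 2 + cumsum(c(0, rr))
    centers <- centers[round(centers * fs) <= n - 1L]
    n_beats <- length(centers)
    is_abn <- runif(n_beats) < config$fraction_abnormal

    sig <- numeric(n)
    t_all <- (seq_len(n) - 1L) / fs
    half <- ceiling(extent * fs) + 1L
    for (b in seq_len(n_beats)) {
      m <- if (is_abn[b]) config$abnormal else config$normal
      r_idx <- round(centers[b] * fs) + 1L
      lo <- max(1L, r_idx - half); hi <- min(n, r_idx + half)
      tt <- t_all[lo:hi] - (r_idx - 1L) / fs
      bump <- numeric(hi - lo + 1L)
      for (k in seq_len(nrow(m))) {
        bump <- bump + m$amplitude[k] * exp(-((tt - m$center[k])^2) / (2 * m$width[k]^2))
      }
      sig[lo:hi] <- sig[lo:hi] + bump
    }
    ann <- tibble(
      sample_index = round(centers * fs),  # 0-based R-wave samples
      symbol = ifelse(is_abn, "V", "N")
    )
    ecg_record(sig, fs, annotations = ann, record_name = sprintf("sim%d", config$seed))
  })
}

#' Noise specification for additive ECG corruption
#'
#' @param snr_db Target signal-to-noise ratio of the white Gaussian
#'   component in dB; `Inf` disables it. The noise realization is rescaled
#'   so the realized power ratio matches the target exactly.
#' @param baseline_wander_hz,baseline_wander_mV Optional sinusoidal baseline
#'   wander (frequency in Hz, amplitude in mV).
#' @param powerline_hz,powerline_mV Optional power-line interference
#'   (50 or 60 Hz) with the given amplitude.
#' @param seed RNG seed fixing the noise realization.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(snr_db = 10, baseline_wander_hz = NULL,
                       baseline_wander_mV = 0.1, powerline_hz = NULL,
                       powerline_mV = 0.05, seed = 1L) {
  if (!is.null(powerline_hz) && !powerline_hz %in% c(50, 60)) {
    ecg_abort("powerline_hz must be 50 or 60", "ecgkit_invalid_config")
  }
  structure(
    list(snr_db = snr_db, baseline_wander_hz = baseline_wander_hz,
         baseline_wander_mV = baseline_wander_mV, powerline_hz = powerline_hz,
         powerline_mV = powerline_mV, seed = as.integer(seed)),
    class = "noise_spec"
  )
}

#' Add controlled noise to a signal
#'
#' Adds white Gaussian noise scaled so the realized SNR
#' `10 * log10(P_signal / P_noise)` equals `spec$snr_db`, plus optional
#' sinusoidal baseline wander and power-line components. The input is not
#' modified.
#'
#' @param signal Numeric vector of amplitudes.
#' @param spec A [noise_spec()].
#' @param sampling_rate Sampling rate in Hz (needed for the sinusoidal
#'   components).
#' @return Numeric vector of the same length.
#' @export
add_noise <- function(signal, spec, sampling_rate = 360) {
  stopifnot(inherits(spec, "noise_spec"))
  if (length(signal) == 0L) ecg_abort("signal must be non-empty", "ecgkit_invalid_input")
  out <- signal
  with_seed(spec$seed, {
    if (is.finite(spec$snr_db)) {
      p_sig <- mean(signal^2)
      if (p_sig <= 0) {
        ecg_abort("cannot target a finite SNR on a zero-power signal", "ecgkit_invalid_input")
      }
      z <- rnorm(length(signal))
      z <- z / sqrt(mean(z^2))
      out <- out + z * sqrt(p_sig * 10^(-spec$snr_db / 10))
    }
    t <- (seq_along(signal) - 1L) / sampling_rate
    if (!is.null(spec$baseline_wander_hz)) {
      out <- out + spec$baseline_wander_mV * sin(2 * pi * spec$baseline_wander_hz * t)
    }
    if (!is.null(spec$powerline_hz)) {
      out <- out + spec$powerline_mV * sin(2 * pi * spec$powerline_hz * t)
    }
  })
  out
}
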