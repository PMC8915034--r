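# Half-sample symmetric (edge-repeating) reflection padding, the edge rule
# shared by every windowed filter here.
pad_reflect <- function(x, left, right = left) {
  n <- length(x)
  if (left > n || right > n) {
    ecg_abort("reflection pad wider than the signal", "ecgkit_invalid_input")
  }
  c(if (left > 0L) x[left:1L], x, if (right > 0L) x[n:(n - right + 1L)])
}

# Centered correlation of x with kernel h (odd or even length) under
# reflection padding; output has length(x).
correlate_reflect <- function(x, h) {
  w <- length(h)
  left <- (w - 1L) %/% 2L
  right <- w %/% 2L
  xp <- pad_reflect(x, left, right)
  n <- length(x)
  out <- numeric(n)
  for (j in seq_len(w)) {            # w is small; vectorized over n
    out <- out + h[j] * xp[j:(j + n - 1L)]
  }
  out
}

#' Median filter
#'
#' Slides an odd-length window over the signal and replaces each sample by
#' the window median; edges are handled by reflection. Removes impulsive
#' (salt-and-pepper) noise.
#'
#' @param signal Numeric signal.
#' @param window Odd window length in samples.
#' @return Filtered signal, same length.
#' @export
median_filter <- function(signal, window = 5L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) ecg_abort("median window must be odd", "ecgkit_invalid_config")
  if (window < 1L || window > length(signal)) {
    ecg_abort("median window must lie in [1, length(signal)]", "ecgkit_invalid_config")
  }
  if (window == 1L) return(signal)
  half <- (window - 1L) %/% 2L
  xp <- pad_reflect(signal, half)
  out <- stats::runmed(xp, window, endrule = "keep")
  as.numeric(out[(half + 1L):(half + length(signal))])
}

#' Gaussian smoothing filter
#'
#' Convolves the signal with a discrete Gaussian kernel truncated at
#' `truncate` standard deviations and renormalized to unit sum, with
#' reflection edges; a constant signal is therefore left unchanged.
#'
#' @param signal Numeric signal.
#' @param sigma Kernel standard deviation in samples (> 0).
#' @param truncate Kernel support half-width in standard deviations.
#' @return Filtered signal, same length.
#' @export
gaussian_filter <- function(signal, sigma = 2, truncate = 4) {
  if (sigma <= 0) ecg_abort("sigma must be > 0", "ecgkit_invalid_config")
  radius <- as.integer(floor(truncate * sigma))
  i <- (-radius):radius
  h <- exp(-0.5 * (i / sigma)^2)
  h <- h / sum(h)
  correlate_reflect(signal, h)
}

#' Moving-average filter
#'
#' Centered mean over a sliding window with reflection edges. For even
#' windows the window extends one sample further to the right.
#'
#' @param signal Numeric signal.
#' @param window Window length in samples (>= 1).
#' @return Filtered signal, same length.
#' @export
moving_average_filter <- function(signal, window = 5L) {
  window <- as.integer(window)
  if (window < 1L) ecg_abort("window must be >= 1", "ecgkit_invalid_config")
  if (window > length(signal)) {
    ecg_abort("moving-average window longer than the signal", "ecgkit_invalid_config")
  }
  correlate_reflect(signal, rep(1 / window, window))
}

# Savitzky-Golay smoothing kernel: value at the window center of the
# least-squares polynomial fit. Abscissae are scaled to [-1, 1] for
# numerical conditioning; the fitted value at 0 is scale-invariant.
savgol_kernel <- function(window, polyorder) {
  m <- (window - 1L) %/% 2L
  x <- ((-m):m) / m
  A <- outer(x, 0:polyorder, `^`)
  # first row of (A^T A)^{-1} A^T evaluates the fit at x = 0
  drop(solve(crossprod(A), t(A))[1L, ])
}

#' Savitzky-Golay smoothing filter
#'
#' Fits a polynomial of degree `polyorder` by least squares in each
#' odd-length window and replaces the center sample by the fitted value;
#' reflection edges. Defaults (window 25, order 7) preserve polynomial
#' trends up to degree 7 exactly.
#'
#' @param signal Numeric signal.
#' @param window Odd window length in samples.
#' @param polyorder Polynomial degree, `< window`.
#' @return Filtered signal, same length.
#' @export
savgol_filter <- function(signal, window = 25L, polyorder = 7L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) ecg_abort("Savitzky-Golay window must be odd", "ecgkit_invalid_config")
  if (polyorder >= window) ecg_abort("polyorder must be < window", "ecgkit_invalid_config")
  correlate_reflect(signal, savgol_kernel(window, polyorder))
}

#' Low-pass Butterworth filter
#'
#' Digital Butterworth low-pass with maximally flat passband; gain is
#' 1/sqrt(2) at the cutoff for a single pass. With `zero_phase = TRUE`
#' (the default) the filter is applied forward and backward, removing
#' phase distortion and doubling the attenuation.
#'
#' @param signal Numeric signal.
#' @param order Filter order.
#' @param cutoff_hz Cutoff frequency in Hz, below Nyquist.
#' @param sampling_rate Sampling rate in Hz.
#' @param zero_phase Forward-backward filtering if `TRUE`.
#' @return Filtered signal, same length.
#' @export
butterworth_lowpass <- function(signal, order = 4L, cutoff_hz = 40,
                                sampling_rate = 360, zero_phase = TRUE) {
  nyquist <- sampling_rate / 2
  if (cutoff_hz <= 0 || cutoff_hz >= nyquist) {
    ecg_abort(sprintf("cutoff (%g Hz) must lie strictly between 0 and Nyquist (%g Hz)",
                      cutoff_hz, nyquist), "ecgkit_invalid_config")
  }
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  if (zero_phase) {
    as.numeric(signal::filtfilt(bf, signal))
  } else {
    as.numeric(signal::filter(bf, signal))
  }
}

#' Denoising filter configuration
#'
#' Tagged parameter set consumed by [apply_filter()]. `type` selects one of
#' the six filters; the remaining arguments are that filter's parameters.
#' Defaults follow conventional choices for 360 Hz ECG; only the
#' Savitzky-Golay (window 25, order 7) and wavelet (sym8, BayesShrink,
#' soft) settings are fixed by the benchmark design.
#'
#' @param type One of `"median"`, `"gaussian"`, `"moving_average"`,
#'   `"savgol"`, `"butterworth"`, `"wavelet"`, or `"none"` (identity
#'   pass-through, the benchmark baseline).
#' @param ... Filter parameters overriding the defaults: `window`
#'   (median / moving_average / savgol), `sigma`, `truncate` (gaussian),
#'   `polyorder` (savgol), `order`, `cutoff_hz`, `zero_phase`
#'   (butterworth), `levels` (wavelet).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(type = c("median", "gaussian", "moving_average",
                                   "savgol", "butterworth", "wavelet", "none"),
                          ...) {
  type <- match.arg(type)
  defaults <- switch(type,
    median = list(window = 5L),
    gaussian = list(sigma = 2, truncate = 4),
    moving_average = list(window = 5L),
    savgol = list(window = 25L, polyorder = 7L),
    butterworth = list(order = 4L, cutoff_hz = 40, zero_phase = TRUE),
    wavelet = list(levels = 4L),
    none = list()
  )
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) {
    ecg_abort(sprintf("unknown parameter(s) for %s filter: %s", type,
                      paste(bad, collapse = ", ")), "ecgkit_invalid_config")
  }
  defaults[names(override)] <- override
  structure(c(list(type = type), defaults), class = "filter_config")
}

#' The six benchmark filters with default configurations
#'
#' @return Named list of [filter_config()] objects, one per filter.
#' @export
default_filter_set <- function() {
  types <- c("median", "gaussian", "moving_average", "savgol", "butterworth", "wavelet")
  stats::setNames(lapply(types, filter_config), types)
}

#' Apply a configured denoising filter
#'
#' Dispatches on `config$type` to the matching filter function. Output
#' always has the input's length; the input is never modified.
#'
#' @param signal Numeric signal.
#' @param config A [filter_config()].
#' @param sampling_rate Sampling rate in Hz (used by the Butterworth
#'   filter).
#' @return Filtered signal.
#' @export
apply_filter <- function(signal, config, sampling_rate = 360) {
  stopifnot(inherits(config, "filter_config"))
  switch(config$type,
    median = median_filter(signal, config$window),
    gaussian = gaussian_filter(signal, config$sigma, config$truncate),
    moving_average = moving_average_filter(signal, config$window),
    savgol = savgol_filter(signal, config$window, config$polyorder),
    butterworth = butterworth_lowpass(signal, config$order, config$cutoff_hz,
                                      sampling_rate, config$zero_phase),
    wavelet = wavelet_denoise(signal, config$levels),
    none = signal
  )
}
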