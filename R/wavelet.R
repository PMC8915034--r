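# Symlet-8 orthonormal filter bank (16 taps, 8 vanishing moments).
# Standard published coefficients; decomposition low-pass given, the rest
# derived by quadrature-mirror relations.
SYM8_DEC_LO <- c(
  -0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
  0.007607487324917605, -0.1432942383508097, -0.061273359067658524,
  0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
  -0.05194583810770904, -0.027219029917056003, 0.049137179673607506,
  0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
  0.0018899503327594609
)
SYM8_DEC_HI <- rev(SYM8_DEC_LO) * (-1)^(seq_along(SYM8_DEC_LO))
SYM8_REC_LO <- rev(SYM8_DEC_LO)
SYM8_REC_HI <- rev(SYM8_DEC_HI)

# One level of the periodized (circular, orthonormal) DWT.
# Odd-length inputs are extended by repeating the last sample, giving
# ceiling(n/2) coefficients per band.
dwt_periodized <- function(x) {
  n0 <- length(x)
  if (n0 < 2L) ecg_abort("signal too short for one decomposition step", "ecgkit_invalid_input")
  if (n0 %% 2L == 1L) x <- c(x, x[n0])
  n <- length(x)
  n2 <- n %/% 2L
  L <- length(SYM8_DEC_LO)
  k <- seq_len(n2) - 1L
  a <- numeric(n2); d <- numeric(n2)
  # circular convolution downsampled by 2, phase-centred at half the
  # filter length (L/2 = 8)
  for (m in seq_len(L) - 1L) {
    idx <- ((2L * k + 8L - m) %% n) + 1L
    a <- a + SYM8_DEC_LO[m + 1L] * x[idx]
    d <- d + SYM8_DEC_HI[m + 1L] * x[idx]
  }
  list(a = a, d = d)
}

# Inverse of dwt_periodized: the transpose of the orthonormal analysis map,
# trimmed to n_out samples.
idwt_periodized <- function(a, d, n_out) {
  n2 <- length(a)
  n <- 2L * n2
  L <- length(SYM8_DEC_LO)
  k <- seq_len(n2) - 1L
  x <- numeric(n)
  for (m in seq_len(L) - 1L) {
    pos <- ((2L * k + 8L - m) %% n) + 1L
    x[pos] <- x[pos] + SYM8_DEC_LO[m + 1L] * a + SYM8_DEC_HI[m + 1L] * d
  }
  x[seq_len(n_out)]
}

#' Multilevel periodized sym8 wavelet decomposition
#'
#' Circular (periodized) discrete wavelet transform with the sym8 filter
#' bank. The transform is orthonormal: coefficient energy equals signal
#' energy and [waverec_sym8()] reconstructs exactly.
#'
#' @param x Numeric signal.
#' @param levels Decomposition depth (>= 1).
#' @return List with `approx` (coarsest approximation), `details` (list of
#'   detail bands, coarsest first) and `lengths` (per-level input lengths,
#'   needed for reconstruction).
#' @export
wavedec_sym8 <- function(x, levels = 4L) {
  levels <- as.integer(levels)
  if (levels < 1L) ecg_abort("levels must be >= 1", "ecgkit_invalid_input")
  if (length(x) < 2L^levels) {
    ecg_abort(sprintf("signal of length %d too short for %d decomposition levels",
                      length(x), levels), "ecgkit_invalid_input")
  }
  details <- vector("list", levels)
  lengths <- integer(levels)
  cur <- x
  for (j in seq_len(levels)) {
    lengths[j] <- length(cur)
    step <- dwt_periodized(cur)
    details[[j]] <- step$d
    cur <- step$a
  }
  list(approx = cur, details = rev(details), lengths = rev(lengths))
}

#' Reconstruct a signal from a [wavedec_sym8()] decomposition
#'
#' @param dec List as returned by [wavedec_sym8()].
#' @return Numeric signal of the original length.
#' @export
waverec_sym8 <- function(dec) {
  cur <- dec$approx
  for (j in seq_along(dec$details)) {
    cur <- idwt_periodized(cur, dec$details[[j]], dec$lengths[j])
  }
  cur
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# BayesShrink threshold for one detail subband given the global noise SD.
bayes_threshold <- function(d, sigma) {
  sigma_x2 <- max(mean(d^2) - sigma^2, 0)
  if (sigma_x2 == 0) return(max(abs(d)))  # subband indistinguishable from noise
  sigma^2 / sqrt(sigma_x2)
}

#' Wavelet shrinkage denoising (sym8, BayesShrink, soft threshold)
#'
#' Decomposes the signal with a multilevel sym8 wavelet transform, estimates
#' the noise standard deviation from the finest detail band as
#' `median(|d|) / 0.6745`, soft-thresholds every detail band at its
#' BayesShrink threshold `sigma^2 / sigma_x` (where `sigma_x` is the
#' estimated noise-free subband SD), and reconstructs. Because the
#' transform is orthonormal and soft thresholding is a contraction, the
#' output L2 norm never exceeds the input's.
#'
#' @param signal Numeric signal.
#' @param levels Decomposition depth.
#' @return Denoised signal of the same length.
#' @export
wavelet_denoise <- function(signal, levels = 4L) {
  dec <- wavedec_sym8(signal, levels)
  finest <- dec$details[[length(dec$details)]]
  sigma <- median(abs(finest)) / 0.6745
  dec$details <- lapply(dec$details, function(d) {
    soft_threshold(d, bayes_threshold(d, sigma))
  })
  waverec_sym8(dec)
}
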