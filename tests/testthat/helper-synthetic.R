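# Shared fixtures, built in code at test time.

# Small two-channel record with a handful of annotations.
tiny_record <- function(n = 400, seed = 42) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / 360
  sig <- cbind(
    sin(2 * pi * 1.2 * t) + 0.05 * rnorm(n),
    0.5 * cos(2 * pi * 1.2 * t) + 0.05 * rnorm(n)
  )
  ann <- tibble::tibble(
    sample_index = c(50L, 180L, 320L),
    symbol = c("N", "V", "N")
  )
  ecg_record(sig, 360, annotations = ann, record_name = "tiny",
             gain = 200, baseline = 0)
}

# Half-sample symmetric padding used by the windowed-filter oracles.
oracle_pad <- function(x, left, right = left) {
  n <- length(x)
  c(if (left > 0) x[left:1], x, if (right > 0) x[n:(n - right + 1)])
}

# Brute-force sliding-window statistic under reflection padding.
oracle_window_apply <- function(x, window, fun) {
  left <- (window - 1) %/% 2
  right <- window %/% 2
  xp <- oracle_pad(x, left, right)
  vapply(seq_along(x), function(i) fun(xp[i:(i + window - 1)]), numeric(1))
}

# A record long enough to yield a usable beat dataset, with both classes.
two_class_record <- function(duration = 120, fraction_abnormal = 0.5,
                             seed = 7, snr_db = NULL) {
  rec <- generate_clean_ecg(sim_config(
    duration = duration, heart_rate = 72, rr_cv = 0.05,
    fraction_abnormal = fraction_abnormal, seed = seed
  ))
  if (!is.null(snr_db)) {
    noisy <- add_noise(record_channel(rec), noise_spec(snr_db, seed = seed + 1L), 360)
    rec <- ecg_record(noisy, 360, annotations = rec$annotations,
                      record_name = rec$header$record_name)
  }
  rec
}
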