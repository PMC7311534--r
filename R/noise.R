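#' Additive white Gaussian noise at a target SNR
#'
#' Measures the input signal power `P_signal = mean(signal^2)`, derives the
#' noise power from `SNR_dB = 10 log10(P_signal / P_noise)`, and adds
#' standard-normal draws scaled by `sqrt(P_noise)` to every frame (real
#' Gaussian noise on the magnitude signal).
#'
#' @param signal Numeric signal vector (or tibble with a `signal` column).
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Optional seed; when given the caller's RNG stream is left
#'   untouched.
#' @return Noisy signal, same shape as the input.
#' @export
#' @examples
#' s <- rep(10, 1000)
#' n <- add_awgn(s, snr_db = 20, seed = 1)
#' 10 * log10(mean(s^2) / mean((n - s)^2))  # close to 20
add_awgn <- function(signal, snr_db, seed = NULL) {
  is_tbl <- is.data.frame(signal) && "signal" %in% names(signal)
  s <- if (is_tbl) signal$signal else signal
  p_signal <- mean(s^2)
  if (p_signal == 0) {
    abort("All-zero signal: SNR is undefined.", class = "dcedict_invalid_inputs")
  }
  p_noise <- p_signal * 10^(-snr_db / 10)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  noisy <- s + rnorm(length(s)) * sqrt(p_noise)
  if (is_tbl) {
    signal$signal <- noisy
    signal
  } else noisy
}
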