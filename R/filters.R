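#' Filtering configuration
#'
#' Mains-interference notch filters plus an optional low-pass. The notches
#' are narrow biquad band-stops (quality factor `notch_q`); the low-pass is a
#' windowed-sinc linear-phase FIR of order `fir_order`. With
#' `zero_phase = TRUE` every stage is applied forward-backward, giving zero
#' group delay (and squaring each stage's magnitude response).
#'
#' @param notch_freqs_hz notch centre frequencies in Hz (default 50 and 60,
#'   covering both mains standards).
#' @param lowpass_cutoff_hz low-pass cutoff in Hz (default 35), or `NULL` to
#'   skip the low-pass stage.
#' @param fir_order FIR order for the low-pass (default 50; must be even so
#'   the linear-phase delay is an integer number of samples).
#' @param zero_phase apply filters forward-backward (default `TRUE`).
#' @param notch_q notch quality factor (centre frequency / -3 dB width).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(notch_freqs_hz = c(50, 60), lowpass_cutoff_hz = 35,
                          fir_order = 50, zero_phase = TRUE, notch_q = 30) {
  if (!is.null(lowpass_cutoff_hz)) {
    stopifnot(lowpass_cutoff_hz > 0)
    if (fir_order %% 2 != 0)
      stop("fir_order must be even for an integer linear-phase delay")
  }
  stopifnot(all(notch_freqs_hz > 0), notch_q > 0)
  structure(list(notch_freqs_hz = notch_freqs_hz,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 fir_order = fir_order, zero_phase = zero_phase,
                 notch_q = notch_q),
            class = "filter_config")
}

# biquad band-stop at f0 Hz: standard audio-EQ notch parameterisation
notch_coefficients <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# all filter stages for a given sampling rate
filter_stages <- function(cfg, fs) {
  stages <- lapply(cfg$notch_freqs_hz[cfg$notch_freqs_hz < fs / 2],
                   function(f0) notch_coefficients(f0, fs, cfg$notch_q))
  if (!is.null(cfg$lowpass_cutoff_hz)) {
    if (cfg$lowpass_cutoff_hz >= fs / 2)
      stop("low-pass cutoff (", cfg$lowpass_cutoff_hz,
           " Hz) must be below the Nyquist frequency ", fs / 2, " Hz")
    b <- signal::fir1(cfg$fir_order, cfg$lowpass_cutoff_hz / (fs / 2))
    stages <- c(stages, list(list(b = as.numeric(b), a = 1)))
  }
  stages
}

#' Apply the configured filters to a recording
#'
#' @param rec an [eeg_recording()].
#' @param cfg a [filter_config()].
#' @return A filtered [eeg_recording()] of identical shape.
#' @export
apply_filters <- function(rec, cfg = filter_config()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "filter_config"))
  if (any(cfg$notch_freqs_hz >= rec$fs / 2))
    warning("notch frequencies at or above Nyquist are skipped")
  stages <- filter_stages(cfg, rec$fs)
  x <- rec$signal
  for (st in stages) {
    for (i in seq_len(nrow(x))) {
      x[i, ] <- if (cfg$zero_phase) lti_filtfilt(st$b, st$a, x[i, ])
                else lti_filter(st$b, st$a, x[i, ])
    }
  }
  out <- rec
  out$signal <- x
  out
}

#' Magnitude frequency response of the filter chain
#'
#' Exact transfer-function magnitude of the configured cascade at the
#' requested frequencies; with `zero_phase` the forward-backward application
#' squares each stage's magnitude. Useful for verifying the notch attenuation
#' and passband-loss contracts independently of any signal.
#'
#' @param cfg a [filter_config()].
#' @param fs sampling rate in Hz.
#' @param freqs_hz frequencies at which to evaluate the response.
#' @return numeric vector of magnitude gains (1 = unity).
#' @export
filter_response <- function(cfg, fs, freqs_hz) {
  stages <- filter_stages(cfg, fs)
  w <- 2 * pi * freqs_hz / fs
  h <- rep(1 + 0i, length(w))
  for (st in stages) {
    z <- exp(-1i * outer(w, seq_along(st$b) - 1))
    num <- drop(z %*% st$b)
    den <- if (length(st$a) > 1)
      drop(exp(-1i * outer(w, seq_along(st$a) - 1)) %*% st$a)
    else st$a
    h <- h * num / den
  }
  mag <- Mod(h)
  if (cfg$zero_phase) mag^2 else mag
}
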