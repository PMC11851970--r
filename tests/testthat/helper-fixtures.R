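# shared fixture builders; everything is generated in code at test time

# bare epoch from a channels x samples matrix
make_epoch <- function(data, fs = 256, label = 0L, subject_id = "t",
                       t_start_s = 0) {
  structure(list(data = data, label = as.integer(label),
                 subject_id = subject_id, t_start_s = t_start_s,
                 epoch_len_s = ncol(data) / fs, fs = fs,
                 channel_labels = paste0("CH", seq_len(nrow(data)))),
            class = "eeg_epoch")
}

sinusoid_epoch <- function(freqs_hz, fs = 256, dur_s = 10, n_channels = 2,
                           amplitude = 1) {
  t <- (0:(fs * dur_s - 1)) / fs
  x <- rowSums(sapply(freqs_hz, function(f) amplitude * sin(2 * pi * f * t)))
  make_epoch(matrix(rep(x, each = n_channels), n_channels, byrow = FALSE,
                    ncol = length(x)), fs = fs)
}

# independent direct-DFT band profile oracle: no fft(), plain O(n^2) sums
dft_band_profile_oracle <- function(epoch, window_s = 1, overlap = 0.5,
                                    bands = band_definitions()) {
  x <- epoch$data; fs <- epoch$fs
  n <- round(window_s * fs)
  hop <- round(n * (1 - overlap))
  n_frames <- (ncol(x) - n) %/% hop + 1
  win <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  f <- (0:(n %/% 2)) * fs / n
  out <- matrix(0, nrow(bands), n_frames, dimnames = list(bands$band, NULL))
  for (tt in seq_len(n_frames)) {
    i0 <- (tt - 1) * hop
    per_ch <- matrix(0, nrow(bands), nrow(x))
    for (ch in seq_len(nrow(x))) {
      seg <- x[ch, (i0 + 1):(i0 + n)] * win
      mags <- vapply(0:(n %/% 2), function(k) {
        ang <- -2 * pi * k * (0:(n - 1)) / n
        Mod(sum(seg * complex(real = cos(ang), imaginary = sin(ang))))
      }, numeric(1)) * 2 / sum(win)
      for (b in seq_len(nrow(bands))) {
        bins <- which(f >= bands$low_hz[b] & f < bands$high_hz[b])
        per_ch[b, ch] <- mean(mags[bins])
      }
    }
    out[, tt] <- rowMeans(per_ch)
  }
  out
}

# brute-force majority vote oracle: count of 1s against count of 0s,
# ties resolved toward the positive class
majority_oracle <- function(outputs) {
  ones <- sum(outputs)
  zeros <- length(outputs) - ones
  if (ones > zeros) 1L else if (ones < zeros) 0L else 1L
}

# brute-force AUC: scaled Mann-Whitney U over all (positive, negative) pairs
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(pairs)
}

# small two-state synthetic recording for feature/pipeline tests
small_two_state_spec <- function(n_channels = 4, seed = 1,
                                 alpha_factor = 2, rho_pre = 0.45,
                                 noise_sd = 1, duration_s = 1100) {
  base_amp <- default_band_amplitudes()
  pre_amp <- replace(base_amp, "alpha", alpha_factor * base_amp[["alpha"]])
  synth_spec(
    n_channels = n_channels, fs = 256, duration_s = duration_s,
    band_amplitudes = list(baseline = base_amp, preictal = pre_amp),
    correlation = list(
      baseline = exchangeable_correlation(n_channels, 0.2),
      preictal = exchangeable_correlation(n_channels, rho_pre)),
    noise_sd = noise_sd,
    seizure_onsets_s = duration_s - 50, preictal_window_s = 500,
    seed = seed)
}
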