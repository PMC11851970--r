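test_that("generation is bit-identical under a fixed seed", {
  sp <- synth_spec(n_channels = 3, duration_s = 4, seed = 42)
  r1 <- generate_recording(sp)
  r2 <- generate_recording(sp)
  expect_identical(r1$signal, r2$signal)
  sp2 <- synth_spec(n_channels = 3, duration_s = 4, seed = 43)
  expect_false(identical(generate_recording(sp2)$signal, r1$signal))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_recording(
    synth_spec(n_channels = 2, duration_s = 2, seed = 1)))
  expect_identical(rnorm(3), before)
})

test_that("a non-PSD correlation target is rejected with a diagnostic", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(
    synth_spec(n_channels = 3, correlation = list(baseline = bad,
                                                  preictal = bad)),
    "positive semidefinite")
  asym <- exchangeable_correlation(3, 0.2); asym[1, 2] <- 0.5
  expect_error(
    synth_spec(n_channels = 3, correlation = list(baseline = asym,
                                                  preictal = asym)),
    "symmetric")
})

test_that("identity correlation target gives vanishing off-diagonal Pearson estimates", {
  mk <- function(dur) {
    sp <- synth_spec(
      n_channels = 4, duration_s = dur,
      correlation = list(baseline = diag(4), preictal = diag(4)),
      noise_sd = 0.5, seed = 11)
    rec <- generate_recording(sp)
    est <- cor(t(rec$signal))
    max(abs(est[upper.tri(est)]))
  }
  short <- mk(8); long <- mk(120)
  expect_lt(long, short)       # Frobenius-style convergence with duration
  expect_lt(long, 0.05)
})

test_that("empirical channel correlation converges to the target", {
  target <- exchangeable_correlation(4, 0.35)
  sp <- synth_spec(n_channels = 4, duration_s = 120,
                   correlation = list(baseline = target, preictal = target),
                   noise_sd = 0, seed = 5)
  est <- cor(t(generate_recording(sp)$signal))
  expect_lt(max(abs(est - target)), 0.05)
})

test_that("per-band spectral power ranks follow the specified amplitudes", {
  amps <- c(delta = 1, theta = 5, alpha = 2, beta = 0.5, gamma = 3)
  sp <- synth_spec(n_channels = 2, duration_s = 60,
                   band_amplitudes = list(baseline = amps, preictal = amps),
                   noise_sd = 0, seed = 9)
  rec <- generate_recording(sp)
  # Welch-style band power from averaged periodograms, 2 s segments
  fs <- rec$fs; nseg <- 2 * fs
  x <- rec$signal[1, ]
  nwin <- floor(length(x) / nseg)
  p <- rowMeans(sapply(seq_len(nwin), function(i)
    Mod(fft(x[((i - 1) * nseg + 1):(i * nseg)]))[1:(nseg / 2)]^2))
  f <- (0:(nseg / 2 - 1)) * fs / nseg
  bands <- band_definitions()
  bp <- vapply(seq_len(nrow(bands)), function(b)
    sum(p[f >= bands$low_hz[b] & f < bands$high_hz[b]]), numeric(1))
  expect_identical(order(bp), order(unname(amps)))
})

test_that("doubling the preictal alpha amplitude doubles the alpha profile ratio (oracle band)", {
  # oracle-frozen expectation under the default band mixture: spectral
  # leakage from neighbouring bands dilutes the ratio to ~1.86
  sp <- small_two_state_spec(seed = 321, rho_pre = 0.2)
  rec <- generate_recording(sp)
  es <- cut_epochs(rec, windowing_config(preictal_window_min = 50 / 6,
                                         baseline_gap_min = 0.5, seed = 1))
  lab <- es$manifest$label
  a <- vapply(es$epochs, function(e)
    mean(band_profile(e)$values["alpha", ]), numeric(1))
  ratio <- mean(a[lab == 1]) / mean(a[lab == 0])
  expect_gt(ratio, 1.80)
  expect_lt(ratio, 1.93)
})

test_that("with an alpha-only carrier the doubling ratio is 2 almost exactly", {
  amps <- c(delta = 0, theta = 0, alpha = 2, beta = 0, gamma = 0)
  sp <- synth_spec(
    n_channels = 3, duration_s = 700, noise_sd = 0,
    band_amplitudes = list(baseline = amps,
                           preictal = replace(amps, "alpha", 4)),
    correlation = list(baseline = exchangeable_correlation(3, 0.2),
                       preictal = exchangeable_correlation(3, 0.2)),
    seizure_onsets_s = 650, preictal_window_s = 300, seed = 13)
  es <- cut_epochs(generate_recording(sp),
                   windowing_config(preictal_window_min = 5,
                                    baseline_gap_min = 0.5, seed = 1))
  lab <- es$manifest$label
  a <- vapply(es$epochs, function(e)
    mean(band_profile(e)$values["alpha", ]), numeric(1))
  expect_equal(mean(a[lab == 1]) / mean(a[lab == 0]), 2, tolerance = 0.05)
})

test_that("annotations mirror the requested onsets", {
  sp <- synth_spec(n_channels = 2, duration_s = 30,
                   seizure_onsets_s = c(10, 20), seizure_duration_s = 5,
                   preictal_window_s = 5, seed = 2)
  rec <- generate_recording(sp)
  expect_equal(rec$annotations$start_s, c(10, 20))
  expect_equal(rec$annotations$end_s, c(15, 25))
  expect_equal(dim(rec$signal), c(2, 30 * 256))
})
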