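test_that("a pure 10 Hz tone concentrates in the alpha row at every time step", {
  ep <- sinusoid_epoch(10)
  bp <- band_profile(ep)
  expect_equal(dim(bp$values), c(5, 19))
  alpha <- bp$values["alpha", ]
  for (b in setdiff(rownames(bp$values), "alpha"))
    expect_true(all(alpha > bp$values[b, ]))
  # unit sinusoid at a bin centre: calibrated magnitude 1 at the tone bin
  # plus 0.5 at each Hann-mainlobe neighbour, averaged over 4 alpha bins
  expect_equal(mean(alpha), 2 / 4, tolerance = 0.02)
})

test_that("zero signal gives an all-zero band profile", {
  ep <- make_epoch(matrix(0, 3, 2560))
  expect_equal(max(band_profile(ep)$values), 0)
})

test_that("band profile matches a direct-DFT oracle on a two-tone mixture", {
  ep <- sinusoid_epoch(c(10, 20), dur_s = 2)   # short epoch keeps O(n^2) cheap
  bp <- band_profile(ep)
  oracle <- dft_band_profile_oracle(ep)
  expect_equal(bp$values, oracle, tolerance = 1e-8)
  # equal-amplitude tones: alpha (4 bins) vs beta (17 bins) average scales
  # with bin count; compare the active-bin masses instead
  expect_equal(mean(bp$values["alpha", ]) * 4,
               mean(bp$values["beta", ]) * 17, tolerance = 0.02)
  expect_lt(max(bp$values[c("delta", "theta"), ]),
            0.02 * mean(bp$values["alpha", ]) * 4)
})

test_that("band profile is linear in signal amplitude", {
  ep <- make_epoch(matrix(rnorm(3 * 2560), 3))
  ep3 <- ep; ep3$data <- 3 * ep$data
  expect_equal(band_profile(ep3)$values, 3 * band_profile(ep)$values,
               tolerance = 1e-12)
})

test_that("bands above Nyquist are a configuration error", {
  ep <- make_epoch(matrix(rnorm(2 * 320), 2), fs = 32)
  expect_error(band_profile(ep), "gamma")   # gamma 30-80 at fs 32
})

test_that("correlation map reproduces +/-1 for (anti)identical channels", {
  x <- rnorm(2560)
  ep <- make_epoch(rbind(x, x, -x))
  cm <- correlation_map(ep)$values
  expect_equal(cm[1, 2], 1)
  expect_equal(cm[1, 3], -1)
  expect_equal(cm, t(cm))
  expect_equal(diag(cm), rep(1, 3), ignore_attr = TRUE)
})

test_that("independent channels stay under the analytic null bound", {
  set.seed(77)
  reps <- 40
  rs <- replicate(reps, {
    ep <- make_epoch(matrix(rnorm(2 * 2560), 2))
    correlation_map(ep)$values[1, 2]
  })
  expect_lt(max(abs(rs)), 0.08)               # |r| ~ 2/sqrt(2560) = 0.04
})

test_that("correlation map is invariant to positive affine channel rescaling", {
  ep <- make_epoch(matrix(rnorm(3 * 2560), 3))
  ep2 <- ep
  ep2$data <- ep$data * c(2, 0.3, 7) + c(-5, 1, 100)
  expect_equal(correlation_map(ep2)$values, correlation_map(ep)$values,
               tolerance = 1e-12)
})

test_that("zero-variance channels are zeroed off-diagonal and QC-flagged", {
  ep <- make_epoch(rbind(rnorm(2560), 0))
  cm <- correlation_map(ep)
  expect_equal(cm$values[1, 2], 0)
  expect_equal(cm$values[2, 2], 1)
  expect_equal(attr(cm, "qc")$zero_variance_channels, 2)
})

test_that("baseline profiles average the member epochs exactly", {
  e1 <- make_epoch(matrix(rnorm(2 * 2560), 2), label = 0)
  e2 <- make_epoch(matrix(rnorm(2 * 2560), 2), label = 0)
  bp <- build_baseline_profiles(list(e1, e2))
  expect_equal(bp$mean_band_profile,
               (band_profile(e1)$values + band_profile(e2)$values) / 2)
  expect_equal(bp$mean_correlation_map,
               (correlation_map(e1)$values + correlation_map(e2)$values) / 2)
  expect_equal(bp$n_profiles_used, 2L)
  # identical epochs: mean equals any one of them
  same <- build_baseline_profiles(list(e1, e1))
  expect_equal(same$mean_band_profile, band_profile(e1)$values)
})

test_that("requesting more profiles than available warns and records the truth", {
  eps <- replicate(3, make_epoch(matrix(rnorm(2 * 2560), 2), label = 0),
                   simplify = FALSE)
  expect_warning(bp <- build_baseline_profiles(eps, n_profiles = 1000),
                 "only 3")
  expect_equal(bp$n_profiles_used, 3L)
  expect_error(build_baseline_profiles(list()), "no baseline")
  bad <- make_epoch(matrix(rnorm(2 * 2560), 2), label = 1)
  expect_error(build_baseline_profiles(list(bad)), "label-0")
})

test_that("self-normalization yields all ones; scaling doubles it", {
  e1 <- make_epoch(matrix(rnorm(2 * 2560), 2), label = 0)
  base <- build_baseline_profiles(list(e1))
  n1 <- normalize_profile(band_profile(e1), base)
  expect_equal(max(abs(n1$values - 1)), 0, tolerance = 1e-12)
  e2 <- e1; e2$data <- 2 * e1$data
  n2 <- normalize_profile(band_profile(e2), base)
  expect_equal(max(abs(n2$values - 2)), 0, tolerance = 1e-12)
  expect_true(attr(n1, "normalized"))
})

test_that("near-zero baseline cells are guarded to 1 and QC-counted", {
  e1 <- make_epoch(matrix(rnorm(2 * 2560), 2), label = 0)
  base <- build_baseline_profiles(list(e1))
  base$mean_band_profile[2, 3] <- 0
  base$mean_band_profile[4, 7] <- 1e-12
  n <- normalize_profile(band_profile(e1), base)
  expect_equal(n$values[2, 3], 1, ignore_attr = TRUE)
  expect_equal(n$values[4, 7], 1, ignore_attr = TRUE)
  expect_equal(attr(n, "qc")$n_guarded, 2)
})

test_that("shape mismatches between profile and baseline are an error", {
  e1 <- make_epoch(matrix(rnorm(2 * 2560), 2), label = 0)
  e3 <- make_epoch(matrix(rnorm(3 * 2560), 3), label = 0)
  base <- build_baseline_profiles(list(e1))
  expect_error(normalize_profile(correlation_map(e3), base),
               "shape mismatch")
})

test_that("normalized baseline epochs have per-cell expectation near 1", {
  sp <- small_two_state_spec(n_channels = 3, seed = 55, duration_s = 900)
  # windowing preictal span must match the generator's 500 s state window,
  # or baseline labels would be contaminated by preictal-state signal
  es <- suppressWarnings(   # baseline span is deliberately smaller here
    cut_epochs(generate_recording(sp),
               windowing_config(preictal_window_min = 500 / 60,
                                baseline_gap_min = 0.5, seed = 2)))
  lab <- es$manifest$label
  base_idx <- which(lab == 0)
  base <- build_baseline_profiles(es$epochs[base_idx[1:15]])
  held_out <- base_idx[16:length(base_idx)]
  cell_means <- Reduce(`+`, lapply(held_out, function(i)
    normalize_profile(band_profile(es$epochs[[i]]), base)$values)) /
    length(held_out)
  expect_equal(mean(cell_means), 1, tolerance = 0.05)
})
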