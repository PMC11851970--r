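dummy_recording <- function(onsets_s, dur_s, fs = 32, n_channels = 2,
                            seizure_len_s = 40, subject_id = "dummy") {
  ann <- if (length(onsets_s))
    data.frame(start_s = onsets_s, end_s = onsets_s + seizure_len_s)
  else NULL
  eeg_recording(matrix(0, n_channels, dur_s * fs), fs,
                annotations = ann, subject_id = subject_id)
}

test_that("nine seizures with a 10 min window yield 540 + 540 balanced epochs", {
  onsets <- (155 + 15 * (0:8)) * 60
  rec <- dummy_recording(onsets, dur_s = max(onsets) + 60)
  es <- cut_epochs(rec, windowing_config(epoch_len_s = 10,
                                         preictal_window_min = 10,
                                         baseline_gap_min = 60, seed = 3))
  m <- epoch_manifest(es)
  expect_equal(sum(m$label == 1), 540)          # 9 x 10 x 60 / 10
  expect_equal(sum(m$label == 0), 540)          # down-sampled to balance
})

test_that("a preictal window reaching before the start is truncated and logged", {
  rec <- dummy_recording(300, dur_s = 500)
  expect_warning(
    expect_warning(
      es <- cut_epochs(rec, windowing_config(baseline_gap_min = 1)),
      "truncated"),
    "fewer eligible baseline")
  expect_equal(sum(epoch_manifest(es)$label == 1), 30)   # 300 s / 10 s
})

test_that("epoch tiling is exhaustive, non-overlapping, and clear of seizures", {
  rec <- dummy_recording(c(2000, 2800), dur_s = 3600, seizure_len_s = 60)
  cfg <- windowing_config(preictal_window_min = 10, baseline_gap_min = 5,
                          seed = 7)
  m <- epoch_manifest(cut_epochs(rec, cfg))
  pre <- sort(m$t_start_s[m$label == 1])
  # count = floor(window_s / epoch_len_s) per seizure, minus seizure overlap
  expect_equal(length(pre), 2 * 60)
  expect_true(all(diff(pre) >= 10 - 1e-9))      # non-overlapping
  ann <- rec$annotations
  for (i in seq_len(nrow(m)))
    expect_false(any(m$t_start_s[i] < ann$end_s &
                     m$t_start_s[i] + 10 > ann$start_s))
  # preictal windows tile back from onset: last epoch ends at the onset
  expect_true(all(c(1990, 2790) %in% pre))
})

test_that("baseline epochs respect the guard distance and balance per subject", {
  rec <- dummy_recording(5000, dur_s = 7200)
  cfg <- windowing_config(preictal_window_min = 10, baseline_gap_min = 30,
                          seed = 1)
  m <- epoch_manifest(cut_epochs(rec, cfg))
  base <- m$t_start_s[m$label == 0]
  expect_equal(length(base), sum(m$label == 1))
  expect_true(all(base + 10 <= 5000 - 1800 + 1e-9 | base >= 5040 + 1800 - 1e-9))
})

test_that("baseline down-sampling is seeded and reproducible", {
  rec <- dummy_recording(5000, dur_s = 7200)
  cfg <- windowing_config(baseline_gap_min = 30, seed = 5)
  m1 <- epoch_manifest(cut_epochs(rec, cfg))
  m2 <- epoch_manifest(cut_epochs(rec, cfg))
  expect_identical(m1, m2)
  m3 <- epoch_manifest(cut_epochs(rec, windowing_config(baseline_gap_min = 30,
                                                        seed = 6)))
  expect_false(identical(m1$t_start_s, m3$t_start_s))
})

test_that("a recording shorter than one epoch yields an empty set with warning", {
  rec <- dummy_recording(numeric(0), dur_s = 5)
  expect_warning(es <- cut_epochs(rec, windowing_config()), "shorter")
  expect_equal(nrow(epoch_manifest(es)), 0)
})

test_that("epoch data slices match the source recording", {
  fs <- 32
  sig <- matrix(seq_len(2 * 600 * fs), 2, byrow = TRUE, ncol = 600 * fs)
  rec <- eeg_recording(sig, fs, subject_id = "s",
                       annotations = data.frame(start_s = 550, end_s = 590))
  es <- cut_epochs(rec, windowing_config(preictal_window_min = 2,
                                         baseline_gap_min = 2, seed = 1))
  ep <- es$epochs[[which(es$manifest$label == 1)[1]]]
  i0 <- round(ep$t_start_s * fs) + 1
  expect_equal(ep$data, sig[, i0:(i0 + 10 * fs - 1)], ignore_attr = TRUE)
  expect_equal(ncol(ep$data), 10 * fs)
})
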