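write_test_recording <- function(n_channels = 3, dur_s = 6, fs = 256,
                                 seed = 4) {
  sp <- synth_spec(n_channels = n_channels, fs = fs, duration_s = dur_s,
                   seed = seed)
  rec <- generate_recording(sp)
  path <- withr::local_tempfile(fileext = ".edf",
                                .local_envir = parent.frame())
  write_edf(rec, path)
  list(rec = rec, path = path)
}

test_that("EDF write/read round-trips within 16-bit quantization", {
  tc <- write_test_recording()
  back <- read_recording(tc$path, expected_fs = 256)
  qstep <- max(apply(tc$rec$signal, 1, function(x) diff(range(x)))) / 65535
  expect_lt(max(abs(back$signal - tc$rec$signal)), qstep)
  expect_identical(back$channel_labels, tc$rec$channel_labels)
  expect_equal(back$fs, 256)
})

test_that("selecting the full label list reproduces the file content", {
  tc <- write_test_recording()
  all_sel <- read_recording(tc$path, channel_selection = tc$rec$channel_labels,
                            expected_fs = 256)
  default <- read_recording(tc$path, expected_fs = 256)
  expect_identical(all_sel$signal, default$signal)
})

test_that("channel selection is honoured in order and misses are named", {
  tc <- write_test_recording()
  sel <- read_recording(tc$path, channel_selection = c("SYN3", "SYN1"),
                        expected_fs = 256)
  expect_identical(sel$channel_labels, c("SYN3", "SYN1"))
  full <- read_recording(tc$path, expected_fs = 256)
  expect_identical(sel$signal[1, ], full$signal[3, ])
  expect_identical(sel$signal[2, ], full$signal[1, ])
  expect_error(read_recording(tc$path, channel_selection = c("SYN1", "FZ-CZ"),
                              expected_fs = 256),
               "FZ-CZ")
})

test_that("an unexpected header sampling rate warns and is logged", {
  tc <- write_test_recording(fs = 256)
  expect_warning(rec <- read_recording(tc$path, expected_fs = 512), "512")
  expect_true(attr(rec, "provenance")$fs_mismatch)
})

test_that("summary parser handles zero, one, and out-of-order seizures", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_chbmit_summary(list(
    "chb01_03.edf" = data.frame(start_s = 2996, end_s = 3036),
    "chb01_04.edf" = data.frame(start_s = numeric(0), end_s = numeric(0))),
    path)
  one <- read_annotations(path, "chb01_03.edf")
  expect_equal(one$start_s, 2996)
  expect_equal(one$end_s, 3036)
  expect_equal(nrow(read_annotations(path, "chb01_04.edf")), 0)

  # hand-written dialect variant without seizure indices, listed out of order
  writeLines(c("Data Sampling Rate: 256 Hz", "",
               "File Name: chb02_01.edf",
               "Number of Seizures in File: 2",
               "Seizure Start Time: 500 seconds",
               "Seizure End Time: 540 seconds",
               "Seizure Start Time: 100 seconds",
               "Seizure End Time: 130 seconds"), path)
  two <- read_annotations(path, "chb02_01.edf")
  expect_equal(two$start_s, c(100, 500))
  expect_equal(two$end_s, c(130, 540))
})

test_that("declared seizures without times are a parse error", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("File Name: chb03_01.edf",
               "Number of Seizures in File: 1"), path)
  expect_error(read_annotations(path, "chb03_01.edf"), "missing")
  expect_error(read_annotations(path, "not_there.edf"), "not listed")
})

test_that("duplicate channel labels resolve to the first occurrence", {
  sp <- synth_spec(n_channels = 3, duration_s = 2, seed = 6)
  rec <- generate_recording(sp)
  rec$channel_labels <- c("A", "B", "A")
  rownames(rec$signal) <- rec$channel_labels
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  expect_message(sel <- read_recording(path, channel_selection = c("A", "B"),
                                       expected_fs = 256),
                 "first occurrence")
  qstep <- diff(range(rec$signal[1, ])) / 65535
  expect_lt(max(abs(sel$signal[1, ] - rec$signal[1, ])), qstep)
})
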