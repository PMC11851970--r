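#' STFT configuration
#'
#' Short-time Fourier transform parameters for the band-profile features:
#' a Hann window of `window_s` seconds with fractional `overlap`. The
#' defaults (1 s window, 50% overlap) resolve the 0.5 Hz delta edge while
#' giving 19 time steps per 10 s epoch at 256 Hz.
#'
#' @param window_s analysis window length in seconds.
#' @param overlap fractional window overlap in `[0, 1)`.
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(window_s = 1, overlap = 0.5) {
  stopifnot(window_s > 0, overlap >= 0, overlap < 1)
  structure(list(window_s = window_s, overlap = overlap),
            class = "stft_config")
}

# frequency bins (rows) falling in each band, for an N-point DFT at fs;
# assignment is half-open [low, high)
band_bins <- function(bands, n, fs) {
  f <- (0:(n %/% 2)) * fs / n
  out <- lapply(seq_len(nrow(bands)), function(b) {
    which(f >= bands$low_hz[b] & f < bands$high_hz[b])
  })
  names(out) <- bands$band
  out
}

#' STFT band-amplitude profile of an epoch
#'
#' Decomposes the epoch with a Hann-windowed short-time Fourier transform and
#' averages spectral magnitude over each band's frequency bins and over
#' channels, giving a bands x time-steps matrix (rows ordered as in
#' `bands`). Magnitudes are scaled so a unit-amplitude sinusoid at a bin
#' centre reads approximately 1.
#'
#' @param epoch an `eeg_epoch` (or any list with `data` and `fs`).
#' @param cfg an [stft_config()].
#' @param bands band table as from [band_definitions()]. Any band lying
#'   entirely at or above the Nyquist frequency is a configuration error.
#' @return An object of class `band_profile`: list with `values`
#'   (bands x T matrix), `band_order`, `time_step_s`.
#' @export
band_profile <- function(epoch, cfg = stft_config(),
                         bands = band_definitions()) {
  x <- epoch$data
  fs <- epoch$fs
  if (any(bands$low_hz >= fs / 2))
    stop("band(s) entirely above the Nyquist frequency: ",
         paste(bands$band[bands$low_hz >= fs / 2], collapse = ", "))
  n <- round(cfg$window_s * fs)
  hop <- max(1L, round(n * (1 - cfg$overlap)))
  n_samp <- ncol(x)
  if (n_samp < n) stop("epoch shorter than one STFT window")
  n_frames <- (n_samp - n) %/% hop + 1L
  win <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))   # periodic Hann
  bb <- band_bins(bands, n, fs)
  nch <- nrow(x)
  # one DFT call per epoch: columns are (frame, channel) windowed segments
  segs <- matrix(0, n, n_frames * nch)
  for (t in seq_len(n_frames)) {
    i0 <- (t - 1L) * hop
    seg <- t(x[, (i0 + 1L):(i0 + n), drop = FALSE]) * win
    segs[, ((t - 1L) * nch + 1L):(t * nch)] <- seg
  }
  mag <- Mod(stats::mvfft(segs))[1:(n %/% 2 + 1), , drop = FALSE]
  mag <- mag * (2 / sum(win))             # amplitude calibration
  vals <- matrix(0, nrow(bands), n_frames,
                 dimnames = list(bands$band, NULL))
  for (b in seq_len(nrow(bands))) {
    bm <- mag[bb[[b]], , drop = FALSE]
    per_col <- colMeans(bm)               # mean over band bins
    vals[b, ] <- colMeans(matrix(per_col, nch, n_frames))  # mean over channels
  }
  structure(list(values = vals, band_order = bands$band,
                 time_step_s = hop / fs),
            class = "band_profile")
}

#' Pearson channel-correlation map of an epoch
#'
#' Standard Pearson correlation between every pair of channels over the
#' epoch's samples. A zero-variance channel has an undefined correlation; its
#' off-diagonal row/column is set to 0 and the channel is recorded in the
#' result's `qc` attribute.
#'
#' @param epoch an `eeg_epoch`.
#' @return An object of class `correlation_map`: list with `values` (C x C
#'   symmetric matrix, unit diagonal) and `channel_order`.
#' @export
correlation_map <- function(epoch) {
  x <- epoch$data
  if (ncol(x) < 2) stop("need at least 2 samples per channel")
  sds <- apply(x, 1, stats::sd)
  flat <- which(sds == 0)
  vals <- suppressWarnings(stats::cor(t(x)))
  if (length(flat)) {
    vals[flat, ] <- 0
    vals[, flat] <- 0
  }
  diag(vals) <- 1
  dimnames(vals) <- list(epoch$channel_labels, epoch$channel_labels)
  out <- structure(list(values = vals,
                        channel_order = epoch$channel_labels %||%
                          paste0("CH", seq_len(nrow(x)))),
                   class = "correlation_map")
  if (length(flat)) attr(out, "qc") <- list(zero_variance_channels = flat)
  out
}

#' Per-subject baseline feature averages
#'
#' Element-wise means of the band profile and the correlation map over a set
#' of baseline (label 0) epochs from one subject. These averages are the
#' divisor in [normalize_profile()], standardising each epoch's features
#' against the subject's own non-epileptic activity.
#'
#' @param epochs list of `eeg_epoch` objects, all label 0, one subject.
#' @param n_profiles number of baseline epochs to average (default all
#'   available; a request exceeding availability is honoured with a warning
#'   and `n_profiles_used` records the truth).
#' @param cfg,bands passed to [band_profile()].
#' @return An object of class `baseline_profiles`: `subject_id`,
#'   `mean_band_profile`, `mean_correlation_map`, `n_profiles_used`.
#' @export
build_baseline_profiles <- function(epochs, n_profiles = Inf,
                                    cfg = stft_config(),
                                    bands = band_definitions()) {
  if (!length(epochs)) stop("no baseline epochs supplied")
  labs <- vapply(epochs, function(e) e$label, integer(1))
  if (any(labs != 0L)) stop("baseline profiles must use label-0 epochs only")
  subj <- unique(vapply(epochs, function(e) e$subject_id, ""))
  if (length(subj) != 1L) stop("baseline epochs span multiple subjects: ",
                               paste(subj, collapse = ", "))
  n_use <- min(n_profiles, length(epochs))
  if (is.finite(n_profiles) && n_profiles > length(epochs))
    warning("requested ", n_profiles, " baseline profiles but only ",
            length(epochs), " epochs are available")
  use <- epochs[seq_len(n_use)]
  bp <- lapply(use, band_profile, cfg = cfg, bands = bands)
  cm <- lapply(use, correlation_map)
  mean_bp <- Reduce(`+`, lapply(bp, `[[`, "values")) / n_use
  mean_cm <- Reduce(`+`, lapply(cm, `[[`, "values")) / n_use
  structure(list(subject_id = subj, mean_band_profile = mean_bp,
                 mean_correlation_map = mean_cm,
                 n_profiles_used = as.integer(n_use)),
            class = "baseline_profiles")
}

#' Normalize a feature profile against the subject baseline
#'
#' Element-wise division of the epoch's feature matrix by the corresponding
#' baseline average. Cells whose baseline mean has magnitude below `eps` are
#' set to 1 (the "no change" ratio) and counted in the result's `qc`
#' attribute, keeping the division total.
#'
#' @param x a `band_profile` or `correlation_map`.
#' @param baseline a [build_baseline_profiles()] result of matching shape.
#' @param eps guard threshold for near-zero baseline cells.
#' @return An object of the same class as `x`, with attribute
#'   `normalized = TRUE` and a `qc` attribute counting guarded cells.
#' @export
normalize_profile <- function(x, baseline, eps = 1e-8) {
  UseMethod("normalize_profile")
}

normalize_values <- function(vals, ref, eps) {
  if (!all(dim(vals) == dim(ref)))
    stop("shape mismatch: profile is ", paste(dim(vals), collapse = "x"),
         ", baseline mean is ", paste(dim(ref), collapse = "x"))
  guard <- abs(ref) < eps
  out <- vals / ref
  out[guard] <- 1
  list(values = out, n_guarded = sum(guard))
}

#' @export
normalize_profile.band_profile <- function(x, baseline, eps = 1e-8) {
  stopifnot(inherits(baseline, "baseline_profiles"))
  nv <- normalize_values(x$values, baseline$mean_band_profile, eps)
  x$values <- nv$values
  attr(x, "normalized") <- TRUE
  attr(x, "qc") <- list(n_guarded = nv$n_guarded)
  x
}

#' @export
normalize_profile.correlation_map <- function(x, baseline, eps = 1e-8) {
  stopifnot(inherits(baseline, "baseline_profiles"))
  nv <- normalize_values(x$values, baseline$mean_correlation_map, eps)
  x$values <- nv$values
  attr(x, "normalized") <- TRUE
  attr(x, "qc") <- list(n_guarded = nv$n_guarded)
  x
}
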