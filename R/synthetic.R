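#' Canonical EEG frequency bands
#'
#' Band edges used throughout the pipeline: delta 0.5-4, theta 4-8,
#' alpha 8-12, beta 13-30, gamma 30-80 Hz. Bin/band assignment everywhere is
#' half-open `[low, high)`.
#'
#' @return data frame with columns `band`, `low_hz`, `high_hz`.
#' @export
band_definitions <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz = c(0.5, 4, 8, 13, 30),
    high_hz = c(4, 8, 12, 30, 80))
}

#' Default per-band carrier amplitudes for synthetic EEG
#'
#' Relative amplitudes (arbitrary microvolt-scale units) with the usual
#' roughly 1/f fall-off of scalp EEG: delta strongest, gamma weakest.
#'
#' @return named numeric vector over the five bands.
#' @export
default_band_amplitudes <- function() {
  c(delta = 4, theta = 2, alpha = 2, beta = 1, gamma = 0.5)
}

#' Exchangeable channel-correlation matrix
#'
#' @param n_channels number of channels.
#' @param rho common off-diagonal correlation.
#' @return `n_channels` x `n_channels` correlation matrix.
#' @export
exchangeable_correlation <- function(n_channels, rho) {
  stopifnot(n_channels >= 2, rho > -1 / (n_channels - 1), rho < 1)
  m <- matrix(rho, n_channels, n_channels)
  diag(m) <- 1
  m
}

#' Specification for a synthetic EEG recording
#'
#' Describes a multichannel recording with two latent states: baseline, and a
#' preictal state occupying the `preictal_window_s` seconds before each listed
#' seizure onset. Each state has its own per-band carrier amplitudes and its
#' own target inter-channel correlation; the generator realises each band as
#' band-limited Gaussian noise and imposes the correlation by Cholesky mixing,
#' so a long realisation's empirical channel correlation converges to the
#' target.
#'
#' @param n_channels number of channels (>= 2; default 21).
#' @param fs sampling rate in Hz (default 256; must exceed twice the highest
#'   band edge).
#' @param duration_s recording length in seconds.
#' @param band_amplitudes list with elements `baseline` and `preictal`, each a
#'   named numeric vector of carrier amplitudes over the bands of
#'   [band_definitions()].
#' @param correlation list with elements `baseline` and `preictal`, each a
#'   symmetric positive-semidefinite correlation matrix (unit diagonal) of
#'   size `n_channels`.
#' @param noise_sd standard deviation of additive white sensor noise.
#' @param seizure_onsets_s sorted vector of seizure onset times in seconds.
#' @param preictal_window_s length of the preictal state before each onset
#'   (default 600 s = 10 min).
#' @param seizure_duration_s nominal seizure length written to the
#'   annotations (default 40 s).
#' @param seed integer seed; a fixed seed makes the realisation bit-identical.
#'
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_channels = 21, fs = 256, duration_s = 600,
                       band_amplitudes = list(
                         baseline = default_band_amplitudes(),
                         preictal = default_band_amplitudes()),
                       correlation = list(
                         baseline = exchangeable_correlation(n_channels, 0.2),
                         preictal = exchangeable_correlation(n_channels, 0.2)),
                       noise_sd = 1, seizure_onsets_s = numeric(0),
                       preictal_window_s = 600, seizure_duration_s = 40,
                       seed = 1L) {
  if (n_channels < 2) stop("n_channels must be >= 2")
  bands <- band_definitions()
  if (fs <= 2 * max(bands$high_hz))
    stop("fs must exceed twice the highest band edge (",
         2 * max(bands$high_hz), " Hz)")
  for (st in c("baseline", "preictal")) {
    amps <- band_amplitudes[[st]]
    if (is.null(amps) || !all(bands$band %in% names(amps)))
      stop("band_amplitudes$", st, " must name every band")
    cm <- correlation[[st]]
    if (is.null(cm) || !is.matrix(cm) ||
        nrow(cm) != n_channels || ncol(cm) != n_channels)
      stop("correlation$", st, " must be a ", n_channels, " x ",
           n_channels, " matrix")
    if (max(abs(cm - t(cm))) > 1e-8 || max(abs(diag(cm) - 1)) > 1e-8)
      stop("correlation$", st, " must be symmetric with unit diagonal")
    ev <- min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      stop("correlation$", st, " is not positive semidefinite ",
           "(smallest eigenvalue ", signif(ev, 3), ")")
  }
  if (is.unsorted(seizure_onsets_s, strictly = TRUE) && length(seizure_onsets_s) > 1)
    stop("seizure_onsets_s must be strictly increasing")
  if (length(seizure_onsets_s) &&
      (min(seizure_onsets_s) < 0 || max(seizure_onsets_s) > duration_s))
    stop("seizure_onsets_s must lie within [0, duration_s]")
  structure(
    list(n_channels = n_channels, fs = fs, duration_s = duration_s,
         band_amplitudes = band_amplitudes, correlation = correlation,
         noise_sd = noise_sd, seizure_onsets_s = seizure_onsets_s,
         preictal_window_s = preictal_window_s,
         seizure_duration_s = seizure_duration_s, seed = as.integer(seed)),
    class = "synth_spec")
}

# run code with a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# band-limited Gaussian noise: white noise band-pass filtered to [low, high),
# one column per channel source, each column rescaled to unit sd
band_noise <- function(n, n_channels, low, high, fs) {
  src <- matrix(stats::rnorm(n * n_channels), n, n_channels)
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  for (j in seq_len(n_channels)) {
    y <- lti_filter(bf$b, bf$a, src[, j])
    s <- stats::sd(y)
    src[, j] <- if (s > 0) y / s else y
  }
  src
}

#' Generate a synthetic EEG recording
#'
#' Realises a [synth_spec()]: per state segment, each frequency band is
#' band-limited Gaussian noise mixed across channels through the Cholesky
#' factor of that state's correlation target, scaled by that state's band
#' amplitude, summed over bands, plus white sensor noise. Segments in the
#' `preictal_window_s` before each onset (and the seizure span itself) carry
#' the preictal parameters; everything else carries baseline parameters.
#' Annotations list each seizure as `[onset, onset + seizure_duration_s)`.
#'
#' @param spec a [synth_spec()].
#' @return An [eeg_recording()] of shape `n_channels` x `fs * duration_s`.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  bands <- band_definitions()
  # state per segment: 0 baseline, 1 preictal (seizure span kept preictal-like)
  bounds_s <- c(0, spec$duration_s)
  for (on in spec$seizure_onsets_s) {
    bounds_s <- c(bounds_s, max(0, on - spec$preictal_window_s),
                  min(spec$duration_s, on + spec$seizure_duration_s))
  }
  bounds_s <- sort(unique(bounds_s))
  chol_f <- lapply(spec$correlation, function(m) {
    # PSD (possibly singular) targets: symmetrise eigenvalues at zero
    e <- eigen(m, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  })
  sig <- matrix(0, n, spec$n_channels)
  with_private_seed(spec$seed, {
    for (k in seq_len(length(bounds_s) - 1L)) {
      i0 <- round(bounds_s[k] * fs) + 1L
      i1 <- round(bounds_s[k + 1L] * fs)
      if (i1 < i0) next
      len <- i1 - i0 + 1L
      mid <- (bounds_s[k] + bounds_s[k + 1L]) / 2
      pre <- any(spec$seizure_onsets_s - mid > 0 &
                   spec$seizure_onsets_s - mid <= spec$preictal_window_s) ||
        any(mid - spec$seizure_onsets_s >= 0 &
              mid - spec$seizure_onsets_s < spec$seizure_duration_s)
      st <- if (pre) "preictal" else "baseline"
      amps <- spec$band_amplitudes[[st]]
      mix <- chol_f[[st]]
      seg <- matrix(0, len, spec$n_channels)
      for (b in seq_len(nrow(bands))) {
        carrier <- band_noise(len, spec$n_channels,
                              bands$low_hz[b], bands$high_hz[b], fs)
        seg <- seg + amps[[bands$band[b]]] * (carrier %*% t(mix))
      }
      if (spec$noise_sd > 0)
        seg <- seg + spec$noise_sd *
          matrix(stats::rnorm(len * spec$n_channels), len, spec$n_channels)
      sig[i0:i1, ] <- seg
    }
  })
  ann <- if (length(spec$seizure_onsets_s)) {
    data.frame(start_s = spec$seizure_onsets_s,
               end_s = pmin(spec$duration_s,
                            spec$seizure_onsets_s + spec$seizure_duration_s))
  } else NULL
  eeg_recording(t(sig), fs,
                channel_labels = paste0("SYN", seq_len(spec$n_channels)),
                annotations = ann,
                subject_id = attr(spec, "subject_id") %||% "synthetic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic cohort specifications
#'
#' A cohort of synthetic subjects used for end-to-end evaluation of the
#' pipeline. Each subject has a 66-minute, 21-channel, 256 Hz recording with
#' two seizures (onsets at 50 and 65 min), giving a 10-min preictal window and
#' 120 preictal epochs per subject; with a 30-min baseline guard this leaves
#' exactly 120 baseline epochs, so classes balance deterministically.
#'
#' In the `"strong"` scenario the preictal state doubles the alpha-band
#' amplitude and raises the exchangeable channel correlation from 0.2 to
#' 0.45; in the `"null"` scenario preictal parameters equal baseline
#' parameters, so classifier accuracy should sit at chance.
#'
#' @param n_subjects number of subjects (default 8).
#' @param scenario `"strong"` or `"null"`.
#' @param seed integer seed; subject `i` uses `seed * 100 + i`.
#' @param n_channels channels per subject (default 21).
#' @return list of [synth_spec()] objects, one per subject, each carrying a
#'   `subject_id` attribute.
#' @export
synthetic_cohort_specs <- function(n_subjects = 8,
                                   scenario = c("strong", "null"),
                                   seed = 1L, n_channels = 21) {
  scenario <- match.arg(scenario)
  base_amp <- default_band_amplitudes()
  pre_amp <- base_amp
  base_cor <- exchangeable_correlation(n_channels, 0.2)
  pre_cor <- base_cor
  if (scenario == "strong") {
    pre_amp[["alpha"]] <- 2 * base_amp[["alpha"]]
    pre_cor <- exchangeable_correlation(n_channels, 0.45)
  }
  lapply(seq_len(n_subjects), function(i) {
    sp <- synth_spec(
      n_channels = n_channels, fs = 256, duration_s = 66 * 60,
      band_amplitudes = list(baseline = base_amp, preictal = pre_amp),
      correlation = list(baseline = base_cor, preictal = pre_cor),
      noise_sd = 1,
      seizure_onsets_s = c(50, 65) * 60,
      preictal_window_s = 600,
      seed = as.integer(seed) * 100L + i)
    attr(sp, "subject_id") <- sprintf("synth%02d", i)
    sp
  })
}
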