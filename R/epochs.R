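#' Epoching configuration
#'
#' Rules for cutting a recording into labeled epochs: the
#' `preictal_window_min` minutes ending at each seizure onset are tiled with
#' non-overlapping `epoch_len_s` epochs labeled 1 (preictal); baseline
#' (label 0) epochs are tiled from spans at least `baseline_gap_min` minutes
#' away from every seizure, then down-sampled (seeded) to match the preictal
#' count per subject.
#'
#' @param epoch_len_s epoch length in seconds (default 10; 20 for the coarse
#'   segmentation ablation arm).
#' @param preictal_window_min preictal window in minutes, typically 10, 20 or
#'   30 (default 10).
#' @param baseline_gap_min minimum distance (minutes) between a baseline
#'   epoch and any seizure interval (default 60), guarding the negative class
#'   against preictal/postictal contamination.
#' @param seed seed for the baseline down-sampling draw.
#' @return An object of class `windowing_config`.
#' @export
windowing_config <- function(epoch_len_s = 10, preictal_window_min = 10,
                             baseline_gap_min = 60, seed = 1L) {
  stopifnot(epoch_len_s > 0, preictal_window_min > 0, baseline_gap_min >= 0)
  structure(list(epoch_len_s = epoch_len_s,
                 preictal_window_min = preictal_window_min,
                 baseline_gap_min = baseline_gap_min, seed = as.integer(seed)),
            class = "windowing_config")
}

new_epoch <- function(rec, t_start_s, label, epoch_len_s) {
  i0 <- round(t_start_s * rec$fs) + 1L
  n <- round(epoch_len_s * rec$fs)
  structure(
    list(data = rec$signal[, i0:(i0 + n - 1L), drop = FALSE],
         label = as.integer(label), subject_id = rec$subject_id,
         t_start_s = t_start_s, epoch_len_s = epoch_len_s, fs = rec$fs,
         channel_labels = rec$channel_labels),
    class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> subject '%s' label %d, t = %.0f s, %d ch x %.0f s at %g Hz\n",
              x$subject_id, x$label, x$t_start_s, nrow(x$data),
              x$epoch_len_s, x$fs))
  invisible(x)
}

# intervals [t, t+len) tiling [from, to) starting at `from`
tile_starts <- function(from, to, len) {
  k <- floor((to - from) / len + 1e-9)
  if (k < 1) return(numeric(0))
  from + (seq_len(k) - 1) * len
}

overlaps_any <- function(starts, len, intervals) {
  if (!NROW(intervals) || !length(starts)) return(rep(FALSE, length(starts)))
  sapply(starts, function(s)
    any(s < intervals$end_s & (s + len) > intervals$start_s))
}

#' Cut a recording into labeled baseline/preictal epochs
#'
#' Preictal epochs tile the configured window backwards from each seizure
#' onset, so the last epoch always ends exactly at onset; windows extending
#' before the recording start are truncated (with a warning). No epoch ever
#' overlaps a seizure interval. Baseline epochs tile the spans further than
#' the baseline guard from every seizure and are down-sampled (seeded,
#' uniform) to match the preictal count.
#'
#' @param rec an [eeg_recording()] with annotations.
#' @param cfg a [windowing_config()].
#' @return An object of class `epoch_set`: a list with elements `epochs`
#'   (list of `eeg_epoch`) and `manifest` (data frame with `subject_id`,
#'   `label`, `t_start_s`, `epoch_len_s`).
#' @export
cut_epochs <- function(rec, cfg = windowing_config()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "windowing_config"))
  dur <- recording_duration(rec)
  len <- cfg$epoch_len_s
  if (dur < len) {
    warning("recording shorter than one epoch; returning empty epoch set")
    return(empty_epoch_set(rec, cfg))
  }
  ann <- rec$annotations
  win_s <- cfg$preictal_window_min * 60
  gap_s <- cfg$baseline_gap_min * 60

  pre_starts <- numeric(0)
  for (on in ann$start_s) {
    k <- floor(win_s / len + 1e-9)
    st <- on - seq_len(k) * len          # tiled backwards from onset
    n_trunc <- sum(st < -1e-9)
    if (n_trunc > 0)
      warning(sprintf("preictal window before onset at %g s truncated at recording start (%d epoch(s) dropped)",
                      on, n_trunc))
    st <- st[st >= -1e-9]
    st <- st[!overlaps_any(st, len, ann)]   # never overlap a seizure
    pre_starts <- c(pre_starts, st)
  }
  pre_starts <- sort(unique(round(pre_starts, 9)))

  # baseline spans: complement of seizure intervals inflated by the guard,
  # with preictal windows excluded as well (relevant when guard < window)
  excl <- ann
  if (NROW(ann)) {
    excl <- data.frame(start_s = ann$start_s - pmax(gap_s, win_s),
                       end_s = ann$end_s + gap_s)
  }
  base_starts <- setdiff_tile(dur, excl, len)
  if (length(pre_starts))
    base_starts <- base_starts[!overlaps_any(base_starts, len,
      data.frame(start_s = pre_starts, end_s = pre_starts + len))]

  n_pre <- length(pre_starts)
  if (length(base_starts) > n_pre && n_pre > 0) {
    base_starts <- with_private_seed(cfg$seed,
      sort(sample(base_starts, n_pre)))
  } else if (length(base_starts) < n_pre) {
    warning("fewer eligible baseline epochs (", length(base_starts),
            ") than preictal epochs (", n_pre, "); classes are unbalanced")
  }

  epochs <- c(lapply(base_starts, function(s) new_epoch(rec, s, 0L, len)),
              lapply(pre_starts, function(s) new_epoch(rec, s, 1L, len)))
  manifest <- data.frame(
    subject_id = rec$subject_id,
    label = c(rep(0L, length(base_starts)), rep(1L, length(pre_starts))),
    t_start_s = c(base_starts, pre_starts),
    epoch_len_s = len)
  structure(list(epochs = epochs, manifest = manifest, config = cfg),
            class = "epoch_set")
}

empty_epoch_set <- function(rec, cfg) {
  structure(list(epochs = list(),
                 manifest = data.frame(subject_id = character(0),
                                       label = integer(0),
                                       t_start_s = numeric(0),
                                       epoch_len_s = numeric(0)),
                 config = cfg),
            class = "epoch_set")
}

# tile [0, dur) with len-second epochs avoiding the exclusion intervals
setdiff_tile <- function(dur, excl, len) {
  free <- data.frame(start_s = 0, end_s = dur)
  if (NROW(excl)) {
    pts <- sort(unique(c(0, dur, pmax(0, pmin(dur, c(excl$start_s, excl$end_s))))))
    free <- data.frame(start_s = pts[-length(pts)], end_s = pts[-1])
    keep <- sapply(seq_len(nrow(free)), function(i) {
      mid <- (free$start_s[i] + free$end_s[i]) / 2
      !any(mid >= excl$start_s & mid < excl$end_s)
    })
    free <- free[keep, , drop = FALSE]
  }
  unlist(lapply(seq_len(nrow(free)), function(i)
    tile_starts(free$start_s[i], free$end_s[i], len)), use.names = FALSE)
}

#' @export
print.epoch_set <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<epoch_set> %d epochs (%d baseline, %d preictal) of %g s, subject '%s'\n",
              nrow(m), sum(m$label == 0), sum(m$label == 1),
              if (nrow(m)) m$epoch_len_s[1] else x$config$epoch_len_s,
              if (nrow(m)) m$subject_id[1] else ""))
  invisible(x)
}

#' Manifest table of an epoch set
#' @param es an `epoch_set` from [cut_epochs()].
#' @return data frame with one row per epoch.
#' @export
epoch_manifest <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  es$manifest
}
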