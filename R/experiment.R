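#' Pipeline experiment configuration
#'
#' Bundles every stage's settings for [run_experiment()]. Subjects come
#' either from a list of [synth_spec()]s (synthetic cohort) or from EDF files
#' with a seizure-summary file.
#'
#' @param subjects list of [synth_spec()] objects, or a data frame with
#'   columns `path`, `subject_id` (and optionally `summary_path`) naming EDF
#'   files.
#' @param windowing a [windowing_config()].
#' @param filters a [filter_config()]. Following the feature definitions,
#'   band features are computed from the notch-filtered signal; the low-pass
#'   stage is applied only when the gamma band is disabled (`use_gamma =
#'   FALSE`), since a 35 Hz low-pass would structurally zero the 30-80 Hz
#'   row.
#' @param stft an [stft_config()].
#' @param backbone_id registered backbone for feature extraction.
#' @param ensemble list with `n_members`, `cfg` ([svm_config()]) and
#'   `diversity`.
#' @param split list with `ratios`, `method`.
#' @param arm ablation arm: `"full"` (default), `"backbone"` (swap in
#'   `ablation_backbone_id`), `"single-svm"` (one member), `"no-vote"`
#'   (report mean per-member accuracy instead of the voted one), `"seg20"`
#'   (20 s epochs).
#' @param ablation_backbone_id backbone used by the `"backbone"` arm.
#' @param use_gamma keep the gamma band (default `TRUE`).
#' @param channel_selection channel labels to read from EDF files.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(subjects,
                              windowing = windowing_config(),
                              filters = filter_config(),
                              stft = stft_config(),
                              backbone_id = "tinycnn",
                              ensemble = list(n_members = 6,
                                              cfg = svm_config(),
                                              diversity = "folds"),
                              split = list(ratios = c(0.6, 0.2, 0.2),
                                           method = "blocked"),
                              arm = c("full", "backbone", "single-svm",
                                      "no-vote", "seg20"),
                              ablation_backbone_id = "blockmean",
                              use_gamma = TRUE,
                              channel_selection = NULL,
                              seed = 1L) {
  arm <- match.arg(arm)
  structure(list(subjects = subjects, windowing = windowing,
                 filters = filters, stft = stft, backbone_id = backbone_id,
                 ensemble = ensemble, split = split, arm = arm,
                 ablation_backbone_id = ablation_backbone_id,
                 use_gamma = use_gamma,
                 channel_selection = channel_selection,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Compute deep feature vectors for an epoch set
#'
#' Per epoch: band profile and correlation map, baseline normalization,
#' two-block image composition at the backbone's input size, backbone
#' forward pass.
#'
#' @param es an `epoch_set` (or plain list of `eeg_epoch`s).
#' @param baseline a [build_baseline_profiles()] result.
#' @param backbone_id registered backbone.
#' @param stft,bands passed to [band_profile()].
#' @return numeric matrix, one row per epoch.
#' @export
featurize_epochs <- function(es, baseline, backbone_id = "tinycnn",
                             stft = stft_config(),
                             bands = band_definitions()) {
  epochs <- if (inherits(es, "epoch_set")) es$epochs else es
  size <- backbone_input_size(backbone_id)
  feats <- lapply(epochs, function(ep) {
    bp <- normalize_profile(band_profile(ep, stft, bands), baseline)
    cm <- normalize_profile(correlation_map(ep), baseline)
    img <- compose_image(bp, cm, size = size)
    extract_features(img, backbone_id)$values
  })
  do.call(rbind, feats)
}

# load one subject's recording from config
subject_recording <- function(cfg, i) {
  s <- cfg$subjects
  if (is.data.frame(s)) {
    ann <- NULL
    if (!is.null(s$summary_path) && nzchar(s$summary_path[i]))
      ann <- read_annotations(s$summary_path[i], basename(s$path[i]))
    read_recording(s$path[i], channel_selection = cfg$channel_selection,
                   subject_id = s$subject_id[i], annotations = ann)
  } else {
    generate_recording(s[[i]])
  }
}

metrics_row <- function(truth, pred) {
  m <- compute_metrics(confusion_counts(truth, pred))
  c(accuracy = m$accuracy, sensitivity = m$sensitivity,
    precision = m$precision, f1 = m$f1)
}

#' Prepare featurized epochs for every subject
#'
#' Runs the data half of the pipeline — load or generate each recording,
#' notch-filter (and low-pass, when the gamma band is disabled), cut labeled
#' epochs, split stratified by label, build baseline feature averages from
#' the *training* baseline epochs only, featurize every epoch through the
#' backbone — and returns the per-subject feature matrices. Separating this
#' stage lets several ablation arms that share features (full, single-SVM,
#' no-vote) reuse one preparation.
#'
#' @param cfg an [experiment_config()].
#' @param backbone_id overrides the configured backbone (used by the
#'   backbone-swap arm).
#' @param epoch_len_s overrides the configured epoch length (used by the
#'   20 s segmentation arm).
#' @param verbose print per-subject progress.
#' @return An object of class `pipeline_features`: list with `subjects`
#'   (per subject: `subject_id`, `feats`, `labels`, `t_start_s`, `role`,
#'   `n_baseline_profiles`) and `params`.
#' @export
prepare_features <- function(cfg, backbone_id = NULL, epoch_len_s = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  n_subj <- if (is.data.frame(cfg$subjects)) nrow(cfg$subjects)
            else length(cfg$subjects)
  windowing <- cfg$windowing
  if (!is.null(epoch_len_s)) windowing$epoch_len_s <- epoch_len_s
  backbone_id <- backbone_id %||% cfg$backbone_id
  filters <- cfg$filters
  if (cfg$use_gamma) filters$lowpass_cutoff_hz <- NULL
  subjects <- vector("list", n_subj)
  for (i in seq_len(n_subj)) {
    rec <- subject_recording(cfg, i)
    if (verbose) message("subject ", rec$subject_id, ": filtering")
    rec <- apply_filters(rec, filters)
    es <- cut_epochs(rec, windowing)
    man <- es$manifest
    role <- split_dataset(man, ratios = cfg$split$ratios,
                          seed = cfg$seed + 17L * i,
                          method = cfg$split$method)
    base_train <- es$epochs[role == "train" & man$label == 0L]
    baseline <- build_baseline_profiles(base_train, cfg = cfg$stft)
    if (verbose) message("subject ", rec$subject_id, ": featurizing ",
                         nrow(man), " epochs")
    feats <- featurize_epochs(es, baseline, backbone_id, stft = cfg$stft)
    subjects[[i]] <- list(subject_id = man$subject_id[1], feats = feats,
                          labels = man$label, t_start_s = man$t_start_s,
                          role = role,
                          n_baseline_profiles = baseline$n_profiles_used)
    rm(rec, es); gc(FALSE)
  }
  structure(list(subjects = subjects,
                 params = list(backbone_id = backbone_id,
                               epoch_len_s = windowing$epoch_len_s,
                               preictal_window_min = windowing$preictal_window_min,
                               baseline_gap_min = windowing$baseline_gap_min,
                               split_ratios = cfg$split$ratios,
                               split_method = cfg$split$method,
                               use_gamma = cfg$use_gamma,
                               seed = cfg$seed)),
            class = "pipeline_features")
}

#' Fit and evaluate the ensemble on prepared features
#'
#' Trains the SVM voting ensemble on each subject's training split and
#' evaluates train/validation/test. Metrics are reported per subject and
#' aggregated as mean and standard deviation across subjects; pooled test
#' epochs additionally yield a ROC curve and AUC from the mean continuous
#' member scores.
#'
#' @param prep a [prepare_features()] result.
#' @param cfg the [experiment_config()] (supplies the arm, ensemble and
#'   seed settings).
#' @return An object of class `seizure_experiment`; see [run_experiment()].
#' @export
evaluate_pipeline <- function(prep, cfg) {
  stopifnot(inherits(prep, "pipeline_features"),
            inherits(cfg, "experiment_config"))
  n_members <- if (cfg$arm == "single-svm") 1L else cfg$ensemble$n_members
  per_subject <- list()
  pooled <- list(truth = integer(0), final = integer(0), score = numeric(0),
                 subject = character(0))
  counts <- list()
  member_acc <- numeric(0)
  for (i in seq_along(prep$subjects)) {
    su <- prep$subjects[[i]]
    feats <- su$feats
    role <- su$role
    man <- data.frame(subject_id = su$subject_id, label = su$labels)
    model <- svm_ensemble(feats[role == "train", , drop = FALSE],
                          man$label[role == "train"],
                          n_members = n_members, cfg = cfg$ensemble$cfg,
                          diversity = cfg$ensemble$diversity,
                          seed = cfg$seed + 31L * i)
    row <- list(subject_id = su$subject_id,
                n_epochs = nrow(man),
                n_preictal = sum(man$label == 1L),
                n_baseline = sum(man$label == 0L),
                n_baseline_profiles = su$n_baseline_profiles)
    for (stage in c("train", "val", "test")) {
      sel <- role == stage
      pr <- predict(model, feats[sel, , drop = FALSE])
      truth <- man$label[sel]
      if (cfg$arm == "no-vote") {
        # per-member accuracies averaged, instead of the voted prediction
        accs <- apply(pr$member_outputs, 2,
                      function(p) mean(p == truth) * 100)
        row[[paste0(stage, "_accuracy")]] <- mean(accs)
        mr <- metrics_row(truth, pr$final)  # keep the rest for reference
        row[[paste0(stage, "_sensitivity")]] <- mr[["sensitivity"]]
        row[[paste0(stage, "_f1")]] <- mr[["f1"]]
        if (stage == "test") member_acc <- c(member_acc, mean(accs))
      } else {
        mr <- metrics_row(truth, pr$final)
        row[[paste0(stage, "_accuracy")]] <- mr[["accuracy"]]
        row[[paste0(stage, "_sensitivity")]] <- mr[["sensitivity"]]
        row[[paste0(stage, "_f1")]] <- mr[["f1"]]
      }
      if (stage == "test") {
        pooled$truth <- c(pooled$truth, truth)
        pooled$final <- c(pooled$final, pr$final)
        pooled$score <- c(pooled$score, pr$score)
        pooled$subject <- c(pooled$subject, rep(su$subject_id, sum(sel)))
        counts[[su$subject_id]] <- confusion_counts(truth, pr$final)
      }
    }
    per_subject[[i]] <- as.data.frame(row)
  }
  per_subject <- do.call(rbind, per_subject)

  metric_cols <- grep("_(accuracy|sensitivity|f1)$", names(per_subject),
                      value = TRUE)
  summary_tab <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(cn)
      mean(per_subject[[cn]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_cols, function(cn)
      stats::sd(per_subject[[cn]], na.rm = TRUE), numeric(1)))
  rownames(summary_tab) <- NULL

  pooled_metrics <- compute_metrics(confusion_counts(pooled$truth,
                                                     pooled$final))
  if (cfg$arm == "no-vote")
    pooled_metrics$accuracy_member_mean <- mean(member_acc)
  roc <- roc_auc(pooled$score, pooled$truth)

  structure(
    list(per_subject = per_subject, summary = summary_tab,
         pooled = list(metrics = pooled_metrics, auc = roc$auc,
                       roc_curve = roc$curve, truth = pooled$truth,
                       final = pooled$final, score = pooled$score,
                       subject = pooled$subject),
         manifest = c(list(arm = cfg$arm, n_members = n_members,
                           n_subjects = length(prep$subjects)),
                      prep$params)),
    class = "seizure_experiment")
}

#' Run the full classification pipeline
#'
#' [prepare_features()] followed by [evaluate_pipeline()], honouring the
#' configured ablation arm (the backbone-swap arm substitutes
#' `ablation_backbone_id`; the 20 s segmentation arm re-cuts epochs at
#' 20 s).
#'
#' @param cfg an [experiment_config()].
#' @param prep optional pre-computed [prepare_features()] result to reuse
#'   (must match the arm's backbone and epoch length).
#' @param verbose print per-subject progress.
#' @return An object of class `seizure_experiment`: list with `per_subject`
#'   (data frame), `summary` (mean/sd per metric and stage), `pooled`
#'   (pooled-epoch metrics, ROC and AUC on the test split), and `manifest`
#'   (arm, seeds, counts, configuration echo).
#' @export
run_experiment <- function(cfg, prep = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(prep)) {
    prep <- prepare_features(
      cfg,
      backbone_id = if (cfg$arm == "backbone") cfg$ablation_backbone_id,
      epoch_len_s = if (cfg$arm == "seg20") 20,
      verbose = verbose)
  }
  evaluate_pipeline(prep, cfg)
}

#' @export
print.seizure_experiment <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<seizure_experiment> arm '%s', backbone '%s', %d SVM member(s), %d subject(s)\n",
              m$arm, m$backbone_id, m$n_members, m$n_subjects))
  cat(sprintf("  epochs: %g s, preictal window %g min, %d epochs total\n",
              m$epoch_len_s, m$preictal_window_min, sum(x$per_subject$n_epochs)))
  fmt <- function(metric) {
    r <- x$summary[x$summary$metric == metric, ]
    if (!nrow(r) || is.na(r$mean)) "-" else sprintf("%.2f +/- %.2f", r$mean, r$sd)
  }
  for (st in c("train", "val", "test"))
    cat(sprintf("  %-5s accuracy %s  sensitivity %s  F1 %s  (%% , mean +/- sd across subjects)\n",
                st, fmt(paste0(st, "_accuracy")),
                fmt(paste0(st, "_sensitivity")), fmt(paste0(st, "_f1"))))
  cat(sprintf("  pooled test: "))
  print(x$pooled$metrics)
  cat(sprintf("  pooled test AUC: %.4f\n", x$pooled$auc))
  invisible(x)
}

#' Run the ablation arms of the pipeline
#'
#' Re-runs [run_experiment()] for the requested arms on the same subjects
#' and collects pooled test accuracies into one table.
#'
#' @param cfg a base [experiment_config()] (its `arm` is ignored).
#' @param arms arms to run.
#' @param verbose print progress.
#' @return list with `results` (named list of `seizure_experiment`) and
#'   `table` (data frame of pooled test metrics per arm).
#' @export
run_ablation <- function(cfg, arms = c("full", "backbone", "single-svm",
                                       "no-vote", "seg20"),
                         verbose = FALSE) {
  results <- list()
  preps <- list()   # arms sharing backbone and epoch length share features
  for (arm in arms) {
    cfg$arm <- arm
    key <- paste(if (arm == "backbone") cfg$ablation_backbone_id
                 else cfg$backbone_id,
                 if (arm == "seg20") 20 else cfg$windowing$epoch_len_s)
    if (is.null(preps[[key]]))
      preps[[key]] <- prepare_features(
        cfg,
        backbone_id = if (arm == "backbone") cfg$ablation_backbone_id,
        epoch_len_s = if (arm == "seg20") 20,
        verbose = verbose)
    results[[arm]] <- evaluate_pipeline(preps[[key]], cfg)
  }
  tab <- data.frame(
    arm = arms,
    test_accuracy = vapply(results, function(r)
      r$pooled$metrics$accuracy, numeric(1)),
    test_auc = vapply(results, function(r) r$pooled$auc, numeric(1)))
  rownames(tab) <- NULL
  list(results = results, table = tab)
}

#' Read an experiment configuration from a YAML file
#'
#' Thin mapping from a YAML document with blocks `synthetic:`, `windowing:`,
#' `filters:`, `stft:`, `backbone:`, `ensemble:`, `split:` onto
#' [experiment_config()]. Unlisted settings keep their defaults.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs needs the 'yaml' package")
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  subjects <- if (!is.null(y$synthetic)) {
    do.call(synthetic_cohort_specs,
            c(y$synthetic, list(seed = seed)))
  } else if (!is.null(y$data)) {
    data.frame(path = y$data$paths, subject_id = y$data$subject_ids,
               summary_path = y$data$summary_path %||% "")
  } else stop("config must contain a 'synthetic:' or 'data:' block")
  args <- list(subjects = subjects, seed = seed)
  if (!is.null(y$windowing)) args$windowing <- do.call(windowing_config, y$windowing)
  if (!is.null(y$filters)) args$filters <- do.call(filter_config, y$filters)
  if (!is.null(y$stft)) args$stft <- do.call(stft_config, y$stft)
  if (!is.null(y$backbone)) args$backbone_id <- y$backbone$id %||% "tinycnn"
  if (!is.null(y$ensemble)) {
    args$ensemble <- list(
      n_members = y$ensemble$n_members %||% 6,
      cfg = do.call(svm_config, y$ensemble$svm %||% list()),
      diversity = y$ensemble$diversity %||% "folds")
  }
  if (!is.null(y$split))
    args$split <- list(ratios = y$split$ratios %||% c(0.6, 0.2, 0.2),
                       method = y$split$method %||% "blocked")
  if (!is.null(y$arm)) args$arm <- y$arm
  do.call(experiment_config, args)
}
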