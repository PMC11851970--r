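#' SVM member configuration
#'
#' Hyperparameters shared by every ensemble member: RBF kernel,
#' regularization constant `cost = 1`, `gamma = "scale"`
#' (`1 / (n_features * var(x))`), tolerance `0.001`. Binary preictal-vs-
#' baseline classification makes the one-vs-rest decision shape degenerate to
#' a single binary machine.
#'
#' @param cost regularization constant C.
#' @param gamma `"scale"` or a positive number.
#' @param tolerance optimizer stopping tolerance.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(cost = 1, gamma = "scale", tolerance = 0.001) {
  stopifnot(cost > 0, tolerance > 0)
  if (!identical(gamma, "scale")) stopifnot(is.numeric(gamma), gamma > 0)
  structure(list(cost = cost, gamma = gamma, tolerance = tolerance,
                 kernel = "radial"),
            class = "svm_config")
}

#' Fit an SVM voting ensemble
#'
#' Trains `n_members` RBF support vector machines on deep feature vectors and
#' combines their binary outputs by the rounding vote of [vote()]. Member
#' diversity comes from bagged stratified leave-one-fold-out training
#' (`diversity = "folds"`, the default): the training set is partitioned into
#' `n_members` stratified folds and member k trains on all folds but fold k.
#' The `"features"` alternative trains each member on the full data but on a
#' random 80% feature subspace.
#'
#' @param x numeric matrix, one row per epoch, columns are deep features.
#' @param y labels in `{0, 1}` (0 baseline, 1 preictal).
#' @param n_members number of members (default 6; 1 gives the single-SVM
#'   ablation arm).
#' @param cfg an [svm_config()].
#' @param diversity `"folds"` or `"features"`.
#' @param seed seed for fold/subspace assignment.
#' @return An object of class `svm_ensemble` with `print`, `summary` and
#'   `predict` methods.
#' @export
svm_ensemble <- function(x, y, n_members = 6, cfg = svm_config(),
                         diversity = c("folds", "features"), seed = 1L) {
  diversity <- match.arg(diversity)
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)), n_members >= 1)
  if (length(unique(y)) < 2)
    stop("training data contains a single class")
  if (min(table(y)) < n_members)
    stop("need at least ", n_members, " samples per class, have ",
         min(table(y)))
  gamma <- if (identical(cfg$gamma, "scale")) {
    v <- stats::var(as.numeric(x))
    1 / (ncol(x) * if (v > 0) v else 1)
  } else cfg$gamma
  yf <- factor(y, levels = c(0, 1))

  assign_folds <- function() {
    f <- integer(length(y))
    for (cl in c(0L, 1L)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(n_members), length(idx)))
    }
    f
  }
  members <- vector("list", n_members)
  member_assignments <- vector("list", n_members)
  feature_idx <- vector("list", n_members)
  with_private_seed(seed, {
    folds <- if (diversity == "folds" && n_members > 1) assign_folds() else NULL
    for (k in seq_len(n_members)) {
      if (diversity == "folds") {
        rows <- if (n_members > 1) which(folds != k) else seq_along(y)
        cols <- seq_len(ncol(x))
      } else {
        rows <- seq_along(y)
        cols <- sort(sample(ncol(x), max(1L, round(0.8 * ncol(x)))))
      }
      members[[k]] <- e1071::svm(
        x[rows, cols, drop = FALSE], yf[rows], type = "C-classification",
        kernel = cfg$kernel, cost = cfg$cost, gamma = gamma,
        tolerance = cfg$tolerance, probability = FALSE, scale = FALSE)
      member_assignments[[k]] <- rows
      feature_idx[[k]] <- cols
    }
  })
  structure(
    list(members = members, member_assignments = member_assignments,
         feature_idx = feature_idx, n_members = n_members, cfg = cfg,
         gamma = gamma, diversity = diversity, seed = as.integer(seed),
         n_features = ncol(x), n_train = nrow(x)),
    class = "svm_ensemble")
}

#' Combine binary member outputs by the rounding vote
#'
#' The ensemble output is the arithmetic mean of the members' binary outputs,
#' rounded to 0 or 1. Rounding is half-up: a tied vote (mean exactly 0.5)
#' predicts preictal, favouring sensitivity.
#'
#' @param member_outputs numeric vector of member outputs in `{0, 1}` (one
#'   epoch), or a matrix with one row per epoch.
#' @return For a vector: list with `member_outputs`, `mean_vote`, `final`.
#'   For a matrix: data frame with columns `mean_vote`, `final`.
#' @export
vote <- function(member_outputs) {
  m <- if (is.matrix(member_outputs)) member_outputs
       else matrix(member_outputs, nrow = 1)
  if (!all(m %in% c(0, 1)))
    stop("member outputs must be binary (0/1)")
  mean_vote <- rowMeans(m)
  final <- as.integer(mean_vote >= 0.5)   # round half up
  if (!is.matrix(member_outputs))
    return(list(member_outputs = as.integer(member_outputs),
                mean_vote = mean_vote, final = final))
  data.frame(mean_vote = mean_vote, final = final)
}

#' Predict with an SVM voting ensemble
#'
#' Applies every member to the feature matrix and combines the binary
#' outputs with [vote()]. The continuous `score` column is the mean of the
#' members' signed decision values oriented toward class 1, used for ROC
#' analysis (the vote itself is taken on hard binary outputs).
#'
#' @param object an [svm_ensemble()].
#' @param newdata numeric feature matrix, one row per epoch.
#' @param ... unused.
#' @return An object of class `ensemble_prediction`: list with
#'   `member_outputs` (n x m integer matrix), `mean_vote`, `final`, `score`.
#' @export
predict.svm_ensemble <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$n_features)
    stop("feature dimension ", ncol(x), " does not match training dimension ",
         object$n_features)
  n <- nrow(x)
  outs <- matrix(0L, n, object$n_members)
  scores <- matrix(0, n, object$n_members)
  for (k in seq_len(object$n_members)) {
    m <- object$members[[k]]
    xk <- x[, object$feature_idx[[k]], drop = FALSE]
    pr <- predict(m, xk, decision.values = TRUE)
    outs[, k] <- as.integer(as.character(pr))
    dv <- attr(pr, "decision.values")
    # e1071 decision values are signed toward the first label in the colname
    first <- strsplit(colnames(dv)[1], "/")[[1]][1]
    scores[, k] <- if (first == "1") dv[, 1] else -dv[, 1]
  }
  v <- vote(outs)
  structure(list(member_outputs = outs, mean_vote = v$mean_vote,
                 final = v$final, score = rowMeans(scores)),
            class = "ensemble_prediction")
}

#' @export
print.svm_ensemble <- function(x, ...) {
  g <- if (identical(x$cfg$gamma, "scale"))
    sprintf("scale (%.3g)", x$gamma) else format(x$gamma)
  cat(sprintf("<svm_ensemble> %d RBF member(s), C = %g, gamma = %s, tol = %g\n",
              x$n_members, x$cfg$cost, g, x$cfg$tolerance))
  cat(sprintf("  diversity: %s; trained on %d epochs x %d features (seed %d)\n",
              x$diversity, x$n_train, x$n_features, x$seed))
  invisible(x)
}

#' @export
summary.svm_ensemble <- function(object, ...) {
  print(object)
  nsv <- vapply(object$members, function(m) m$tot.nSV, integer(1))
  cat("  support vectors per member:", paste(nsv, collapse = ", "), "\n")
  invisible(object)
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("<ensemble_prediction> %d epochs, %d members; %d voted preictal\n",
              length(x$final), ncol(x$member_outputs), sum(x$final)))
  invisible(x)
}
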