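#' Stratified train/validation/test split
#'
#' Splits epochs by the given ratios, stratified by label within subject.
#' The default `"blocked"` method keeps each split a set of temporally
#' contiguous blocks: within each subject-label group the time-ordered
#' epochs are cut into three contiguous chunks sized by the ratios, and the
#' seed permutes which chunk plays which role, so adjacent epochs never
#' straddle splits. `"random"` is a plain stratified random split for
#' fidelity to protocols that ignore temporal leakage.
#'
#' @param manifest data frame with columns `subject_id`, `label`,
#'   `t_start_s` (as from [epoch_manifest()]), or an `epoch_set`.
#' @param ratios numeric length-3 vector summing to 1 (train, val, test).
#' @param seed integer seed.
#' @param method `"blocked"` (default) or `"random"`.
#' @return character vector along the manifest rows with values `"train"`,
#'   `"val"`, `"test"`.
#' @export
split_dataset <- function(manifest, ratios = c(0.6, 0.2, 0.2), seed = 1L,
                          method = c("blocked", "random")) {
  method <- match.arg(method)
  if (inherits(manifest, "epoch_set")) manifest <- manifest$manifest
  stopifnot(abs(sum(ratios) - 1) < 1e-9, length(ratios) == 3)
  roles <- c("train", "val", "test")
  out <- character(nrow(manifest))
  groups <- split(seq_len(nrow(manifest)),
                  list(manifest$subject_id, manifest$label), drop = TRUE)
  with_private_seed(seed, {
    for (idx in groups) {
      n <- length(idx)
      if (n < 3) stop("too few epochs (", n, ") in a subject-label group ",
                      "to stratify into three splits")
      sizes <- floor(n * ratios)
      rem <- n - sum(sizes)
      if (rem > 0) {
        extra <- order(n * ratios - sizes, decreasing = TRUE)[seq_len(rem)]
        sizes[extra] <- sizes[extra] + 1
      }
      if (method == "blocked") {
        ord <- idx[order(manifest$t_start_s[idx])]
        role_order <- sample(3L)
        chunk_sizes <- sizes[role_order]
        bounds <- cumsum(c(0, chunk_sizes))
        for (j in 1:3) {
          rows <- ord[(bounds[j] + 1):bounds[j + 1]]
          out[rows] <- roles[role_order[j]]
        }
      } else {
        shuffled <- sample(idx)
        bounds <- cumsum(c(0, sizes))
        for (j in 1:3) {
          rows <- shuffled[(bounds[j] + 1):bounds[j + 1]]
          out[rows] <- roles[j]
        }
      }
    }
  })
  out
}
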