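# deterministic bilinear resampling with aligned corners: output and input
# grids share their first and last sample, so resizing to the input size is
# the identity
bilinear_resize <- function(mat, out_h, out_w) {
  in_h <- nrow(mat); in_w <- ncol(mat)
  ri <- if (out_h == 1) rep(1, 1) else 1 + (0:(out_h - 1)) * (in_h - 1) / (out_h - 1)
  ci <- if (out_w == 1) rep(1, 1) else 1 + (0:(out_w - 1)) * (in_w - 1) / (out_w - 1)
  r0 <- pmin(floor(ri), in_h - 1); r0[in_h == 1] <- 1
  c0 <- pmin(floor(ci), in_w - 1); c0[in_w == 1] <- 1
  fr <- ri - r0; fc <- ci - c0
  if (in_h == 1) { r0 <- rep(1, out_h); fr <- rep(0, out_h) }
  if (in_w == 1) { c0 <- rep(1, out_w); fc <- rep(0, out_w) }
  r1 <- pmin(r0 + 1, in_h); c1 <- pmin(c0 + 1, in_w)
  a <- mat[r0, c0, drop = FALSE]; b <- mat[r0, c1, drop = FALSE]
  d <- mat[r1, c0, drop = FALSE]; e <- mat[r1, c1, drop = FALSE]
  wr <- matrix(fr, out_h, out_w); wc <- matrix(fc, out_h, out_w, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * (1 - wr) * wc + d * wr * (1 - wc) + e * wr * wc
}

#' Compose normalized features into a backbone input image
#'
#' Deterministic two-block layout: the normalized band profile is bilinearly
#' resampled into the top half of the image and the normalized correlation
#' map into the bottom half; the result is min-max scaled to `[0, 1]` and
#' replicated across 3 channels. A constant (perfectly baseline-like) layout
#' has no dynamic range and maps to an all-zero image.
#'
#' @param band a baseline-normalized `band_profile`.
#' @param corr a baseline-normalized `correlation_map`.
#' @param size integer `c(H, W)` output size (default the test backbone's
#'   64 x 64).
#' @return An object of class `feature_image`: list with `pixels`
#'   (H x W x 3 array in `[0, 1]`) and `provenance`.
#' @export
compose_image <- function(band, corr, size = c(64, 64)) {
  stopifnot(inherits(band, "band_profile"), inherits(corr, "correlation_map"))
  if (!isTRUE(attr(band, "normalized")) || !isTRUE(attr(corr, "normalized")))
    stop("compose_image expects baseline-normalized inputs; ",
         "see normalize_profile()")
  check_finite <- function(m, what) {
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad))
      stop("non-finite ", what, " cells at (row, col): ",
           paste(apply(utils::head(bad, 10), 1, paste, collapse = ","),
                 collapse = "; "))
  }
  check_finite(band$values, "band-profile")
  check_finite(corr$values, "correlation-map")
  h <- size[1]; w <- size[2]
  top_h <- h %/% 2
  top <- bilinear_resize(band$values, top_h, w)
  bottom <- bilinear_resize(corr$values, h - top_h, w)
  img <- rbind(top, bottom)
  rng <- range(img)
  img <- if (diff(rng) < 1e-12) matrix(0, h, w)
         else (img - rng[1]) / diff(rng)
  structure(
    list(pixels = array(rep(img, 3), dim = c(h, w, 3)),
         provenance = list(band_dim = dim(band$values),
                           corr_dim = dim(corr$values), size = size)),
    class = "feature_image")
}
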