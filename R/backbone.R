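# Registry of image-feature backbones. A backbone turns a feature_image into
# a fixed-length descriptor; the pipeline is agnostic to which one is
# plugged in. The built-in "tinycnn" is a deterministic random-weight
# convolutional network that needs no download, so the whole pipeline runs
# and tests offline; a pretrained network (e.g. an EfficientNet-B0 feature
# layer exported from another framework) can be registered the same way.

.backbones <- new.env(parent = emptyenv())
.backbone_cache <- new.env(parent = emptyenv())

#' Register an image-feature backbone
#'
#' @param id backbone identifier string.
#' @param fn function taking an H x W x 3 pixel array and returning a numeric
#'   feature vector of fixed length.
#' @param input_size integer `c(H, W)` expected by `fn`.
#' @param n_features length of the returned vector.
#' @param layer_id label of the read-out layer.
#' @param description one-line human-readable description.
#' @return `id`, invisibly.
#' @export
register_backbone <- function(id, fn, input_size, n_features,
                              layer_id = "features", description = "") {
  stopifnot(is.character(id), is.function(fn))
  assign(id, list(fn = fn, input_size = as.integer(input_size),
                  n_features = as.integer(n_features),
                  layer_id = layer_id, description = description),
         envir = .backbones)
  invisible(id)
}

#' List registered backbones
#' @return data frame with one row per backbone.
#' @export
list_backbones <- function() {
  ids <- sort(ls(.backbones))
  data.frame(
    id = ids,
    input = vapply(ids, function(i)
      paste(get(i, .backbones)$input_size, collapse = "x"), ""),
    n_features = vapply(ids, function(i)
      get(i, .backbones)$n_features, integer(1)),
    description = vapply(ids, function(i)
      get(i, .backbones)$description, ""))
}

backbone_get <- function(id) {
  if (!exists(id, envir = .backbones))
    stop("unknown backbone '", id, "'; registered: ",
         paste(ls(.backbones), collapse = ", "))
  get(id, envir = .backbones)
}

#' Extract a deep feature vector from a feature image
#'
#' Runs the registered backbone's forward pass on the image pixels. The
#' output length is constant for a given backbone across all epochs, and the
#' mapping is deterministic: the same image always yields the same vector.
#'
#' @param img a [compose_image()] result (or a raw H x W x 3 array).
#' @param backbone_id registered backbone identifier (default `"tinycnn"`).
#' @return An object of class `deep_features`: list with `values`,
#'   `backbone_id`, `layer_id`.
#' @export
extract_features <- function(img, backbone_id = "tinycnn") {
  bb <- backbone_get(backbone_id)
  px <- if (inherits(img, "feature_image")) img$pixels else img
  stopifnot(length(dim(px)) == 3, dim(px)[3] == 3)
  if (!all(dim(px)[1:2] == bb$input_size))
    stop("image is ", paste(dim(px)[1:2], collapse = "x"),
         " but backbone '", backbone_id, "' expects ",
         paste(bb$input_size, collapse = "x"))
  v <- as.numeric(bb$fn(px))
  stopifnot(length(v) == bb$n_features)
  structure(list(values = v, backbone_id = backbone_id,
                 layer_id = bb$layer_id),
            class = "deep_features")
}

#' Expected input size of a backbone
#' @param backbone_id registered backbone identifier.
#' @return integer `c(H, W)`.
#' @export
backbone_input_size <- function(backbone_id) backbone_get(backbone_id)$input_size

# ---- built-in test backbone: deterministic random-weight CNN ----

# 2D convolution, 3x3 kernel, stride 2, zero padding 1, via im2col
conv3x3_s2 <- function(x, w, b) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cin <- dim(x)[3]
  oh <- h %/% 2L; ow <- wd %/% 2L
  xp <- array(0, dim = c(h + 2L, wd + 2L, cin))
  xp[2:(h + 1L), 2:(wd + 1L), ] <- x
  # patch matrix: one row per output pixel, 9*cin columns
  oc <- seq_len(ow) * 2L - 1L   # top-left corner (in padded coords) per output col
  or_ <- seq_len(oh) * 2L - 1L
  cols <- vector("list", 9L * cin)
  k <- 0L
  for (c in seq_len(cin)) for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1L
    cols[[k]] <- as.numeric(xp[or_ + dr, oc + dc, c])
  }
  p <- matrix(unlist(cols, use.names = FALSE), nrow = oh * ow)
  out <- p %*% w   # w: (9*cin) x cout
  out <- sweep(out, 2, b, `+`)
  out[out < 0] <- 0   # ReLU
  array(out, dim = c(oh, ow, ncol(w)))
}

tinycnn_weights <- function() {
  if (!exists("tinycnn_w", envir = .backbone_cache)) {
    chans <- c(3L, 16L, 32L, 64L, 128L)
    w <- with_private_seed(81201L, {
      lapply(seq_len(4), function(l) {
        fan_in <- 9L * chans[l]
        list(w = matrix(stats::rnorm(fan_in * chans[l + 1L],
                                     sd = sqrt(2 / fan_in)),
                        fan_in, chans[l + 1L]),
             b = rep(0, chans[l + 1L]))
      })
    })
    assign("tinycnn_w", w, envir = .backbone_cache)
  }
  get("tinycnn_w", envir = .backbone_cache)
}

# read-out: global mean and sd of every channel at every stage. Pooling all
# stages (not just the last) retains both the coarse block contrasts and the
# fine texture statistics of the feature image; with random frozen weights a
# last-stage-only read-out measurably discards class information.
tinycnn_forward <- function(px) {
  w <- tinycnn_weights()
  x <- px
  out <- numeric(0)
  for (l in seq_along(w)) {
    x <- conv3x3_s2(x, w[[l]]$w, w[[l]]$b)
    out <- c(out, apply(x, 3, mean), apply(x, 3, stats::sd))
  }
  out   # 2 * (16 + 32 + 64 + 128) = 480-d
}

# crude non-convolutional comparison backbone: 8x8 block means of channel 1
blockmean_forward <- function(px) {
  m <- px[, , 1]
  h <- nrow(m); w <- ncol(m)
  rb <- ceiling(seq_len(h) / (h / 8)); cb <- ceiling(seq_len(w) / (w / 8))
  as.numeric(tapply(m, list(rb[row(m)], cb[col(m)]), mean))
}

register_builtin_backbones <- function() {
  register_backbone(
    "tinycnn", tinycnn_forward, input_size = c(64L, 64L), n_features = 480L,
    layer_id = "msgap480",
    description = "deterministic random-weight 4-layer CNN, multi-scale mean/sd pooled")
  register_backbone(
    "blockmean", blockmean_forward, input_size = c(64L, 64L), n_features = 64L,
    layer_id = "block8x8",
    description = "8x8 block-mean intensity descriptor (backbone-swap ablation)")
}

.onLoad <- function(libname, pkgname) {
  register_builtin_backbones()
}
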