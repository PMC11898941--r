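# Feature extraction: ViT-style patch-grid arithmetic, a small convolutional
# backbone producing 768-d global features, and the trainable embedding head
# (768 -> 512 -> BN -> ReLU -> dropout -> 64 -> BN).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Patch-grid arithmetic for a square image
#'
#' A square image cut into non-overlapping square patches yields
#' `(image_size / patch_size)^2` patches, each flattened to
#' `patch_size^2 * channels` values. A 224x224 RGB image with 16x16 patches
#' gives 196 patches of dimension 768.
#'
#' @param image_size image side length in pixels.
#' @param patch_size patch side length in pixels; must divide `image_size`.
#' @param channels number of channels.
#' @return list with `num_patches` and `patch_dim`.
#' @export
patch_grid <- function(image_size, patch_size, channels = 3) {
  if (image_size < 1 || patch_size < 1 || channels < 1)
    stop_validation("image_size, patch_size and channels must be positive")
  if (image_size %% patch_size != 0)
    stop_validation("image_size (", image_size,
                    ") is not divisible by patch_size (", patch_size, ")")
  list(num_patches = as.integer((image_size / patch_size)^2),
       patch_dim = as.integer(patch_size^2 * channels))
}

#' Create an embedding head
#'
#' Two fully connected layers with batch normalization: in_dim -> hidden_dim
#' (BN, ReLU, dropout) -> out_dim (BN). In training mode batch statistics are
#' used and running statistics updated; in inference mode running statistics
#' make the head a deterministic pure function of its weights and input.
#'
#' @param in_dim input feature dimension (default 768, a ViT CLS feature).
#' @param hidden_dim hidden width (default 512).
#' @param out_dim embedding dimension (default 64).
#' @param dropout dropout rate in `[0, 1)` applied after the hidden ReLU.
#' @param seed seed for weight initialization.
#' @return an `embedding_head` parameter list.
#' @export
embedding_head <- function(in_dim = 768, hidden_dim = 512, out_dim = 64,
                           dropout = 0.2, seed = 1L) {
  if (in_dim < 1 || hidden_dim < 1 || out_dim < 1)
    stop_validation("all head dimensions must be >= 1")
  if (dropout < 0 || dropout >= 1)
    stop_validation("dropout must be in [0, 1)")
  set.seed(as.integer(seed))
  he <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))
  structure(list(
    W1 = matrix(he(in_dim, in_dim * hidden_dim), in_dim, hidden_dim),
    b1 = rep(0, hidden_dim),
    g1 = rep(1, hidden_dim), be1 = rep(0, hidden_dim),
    rm1 = rep(0, hidden_dim), rv1 = rep(1, hidden_dim),
    W2 = matrix(he(hidden_dim, hidden_dim * out_dim), hidden_dim, out_dim),
    b2 = rep(0, out_dim),
    g2 = rep(1, out_dim), be2 = rep(0, out_dim),
    rm2 = rep(0, out_dim), rv2 = rep(1, out_dim),
    in_dim = as.integer(in_dim), hidden_dim = as.integer(hidden_dim),
    out_dim = as.integer(out_dim), dropout = dropout
  ), class = "embedding_head")
}

bn_forward <- function(x, gamma, beta, rm, rv, training) {
  if (training) {
    mu <- colMeans(x)
    va <- colMeans(sweep(x, 2, mu)^2)       # biased batch variance
    xc <- sweep(x, 2, mu)
    inv <- 1 / sqrt(va + BN_EPS)
    xhat <- sweep(xc, 2, inv, `*`)
    rm_new <- (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mu
    n <- nrow(x)
    rv_new <- (1 - BN_MOMENTUM) * rv +
      BN_MOMENTUM * va * n / max(n - 1, 1)  # unbiased for running stats
    list(out = sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`),
         cache = list(xc = xc, inv = inv, xhat = xhat, gamma = gamma),
         rm = rm_new, rv = rv_new)
  } else {
    xhat <- sweep(sweep(x, 2, rm), 2, 1 / sqrt(rv + BN_EPS), `*`)
    list(out = sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`),
         cache = NULL, rm = rm, rv = rv)
  }
}

bn_backward <- function(g_out, cache) {
  n <- nrow(g_out)
  g_xhat <- sweep(g_out, 2, cache$gamma, `*`)
  g_gamma <- colSums(g_out * cache$xhat)
  g_beta <- colSums(g_out)
  # fused batch-norm input gradient
  t1 <- sweep(g_xhat, 2, colMeans(g_xhat))
  t2 <- sweep(cache$xhat, 2, colMeans(g_xhat * cache$xhat), `*`)
  g_x <- sweep(t1 - t2, 2, cache$inv, `*`)
  list(g_x = g_x, g_gamma = g_gamma, g_beta = g_beta)
}

# forward pass through the head; in training mode returns a cache for
# backprop and updated running statistics
head_forward <- function(features, head, training = FALSE) {
  x <- as_embedding_matrix(features, "features")
  if (ncol(x) != head$in_dim)
    stop_shape("feature dimension ", ncol(x), " does not match head in_dim ",
               head$in_dim)
  if (training && nrow(x) < 2)
    stop_validation("training mode requires a batch of at least 2 samples: ",
                    "batch normalization needs batch statistics")
  z1 <- sweep(x %*% head$W1, 2, head$b1, `+`)
  bn1 <- bn_forward(z1, head$g1, head$be1, head$rm1, head$rv1, training)
  a1 <- pmax(bn1$out, 0)
  if (training && head$dropout > 0) {
    mask <- matrix(stats::runif(length(a1)) >= head$dropout,
                   nrow(a1), ncol(a1))
    h <- a1 * mask / (1 - head$dropout)
  } else {
    mask <- NULL
    h <- a1
  }
  z2 <- sweep(h %*% head$W2, 2, head$b2, `+`)
  bn2 <- bn_forward(z2, head$g2, head$be2, head$rm2, head$rv2, training)
  list(out = bn2$out,
       cache = if (training) list(x = x, bn1 = bn1$cache, a1 = a1,
                                  mask = mask, h = h, bn2 = bn2$cache),
       rm1 = bn1$rm, rv1 = bn1$rv, rm2 = bn2$rm, rv2 = bn2$rv)
}

head_backward <- function(g_out, head, cache) {
  b2 <- bn_backward(g_out, cache$bn2)
  g_z2 <- b2$g_x
  g_W2 <- t(cache$h) %*% g_z2
  g_b2 <- colSums(g_z2)
  g_h <- g_z2 %*% t(head$W2)
  if (!is.null(cache$mask)) g_h <- g_h * cache$mask / (1 - head$dropout)
  g_a1 <- g_h * (cache$a1 > 0)  # ReLU passes gradient where activation > 0
  b1 <- bn_backward(g_a1, cache$bn1)
  g_z1 <- b1$g_x
  list(W1 = t(cache$x) %*% g_z1, b1 = colSums(g_z1),
       g1 = b1$g_gamma, be1 = b1$g_beta,
       W2 = g_W2, b2 = g_b2, g2 = b2$g_gamma, be2 = b2$g_beta)
}

#' Apply the embedding head to a feature batch
#'
#' @param features batch x in_dim matrix of backbone features.
#' @param head an [embedding_head()].
#' @param mode `"inference"` (running statistics; deterministic, dropout off)
#'   or `"train"` (batch statistics and dropout; requires batch >= 2).
#' @return batch x out_dim matrix of embeddings (not normalized).
#' @export
embed_head <- function(features, head, mode = c("inference", "train")) {
  mode <- match.arg(mode)
  head_forward(features, head, training = mode == "train")$out
}

#' Small convolutional backbone with fixed random filters
#'
#' Three 3x3 convolution + ReLU + 2x2 mean-pool blocks followed by global
#' mean and max pooling and a fixed random projection to `feature_dim`
#' outputs. Filters and projection are drawn once from the seed and never
#' updated: the backbone is a frozen generic feature extractor (the
#' transfer-learning role a pretrained network plays), and only the
#' embedding head is trained on top of it.
#'
#' @param channels input image channels.
#' @param feature_dim output feature dimension (default 768).
#' @param seed seed for the filter draw.
#' @return a `conv_backbone` object.
#' @export
conv_backbone <- function(channels = 1, feature_dim = 768, seed = 1L) {
  set.seed(as.integer(seed))
  widths <- c(8L, 16L, 32L)
  ins <- c(channels, widths[1], widths[2])
  filters <- lapply(seq_along(widths), function(i) {
    fan_in <- 9 * ins[i]
    matrix(stats::rnorm(fan_in * widths[i], sd = sqrt(2 / fan_in)),
           fan_in, widths[i])
  })
  pooled_dim <- 2L * widths[3]
  proj <- matrix(stats::rnorm(pooled_dim * feature_dim,
                              sd = 1 / sqrt(pooled_dim)),
                 pooled_dim, feature_dim)
  structure(list(filters = filters, proj = proj, channels = channels,
                 feature_dim = as.integer(feature_dim), seed = seed),
            class = "conv_backbone")
}

# 3x3 valid convolution via im2col; x is H x W x C
conv3x3 <- function(x, filt) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  oh <- h - 2; ow <- w - 2
  cols <- matrix(NA_real_, oh * ow, 9 * cin)
  k <- 1
  for (ci in seq_len(cin)) for (dj in 0:2) for (di in 0:2) {
    cols[, k] <- as.vector(x[(1 + di):(oh + di), (1 + dj):(ow + dj), ci])
    k <- k + 1
  }
  out <- pmax(cols %*% filt, 0)
  array(out, dim = c(oh, ow, ncol(filt)))
}

pool2x2 <- function(x) {
  h <- dim(x)[1] %/% 2; w <- dim(x)[2] %/% 2; ch <- dim(x)[3]
  if (h < 1 || w < 1) stop_validation("image too small for the backbone")
  out <- array(NA_real_, dim = c(h, w, ch))
  for (ci in seq_len(ch)) {
    m <- x[seq_len(2 * h), seq_len(2 * w), ci]
    out[, , ci] <- (m[seq(1, 2 * h, 2), seq(1, 2 * w, 2)] +
                    m[seq(2, 2 * h, 2), seq(1, 2 * w, 2)] +
                    m[seq(1, 2 * h, 2), seq(2, 2 * w, 2)] +
                    m[seq(2, 2 * h, 2), seq(2, 2 * w, 2)]) / 4
  }
  out
}

#' Extract backbone features from images
#'
#' @param backbone a [conv_backbone()].
#' @param images a list of image arrays (H x W x channels, values in [0,1];
#'   an H x W matrix is treated as single-channel).
#' @return matrix of `length(images)` x `feature_dim` features.
#' @export
backbone_features <- function(backbone, images) {
  if (!is.list(images)) images <- list(images)
  feats <- matrix(NA_real_, length(images), backbone$feature_dim)
  for (i in seq_along(images)) {
    x <- images[[i]]
    if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
    if (dim(x)[3] != backbone$channels)
      stop_shape("image has ", dim(x)[3], " channels; backbone expects ",
                 backbone$channels)
    for (f in backbone$filters) x <- pool2x2(conv3x3(x, f))
    gmean <- apply(x, 3, mean)
    gmax <- apply(x, 3, max)
    feats[i, ] <- tanh(c(gmean, gmax) %*% backbone$proj)
  }
  feats
}
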