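# Dual-loss objective: sub-center additive-angular-margin (ArcFace) loss
# plus center loss. Embeddings and sub-center weights live on the unit
# hypersphere for the angular term; the center loss acts in the raw
# embedding space.

COS_CLAMP <- 1e-7  # cosines clamped to [-1 + COS_CLAMP, 1 - COS_CLAMP]

#' Configuration of the dual-loss objective
#'
#' @param margin_deg additive angular margin m, in degrees (converted to
#'   radians internally). Default 28.6 degrees (about 0.499 rad, the
#'   canonical ArcFace margin).
#' @param scale logit scale s applied to cosines before the softmax.
#' @param num_subcenters number of sub-center weight vectors per class (K).
#'   Sub-centers absorb intra-class multimodality: the class cosine is the
#'   maximum over its K sub-centers.
#' @param lambda_arcface weight of the angular-margin term in the total loss.
#' @param lambda_center weight of the center-loss term.
#' @param center_reduction `"sum"` (squared distances summed over the batch,
#'   the printed definition) or `"mean"`.
#' @return a `dual_loss_config` list.
#' @export
dual_loss_config <- function(margin_deg = 28.6, scale = 64,
                             num_subcenters = 3,
                             lambda_arcface = 1, lambda_center = 0.5,
                             center_reduction = c("sum", "mean")) {
  center_reduction <- match.arg(center_reduction)
  if (scale <= 0) stop_validation("scale must be > 0")
  if (margin_deg < 0) stop_validation("margin must be >= 0")
  if (lambda_arcface < 0 || lambda_center < 0)
    stop_validation("loss weights must be >= 0")
  if (num_subcenters < 1) stop_validation("num_subcenters must be >= 1")
  structure(list(margin_deg = margin_deg,
                 margin_rad = margin_deg * pi / 180,
                 scale = scale,
                 num_subcenters = as.integer(num_subcenters),
                 lambda_arcface = lambda_arcface,
                 lambda_center = lambda_center,
                 center_reduction = center_reduction),
            class = "dual_loss_config")
}

#' Create a bank of per-class sub-center weight vectors
#'
#' Each of the C classes owns K unit-norm sub-center vectors in the
#' embedding space. Stored as a 3-d array (class x sub-center x dimension).
#'
#' @param num_classes C, number of identities.
#' @param num_subcenters K, sub-centers per class.
#' @param dim embedding dimension D.
#' @param seed integer seed for the isotropic Gaussian initialization.
#' @return a `subcenter_bank` object.
#' @export
subcenter_bank <- function(num_classes, num_subcenters, dim, seed = 1L) {
  if (num_classes < 1) stop_validation("num_classes must be >= 1")
  if (num_subcenters < 1) stop_validation("num_subcenters must be >= 1")
  set.seed(as.integer(seed))
  w <- array(stats::rnorm(num_classes * num_subcenters * dim),
             dim = c(num_classes, num_subcenters, dim))
  new_subcenter_bank(normalize_bank(w))
}

new_subcenter_bank <- function(weights) {
  stopifnot(length(dim(weights)) == 3)
  structure(list(weights = weights,
                 num_classes = dim(weights)[1],
                 num_subcenters = dim(weights)[2],
                 dim = dim(weights)[3]),
            class = "subcenter_bank")
}

normalize_bank <- function(w) {
  d <- dim(w)
  flat <- matrix(w, nrow = d[1] * d[2], ncol = d[3])
  array(l2_normalize(flat), dim = d)
}

# flatten the bank to a (C*K) x D matrix of unit rows (raw weights are
# normalized here, so cosines are well defined whatever their scale);
# row (j-1)*K + k is sub-center k of class j
bank_matrix <- function(bank) {
  d <- dim(bank$weights)
  m <- matrix(NA_real_, nrow = d[1] * d[2], ncol = d[3])
  for (j in seq_len(d[1]))
    for (k in seq_len(d[2]))
      m[(j - 1) * d[2] + k, ] <- bank$weights[j, k, ]
  l2_normalize(m)
}

validate_batch <- function(embeddings, labels, num_classes) {
  embeddings <- as_embedding_matrix(embeddings)
  if (length(labels) != nrow(embeddings))
    stop_validation("labels length must equal the number of embedding rows")
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > num_classes))
    stop_validation("labels must lie in [1, num_classes]")
  list(embeddings = embeddings, labels = labels)
}

#' Angles between embeddings and their best class sub-center
#'
#' For sample i and class j the angle is
#' `theta[i, j] = arccos(max_k cos(x_i, W_jk))`, the arccos of the best
#' cosine similarity over the K sub-centers of class j. Embeddings are
#' normalized internally; cosines are clamped away from +-1 before arccos.
#'
#' @param embeddings numeric matrix, one sample per row (any scale).
#' @param bank a [subcenter_bank()].
#' @return list with `theta` (N x C matrix of angles in radians, entries in
#'   (0, pi)) and `argmax_k` (N x C matrix, which sub-center attained the max).
#' @export
angular_logits <- function(embeddings, bank) {
  embeddings <- as_embedding_matrix(embeddings)
  if (ncol(embeddings) != bank$dim)
    stop_shape("embedding dimension ", ncol(embeddings),
               " does not match sub-center dimension ", bank$dim)
  xn <- l2_normalize(embeddings)
  wm <- bank_matrix(bank)                      # (C*K) x D, unit rows
  cs <- xn %*% t(wm)                           # N x (C*K)
  n <- nrow(xn); C <- bank$num_classes; K <- bank$num_subcenters
  theta <- matrix(NA_real_, n, C)
  argk <- matrix(NA_integer_, n, C)
  for (j in seq_len(C)) {
    cols <- ((j - 1) * K + 1):(j * K)
    block <- cs[, cols, drop = FALSE]
    argk[, j] <- max.col(block, ties.method = "first")
    best <- block[cbind(seq_len(n), argk[, j])]
    theta[, j] <- acos(pmin(pmax(best, -1 + COS_CLAMP), 1 - COS_CLAMP))
  }
  list(theta = theta, argmax_k = argk)
}

#' Sub-center additive-angular-margin (ArcFace) loss
#'
#' Mean over the batch of
#' `-log( exp(s cos(theta_y + m)) / (exp(s cos(theta_y + m)) +
#' sum_{j != y} exp(s cos(theta_j))) )`, where `theta_j` is the angle to the
#' best sub-center of class j (see [angular_logits()]), `m` the additive
#' angular margin and `s` the logit scale. With a single class the
#' denominator sum is empty and the loss is exactly 0.
#'
#' @param embeddings numeric matrix, one sample per row.
#' @param labels integer class indices in `[1, num_classes]`.
#' @param bank a [subcenter_bank()].
#' @param config a [dual_loss_config()].
#' @return scalar loss (batch mean).
#' @export
subcenter_arcface_loss <- function(embeddings, labels, bank,
                                   config = dual_loss_config()) {
  sal_forward(embeddings, labels, bank, config)$loss
}

# forward pass keeping intermediates needed by the backward pass
sal_forward <- function(embeddings, labels, bank, config) {
  b <- validate_batch(embeddings, labels, bank$num_classes)
  x <- b$embeddings; y <- b$labels
  ang <- angular_logits(x, bank)
  theta <- ang$theta
  n <- nrow(x); C <- bank$num_classes
  s <- config$scale; m <- config$margin_rad
  logits <- s * cos(theta)
  idx <- cbind(seq_len(n), y)
  logits[idx] <- s * cos(theta[idx] + m)
  # row-wise stable log-softmax
  mx <- apply(logits, 1, max)
  z <- exp(logits - mx)
  p <- z / rowSums(z)
  loss <- mean(-log(pmax(p[idx], 1e-300)))
  list(loss = loss, theta = theta, argmax_k = ang$argmax_k, p = p,
       x = x, y = y, idx = idx)
}

# gradient of the sub-center ArcFace loss w.r.t. raw embeddings and bank
# weights (both unnormalized); batch-mean reduction
sal_backward <- function(embeddings, labels, bank, config) {
  fw <- sal_forward(embeddings, labels, bank, config)
  x <- fw$x; y <- fw$y; theta <- fw$theta; argk <- fw$argmax_k
  n <- nrow(x); C <- bank$num_classes; D <- bank$dim
  s <- config$scale; m <- config$margin_rad
  # dL/dlogit = (p - onehot)/n
  g_logit <- fw$p
  g_logit[fw$idx] <- g_logit[fw$idx] - 1
  g_logit <- g_logit / n
  # dlogit/dcos: s for non-target; s*sin(theta+m)/sin(theta) for target
  sin_th <- pmax(sin(theta), 1e-6)
  dl_dcos <- matrix(s, n, C)
  dl_dcos[fw$idx] <- s * sin(theta[fw$idx] + m) / sin_th[fw$idx]
  g_cos <- g_logit * dl_dcos                  # N x C
  # chain to normalized embedding and to the selected sub-center
  nrm_x <- sqrt(rowSums(x^2))
  xn <- x / nrm_x
  g_xn <- matrix(0, n, D)
  g_w <- array(0, dim = dim(bank$weights))    # grad w.r.t. raw bank weights
  raw <- bank$weights
  raw_norm <- apply(raw, c(1, 2), function(v) sqrt(sum(v^2)))
  for (j in seq_len(C)) {
    for (k in seq_len(bank$num_subcenters)) {
      sel <- which(argk[, j] == k)
      if (!length(sel)) next
      w_raw <- raw[j, k, ]
      w_hat <- w_raw / raw_norm[j, k]
      g <- g_cos[sel, j]
      g_xn[sel, ] <- g_xn[sel, ] + outer(g, w_hat)
      # dcos/dW_raw = (xn - (w_hat . xn) w_hat) / ||W_raw||
      xs <- xn[sel, , drop = FALSE]
      proj <- drop(xs %*% w_hat)
      tang <- xs - outer(proj, w_hat)
      g_w[j, k, ] <- g_w[j, k, ] + colSums(g * tang) / raw_norm[j, k]
    }
  }
  # through x -> xn: (I - xn xn^T)/||x||
  proj <- rowSums(g_xn * xn)
  g_x <- (g_xn - xn * proj) / nrm_x
  list(loss = fw$loss, grad_embeddings = g_x, grad_weights = g_w)
}

#' Center loss
#'
#' Sum (default) or mean over the batch of squared Euclidean distances
#' between each embedding and its class center, promoting intra-class
#' compactness in the raw embedding space.
#'
#' @param embeddings numeric matrix, one sample per row.
#' @param labels integer class indices.
#' @param centers C x D matrix of class centers.
#' @param reduction `"sum"` or `"mean"`.
#' @return scalar loss.
#' @export
center_loss <- function(embeddings, labels, centers,
                        reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  centers <- as_embedding_matrix(centers, "centers")
  b <- validate_batch(embeddings, labels, nrow(centers))
  if (ncol(b$embeddings) != ncol(centers))
    stop_shape("embedding and center dimensions differ")
  d2 <- rowSums((b$embeddings - centers[b$labels, , drop = FALSE])^2)
  if (reduction == "sum") sum(d2) else mean(d2)
}

# gradient of center loss w.r.t. embeddings and centers
center_backward <- function(embeddings, labels, centers,
                            reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  centers <- as_embedding_matrix(centers, "centers")
  b <- validate_batch(embeddings, labels, nrow(centers))
  x <- b$embeddings; y <- b$labels
  diff <- x - centers[y, , drop = FALSE]
  scale <- if (reduction == "sum") 2 else 2 / nrow(x)
  g_x <- scale * diff
  g_c <- matrix(0, nrow(centers), ncol(centers))
  for (i in seq_len(nrow(x))) g_c[y[i], ] <- g_c[y[i], ] - g_x[i, ]
  list(loss = if (reduction == "sum") sum(diff^2) else mean(rowSums(diff^2)),
       grad_embeddings = g_x, grad_centers = g_c)
}

#' Dual loss: weighted sum of angular-margin and center terms
#'
#' `total = lambda_arcface * L_arcface + lambda_center * L_center`. With the
#' defaults (1 and 0.5) the total is the angular-margin loss plus half the
#' center loss.
#'
#' @inheritParams subcenter_arcface_loss
#' @param centers C x D matrix of class centers.
#' @return list with `total`, `arcface` and `center` components.
#' @export
dual_loss <- function(embeddings, labels, bank, centers,
                      config = dual_loss_config()) {
  l_sal <- subcenter_arcface_loss(embeddings, labels, bank, config)
  l_cen <- center_loss(embeddings, labels, centers,
                       reduction = config$center_reduction)
  list(total = config$lambda_arcface * l_sal + config$lambda_center * l_cen,
       arcface = l_sal, center = l_cen)
}
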