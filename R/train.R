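# Dual-loss training of the embedding head (plus sub-center weights and
# class centers) over frozen backbone features, with Adam and step decay.

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_update <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mh <- st$m / (1 - beta1^t)
  vh <- st$v / (1 - beta2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), st = st)
}

#' Train an open-set identification embedder with the dual loss
#'
#' Fits the embedding head, the per-class sub-center weight vectors of the
#' angular-margin loss, and the class centers of the center loss jointly by
#' Adam, minimizing `lambda_arcface * L_arcface + lambda_center * L_center`
#' over mini-batches. Inputs are either precomputed backbone features (a
#' numeric matrix, one sample per row) or a list of image arrays, in which
#' case a frozen seeded convolutional backbone ([conv_backbone()]) supplies
#' the features.
#'
#' @param x numeric feature matrix (N x in_dim) or list of image arrays.
#' @param labels identity labels (factor, character or integer), one per row
#'   of `x`; at least two distinct identities are required.
#' @param config a [dual_loss_config()].
#' @param hidden_dim,out_dim,dropout embedding-head hyperparameters
#'   (defaults 512, 64, 0.2).
#' @param epochs number of passes over the data.
#' @param batch_size mini-batch size (clipped to the sample count).
#' @param lr initial Adam learning rate.
#' @param lr_step,lr_factor step decay: every `lr_step` epochs the learning
#'   rate is multiplied by `lr_factor`.
#' @param seed single integer seed controlling initialization, shuffling and
#'   dropout; identical seeds give identical loss histories.
#' @param backbone optional [conv_backbone()] to use when `x` is a list of
#'   images (one is created from `seed` otherwise).
#' @param verbose print the loss each epoch.
#' @return an object of class `osr_embedder` with components `head`, `bank`,
#'   `centers`, `config`, `history` (per-epoch data frame of total, angular
#'   and center losses), `classes`, and optionally `backbone`. Use
#'   [predict.osr_embedder()] to embed new samples.
#' @export
train_embedder <- function(x, labels, config = dual_loss_config(),
                           hidden_dim = 512, out_dim = 64, dropout = 0.2,
                           epochs = 30, batch_size = 64, lr = 1e-3,
                           lr_step = 40, lr_factor = 0.5,
                           seed = 1L, backbone = NULL, verbose = FALSE) {
  seed <- as.integer(seed)
  if (is.list(x) && !is.data.frame(x)) {
    if (is.null(backbone)) {
      img <- x[[1]]
      ch <- if (is.matrix(img)) 1L else dim(img)[3]
      backbone <- conv_backbone(channels = ch, seed = derive_seed(seed, 11L))
    }
    features <- backbone_features(backbone, x)
  } else {
    features <- as_embedding_matrix(x, "features")
  }
  f <- factor(labels)
  classes <- levels(f)
  y <- as.integer(f)
  if (length(classes) < 2)
    stop_validation("training requires at least 2 identities: the ",
                    "angular-margin loss is degenerate with a single class")
  if (length(y) != nrow(features))
    stop_validation("labels length must match the number of samples")
  n <- nrow(features); C <- length(classes)
  batch_size <- min(batch_size, n)
  if (batch_size < 2) stop_validation("batch_size must be at least 2")

  head <- embedding_head(in_dim = ncol(features), hidden_dim = hidden_dim,
                         out_dim = out_dim, dropout = dropout,
                         seed = derive_seed(seed, 1L))
  bank <- subcenter_bank(C, config$num_subcenters, out_dim,
                         seed = derive_seed(seed, 2L))
  centers <- matrix(0, C, out_dim)

  pn <- c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2")
  st <- adam_state(c(head[pn], list(bank = bank$weights, centers = centers)))
  hist <- data.frame(epoch = integer(), total = numeric(),
                     arcface = numeric(), center = numeric())
  set.seed(derive_seed(seed, 3L))
  t_step <- 0L
  for (ep in seq_len(epochs)) {
    lr_ep <- lr * lr_factor^((ep - 1) %/% lr_step)
    ord <- sample.int(n)
    ep_tot <- ep_sal <- ep_cen <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      if (length(idx) < 2) next     # BN needs batch statistics
      fb <- features[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- head_forward(fb, head, training = TRUE)
      head$rm1 <- fw$rm1; head$rv1 <- fw$rv1
      head$rm2 <- fw$rm2; head$rv2 <- fw$rv2
      e <- fw$out
      sal <- sal_backward(e, yb, bank, config)
      cen <- center_backward(e, yb, centers,
                             reduction = config$center_reduction)
      g_e <- config$lambda_arcface * sal$grad_embeddings +
        config$lambda_center * cen$grad_embeddings
      hg <- head_backward(g_e, head, fw$cache)
      t_step <- t_step + 1L
      for (p in pn) {
        up <- adam_update(head[[p]], hg[[p]], st[[p]], lr_ep, t_step)
        head[[p]] <- up$p; st[[p]] <- up$st
      }
      up <- adam_update(bank$weights,
                        config$lambda_arcface * sal$grad_weights,
                        st$bank, lr_ep, t_step)
      st$bank <- up$st
      bank <- new_subcenter_bank(normalize_bank(up$p))
      up <- adam_update(centers, config$lambda_center * cen$grad_centers,
                        st$centers, lr_ep, t_step)
      centers <- up$p; st$centers <- up$st
      tot <- config$lambda_arcface * sal$loss + config$lambda_center * cen$loss
      ep_tot <- ep_tot + tot; ep_sal <- ep_sal + sal$loss
      ep_cen <- ep_cen + cen$loss; nb <- nb + 1
    }
    hist <- rbind(hist, data.frame(epoch = ep, total = ep_tot / nb,
                                   arcface = ep_sal / nb,
                                   center = ep_cen / nb))
    if (verbose)
      message(sprintf("epoch %3d  total %.4f  angular %.4f  center %.4f",
                      ep, ep_tot / nb, ep_sal / nb, ep_cen / nb))
  }
  structure(list(head = head, bank = bank, centers = centers,
                 config = config, history = hist, classes = classes,
                 backbone = backbone, feature_dim = ncol(features),
                 out_dim = as.integer(out_dim), seed = seed),
            class = "osr_embedder")
}

#' Embed new samples with a trained model
#'
#' @param object an `osr_embedder` from [train_embedder()].
#' @param newdata feature matrix or list of image arrays (the latter requires
#'   the model to have been trained on images).
#' @param normalize return unit-norm embeddings (default), the form consumed
#'   by the cosine gallery.
#' @param ... unused.
#' @return matrix of embeddings, one row per sample.
#' @export
predict.osr_embedder <- function(object, newdata, normalize = TRUE, ...) {
  if (is.list(newdata) && !is.data.frame(newdata)) {
    if (is.null(object$backbone))
      stop_validation("model was trained on features; supply a feature matrix")
    newdata <- backbone_features(object$backbone, newdata)
  }
  e <- embed_head(newdata, object$head, mode = "inference")
  if (normalize) l2_normalize(e) else e
}

#' @export
print.osr_embedder <- function(x, ...) {
  cat("Dual-loss open-set embedder\n")
  cat(sprintf("  classes: %d   features: %d -> embedding: %d\n",
              length(x$classes), x$feature_dim, x$out_dim))
  cat(sprintf("  sub-centers/class: %d   margin: %.1f deg   scale: %g\n",
              x$config$num_subcenters, x$config$margin_deg, x$config$scale))
  cat(sprintf("  epochs: %d   final loss: %.4f (angular %.4f, center %.4f)\n",
              nrow(x$history), utils::tail(x$history$total, 1),
              utils::tail(x$history$arcface, 1),
              utils::tail(x$history$center, 1)))
  invisible(x)
}

#' @export
summary.osr_embedder <- function(object, ...) {
  print(object)
  cat("\nLoss history (first/last epochs):\n")
  h <- object$history
  show <- unique(c(seq_len(min(3, nrow(h))),
                   seq(max(1, nrow(h) - 2), nrow(h))))
  print(h[show, ], row.names = FALSE)
  invisible(object$history)
}

#' Plot the training loss history
#'
#' @param x an `osr_embedder`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.osr_embedder <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$total, h$arcface, h$center),
                    type = "l", lty = 1, col = c("black", "steelblue",
                                                 "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("total", "angular margin", "center"),
                   lty = 1, col = c("black", "steelblue", "firebrick"),
                   bty = "n")
  invisible(h)
}
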