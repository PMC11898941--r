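# Independent reference implementations used as oracles. These are written
# as plain per-element loops, deliberately sharing no code with the package
# internals they check.

# plain ArcFace (one center per class): scalar loop evaluation
arcface_reference <- function(x, y, W, s, m_rad) {
  n <- nrow(x)
  losses <- numeric(n)
  for (i in seq_len(n)) {
    xi <- x[i, ] / sqrt(sum(x[i, ]^2))
    cosines <- numeric(nrow(W))
    for (j in seq_len(nrow(W))) {
      wj <- W[j, ] / sqrt(sum(W[j, ]^2))
      cosines[j] <- min(max(sum(wj * xi), -1 + 1e-7), 1 - 1e-7)
    }
    theta <- acos(cosines)
    num <- exp(s * cos(theta[y[i]] + m_rad))
    den <- num
    for (j in seq_len(nrow(W))) if (j != y[i]) den <- den + exp(s * cosines[j])
    losses[i] <- -log(num / den)
  }
  mean(losses)
}

# angular logits by direct per-element evaluation
angular_logits_reference <- function(x, bank_weights) {
  C <- dim(bank_weights)[1]; K <- dim(bank_weights)[2]
  out <- matrix(NA_real_, nrow(x), C)
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ] / sqrt(sum(x[i, ]^2))
    for (j in seq_len(C)) {
      best <- -Inf
      for (k in seq_len(K)) {
        w <- bank_weights[j, k, ] / sqrt(sum(bank_weights[j, k, ]^2))
        best <- max(best, sum(w * xi))
      }
      out[i, j] <- acos(min(max(best, -1 + 1e-7), 1 - 1e-7))
    }
  }
  out
}

# AUROC as the normalized count of correctly ordered known/unknown pairs
auroc_paircount <- function(scores_known, scores_unknown) {
  tot <- 0
  for (sk in scores_known) for (su in scores_unknown)
    tot <- tot + (sk > su) + 0.5 * (sk == su)
  tot / (length(scores_known) * length(scores_unknown))
}

# OSCR by trapezoidal integration of (FAR, CCR) sampled on a dense
# threshold grid (direct enumeration at every grid point)
oscr_grid <- function(truth, pred, score, n_grid = 20001) {
  known <- truth != pigosr::OSR_UNKNOWN
  grid <- seq(max(score) + 1e-3, -1 - 1e-3, length.out = n_grid)
  far <- ccr <- numeric(n_grid)
  for (g in seq_len(n_grid)) {
    acc <- score >= grid[g]
    ccr[g] <- sum(acc & known & pred == truth) / sum(known)
    far[g] <- sum(acc & !known) / sum(!known)
  }
  sum(diff(far) * (head(ccr, -1) + tail(ccr, -1)) / 2)
}

# build a score table from parallel vectors, terse fixture constructor
tab <- function(truth, pred, score) pigosr::score_table(truth, pred, score)

# mean within- and between-identity cosine of an embedding set
cosine_margin <- function(emb, labels) {
  emb <- emb / sqrt(rowSums(emb^2))
  cs <- emb %*% t(emb)
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  mean(cs[same & !is.na(same)]) - mean(cs[!same & !is.na(same)])
}
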