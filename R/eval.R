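# Closed- and open-set evaluation over similarity score tables, and the
# F1-Open-maximizing threshold sweep.

#' Build an open-set score table
#'
#' One row per query: ground-truth label (a known identity or [OSR_UNKNOWN]),
#' the argmax-matched identity, and its best similarity score. This table is
#' the input to all open-set metrics.
#'
#' @param true_label character vector of ground truth; unknown queries carry
#'   [OSR_UNKNOWN].
#' @param predicted_label character vector of argmax-matched identities.
#' @param best_score numeric vector of best cosine similarities.
#' @param query_id optional identifiers (defaults to the row index).
#' @return a `score_table` data frame.
#' @export
score_table <- function(true_label, predicted_label, best_score,
                        query_id = seq_along(true_label)) {
  n <- length(true_label)
  if (length(predicted_label) != n || length(best_score) != n)
    stop_validation("score table columns must have equal length")
  check_finite(best_score, "best_score")
  structure(data.frame(query_id = as.character(query_id),
                       true_label = as.character(true_label),
                       predicted_label = as.character(predicted_label),
                       best_score = as.numeric(best_score),
                       stringsAsFactors = FALSE),
            class = c("score_table", "data.frame"))
}

#' Score a query set against a gallery
#'
#' Convenience wrapper: matches every query embedding and assembles the
#' [score_table()].
#'
#' @param gallery a [feature_gallery()].
#' @param queries matrix of query embeddings, one per row.
#' @param true_label ground-truth labels ([OSR_UNKNOWN] for unknown queries).
#' @param aggregation passed to [match_query()].
#' @return a `score_table`.
#' @export
score_queries <- function(gallery, queries, true_label,
                          aggregation = "max") {
  q <- as_embedding_matrix(queries, "queries")
  if (nrow(q) != length(true_label))
    stop_validation("one true label per query row is required")
  res <- lapply(seq_len(nrow(q)), function(i)
    match_query(gallery, q[i, ], k = 1, aggregation = aggregation))
  score_table(true_label,
              vapply(res, function(r) r$best_identity, character(1)),
              vapply(res, function(r) r$best_score, numeric(1)))
}

is_known <- function(table) table$true_label != OSR_UNKNOWN

require_both_populations <- function(table) {
  k <- is_known(table)
  if (!any(k) || all(k))
    stop_validation("this metric needs both known and unknown queries")
  invisible(k)
}

#' Closed-set accuracy
#'
#' Fraction of known queries whose argmax match equals the true identity; no
#' rejection threshold is applied and unknown queries are ignored.
#'
#' @param table a [score_table()].
#' @return rate in `[0, 1]`.
#' @export
csa <- function(table) {
  k <- is_known(table)
  if (!any(k)) stop_validation("closed-set accuracy needs known queries")
  mean(table$predicted_label[k] == table$true_label[k])
}

#' Correct classification rate and false accept rate at a threshold
#'
#' CCR is the fraction of known queries that are both correctly matched and
#' accepted (score >= threshold); FAR is the fraction of unknown queries
#' whose score clears the threshold. Both are non-increasing in the
#' threshold.
#'
#' @param table a [score_table()].
#' @param threshold acceptance threshold.
#' @return named numeric vector `c(ccr=, far=)`.
#' @export
ccr_far_at <- function(table, threshold) {
  k <- require_both_populations(table)
  acc <- table$best_score >= threshold
  ccr <- mean(acc[k] & table$predicted_label[k] == table$true_label[k])
  far <- mean(acc[!k])
  c(ccr = ccr, far = far)
}

#' Open-set classification rate (area under the CCR-FAR curve)
#'
#' Sweeps the acceptance threshold over all observed scores (plus sentinels
#' outside the score range) and integrates CCR over FAR by the trapezoidal
#' rule; in `[0, 1]`.
#'
#' @param table a [score_table()].
#' @return scalar area.
#' @export
oscr <- function(table) {
  require_both_populations(table)
  thr <- sort(unique(c(table$best_score, -1, max(table$best_score) + 1)),
              decreasing = TRUE)
  pts <- t(vapply(thr, function(t) ccr_far_at(table, t), numeric(2)))
  far <- pts[, "far"]; ccr <- pts[, "ccr"]
  # thresholds descend, so FAR ascends from 0 to 1
  sum(diff(far) * (utils::head(ccr, -1) + utils::tail(ccr, -1)) / 2)
}

#' Area under the ROC curve for known-vs-unknown separation
#'
#' The best similarity score is the detector statistic, knowns the positive
#' class. Computed by the rank (Mann-Whitney) formulation with midranks for
#' ties.
#'
#' @param table a [score_table()].
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(table) {
  k <- require_both_populations(table)
  r <- rank(table$best_score)       # midranks handle ties
  n1 <- sum(k); n0 <- sum(!k)
  (sum(r[k]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve for known-vs-unknown separation
#'
#' Step-wise (non-interpolated) average precision: queries sorted by
#' descending score, precision accumulated at each known query's rank. Ties
#' are broken by original row order (documented for reproducibility).
#'
#' @param table a [score_table()].
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(table) {
  k <- require_both_populations(table)
  ord <- order(-table$best_score, seq_len(nrow(table)))
  pos <- k[ord]
  prec <- cumsum(pos) / seq_along(pos)
  sum(prec[pos]) / sum(pos)
}

#' F1-Open at a threshold
#'
#' Macro average over the known classes of per-class F1 with rejection in
#' effect: a rejected known query is a false negative for its class, an
#' accepted unknown query is a false positive for the identity it matched,
#' and an accepted known query predicted as the wrong class is a false
#' negative for its class and a false positive for the predicted one. A class
#' with an empty F1 denominator contributes 0. The micro-averaged variant
#' (pooled counts) is available via `average = "micro"`.
#'
#' @param table a [score_table()].
#' @param threshold acceptance threshold.
#' @param average `"macro"` (default) or `"micro"`.
#' @return F1-Open in `[0, 1]`.
#' @export
f1_open <- function(table, threshold, average = c("macro", "micro")) {
  average <- match.arg(average)
  k <- require_both_populations(table)
  accepted <- table$best_score >= threshold
  classes <- sort(unique(table$true_label[k]))
  pred <- ifelse(accepted, table$predicted_label, OSR_UNKNOWN)
  tp <- fp <- fn <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    truth_c <- table$true_label == cl
    pred_c <- pred == cl
    tp[cl] <- sum(truth_c & pred_c)
    fp[cl] <- sum(!truth_c & pred_c)
    fn[cl] <- sum(truth_c & !pred_c)
  }
  if (average == "micro") {
    den <- 2 * sum(tp) + sum(fp) + sum(fn)
    return(if (den == 0) 0 else 2 * sum(tp) / den)
  }
  den <- 2 * tp + fp + fn
  f1 <- ifelse(den == 0, 0, 2 * tp / den)
  mean(f1)
}

#' Threshold sweep maximizing F1-Open
#'
#' Evaluates F1-Open, CCR and FAR at every unique observed score (ascending)
#' and reports the threshold with maximal F1-Open; ties are broken toward the
#' smallest threshold. FAR and CCR are non-increasing along the sweep.
#'
#' @param table a [score_table()].
#' @param average F1 averaging convention, see [f1_open()].
#' @return a `threshold_sweep` list: `thresholds`, `f1_open`, `ccr`, `far`,
#'   `best_threshold`, `best_f1_open`.
#' @export
threshold_sweep <- function(table, average = "macro") {
  require_both_populations(table)
  thr <- sort(unique(table$best_score))
  f1 <- vapply(thr, function(t) f1_open(table, t, average), numeric(1))
  cf <- t(vapply(thr, function(t) ccr_far_at(table, t), numeric(2)))
  best <- which.max(f1)   # first (smallest) threshold on ties
  structure(list(thresholds = thr, f1_open = f1,
                 ccr = cf[, "ccr"], far = cf[, "far"],
                 best_threshold = thr[best], best_f1_open = f1[best],
                 average = average),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf(
    "threshold sweep over %d scores: best threshold %.4f (F1-Open %.4f)\n",
    length(x$thresholds), x$best_threshold, x$best_f1_open))
  i <- which(x$thresholds == x$best_threshold)
  cat(sprintf("at the optimum: CCR %.4f, FAR %.4f\n", x$ccr[i], x$far[i]))
  invisible(x)
}

#' Plot F1-Open, CCR and FAR against the threshold
#'
#' @param x a `threshold_sweep`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.threshold_sweep <- function(x, ...) {
  graphics::matplot(x$thresholds, cbind(x$f1_open, x$ccr, x$far),
                    type = "l", lty = 1,
                    col = c("black", "steelblue", "firebrick"),
                    xlab = "threshold", ylab = "rate", ylim = c(0, 1), ...)
  graphics::abline(v = x$best_threshold, lty = 3)
  graphics::legend("left", c("F1-Open", "CCR", "FAR"), lty = 1,
                   col = c("black", "steelblue", "firebrick"), bty = "n")
  invisible(x)
}

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

mutual_information <- function(cont) {
  n <- sum(cont)
  mi <- 0
  a <- rowSums(cont); b <- colSums(cont)
  for (i in seq_len(nrow(cont))) for (j in seq_len(ncol(cont))) {
    nij <- cont[i, j]
    if (nij > 0) mi <- mi + nij / n * log(nij * n / (a[i] * b[j]))
  }
  mi
}

# expected mutual information under the permutation model
# (hypergeometric sum, log-factorials for stability)
expected_mi <- function(a, b, n) {
  emi <- 0
  lf <- lgamma(seq_len(n + 1))                 # lf[k+1] = log(k!)
  for (ai in a) for (bj in b) {
    lo <- max(1, ai + bj - n)
    for (nij in lo:min(ai, bj)) {
      term <- nij / n * log(n * nij / (ai * bj))
      lp <- lf[ai + 1] + lf[bj + 1] + lf[n - ai + 1] + lf[n - bj + 1] -
        lf[n + 1] - lf[nij + 1] - lf[ai - nij + 1] - lf[bj - nij + 1] -
        lf[n - ai - bj + nij + 1]
      emi <- emi + term * exp(lp)
    }
  }
  emi
}

#' Mutual-information agreement between two labelings
#'
#' NMI normalizes mutual information by the arithmetic mean of the two
#' entropies; AMI additionally adjusts for chance by subtracting the expected
#' mutual information under random permutations (arithmetic-mean
#' normalization in both cases). Degenerate partitions (a single cluster on
#' either side) return 0 by convention for NMI, and 0 for AMI when the
#' denominator vanishes.
#'
#' @param truth,pred label vectors of equal length.
#' @return named vector `c(nmi=, ami=)`.
#' @export
ami_nmi <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop_validation("labelings differ in length")
  cont <- table(truth, pred)
  n <- sum(cont)
  mi <- mutual_information(cont)
  hu <- entropy_counts(rowSums(cont)); hv <- entropy_counts(colSums(cont))
  mean_h <- (hu + hv) / 2
  nmi <- if (mean_h == 0) {
    if (nrow(cont) == 1 && ncol(cont) == 1) 1 else 0
  } else mi / mean_h
  emi <- expected_mi(rowSums(cont), colSums(cont), n)
  den <- mean_h - emi
  ami <- if (abs(den) < 1e-12) {
    if (abs(mi - emi) < 1e-12) 1 else 0
  } else (mi - emi) / den
  c(nmi = unname(nmi), ami = unname(ami))
}

#' Closed-set report: precision, recall, F1, AMI/NMI and confusion matrix
#'
#' Computed on the known queries with no rejection (pure argmax matching).
#' Precision, recall and F1 are macro-averaged over the true classes; a class
#' never predicted contributes precision 0.
#'
#' @param table a [score_table()]; unknown queries, if present, are dropped.
#' @return list with `precision`, `recall`, `f1`, `ami`, `nmi`, `csa` and
#'   `confusion` (true classes x predicted classes, rows summing to per-class
#'   query counts).
#' @export
closed_set_report <- function(table) {
  k <- is_known(table)
  if (!any(k)) stop_validation("closed-set report needs known queries")
  truth <- table$true_label[k]; pred <- table$predicted_label[k]
  classes <- sort(unique(truth))
  pred_levels <- sort(unique(c(classes, pred)))
  conf <- table(factor(truth, levels = pred_levels),
                factor(pred, levels = pred_levels))
  prec <- rec <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    tp <- sum(truth == cl & pred == cl)
    prec[cl] <- if (sum(pred == cl) == 0) 0 else tp / sum(pred == cl)
    rec[cl] <- tp / sum(truth == cl)
  }
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  an <- ami_nmi(truth, pred)
  list(precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       ami = unname(an["ami"]), nmi = unname(an["nmi"]),
       csa = mean(truth == pred),
       confusion = conf[classes, , drop = FALSE])
}

#' Retrieval metrics against a gallery
#'
#' For each query, all gallery vectors are ranked by cosine similarity.
#' Precision@1 is the rate at which the top-ranked vector shares the query's
#' identity; with R the number of gallery vectors of that identity,
#' R-precision is the same-identity fraction of the top R, and MAP@R the mean
#' average precision truncated at R. All three are macro-averaged over
#' queries. When `exclude_self` is set, a single stored vector identical to
#' the query (same identity, similarity 1 to float tolerance) is dropped from
#' its own ranking.
#'
#' @param gallery a [feature_gallery()].
#' @param queries matrix of query embeddings.
#' @param query_labels identity per query (must be enrolled).
#' @param exclude_self drop the query's own gallery copy from its ranking.
#' @return named vector `c(precision_at_1=, r_precision=, map_at_r=)`.
#' @export
retrieval_report <- function(gallery, queries, query_labels,
                             exclude_self = FALSE) {
  q <- as_embedding_matrix(queries, "queries")
  if (nrow(q) != length(query_labels))
    stop_validation("one label per query row is required")
  ids <- rep(identity_ids(gallery),
             vapply(gallery$embeddings, nrow, integer(1)))
  mat <- do.call(rbind, gallery$embeddings)
  qn <- l2_normalize(q)
  p1 <- rp <- mapr <- numeric(nrow(q))
  for (i in seq_len(nrow(q))) {
    sims <- drop(mat %*% qn[i, ])
    lab <- as.character(query_labels[i])
    keep <- rep(TRUE, length(sims))
    if (exclude_self) {
      self <- which(ids == lab & sims >= 1 - 1e-10)
      if (length(self)) keep[self[1]] <- FALSE
    }
    s <- sims[keep]; l <- ids[keep]
    ord <- order(-s, seq_along(s))
    rel <- l[ord] == lab
    R <- sum(rel)
    if (R == 0) stop_validation("query identity '", lab,
                                "' has no gallery vectors to retrieve")
    p1[i] <- as.numeric(rel[1])
    rp[i] <- mean(rel[seq_len(R)])
    topR <- rel[seq_len(R)]
    mapr[i] <- sum(cumsum(topR) / seq_len(R) * topR) / R
  }
  c(precision_at_1 = mean(p1), r_precision = mean(rp), map_at_r = mean(mapr))
}

#' Full evaluation report
#'
#' Bundles the open-set metrics (CSA, AUROC, AUPR, OSCR, and F1-Open/CCR/FAR
#' at the swept-optimal threshold unless one is supplied) with the closed-set
#' report.
#'
#' @param table a [score_table()] containing known and unknown queries.
#' @param threshold operating threshold; if `NULL` the F1-Open-optimal
#'   threshold from [threshold_sweep()] is used.
#' @return an `eval_report` list.
#' @export
evaluate_open_set <- function(table, threshold = NULL) {
  sweep <- threshold_sweep(table)
  if (is.null(threshold)) threshold <- sweep$best_threshold
  cf <- ccr_far_at(table, threshold)
  closed <- closed_set_report(table)
  structure(list(csa = csa(table), auroc = auroc(table), aupr = aupr(table),
                 oscr = oscr(table),
                 threshold = threshold,
                 f1_open = f1_open(table, threshold),
                 ccr = unname(cf["ccr"]), far = unname(cf["far"]),
                 sweep = sweep, closed_set = closed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("open-set evaluation\n")
  cat(sprintf("  CSA    %.4f   AUROC %.4f   AUPR %.4f   OSCR %.4f\n",
              x$csa, x$auroc, x$aupr, x$oscr))
  cat(sprintf("  at threshold %.4f: F1-Open %.4f   CCR %.4f   FAR %.4f\n",
              x$threshold, x$f1_open, x$ccr, x$far))
  cs <- x$closed_set
  cat(sprintf(
    "  closed set: precision %.4f recall %.4f F1 %.4f AMI %.4f NMI %.4f\n",
    cs$precision, cs$recall, cs$f1, cs$ami, cs$nmi))
  invisible(x)
}

#' Write / read a score table as CSV
#'
#' @param table a [score_table()].
#' @param path CSV file path.
#' @return `path` invisibly / the re-read `score_table`.
#' @export
write_score_table <- function(table, path) {
  df <- as.data.frame(table)
  df$best_score <- format(df$best_score, digits = 17, trim = TRUE,
                          scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  score_table(df$true_label, df$predicted_label,
              as.numeric(df$best_score), df$query_id)
}
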