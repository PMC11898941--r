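# Closed- and open-set metrics against independent enumeration oracles.

UNK <- OSR_UNKNOWN

# 10 known queries, 7 correct; plus unknowns with assorted scores
mixed_table <- function() {
  truth <- c(rep("a", 5), rep("b", 5), rep(UNK, 4))
  pred <- c("a", "a", "a", "b", "a", "b", "b", "b", "a", "b", "a", "b",
            "a", "b")
  score <- c(0.95, 0.9, 0.85, 0.7, 0.92, 0.88, 0.93, 0.8, 0.65, 0.9,
             0.6, 0.75, 0.5, 0.86)
  tab(truth, pred, score)
}

test_that("closed-set accuracy counts correct argmax matches over knowns", {
  expect_equal(csa(tab(c("a", "b"), c("a", "b"), c(1, 1))), 1)
  expect_equal(csa(tab(c("a", "b"), c("b", "a"), c(1, 1))), 0)
  t10 <- tab(c(rep("a", 6), rep("b", 4)),
             c("a", "a", "a", "b", "a", "a", "b", "b", "a", "b"),
             runif(10))
  expect_equal(csa(t10), 0.8)   # 8 of 10 by hand count
  expect_error(csa(tab(rep(UNK, 3), c("a", "b", "a"), c(1, 1, 1))), "known")
})

test_that("CCR and FAR match hand enumeration and degenerate thresholds", {
  # 6-query toy: knowns (a,0.9,correct) (a,0.4,wrong) (b,0.7,correct);
  # unknowns at 0.8, 0.5, 0.3
  t6 <- tab(c("a", "a", "b", UNK, UNK, UNK),
            c("a", "b", "b", "a", "b", "a"),
            c(0.9, 0.4, 0.7, 0.8, 0.5, 0.3))
  expect_equal(ccr_far_at(t6, 0.6), c(ccr = 2 / 3, far = 1 / 3))
  expect_equal(ccr_far_at(t6, 0.45), c(ccr = 2 / 3, far = 2 / 3))
  expect_equal(ccr_far_at(t6, 0.85), c(ccr = 1 / 3, far = 0))
  # below all scores: everything accepted; above all: nothing
  expect_equal(ccr_far_at(t6, -1), c(ccr = csa(t6), far = 1))
  expect_equal(ccr_far_at(t6, 0.95), c(ccr = 0, far = 0))
  expect_error(ccr_far_at(tab(c("a", "b"), c("a", "b"), c(1, 1)), 0.5),
               "unknown")
})

test_that("OSCR equals dense-grid integration and hits its extremes", {
  # perfectly separated, all knowns correct
  tsep <- tab(c("a", "a", "b", UNK, UNK), c("a", "a", "b", "a", "b"),
              c(0.9, 0.85, 0.8, 0.3, 0.2))
  expect_equal(oscr(tsep), 1)
  # knowns never correct
  tbad <- tab(c("a", "a", UNK), c("b", "b", "a"), c(0.9, 0.8, 0.5))
  expect_equal(oscr(tbad), 0)
  tm <- mixed_table()
  expect_equal(oscr(tm),
               oscr_grid(tm$true_label, tm$predicted_label, tm$best_score),
               tolerance = 1e-6)
  expect_gte(oscr(tm), 0); expect_lte(oscr(tm), 1)
})

test_that("AUROC equals the pairwise-comparison oracle including ties", {
  tm <- mixed_table()
  k <- tm$true_label != UNK
  expect_equal(auroc(tm),
               auroc_paircount(tm$best_score[k], tm$best_score[!k]),
               tolerance = 1e-12)
  # disjoint ranges and identical multisets
  expect_equal(auroc(tab(c("a", "a", UNK, UNK), rep("a", 4),
                         c(0.9, 0.8, 0.2, 0.1))), 1)
  expect_equal(auroc(tab(c("a", "a", UNK, UNK), rep("a", 4),
                         c(0.7, 0.3, 0.7, 0.3))), 0.5)
  # random toys against the O(n^2) count
  set.seed(5)
  for (rep in 1:5) {
    nk <- sample(3:8, 1); nu <- sample(3:8, 1)
    sc <- round(runif(nk + nu), 2)   # rounding forces occasional ties
    t_r <- tab(c(rep("a", nk), rep(UNK, nu)), rep("a", nk + nu), sc)
    expect_equal(auroc(t_r), auroc_paircount(sc[1:nk], sc[-(1:nk)]),
                 tolerance = 1e-12)
  }
})

test_that("AUPR follows step-wise average precision", {
  # hand case: scores desc -> known, unknown, known, unknown
  t4 <- tab(c("a", UNK, "a", UNK), rep("a", 4), c(0.9, 0.8, 0.7, 0.6))
  expect_equal(aupr(t4), (1 / 1 + 2 / 3) / 2, tolerance = 1e-12)
  tsep <- tab(c("a", "a", UNK), rep("a", 3), c(0.9, 0.8, 0.1))
  expect_equal(aupr(tsep), 1)
})

test_that("F1-Open matches the per-class confusion oracle", {
  # 8-query toy, threshold 0.6:
  # a: q1 (0.9, correct, accepted) TP; q2 (0.5, correct, rejected) FN
  # b: q3 (0.8, predicted a) -> FN for b, FP for a; q4 (0.7, correct) TP
  # unknowns: 0.65 predicted a -> FP for a; 0.4 predicted b rejected;
  #           0.3, 0.2 rejected
  t8 <- tab(c("a", "a", "b", "b", UNK, UNK, UNK, UNK),
            c("a", "a", "a", "b", "a", "b", "a", "b"),
            c(0.9, 0.5, 0.8, 0.7, 0.65, 0.4, 0.3, 0.2))
  f1_a <- 2 * 1 / (2 * 1 + 2 + 1)   # tp=1 fp=2 fn=1
  f1_b <- 2 * 1 / (2 * 1 + 0 + 1)   # tp=1 fp=0 fn=1
  expect_equal(f1_open(t8, 0.6), mean(c(f1_a, f1_b)), tolerance = 1e-12)
  micro <- 2 * 2 / (2 * 2 + 2 + 2)
  expect_equal(f1_open(t8, 0.6, average = "micro"), micro, tolerance = 1e-12)
  # all knowns accepted+correct, unknowns rejected -> 1; all rejected -> 0
  tperf <- tab(c("a", "b", UNK), c("a", "b", "a"), c(0.9, 0.9, 0.1))
  expect_equal(f1_open(tperf, 0.5), 1)
  expect_equal(f1_open(tperf, 0.95), 0)
})

test_that("threshold sweep maximizes F1-Open with monotone CCR and FAR", {
  tm <- mixed_table()
  sw <- threshold_sweep(tm)
  expect_true(all(diff(sw$far) <= 1e-12))
  expect_true(all(diff(sw$ccr) <= 1e-12))
  expect_equal(sw$best_f1_open, max(sw$f1_open))
  expect_equal(sw$best_threshold,
               min(sw$thresholds[sw$f1_open == sw$best_f1_open]))
  # well-separated construction: optimum lies strictly between the
  # known-correct and unknown score ranges
  tsep <- tab(c(rep("a", 3), rep("b", 3), rep(UNK, 4)),
              c(rep("a", 3), rep("b", 3), "a", "b", "a", "b"),
              c(0.92, 0.9, 0.88, 0.91, 0.89, 0.87, 0.4, 0.35, 0.3, 0.25))
  sws <- threshold_sweep(tsep)
  expect_gt(sws$best_threshold, 0.4)
  expect_lte(sws$best_threshold, 0.87)
  expect_equal(sws$best_f1_open, 1)
  # single unique score: one-point sweep returning that score
  t1 <- tab(c("a", UNK), c("a", "a"), c(0.5, 0.5))
  sw1 <- threshold_sweep(t1)
  expect_equal(sw1$thresholds, 0.5)
  expect_equal(sw1$best_threshold, 0.5)
})

test_that("mutual-information scores match the scikit-learn oracle values", {
  # frozen from sklearn.metrics normalized_/adjusted_mutual_info_score
  # (arithmetic normalization) on the same partitions
  r1 <- ami_nmi(c(0, 0, 1, 1, 2, 2), c(0, 0, 1, 2, 2, 2))
  expect_equal(unname(r1["nmi"]), 0.7396673768007592, tolerance = 1e-12)
  expect_equal(unname(r1["ami"]), 0.5023607027202738, tolerance = 1e-12)
  r2 <- ami_nmi(c(0, 0, 0, 1, 1, 2), c(1, 1, 0, 0, 2, 2))
  expect_equal(unname(r2["nmi"]), 0.5206652463984818, tolerance = 1e-12)
  expect_equal(unname(r2["ami"]), 0.08372678378671243, tolerance = 1e-12)
  r3 <- ami_nmi(c(0, 1, 0, 1, 0, 1), c(0, 0, 0, 1, 1, 1))
  expect_equal(unname(r3["nmi"]), 0.08170416594551037, tolerance = 1e-12)
  expect_equal(unname(r3["ami"]), -0.1111111111111111, tolerance = 1e-10)
  # perfect agreement and single-cluster degeneracy
  expect_equal(ami_nmi(c(1, 2, 3), c(1, 2, 3)),
               c(nmi = 1, ami = 1), tolerance = 1e-12)
  expect_equal(unname(ami_nmi(c(1, 2, 1, 2), c(7, 7, 7, 7))["nmi"]), 0)
})

test_that("closed-set report aggregates precision, recall, F1 and the confusion matrix", {
  tperf <- tab(c("a", "a", "b"), c("a", "a", "b"), c(1, 1, 1))
  rp <- closed_set_report(tperf)
  expect_equal(rp[c("precision", "recall", "f1", "ami", "nmi", "csa")],
               list(precision = 1, recall = 1, f1 = 1, ami = 1, nmi = 1,
                    csa = 1))
  t6 <- tab(c("a", "a", "b", "b", "c", "c"),
            c("a", "b", "b", "b", "c", "a"), rep(1, 6))
  rp6 <- closed_set_report(t6)
  # per-class by hand: a p=1/2 r=1/2; b p=2/3 r=1; c p=1 r=1/2
  expect_equal(rp6$precision, mean(c(1 / 2, 2 / 3, 1)), tolerance = 1e-12)
  expect_equal(rp6$recall, mean(c(1 / 2, 1, 1 / 2)), tolerance = 1e-12)
  conf <- rp6$confusion
  expect_equal(rowSums(conf), c(a = 2, b = 2, c = 2), ignore_attr = TRUE)
  expect_equal(conf["a", "b"], 1, ignore_attr = TRUE)
})

test_that("retrieval metrics equal the exhaustive-ranking oracle", {
  g <- feature_gallery(dim = 2, images_per_identity = 2)
  g <- register_identity(g, "a", rbind(c(1, 0), l2_normalize(c(1, 0.05))))
  g <- register_identity(g, "b", rbind(c(0, 1), l2_normalize(c(0.05, 1))))
  g <- register_identity(g, "c", rbind(l2_normalize(c(-1, 0.2)),
                                       l2_normalize(c(-1, -0.2))))
  # query duplicating a stored vector, excluded from its own ranking
  r <- retrieval_report(g, rbind(c(1, 0)), "a", exclude_self = TRUE)
  expect_equal(unname(r["precision_at_1"]), 1)
  # near (0.6,0.8): ranking by hand -> b,b,a,a,c,c; R=2 for each identity
  q <- rbind(c(0.6, 0.8))
  rb <- retrieval_report(g, q, "b")
  expect_equal(unname(rb), c(1, 1, 1))
  ra <- retrieval_report(g, q, "a")
  # top-2 are b's: p@1 = 0, r-prec = 0, map@r = 0
  expect_equal(unname(ra), c(0, 0, 0))
  # interleaved relevance exercises the truncated AP formula: gallery
  # angles a = {10, 70} deg, b = {30, 50} deg, query at 15 deg ->
  # ranking a, b, b, a; R = 2 -> p@1 = 1, r-prec = 1/2, map@r = 1/2
  deg <- function(d) c(cos(d * pi / 180), sin(d * pi / 180))
  # adversarial query at 80 deg: nearest neighbours are both b's
  radv <- retrieval_report(g, rbind(deg(80)), "a")
  expect_equal(unname(radv["precision_at_1"]), 0)
  g2 <- feature_gallery(dim = 2, images_per_identity = 2)
  g2 <- register_identity(g2, "a", rbind(deg(10), deg(70)))
  g2 <- register_identity(g2, "b", rbind(deg(30), deg(50)))
  r2 <- retrieval_report(g2, rbind(deg(15)), "a")
  expect_equal(unname(r2), c(1, 0.5, 0.5))
  expect_error(retrieval_report(g, rbind(c(1, 0)), "zz"), "no gallery")
})

test_that("score tables persist and reload bit-identically", {
  tm <- mixed_table()
  f <- withr::local_tempfile(fileext = ".csv")
  write_score_table(tm, f)
  t2 <- read_score_table(f)
  expect_equal(as.data.frame(t2), as.data.frame(tm))
  r1 <- evaluate_open_set(tm); r2 <- evaluate_open_set(t2)
  expect_identical(r1$auroc, r2$auroc)
  expect_identical(r1$oscr, r2$oscr)
  expect_identical(r1$f1_open, r2$f1_open)
})

test_that("the bundled report exposes consistent open-set numbers", {
  tm <- mixed_table()
  rep <- evaluate_open_set(tm)
  expect_equal(rep$csa, csa(tm))
  expect_equal(rep$auroc, auroc(tm))
  expect_equal(rep$oscr, oscr(tm))
  expect_equal(rep$threshold, threshold_sweep(tm)$best_threshold)
  expect_equal(rep$f1_open, f1_open(tm, rep$threshold))
  cf <- ccr_far_at(tm, rep$threshold)
  expect_equal(rep$ccr, unname(cf["ccr"]))
  expect_equal(rep$far, unname(cf["far"]))
})
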