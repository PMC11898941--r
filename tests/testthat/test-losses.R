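# Dual-loss objective: angular logits, sub-center angular-margin loss,
# center loss, and their weighted combination.

test_that("angular logits match direct per-element evaluation", {
  set.seed(11)
  bank <- subcenter_bank(num_classes = 3, num_subcenters = 2, dim = 4,
                         seed = 2)
  x <- matrix(rnorm(5 * 4), 5, 4)
  got <- angular_logits(x, bank)$theta
  expect_equal(got, angular_logits_reference(x, bank$weights),
               tolerance = 1e-12)
  expect_true(all(got > 0 & got < pi))

  # alignment with a sub-center gives angle ~0; orthogonality gives pi/2
  aligned <- rbind(2.5 * bank$weights[2, 1, ])   # scale must not matter
  th <- angular_logits(aligned, bank)$theta
  expect_lt(th[1, 2], 1e-3)
  w <- bank$weights[1, , ]
  ortho <- rbind(qr.Q(qr(t(w)), complete = TRUE)[, 3])
  th2 <- angular_logits(ortho, bank)$theta
  expect_equal(th2[1, 1], pi / 2, tolerance = 1e-8)
})

test_that("angular logits validate shapes and finiteness", {
  bank <- subcenter_bank(2, 1, 4, seed = 1)
  expect_error(angular_logits(matrix(1, 2, 3), bank), "dimension")
  expect_error(angular_logits(matrix(c(1, NA, 1, 1), 1, 4), bank), "finite")
})

test_that("sub-center angular-margin loss matches scalar evaluation of the formula", {
  # C = 2, D = 2, K = 1, W1 = (1,0), W2 = (0,1), x = (1,0), y = 1
  bank <- subcenter_bank(2, 1, 2, seed = 1)
  bank$weights[1, 1, ] <- c(1, 0)
  bank$weights[2, 1, ] <- c(0, 1)
  cfg <- dual_loss_config()
  s <- cfg$scale; m <- cfg$margin_rad
  # theta_1 = acos(1 - clamp), theta_2 = acos(0) = pi/2
  th1 <- acos(1 - 1e-7)
  expected <- -log(exp(s * cos(th1 + m)) /
                     (exp(s * cos(th1 + m)) + exp(s * cos(pi / 2))))
  got <- subcenter_arcface_loss(matrix(c(1, 0), 1, 2), 1, bank, cfg)
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("with one sub-center the loss reduces to plain ArcFace", {
  set.seed(21)
  for (rep in 1:3) {
    C <- sample(2:5, 1); D <- sample(3:6, 1); N <- sample(2:6, 1)
    bank <- subcenter_bank(C, 1, D, seed = rep)
    x <- matrix(rnorm(N * D), N, D)
    y <- sample.int(C, N, replace = TRUE)
    cfg <- dual_loss_config()
    W <- matrix(bank$weights[, 1, ], C, D)
    expect_equal(subcenter_arcface_loss(x, y, bank, cfg),
                 arcface_reference(x, y, W, cfg$scale, cfg$margin_rad),
                 tolerance = 1e-6)
  }
})

test_that("single-class angular-margin loss is exactly zero", {
  bank <- subcenter_bank(1, 3, 5, seed = 4)
  x <- matrix(rnorm(4 * 5), 4, 5)
  expect_equal(subcenter_arcface_loss(x, rep(1, 4), bank), 0)
})

test_that("angular-margin loss validates labels", {
  bank <- subcenter_bank(3, 2, 4, seed = 1)
  x <- matrix(rnorm(8), 2, 4)
  expect_error(subcenter_arcface_loss(x, c(1, 4), bank), "labels")
  expect_error(subcenter_arcface_loss(x, c(0, 1), bank), "labels")
})

test_that("angular-margin loss is scale invariant and permutation equivariant", {
  set.seed(31)
  bank <- subcenter_bank(4, 3, 6, seed = 5)
  x <- matrix(rnorm(6 * 6), 6, 6)
  y <- c(1, 2, 3, 4, 1, 2)
  base <- subcenter_arcface_loss(x, y, bank)
  scaled <- x * rep(runif(6, 0.1, 10), 6)   # per-row positive rescaling
  expect_equal(subcenter_arcface_loss(scaled, y, bank), base,
               tolerance = 1e-5)
  perm <- sample.int(6)
  expect_equal(subcenter_arcface_loss(x[perm, ], y[perm], bank), base,
               tolerance = 1e-10)
})

test_that("loss is finite and decreases as the true-class angle shrinks", {
  bank <- subcenter_bank(2, 1, 2, seed = 1)
  bank$weights[1, 1, ] <- c(1, 0)
  bank$weights[2, 1, ] <- c(0, 1)
  angles <- c(1.2, 0.8, 0.4, 0.1)
  losses <- vapply(angles, function(a)
    subcenter_arcface_loss(matrix(c(cos(a), sin(a)), 1, 2), 1, bank),
    numeric(1))
  expect_true(all(is.finite(losses)))
  expect_true(all(diff(losses) < 0))
})

test_that("center loss matches the loop oracle under both reductions", {
  set.seed(41)
  centers <- matrix(rnorm(3 * 4), 3, 4)
  x <- matrix(rnorm(6 * 4), 6, 4)
  y <- c(1, 2, 3, 1, 2, 3)
  oracle <- 0
  for (i in 1:6) oracle <- oracle + sum((x[i, ] - centers[y[i], ])^2)
  expect_equal(center_loss(x, y, centers), oracle, tolerance = 1e-12)
  expect_equal(center_loss(x, y, centers, reduction = "mean"), oracle / 6,
               tolerance = 1e-12)
  # zero at the centers; 2.0 for two unit vectors about the origin
  expect_equal(center_loss(centers[y, ], y, centers), 0)
  expect_equal(center_loss(rbind(c(1, 0), c(0, 1)), c(1, 1),
                           matrix(0, 1, 2)), 2)
  expect_gte(center_loss(x, y, centers), 0)
  expect_error(center_loss(x, c(1, 2, 3, 1, 2, 4), centers), "labels")
})

test_that("dual loss is the weighted sum of its components", {
  set.seed(51)
  bank <- subcenter_bank(3, 2, 5, seed = 6)
  centers <- matrix(rnorm(15), 3, 5)
  x <- matrix(rnorm(4 * 5), 4, 5)
  y <- c(1, 2, 3, 1)
  cfg <- dual_loss_config(lambda_arcface = 1, lambda_center = 0.5)
  dl <- dual_loss(x, y, bank, centers, cfg)
  expect_equal(dl$total, dl$arcface + 0.5 * dl$center, tolerance = 1e-12)
  expect_equal(dl$arcface, subcenter_arcface_loss(x, y, bank, cfg))
  expect_equal(dl$center, center_loss(x, y, centers))
  # degenerate weight recovers the angular term alone
  cfg0 <- dual_loss_config(lambda_center = 0)
  expect_equal(dual_loss(x, y, bank, centers, cfg0)$total,
               subcenter_arcface_loss(x, y, bank, cfg0))
  # arbitrary weights: composition oracle
  cfg2 <- dual_loss_config(lambda_arcface = 0.3, lambda_center = 1.7)
  expect_equal(dual_loss(x, y, bank, centers, cfg2)$total,
               0.3 * subcenter_arcface_loss(x, y, bank, cfg2) +
                 1.7 * center_loss(x, y, centers), tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences on a 3-sample toy", {
  set.seed(61)
  bank <- subcenter_bank(3, 2, 4, seed = 7)
  centers <- matrix(rnorm(12), 3, 4)
  x <- matrix(rnorm(3 * 4), 3, 4)
  y <- c(1, 2, 3)
  cfg <- dual_loss_config()
  h <- 1e-6
  sal <- pigosr:::sal_backward(x, y, bank, cfg)
  cen <- pigosr:::center_backward(x, y, centers)
  fd <- function(f) {
    g <- x * 0
    for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
      xp <- x; xp[i, j] <- xp[i, j] + h
      xm <- x; xm[i, j] <- xm[i, j] - h
      g[i, j] <- (f(xp) - f(xm)) / (2 * h)
    }
    g
  }
  g_sal <- fd(function(z) subcenter_arcface_loss(z, y, bank, cfg))
  g_cen <- fd(function(z) center_loss(z, y, centers))
  expect_equal(sal$grad_embeddings, g_sal, tolerance = 1e-4)
  expect_equal(cen$grad_embeddings, g_cen, tolerance = 1e-4)
  # sub-center weight gradient
  gw <- bank$weights * 0
  for (j in 1:3) for (k in 1:2) for (d in 1:4) {
    wp <- bank$weights; wp[j, k, d] <- wp[j, k, d] + h
    wm <- bank$weights; wm[j, k, d] <- wm[j, k, d] - h
    gw[j, k, d] <-
      (subcenter_arcface_loss(x, y, pigosr:::new_subcenter_bank(wp), cfg) -
       subcenter_arcface_loss(x, y, pigosr:::new_subcenter_bank(wm), cfg)) /
      (2 * h)
  }
  expect_equal(sal$grad_weights, gw, tolerance = 1e-4)
  # center gradient
  gc <- centers * 0
  for (j in 1:3) for (d in 1:4) {
    cp <- centers; cp[j, d] <- cp[j, d] + h
    cm <- centers; cm[j, d] <- cm[j, d] - h
    gc[j, d] <- (center_loss(x, y, cp) - center_loss(x, y, cm)) / (2 * h)
  }
  expect_equal(cen$grad_centers, gc, tolerance = 1e-4)
})

test_that("config defaults and validation follow the published settings", {
  cfg <- dual_loss_config()
  expect_equal(cfg$margin_deg, 28.6)
  expect_equal(cfg$margin_rad, 28.6 * pi / 180)
  expect_equal(cfg$scale, 64)
  expect_equal(cfg$num_subcenters, 3L)
  expect_equal(cfg$lambda_arcface, 1)
  expect_equal(cfg$lambda_center, 0.5)
  expect_error(dual_loss_config(scale = 0), "scale")
  expect_error(dual_loss_config(margin_deg = -1), "margin")
  expect_error(dual_loss_config(num_subcenters = 0), "num_subcenters")
})
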