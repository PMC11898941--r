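# Synthetic identities at two fidelity levels: von Mises-Fisher embedding
# clusters on the unit hypersphere (fast; exercises gallery + evaluation and
# stands in for backbone features), and procedural identity images (exercises
# the backbone + trainer), arranged into the five-way open-set protocol:
# known-identity training, gallery registration, known test, unknown
# registration and unknown test splits.

#' Specification of synthetic identity clusters on the hypersphere
#'
#' Each identity is a von Mises-Fisher cluster: a mean direction plus samples
#' concentrated around it with concentration `kappa` (larger kappa, tighter
#' cluster, higher within-identity cosine; kappa = 0 is uniform on the
#' sphere, i.e. no identity signal). Mean directions are drawn with a
#' guaranteed minimum pairwise angle.
#'
#' @param num_identities number of identities.
#' @param samples_per_identity samples drawn per identity.
#' @param dim embedding dimension (>= 2).
#' @param kappa concentration (>= 0); default `4 * dim`, which puts the mean
#'   within-identity cosine near 0.9.
#' @param min_angle_deg minimum pairwise angle between identity means, in
#'   degrees.
#' @param seed integer seed.
#' @return a `cluster_spec` list.
#' @export
cluster_spec <- function(num_identities, samples_per_identity, dim = 64,
                         kappa = NULL, min_angle_deg = 45, seed = 1L) {
  if (dim < 2) stop_validation("dim must be >= 2")
  if (is.null(kappa)) kappa <- 4 * dim
  if (kappa < 0) stop_validation("kappa must be >= 0")
  structure(list(num_identities = as.integer(num_identities),
                 samples_per_identity = as.integer(samples_per_identity),
                 dim = as.integer(dim), kappa = kappa,
                 min_angle_deg = min_angle_deg, seed = as.integer(seed)),
            class = "cluster_spec")
}

runif_sphere <- function(n, d) {
  l2_normalize(matrix(stats::rnorm(n * d), n, d))
}

# Wood (1994) rejection sampler for the vMF w-marginal (cosine to the mean)
rvmf_w <- function(n, kappa, d) {
  if (kappa == 0) {
    # w density prop. to (1-w^2)^((d-3)/2): via a symmetric Beta draw
    return(2 * stats::rbeta(n, (d - 1) / 2, (d - 1) / 2) - 1)
  }
  b <- (-2 * kappa + sqrt(4 * kappa^2 + (d - 1)^2)) / (d - 1)
  x0 <- (1 - b) / (1 + b)
  c0 <- kappa * x0 + (d - 1) * log(1 - x0^2)
  out <- numeric(n); got <- 0
  while (got < n) {
    m <- n - got
    z <- stats::rbeta(m, (d - 1) / 2, (d - 1) / 2)
    w <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
    u <- stats::runif(m)
    ok <- kappa * w + (d - 1) * log(1 - x0 * w) - c0 >= log(u)
    nok <- sum(ok)
    if (nok) {
      out[(got + 1):(got + nok)] <- w[ok]
      got <- got + nok
    }
  }
  out
}

rvmf <- function(n, mu, kappa) {
  d <- length(mu)
  if (kappa == 0) return(runif_sphere(n, d))
  w <- rvmf_w(n, kappa, d)
  g <- matrix(stats::rnorm(n * d), n, d)
  g <- g - outer(drop(g %*% mu), mu)        # project out the mean direction
  v <- l2_normalize(g)
  w * matrix(mu, n, d, byrow = TRUE) + sqrt(pmax(1 - w^2, 0)) * v
}

# identity mean directions with minimum pairwise angle, by rejection
sample_means <- function(n_id, d, min_angle_deg, max_tries = 2000) {
  cos_max <- cos(min_angle_deg * pi / 180)
  means <- matrix(NA_real_, n_id, d)
  for (i in seq_len(n_id)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- drop(runif_sphere(1, d))
      if (i == 1 ||
          max(means[seq_len(i - 1), , drop = FALSE] %*% cand) <= cos_max) {
        means[i, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed)
      stop_validation("could not place ", n_id, " identity means at >= ",
                      min_angle_deg, " degrees apart in dimension ", d,
                      " after ", max_tries, " tries; lower min_angle_deg ",
                      "or raise dim")
  }
  means
}

#' Sample labeled unit-norm embeddings from identity clusters
#'
#' @param spec a [cluster_spec()].
#' @param means optional matrix of identity mean directions (one per row);
#'   drawn from the spec's seed if omitted.
#' @return list with `embeddings` (unit rows), `labels` (character identity
#'   per row) and `means`.
#' @export
sample_cluster_embeddings <- function(spec, means = NULL) {
  set.seed(spec$seed)
  if (is.null(means))
    means <- sample_means(spec$num_identities, spec$dim, spec$min_angle_deg)
  ids <- sprintf("id%03d", seq_len(spec$num_identities))
  emb <- vector("list", spec$num_identities)
  for (i in seq_len(spec$num_identities))
    emb[[i]] <- rvmf(spec$samples_per_identity, means[i, ], spec$kappa)
  list(embeddings = do.call(rbind, emb),
       labels = rep(ids, each = spec$samples_per_identity),
       means = means)
}

#' Specification of procedural identity images
#'
#' Every identity owns a seeded pattern (a superposition of oriented
#' sinusoidal gratings plus a soft blob); images of the same identity share
#' the pattern and differ only by nuisance draws (brightness, circular
#' translation, rectangular occlusion), emulating the pose/lighting/occlusion
#' variability of real footage.
#'
#' @param canvas image side length in pixels (>= 32).
#' @param channels image channels.
#' @param brightness_range additive brightness offset range.
#' @param max_shift maximum circular translation in pixels.
#' @param occlusion fraction of the canvas side occluded, in `[0, 1)`.
#' @param seed integer seed.
#' @return an `image_spec` list.
#' @export
image_spec <- function(canvas = 32, channels = 1,
                       brightness_range = c(-0.1, 0.1), max_shift = 3,
                       occlusion = 0.2, seed = 1L) {
  if (canvas < 32) stop_validation("canvas must be >= 32 pixels")
  if (occlusion < 0 || occlusion >= 1)
    stop_validation("occlusion fraction must be in [0, 1)")
  structure(list(canvas = as.integer(canvas), channels = as.integer(channels),
                 brightness_range = brightness_range,
                 max_shift = max_shift, occlusion = occlusion,
                 seed = as.integer(seed)),
            class = "image_spec")
}

identity_pattern_params <- function(n_id, spec) {
  lapply(seq_len(n_id), function(i) list(
    freq = stats::runif(2, 2, 6),
    angle = stats::runif(2, 0, pi),
    phase = stats::runif(2, 0, 2 * pi),
    blob = c(stats::runif(2, 0.25, 0.75), stats::runif(1, 0.1, 0.25)),
    weight = stats::runif(3, 0.5, 1)))
}

render_one <- function(params, spec, nuisance = TRUE) {
  s <- spec$canvas
  xy <- (seq_len(s) - 0.5) / s
  X <- matrix(xy, s, s); Y <- t(X)
  img <- matrix(0, s, s)
  for (k in 1:2) {
    u <- cos(params$angle[k]) * X + sin(params$angle[k]) * Y
    img <- img + params$weight[k] *
      sin(2 * pi * params$freq[k] * u + params$phase[k])
  }
  d2 <- (X - params$blob[1])^2 + (Y - params$blob[2])^2
  img <- img + params$weight[3] * 2 * exp(-d2 / (2 * params$blob[3]^2))
  img <- (img - min(img)) / (max(img) - min(img) + 1e-12)
  if (nuisance) {
    img <- img + stats::runif(1, spec$brightness_range[1],
                              spec$brightness_range[2])
    if (spec$max_shift > 0) {
      dx <- sample.int(2 * spec$max_shift + 1, 1) - spec$max_shift - 1
      dy <- sample.int(2 * spec$max_shift + 1, 1) - spec$max_shift - 1
      img <- img[((seq_len(s) - 1 + dx) %% s) + 1,
                 ((seq_len(s) - 1 + dy) %% s) + 1]
    }
    if (spec$occlusion > 0) {
      side <- max(1L, round(spec$occlusion * s))
      ox <- sample.int(s - side + 1, 1); oy <- sample.int(s - side + 1, 1)
      img[ox:(ox + side - 1), oy:(oy + side - 1)] <- 0
    }
  }
  img <- pmin(pmax(img, 0), 1)
  if (spec$channels == 1) img else array(rep(img, spec$channels),
                                         dim = c(s, s, spec$channels))
}

#' Render procedural identity images
#'
#' @param spec an [image_spec()].
#' @param num_identities number of identities.
#' @param images_per_identity images rendered per identity.
#' @param nuisance apply nuisance transforms (brightness, shift, occlusion);
#'   with `FALSE` all images of an identity are identical.
#' @return list with `images` (list of arrays in [0,1]), `labels`, and
#'   `params` (the per-identity pattern parameters).
#' @export
render_identity_images <- function(spec, num_identities,
                                   images_per_identity, nuisance = TRUE) {
  set.seed(spec$seed)
  params <- identity_pattern_params(num_identities, spec)
  ids <- sprintf("id%03d", seq_len(num_identities))
  images <- list(); labels <- character()
  for (i in seq_len(num_identities)) {
    for (j in seq_len(images_per_identity)) {
      images[[length(images) + 1]] <- render_one(params[[i]], spec, nuisance)
      labels <- c(labels, ids[i])
    }
  }
  list(images = images, labels = labels, params = params)
}

#' Generate the five-way open-set protocol
#'
#' Produces disjoint splits over synthetic identities: a known-identity
#' training set, a per-identity gallery-registration set, a known-identity
#' test set, an unknown-identity registration set, and an unknown-identity
#' test set. Unknown identities never appear in known splits. Defaults mirror
#' the study conditions (56 known and 9 unknown identities, 30 registration
#' images per identity); [scaled_protocol()] gives the small preset used
#' throughout the tests.
#'
#' @param n_known,n_unknown identity counts.
#' @param n_img gallery/registration embeddings per identity.
#' @param train_per_identity,known_test_per_identity,unknown_test_per_identity
#'   per-identity sizes of the remaining splits.
#' @param level `"embedding"` (von Mises-Fisher clusters) or `"image"`
#'   (procedural images).
#' @param dim embedding dimension (embedding level).
#' @param kappa cluster concentration; `NULL` for the [cluster_spec()]
#'   default, 0 ablates all identity signal.
#' @param min_angle_deg minimum angle between identity means.
#' @param image_opts list of [image_spec()] arguments (image level).
#' @param seed integer master seed; identical seeds give identical protocols.
#' @return a `synthetic_protocol` list with elements `known_train`,
#'   `known_gallery`, `known_test`, `unknown_register`, `unknown_test` (each
#'   with `items` and `labels`), plus `known_ids`, `unknown_ids`, `level`.
#' @export
make_protocol <- function(n_known = 56, n_unknown = 9, n_img = 30,
                          train_per_identity = 214,
                          known_test_per_identity = 70,
                          unknown_test_per_identity = 100,
                          level = c("embedding", "image"),
                          dim = 64, kappa = NULL, min_angle_deg = 45,
                          image_opts = list(), seed = 1L) {
  level <- match.arg(level)
  seed <- as.integer(seed)
  if (n_known < 2 || n_unknown < 1)
    stop_validation("need at least 2 known and 1 unknown identity")
  n_id <- n_known + n_unknown
  known_ids <- sprintf("id%03d", seq_len(n_known))
  unknown_ids <- sprintf("unk%03d", seq_len(n_unknown))
  sizes <- list(known_train = train_per_identity, known_gallery = n_img,
                known_test = known_test_per_identity,
                unknown_register = n_img,
                unknown_test = unknown_test_per_identity)
  split_known <- c(TRUE, TRUE, TRUE, FALSE, FALSE)

  if (level == "embedding") {
    set.seed(derive_seed(seed, 1L))
    if (is.null(kappa)) kappa <- 4 * dim
    means <- sample_means(n_id, dim, min_angle_deg)
    draw <- function(id_idx, n) rvmf(n, means[id_idx, ], kappa)
  } else {
    iopts <- utils::modifyList(list(seed = derive_seed(seed, 1L)), image_opts)
    ispec <- do.call(image_spec, iopts)
    set.seed(derive_seed(seed, 1L))
    params <- identity_pattern_params(n_id, ispec)
    draw <- function(id_idx, n)
      lapply(seq_len(n), function(j) render_one(params[[id_idx]], ispec))
  }

  set.seed(derive_seed(seed, 2L))
  proto <- list()
  for (si in seq_along(sizes)) {
    nm <- names(sizes)[si]
    ids <- if (split_known[si]) known_ids else unknown_ids
    idx <- if (split_known[si]) seq_len(n_known) else
      n_known + seq_len(n_unknown)
    items <- list(); labels <- character()
    for (ii in seq_along(idx)) {
      it <- draw(idx[ii], sizes[[si]])
      items[[ii]] <- it
      labels <- c(labels, rep(ids[ii], sizes[[si]]))
    }
    items <- if (level == "embedding") do.call(rbind, items) else
      do.call(c, items)
    proto[[nm]] <- list(items = items, labels = labels)
  }
  structure(c(proto, list(known_ids = known_ids, unknown_ids = unknown_ids,
                          level = level, dim = if (level == "embedding") dim
                          else NULL,
                          kappa = if (level == "embedding") kappa else NULL,
                          n_img = n_img, seed = seed)),
            class = "synthetic_protocol")
}

#' Small protocol preset for fast experimentation
#'
#' 8 known and 3 unknown identities with 10 registration embeddings per
#' identity, the scaled-down analogue of the full study conditions.
#'
#' @param ... overrides passed to [make_protocol()].
#' @export
scaled_protocol <- function(...) {
  args <- utils::modifyList(
    list(n_known = 8, n_unknown = 3, n_img = 10, train_per_identity = 40,
         known_test_per_identity = 20, unknown_test_per_identity = 20),
    list(...))
  do.call(make_protocol, args)
}

#' @export
print.synthetic_protocol <- function(x, ...) {
  cat(sprintf("synthetic %s-level protocol: %d known + %d unknown identities\n",
              x$level, length(x$known_ids), length(x$unknown_ids)))
  for (nm in c("known_train", "known_gallery", "known_test",
               "unknown_register", "unknown_test"))
    cat(sprintf("  %-17s %d items\n", nm, length(x[[nm]]$labels)))
  invisible(x)
}
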