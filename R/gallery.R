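# The feature gallery: an identity-indexed store of unit-norm reference
# embeddings supporting 1:N cosine matching, threshold-gated open-set
# decisions, and dynamic enrollment of unseen individuals.

#' Sentinel label for queries rejected as unknown
#' @export
OSR_UNKNOWN <- "<unknown>"

#' Cosine similarity of two vectors
#'
#' `sum(a*b) / (|a| |b|)`; magnitude-free, in `[-1, 1]`.
#'
#' @param a,b numeric vectors of equal length, neither zero.
#' @return scalar similarity.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop_shape("vectors differ in length")
  check_finite(a, "a"); check_finite(b, "b")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12)
    stop_validation("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Create an empty feature gallery
#'
#' The gallery stores, per enrolled identity, a fixed number of unit-norm
#' reference embeddings (conceptually an identities x images x dimension
#' array). In strict mode every identity must contribute exactly
#' `images_per_identity` embeddings; in lenient mode ragged counts are kept.
#'
#' @param dim embedding dimension.
#' @param images_per_identity reference embeddings per identity (default 30).
#' @param strict enforce the per-identity count exactly.
#' @return a `feature_gallery` object.
#' @export
feature_gallery <- function(dim, images_per_identity = 30, strict = FALSE) {
  if (dim < 1) stop_validation("dim must be >= 1")
  if (images_per_identity < 1)
    stop_validation("images_per_identity must be >= 1")
  structure(list(embeddings = list(), dim = as.integer(dim),
                 images_per_identity = as.integer(images_per_identity),
                 strict = strict),
            class = "feature_gallery")
}

#' Number of enrolled identities
#' @param gallery a `feature_gallery`.
#' @return integer count.
#' @export
n_identities <- function(gallery) length(gallery$embeddings)

#' Identity labels enrolled in a gallery
#' @param gallery a `feature_gallery`.
#' @return character vector in enrollment order.
#' @export
identity_ids <- function(gallery) names(gallery$embeddings)

#' Register an identity's reference embeddings
#'
#' Adds one identity and its reference set; vectors are unit-normalized on
#' entry and existing entries are untouched.
#'
#' @param gallery a [feature_gallery()].
#' @param identity label (coerced to character); must not already be enrolled.
#' @param embeddings matrix of reference embeddings, one per row.
#' @return the grown gallery.
#' @export
register_identity <- function(gallery, identity, embeddings) {
  identity <- as.character(identity)
  if (identity %in% identity_ids(gallery))
    stop_state("identity '", identity, "' is already registered")
  m <- as_embedding_matrix(embeddings)
  if (ncol(m) != gallery$dim)
    stop_shape("embedding dimension ", ncol(m),
               " does not match gallery dimension ", gallery$dim)
  if (gallery$strict && nrow(m) != gallery$images_per_identity)
    stop_validation("strict gallery expects exactly ",
                    gallery$images_per_identity,
                    " embeddings per identity, got ", nrow(m))
  gallery$embeddings[[identity]] <- l2_normalize(m)
  gallery
}

#' Match a query embedding against the gallery (1:N)
#'
#' Computes the cosine similarity of the query to every stored vector. Under
#' `"max"` aggregation an identity's score is the highest similarity over its
#' stored vectors (so the overall best score is the maximum over all vectors
#' in the gallery); `"mean"` averages per identity. Matching is invariant to
#' positive rescaling of the query.
#'
#' @param gallery a non-empty [feature_gallery()].
#' @param query numeric vector of gallery dimension.
#' @param k how many ranked identities to return (truncated to the number
#'   enrolled).
#' @param aggregation `"max"` or `"mean"` per-identity score.
#' @return a `match_result` list: `best_identity`, `best_score`, and `topk`
#'   data frame (identity, score) sorted by descending score.
#' @export
match_query <- function(gallery, query, k = 5,
                        aggregation = c("max", "mean")) {
  aggregation <- match.arg(aggregation)
  if (n_identities(gallery) == 0)
    stop_state("cannot match against an empty gallery")
  if (length(query) != gallery$dim)
    stop_shape("query dimension ", length(query),
               " does not match gallery dimension ", gallery$dim)
  q <- l2_normalize(query)
  scores <- vapply(gallery$embeddings, function(m) {
    sims <- drop(m %*% q)
    if (aggregation == "max") max(sims) else mean(sims)
  }, numeric(1))
  ord <- order(-scores, seq_along(scores))   # ties -> earliest enrolled
  kk <- min(k, length(scores))
  topk <- data.frame(identity = names(scores)[ord][seq_len(kk)],
                     score = unname(scores[ord][seq_len(kk)]),
                     stringsAsFactors = FALSE)
  structure(list(best_identity = topk$identity[1],
                 best_score = topk$score[1], topk = topk,
                 aggregation = aggregation),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("best match: %s (score %.4f, %s aggregation)\n",
              x$best_identity, x$best_score, x$aggregation))
  print(x$topk, row.names = FALSE)
  invisible(x)
}

#' Threshold-gated open-set decision
#'
#' A best score at or above the threshold accepts the match (a score exactly
#' equal to the threshold counts as known: only scores strictly below it are
#' rejected); otherwise the query is declared unknown.
#'
#' @param result a `match_result` from [match_query()].
#' @param threshold acceptance threshold in `[-1, 1]`.
#' @return the matched identity, or [OSR_UNKNOWN].
#' @export
open_set_decide <- function(result, threshold) {
  if (threshold < -1 || threshold > 1)
    stop_validation("threshold must lie in [-1, 1]")
  if (result$best_score >= threshold) result$best_identity else OSR_UNKNOWN
}

#' Dynamic registration of unknown individuals
#'
#' Processes query batches grouped by putative individual. For each group the
#' best similarity over its queries is compared with the threshold: if it
#' clears the threshold the group is mapped to the best-matching enrolled
#' identity (no growth); otherwise the individual is enrolled under a fresh
#' auto-generated ID using its supplied registration embeddings. IDs are
#' `novel_<n>` with n increasing in processing order, so the outcome is
#' deterministic given the stream order.
#'
#' @param gallery a non-empty [feature_gallery()].
#' @param groups named list; each element is a list with `queries` (matrix of
#'   query embeddings for that individual) and `register` (matrix of
#'   registration embeddings stored if the individual is new).
#' @param threshold acceptance threshold.
#' @param aggregation passed to [match_query()].
#' @return list with `gallery` (possibly grown) and `log`, a data frame with
#'   one row per query (group, query index, best identity, score, decision,
#'   assigned ID, threshold).
#' @export
dynamic_register <- function(gallery, groups, threshold,
                             aggregation = "max") {
  if (n_identities(gallery) == 0)
    stop_state("dynamic registration requires a non-empty gallery")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop_validation("groups must be a named list (one name per individual)")
  novel_counter <- sum(grepl("^novel_", identity_ids(gallery)))
  logs <- list()
  for (g in names(groups)) {
    grp <- groups[[g]]
    q <- as_embedding_matrix(grp$queries, "queries")
    res <- lapply(seq_len(nrow(q)), function(i)
      match_query(gallery, q[i, ], k = 1, aggregation = aggregation))
    best_scores <- vapply(res, function(r) r$best_score, numeric(1))
    ib <- which.max(best_scores)
    accept <- best_scores[ib] >= threshold
    if (accept) {
      assigned <- res[[ib]]$best_identity
    } else {
      if (is.null(grp$register))
        stop_validation("group '", g, "' is unknown but supplies no ",
                        "registration embeddings")
      reg <- as_embedding_matrix(grp$register, "register")
      if (gallery$strict && nrow(reg) != gallery$images_per_identity)
        stop_validation("registration set for '", g, "' has ", nrow(reg),
                        " embeddings; strict gallery requires ",
                        gallery$images_per_identity)
      novel_counter <- novel_counter + 1
      assigned <- paste0("novel_", novel_counter)
      gallery <- register_identity(gallery, assigned, reg)
    }
    logs[[g]] <- data.frame(
      group = g, query = seq_len(nrow(q)),
      best_identity = vapply(res, function(r) r$best_identity, character(1)),
      best_score = best_scores,
      decision = if (accept) "known" else "new",
      assigned_id = assigned, threshold = threshold,
      stringsAsFactors = FALSE)
  }
  list(gallery = gallery, log = do.call(rbind, c(logs, make.row.names = FALSE)))
}

#' @export
print.feature_gallery <- function(x, ...) {
  cat(sprintf("feature gallery: %d identities, dim %d, %d ref/identity (%s)\n",
              n_identities(x), x$dim, x$images_per_identity,
              if (x$strict) "strict" else "lenient"))
  invisible(x)
}

#' Persist a gallery to disk
#'
#' Writes a JSON manifest (identity order, per-identity counts, dimension,
#' images-per-identity, strictness) alongside a CSV of all embeddings
#' (identity column + one column per dimension, full precision). The
#' [read_gallery()] round trip reproduces the gallery to floating-point
#' representation.
#'
#' @param gallery a [feature_gallery()].
#' @param path directory to write `manifest.json` and `embeddings.csv` into.
#' @return `path`, invisibly.
#' @export
write_gallery <- function(gallery, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = "pigosr-gallery", version = 1L,
                   dim = gallery$dim,
                   images_per_identity = gallery$images_per_identity,
                   strict = gallery$strict,
                   identity_ids = as.list(identity_ids(gallery)),
                   counts = lapply(gallery$embeddings, nrow))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (n_identities(gallery) > 0) {
    rows <- do.call(rbind, gallery$embeddings)
    df <- data.frame(identity = rep(identity_ids(gallery),
                                    vapply(gallery$embeddings, nrow,
                                           integer(1))),
                     rows, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(identity = character())
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   file.path(path, "embeddings.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a gallery written by [write_gallery()]
#'
#' @param path directory containing `manifest.json` and `embeddings.csv`.
#' @return a [feature_gallery()].
#' @export
read_gallery <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop_validation("no manifest.json under ", path)
  manifest <- tryCatch(jsonlite::read_json(mf),
                       error = function(e)
                         stop_validation("corrupt gallery manifest: ",
                                         conditionMessage(e)))
  if (!identical(manifest$format, "pigosr-gallery"))
    stop_validation("not a gallery manifest: ", mf)
  g <- feature_gallery(dim = manifest$dim,
                       images_per_identity = manifest$images_per_identity,
                       strict = isTRUE(manifest$strict))
  ids <- unlist(manifest$identity_ids)
  if (length(ids) == 0) return(g)
  df <- utils::read.csv(file.path(path, "embeddings.csv"),
                        stringsAsFactors = FALSE)
  m <- unname(as.matrix(df[, -1, drop = FALSE]))
  for (id in ids)
    g <- register_identity(g, id, m[df$identity == id, , drop = FALSE])
  g
}
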