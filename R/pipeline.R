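# Glue between the synthetic protocol, the embedder, the gallery and the
# evaluation suite: register a gallery from a protocol, score its test
# queries, and run threshold-gated dynamic registration.

embed_items <- function(items, model = NULL) {
  if (is.null(model)) {
    if (!is.matrix(items))
      stop_validation("no model supplied: protocol items must already be ",
                      "embedding vectors")
    l2_normalize(items)
  } else {
    predict(model, items)
  }
}

#' Register a protocol's gallery split
#'
#' Enrolls every known identity with its gallery-registration embeddings
#' (embedded through `model` when one is given, otherwise the raw
#' embedding-level items).
#'
#' @param protocol a [make_protocol()] object.
#' @param model optional `osr_embedder`.
#' @param strict enforce the per-identity count.
#' @return a [feature_gallery()].
#' @export
protocol_gallery <- function(protocol, model = NULL, strict = FALSE) {
  sp <- protocol$known_gallery
  first <- if (is.matrix(sp$items)) sp$items[1, , drop = FALSE] else
    sp$items[1]
  dim_out <- ncol(embed_items(
    if (is.matrix(sp$items)) first else first, model))
  g <- feature_gallery(dim = dim_out,
                       images_per_identity = protocol$n_img, strict = strict)
  for (id in unique(sp$labels)) {
    sel <- sp$labels == id
    items <- if (is.matrix(sp$items)) sp$items[sel, , drop = FALSE] else
      sp$items[sel]
    g <- register_identity(g, id, embed_items(items, model))
  }
  g
}

#' Score a protocol's test queries against a gallery
#'
#' Known-test queries keep their identity as ground truth; unknown-test
#' queries carry [OSR_UNKNOWN].
#'
#' @param protocol a [make_protocol()] object.
#' @param gallery a [feature_gallery()].
#' @param model optional `osr_embedder`.
#' @param aggregation passed to [match_query()].
#' @return a [score_table()].
#' @export
protocol_scores <- function(protocol, gallery, model = NULL,
                            aggregation = "max") {
  kt <- protocol$known_test; ut <- protocol$unknown_test
  q_known <- embed_items(kt$items, model)
  q_unknown <- embed_items(ut$items, model)
  score_queries(gallery, rbind(q_known, q_unknown),
                c(kt$labels, rep(OSR_UNKNOWN, length(ut$labels))),
                aggregation = aggregation)
}

#' Dynamic-registration groups from a protocol
#'
#' One group per unknown identity (its test queries plus its registration
#' embeddings) and one per known identity (its test queries; resubmission of
#' an enrolled individual must not grow the gallery).
#'
#' @param protocol a [make_protocol()] object.
#' @param model optional `osr_embedder`.
#' @param include_known include the known identities as resubmitted groups.
#' @return named list consumable by [dynamic_register()].
#' @export
protocol_groups <- function(protocol, model = NULL, include_known = TRUE) {
  groups <- list()
  ur <- protocol$unknown_register; ut <- protocol$unknown_test
  for (id in unique(ur$labels)) {
    sel_q <- ut$labels == id; sel_r <- ur$labels == id
    groups[[id]] <- list(
      queries = embed_items(
        if (is.matrix(ut$items)) ut$items[sel_q, , drop = FALSE] else
          ut$items[sel_q], model),
      register = embed_items(
        if (is.matrix(ur$items)) ur$items[sel_r, , drop = FALSE] else
          ur$items[sel_r], model))
  }
  if (include_known) {
    kt <- protocol$known_test
    for (id in unique(kt$labels)) {
      sel <- kt$labels == id
      groups[[id]] <- list(queries = embed_items(
        if (is.matrix(kt$items)) kt$items[sel, , drop = FALSE] else
          kt$items[sel], model))
    }
  }
  groups
}

#' End-to-end open-set run on a protocol
#'
#' Registers the gallery, scores the known and unknown test queries, and
#' evaluates (sweeping the threshold when none is given).
#'
#' @param protocol a [make_protocol()] object.
#' @param model optional `osr_embedder` (required at image level).
#' @param threshold operating threshold; `NULL` sweeps for the F1-Open
#'   optimum.
#' @param aggregation passed to [match_query()].
#' @return list with `gallery`, `table` and `report` (an `eval_report`).
#' @export
run_open_set <- function(protocol, model = NULL, threshold = NULL,
                         aggregation = "max") {
  gallery <- protocol_gallery(protocol, model)
  table <- protocol_scores(protocol, gallery, model, aggregation)
  list(gallery = gallery, table = table,
       report = evaluate_open_set(table, threshold))
}
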