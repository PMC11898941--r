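# internal validation helpers shared across modules

stop_validation <- function(...) {
  stop(structure(class = c("pigosr_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_state <- function(...) {
  stop(structure(class = c("pigosr_state_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_shape <- function(...) {
  stop(structure(class = c("pigosr_shape_error", "pigosr_validation_error",
                           "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_validation(what, " must be finite")
  invisible(x)
}

as_embedding_matrix <- function(x, what = "embeddings") {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(x) || !is.numeric(x))
    stop_validation(what, " must be a numeric matrix (rows = samples)")
  check_finite(x, what)
  x
}

#' Normalize vectors to unit Euclidean length
#'
#' Row-wise L2 normalization. Cosine matching and the angular-margin loss
#' both operate on directions only, so every embedding entering the gallery
#' or the loss is first projected onto the unit hypersphere.
#'
#' @param x numeric vector, or matrix with one vector per row.
#' @return object of the same shape with each (row) vector of norm 1.
#' @examples
#' l2_normalize(c(3, 4))            # 0.6 0.8
#' l2_normalize(rbind(c(1, 0), c(2, 2)))
#' @export
l2_normalize <- function(x) {
  vec <- is.vector(x)
  m <- as_embedding_matrix(x, "vectors")
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-12))
    stop_validation("cannot normalize a zero vector")
  out <- m / nrm
  if (vec) drop(out) else out
}

# deterministic child seeds derived from one master seed; kept < 2^31
derive_seed <- function(seed, stream) {
  # double arithmetic: integer multiplication overflows for large seeds
  as.integer((as.numeric(seed) * 69069 + as.numeric(stream) * 1013) %%
               2147483629)
}
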