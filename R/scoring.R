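#' Bilinear and inner-product pair scores
#'
#' `score_bilinear()` evaluates the relational score
#' \eqn{E_i M^{(k)} E_j^T} of a drug pair under the type-\eqn{k} relation
#' matrix. Because the learned \eqn{M^{(k)}} is not constrained to be
#' symmetric while the DDI network is undirected, the pair-level score
#' used everywhere downstream is the orientation-symmetrized average
#' \eqn{\frac{1}{2}(s_{ij} + s_{ji})} (see [score_pairs()]).
#' `score_inner()` is the inner-product score \eqn{\langle E_i, E_j
#' \rangle} used with SVD-style embeddings, defined for distinct drugs.
#'
#' @param E_i,E_j Length-d embedding vectors.
#' @param M_k d x d relation matrix.
#' @return A scalar score; higher means a more probable interaction.
#' @examples
#' score_bilinear(c(1, 0), diag(2), c(1, 0))  # 1
#' score_inner(c(1, 2, 3), c(4, 5, 6))        # 32
#' @export
score_bilinear <- function(E_i, M_k, E_j) {
  E_i <- as.numeric(E_i)
  E_j <- as.numeric(E_j)
  d <- length(E_i)
  if (length(E_j) != d || !all(dim(M_k) == c(d, d))) {
    abort("dimension mismatch between embeddings and relation matrix")
  }
  drop(E_i %*% M_k %*% E_j)
}

#' @rdname score_bilinear
#' @export
score_inner <- function(E_i, E_j) {
  E_i <- as.numeric(E_i)
  E_j <- as.numeric(E_j)
  if (length(E_i) != length(E_j)) abort("embedding length mismatch")
  if (identical(E_i, E_j)) {
    warn("inner-product score of a drug with itself requested")
  }
  sum(E_i * E_j)
}

#' Score a set of drug pairs for every interaction type
#'
#' Fills a pairs x types score matrix: the symmetrized bilinear score per
#' relation matrix, or a single inner-product column. Embedding rows may
#' come from training (existing drugs) or from the attribute mapping (new
#' drugs); every drug named in `pairs` must have a row in `E`.
#'
#' @param E Embedding matrix with drug identifiers as row names.
#' @param M List of d x d relation matrices (one per type); ignored for
#'   `scorer = "inner"`.
#' @param pairs Data frame with columns `drug1`, `drug2`.
#' @param scorer `"bilinear"` (multi- or single-type) or `"inner"`
#'   (single-type baseline).
#' @return A `ddi_scores` object: `pairs` (tibble), `scores` (pairs x
#'   types matrix), `scorer`, `mode`. `as_tibble()` gives the long
#'   (drug1, drug2, type, score) form.
#' @export
score_pairs <- function(E, M, pairs, scorer = c("bilinear", "inner")) {
  scorer <- match.arg(scorer)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("drug1", "drug2") %in% names(pairs)))
  missing <- setdiff(unique(c(pairs$drug1, pairs$drug2)), rownames(E))
  if (length(missing) > 0L) {
    abort(paste0("no embedding for drug(s): ", paste(missing, collapse = ", ")))
  }
  Ei <- E[pairs$drug1, , drop = FALSE]
  Ej <- E[pairs$drug2, , drop = FALSE]
  if (scorer == "inner") {
    scores <- matrix(unname(rowSums(Ei * Ej)), ncol = 1)
    colnames(scores) <- names(M)[1] %||% "interacts"
  } else {
    scores <- vapply(M, function(Mk) {
      Ms <- (Mk + t(Mk)) / 2  # symmetrized pair score 0.5*(s_ij + s_ji)
      unname(rowSums((Ei %*% Ms) * Ej))
    }, numeric(nrow(pairs)))
    if (nrow(pairs) == 1L) scores <- matrix(scores, nrow = 1)
    dimnames(scores) <- list(NULL, names(M))
  }
  structure(list(pairs = as_tibble(pairs[, c("drug1", "drug2")]),
                 scores = scores, scorer = scorer,
                 mode = if (ncol(scores) > 1L) "multi-type" else "single-type"),
            class = "ddi_scores")
}

#' @export
print.ddi_scores <- function(x, ...) {
  cat("<ddi_scores> ", nrow(x$scores), " pair(s) x ", ncol(x$scores),
      " type(s), scorer = ", x$scorer, "\n", sep = "")
  invisible(x)
}

#' @method as_tibble ddi_scores
#' @export
as_tibble.ddi_scores <- function(x, ...) {
  long <- as.data.frame(x$scores)
  long <- dplyr::bind_cols(x$pairs, long)
  tidyr::pivot_longer(long, -c("drug1", "drug2"),
                      names_to = "type", values_to = "score")
}

#' Predict the interaction type of each scored pair
#'
#' Per pair, the predicted type is the argmax over type columns (ties
#' broken by the smallest type index); the pair is flagged as interacting
#' when that maximum score reaches `threshold`. Scores live on the 0/1
#' reconstruction scale of the training loss, so 0.5 is the natural
#' occurrence threshold.
#'
#' @param result A multi-type [score_pairs()] result.
#' @param threshold Occurrence decision threshold on the raw score.
#' @return A tibble: `drug1`, `drug2`, `type` (predicted), `score` (the
#'   maximum), `interacts` (logical flag).
#' @export
predict_types <- function(result, threshold = 0.5) {
  stopifnot(inherits(result, "ddi_scores"))
  if (result$mode != "multi-type") abort("predict_types needs a multi-type result")
  best <- max.col(result$scores, ties.method = "first")
  smax <- result$scores[cbind(seq_len(nrow(result$scores)), best)]
  dplyr::mutate(result$pairs,
                type = colnames(result$scores)[best],
                score = smax,
                interacts = smax >= threshold)
}
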