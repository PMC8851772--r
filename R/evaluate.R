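#' Drug-wise cold-start cross-validation folds
#'
#' Splits the drugs (not the edges) into `k_folds` near-equal groups by a
#' seeded permutation. In fold \eqn{f} the \eqn{f}-th group plays the
#' "new" drugs — removed from the network entirely — and the rest are
#' the "existing" drugs used for training. Each fold carries the derived
#' evaluation pair sets: S1 = all (new, existing) unordered pairs and
#' S2 = all (new, new) unordered pairs. Every drug is "new" exactly once
#' across the folds.
#'
#' @param n_drugs Number of drugs.
#' @param k_folds Number of folds (>= 2).
#' @param seed Integer seed for the permutation.
#' @return A list of `cold_start_split` objects with fields `fold`,
#'   `existing`, `new` (drug index vectors), `s1_pairs` and `s2_pairs`
#'   (2-column index matrices, new drug first).
#' @export
make_folds <- function(n_drugs, k_folds = 10, seed = 1) {
  stopifnot(k_folds >= 2, n_drugs >= k_folds)
  withr::local_seed(seed)
  perm <- sample.int(n_drugs)
  group <- integer(n_drugs)
  group[perm] <- rep(seq_len(k_folds), length.out = n_drugs)
  lapply(seq_len(k_folds), function(f) {
    new <- which(group == f)
    existing <- which(group != f)
    s1 <- cbind(new = rep(new, each = length(existing)),
                existing = rep(existing, times = length(new)))
    s2 <- if (length(new) >= 2) t(utils::combn(new, 2)) else
      matrix(integer(0), 0, 2)
    colnames(s2) <- c("new1", "new2")
    structure(list(fold = f, existing = existing, new = new,
                   s1_pairs = s1, s2_pairs = s2),
              class = "cold_start_split")
  })
}

#' Restrict a dataset to a fold's existing-drug subnetwork
#'
#' The training view of a cold-start fold: the adjacency tensor over
#' existing x existing drugs only (attributes subset accordingly). Edges
#' touching any held-out drug are absent by construction; see
#' [audit_leakage()] for the explicit check.
#'
#' @param dataset A [ddi_dataset()].
#' @param split A `cold_start_split` from [make_folds()].
#' @return A `ddi_dataset` over the existing drugs.
#' @export
fold_training_dataset <- function(dataset, split) {
  ex <- split$existing
  adjacency <- lapply(dataset$adjacency, function(A) A[ex, ex, drop = FALSE])
  out <- dataset
  out$drug_ids <- dataset$drug_ids[ex]
  out$adjacency <- adjacency
  if (!is.null(dataset$attributes)) {
    out$attributes <- dataset$attributes[ex, , drop = FALSE]
  }
  out
}

#' Audit cold-start folds for training leakage
#'
#' Rebuilds every fold's training tensor and counts nonzero entries that
#' involve a held-out ("new") drug — embedding each training slice back
#' into the full drug index space and masking pairs with at least one new
#' drug. Any nonzero count means an edge of a new drug reached training.
#'
#' @param dataset A [ddi_dataset()].
#' @param folds List of splits from [make_folds()].
#' @return A tibble with one row per fold: `fold`, `n_violations`
#'   (should be 0 everywhere), `n_train_edges`.
#' @export
audit_leakage <- function(dataset, folds) {
  n <- n_drugs(dataset)
  rows <- lapply(folds, function(split) {
    train <- fold_training_dataset(dataset, split)
    new_mask <- matrix(FALSE, n, n)
    new_mask[split$new, ] <- TRUE
    new_mask[, split$new] <- TRUE
    violations <- 0
    edges <- 0
    for (k in seq_along(train$adjacency)) {
      full <- matrix(0, n, n)
      full[split$existing, split$existing] <- train$adjacency[[k]]
      violations <- violations + sum(full[new_mask] != 0)
      edges <- edges + sum(full) / 2
    }
    tibble(fold = split$fold, n_violations = violations, n_train_edges = edges)
  })
  dplyr::bind_rows(rows)
}

#' Ground-truth labels for a fold's evaluation pairs
#'
#' The label of pair (i, j) for type k is the adjacency entry
#' \eqn{a^{(k)}_{ij}} of the full dataset. All enumerated pairs are kept:
#' every non-edge is a negative (no negative subsampling).
#'
#' @param dataset A [ddi_dataset()] (already collapsed for single-type
#'   evaluation).
#' @param split A `cold_start_split`.
#' @param task `"S1"` (new vs existing) or `"S2"` (new vs new).
#' @return A pairs x types 0/1 matrix (type identifiers as column
#'   names), rows aligned with the split's pair matrix.
#' @export
truth_labels <- function(dataset, split, task = c("S1", "S2")) {
  task <- match.arg(task)
  pairs <- if (task == "S1") split$s1_pairs else split$s2_pairs
  out <- vapply(dataset$adjacency, function(A) A[pairs, drop = FALSE],
                numeric(nrow(pairs)))
  if (nrow(pairs) == 1L) out <- matrix(out, nrow = 1)
  if (nrow(pairs) == 0L) out <- matrix(numeric(0), 0, n_types(dataset))
  colnames(out) <- dataset$type_ids
  out
}

#' Ranking metrics: AUC and area under the precision-recall curve
#'
#' `auc_score()` is the Mann-Whitney statistic (probability that a random
#' positive outscores a random negative, ties counted half), computed
#' from midranks. `aupr_score()` is the average-precision form of the
#' area under the precision-recall step curve, stepping through the
#' unique score values in decreasing order. Both need at least one
#' positive; AUC also needs a negative — otherwise `NA` is returned and
#' the caller should mark the type as skipped.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 (or logical) label vector of the same length.
#' @return A scalar in \[0, 1\], or `NA` when undefined.
#' @examples
#' auc_score(c(3, 2, 1), c(1, 0, 0))   # 1
#' auc_score(c(1, 1, 1, 1), c(1, 0, 1, 0))  # 0.5 by the tie convention
#' @export
auc_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  np <- sum(labels)
  nn <- length(labels) - np
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)  # midranks give half credit to ties
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' @rdname auc_score
#' @export
aupr_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  np <- sum(labels)
  if (np == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]
  s <- scores[ord]
  cum_tp <- cumsum(l)
  # last index of each tied-score group = the attainable operating points
  last <- c(which(diff(s) != 0), length(s))
  prec <- cum_tp[last] / last
  rec <- cum_tp[last] / np
  sum(diff(c(0, rec)) * prec)
}

#' F1 score of thresholded single-type predictions
#'
#' Binarizes scores at `threshold` and returns
#' \eqn{F1 = 2PR/(P + R)}. When there are neither predicted nor true
#' positives the score is defined as 0 with a warning.
#'
#' @inheritParams auc_score
#' @param threshold Decision threshold (score >= threshold is positive).
#' @return F1 in \[0, 1\].
#' @export
f1_binary <- function(scores, labels, threshold = 0.5) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (tp == 0 && fp == 0 && fn == 0) {
    warn("no predicted and no true positives; F1 defined as 0")
    return(0)
  }
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# threshold maximizing F1 over the attainable operating points of a
# score vector (used to report a training-data-optimal threshold)
best_f1_threshold <- function(scores, labels) {
  labels <- as.numeric(labels)
  np <- sum(labels)
  if (np == 0) return(0.5)
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]
  s <- scores[ord]
  cum_tp <- cumsum(l)
  last <- c(which(diff(s) != 0), length(s))
  f1 <- 2 * cum_tp[last] / (last + np)
  s[last[which.max(f1)]]
}

#' Micro-averaged F1 for multi-type predictions
#'
#' Restricted to test pairs with at least one true interaction type, each
#' pair's predicted type is the argmax score column. A prediction is a
#' true positive when the predicted type is among the pair's true types;
#' every unmatched true type contributes a false negative and every wrong
#' prediction a false positive. Type-level counts are pooled globally
#' (micro-averaging): \eqn{F1 = 2TP / (2TP + FP + FN)}.
#'
#' @param scores Pairs x types score matrix (e.g. from [score_pairs()]).
#' @param truth Pairs x types 0/1 matrix of true types (possibly
#'   multi-label).
#' @return Micro-F1 in \[0, 1\], or `NA` (with a warning) when no test
#'   pair interacts.
#' @export
f1_micro <- function(scores, truth) {
  stopifnot(all(dim(scores) == dim(truth)))
  has_true <- rowSums(truth) > 0
  if (!any(has_true)) {
    warn("no interacting test pairs; micro-F1 undefined")
    return(NA_real_)
  }
  S <- scores[has_true, , drop = FALSE]
  Tr <- truth[has_true, , drop = FALSE]
  pred <- max.col(S, ties.method = "first")
  hit <- Tr[cbind(seq_len(nrow(Tr)), pred)] == 1
  tp <- sum(hit)
  fp <- sum(!hit)
  fn <- sum(Tr) - tp
  2 * tp / (2 * tp + fp + fn)
}
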