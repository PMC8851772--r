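# Shared fixtures, all built in code.

# 3-edge, 2-type toy network: pairs (a,b) and (b,c) of type T1, (a,c) of T2
toy_edges <- function() {
  data.frame(drug1 = c("a", "b", "a"),
             drug2 = c("b", "c", "c"),
             type = c("T1", "T1", "T2"),
             stringsAsFactors = FALSE)
}

# random symmetric zero-diagonal binary dataset built directly (bypasses
# the generator so io/rescal tests don't depend on it)
random_dataset <- function(n, m, density = 0.3, seed = 1, attributes_p = NULL) {
  withr::local_seed(seed)
  drug_ids <- sprintf("d%02d", seq_len(n))
  adjacency <- lapply(seq_len(m), function(k) {
    A <- matrix(0, n, n, dimnames = list(drug_ids, drug_ids))
    up <- which(upper.tri(A))
    on <- sample(up, max(1, round(density * length(up))))
    A[on] <- 1
    A + t(A)
  })
  names(adjacency) <- sprintf("T%d", seq_len(m))
  out <- structure(list(drug_ids = drug_ids,
                        type_ids = names(adjacency),
                        adjacency = adjacency,
                        attributes = NULL, attribute_ids = NULL),
                   class = "ddi_dataset")
  if (!is.null(attributes_p)) {
    F_mat <- matrix(rbinom(n * attributes_p, 1, 0.3), n, attributes_p,
                    dimnames = list(drug_ids, sprintf("P%d", seq_len(attributes_p))))
    out$attributes <- F_mat
    out$attribute_ids <- colnames(F_mat)
  }
  out
}

# a small realizable tensor: A^(k) = E0 M0^(k) E0^T exactly (real-valued,
# stored in the adjacency slot for loss/gradient arithmetic tests)
realizable_dataset <- function(n = 12, m = 2, d_true = 3, seed = 1) {
  withr::local_seed(seed)
  E0 <- matrix(rnorm(n * d_true, sd = 0.5), n, d_true)
  M0 <- lapply(seq_len(m), function(k) matrix(rnorm(d_true^2, sd = 0.5), d_true, d_true))
  adjacency <- lapply(M0, function(Mk) E0 %*% Mk %*% t(E0))
  drug_ids <- sprintf("d%02d", seq_len(n))
  adjacency <- lapply(adjacency, function(A) {
    dimnames(A) <- list(drug_ids, drug_ids)
    A
  })
  names(adjacency) <- sprintf("T%d", seq_len(m))
  list(dataset = structure(list(drug_ids = drug_ids, type_ids = names(adjacency),
                                adjacency = adjacency, attributes = NULL,
                                attribute_ids = NULL),
                           class = "ddi_dataset"),
       E0 = E0, M0 = M0)
}

random_model <- function(n, m, d, seed = 1, scale = 0.5) {
  withr::local_seed(seed)
  list(E = matrix(rnorm(n * d, sd = scale), n, d),
       M = lapply(seq_len(m), function(k) matrix(rnorm(d * d, sd = scale), d, d)))
}

# brute-force oracles ---------------------------------------------------

# elementwise triple-loop reconstruction loss
oracle_rescal_loss <- function(A, E, M, penalty) {
  total <- 0
  d <- ncol(E)
  for (k in seq_along(A)) {
    for (i in seq_len(nrow(E))) {
      for (j in seq_len(nrow(E))) {
        pred <- 0
        for (a in seq_len(d)) for (b in seq_len(d)) {
          pred <- pred + E[i, a] * M[[k]][a, b] * E[j, b]
        }
        total <- total + (A[[k]][i, j] - pred)^2
      }
    }
  }
  pen <- sum(unlist(lapply(M, function(Mk) Mk^2))) + sum(E^2)
  total + penalty * pen
}

# all-pairs Mann-Whitney AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  wins <- 0
  for (sp in pos) for (sn in neg) {
    wins <- wins + (sp > sn) + 0.5 * (sp == sn)
  }
  wins / (length(pos) * length(neg))
}

# precision-recall step curve walked threshold by threshold
oracle_aupr <- function(scores, labels) {
  np <- sum(labels)
  if (np == 0) return(NA_real_)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  for (t in thresholds) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / np
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

expect_same_adjacency <- function(a, b) {
  expect_identical(a$type_ids, b$type_ids)
  expect_identical(a$drug_ids, b$drug_ids)
  for (k in seq_along(a$adjacency)) {
    expect_equal(unname(a$adjacency[[k]]), unname(b$adjacency[[k]]))
  }
}
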