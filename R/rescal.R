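#' Training configuration for the bilinear embedding model
#'
#' @param dim Embedding dimension \eqn{d} (200 is a typical choice for a
#'   corpus of ~1300 drugs; tests and examples use far smaller values).
#' @param learning_rate Constant step size of full-batch gradient descent.
#' @param penalty L2 (Frobenius) regularization coefficient applied to the
#'   embedding matrix and every relation matrix.
#' @param max_iter Maximum number of gradient iterations.
#' @param patience Early stopping fires once this many iterations have
#'   produced a loss greater than the best loss seen so far (3 by default).
#' @param seed Seed for the Gaussian initialization.
#' @param init_scale Standard deviation of the Gaussian initialization.
#' @param consecutive Count only consecutive worse-than-best iterations
#'   toward `patience` instead of the cumulative total.
#' @return A `rescal_config` list.
#' @export
rescal_config <- function(dim = 200, learning_rate = 0.001, penalty = 0.01,
                          max_iter = 1000, patience = 3, seed = 1,
                          init_scale = 0.1, consecutive = FALSE) {
  stopifnot(dim >= 1, learning_rate > 0, penalty >= 0, max_iter >= 1,
            patience >= 1, init_scale > 0)
  structure(list(dim = as.integer(dim), learning_rate = learning_rate,
                 penalty = penalty, max_iter = as.integer(max_iter),
                 patience = as.integer(patience), seed = as.integer(seed),
                 init_scale = init_scale, consecutive = isTRUE(consecutive)),
            class = "rescal_config")
}

check_rescal_dims <- function(dataset, model) {
  n <- n_drugs(dataset)
  m <- n_types(dataset)
  if (nrow(model$E) != n) {
    abort(paste0("embedding rows (", nrow(model$E),
                 ") do not match drug count (", n, ")"))
  }
  if (length(model$M) != m) {
    abort(paste0("relation matrix count (", length(model$M),
                 ") does not match type count (", m, ")"))
  }
  d <- ncol(model$E)
  ok <- vapply(model$M, function(Mk) all(dim(Mk) == c(d, d)), logical(1))
  if (!all(ok)) abort("relation matrices must be d x d with d = ncol(E)")
  invisible(TRUE)
}

#' Reconstruction loss of the bilinear tensor factorization
#'
#' The training objective is the closed-world squared reconstruction
#' error of the adjacency tensor,
#' \deqn{l = \sum_k \|A^{(k)} - E M^{(k)} E^T\|_F^2
#'   + \lambda (\|E\|_F^2 + \sum_k \|M^{(k)}\|_F^2),}
#' where every tensor cell, zeros included, enters the sum: absent edges
#' are treated as observed negatives.
#'
#' @param dataset A [ddi_dataset()].
#' @param model A list with `E` (n x d) and `M` (list of d x d matrices),
#'   e.g. a fitted `rescal_model`.
#' @param penalty L2 coefficient \eqn{\lambda}.
#' @return The scalar loss.
#' @export
rescal_loss <- function(dataset, model, penalty = 0) {
  check_rescal_dims(dataset, model)
  loss_EM(dataset$adjacency, model$E, model$M, penalty)
}

loss_EM <- function(A, E, M, penalty) {
  recon <- sum(vapply(seq_along(A), function(k) {
    R <- A[[k]] - E %*% M[[k]] %*% t(E)
    sum(R * R)
  }, numeric(1)))
  recon + penalty * (sum(E * E) + sum(vapply(M, function(Mk) sum(Mk * Mk), numeric(1))))
}

#' Analytic gradients of the bilinear reconstruction loss
#'
#' With residual \eqn{R^{(k)} = A^{(k)} - E M^{(k)} E^T}:
#' \deqn{\nabla_E = \sum_k (-2 R^{(k)} E M^{(k)T} - 2 R^{(k)T} E M^{(k)})
#'   + 2\lambda E,}
#' \deqn{\nabla_{M^{(k)}} = -2 E^T R^{(k)} E + 2\lambda M^{(k)}.}
#'
#' @inheritParams rescal_loss
#' @return A list with `grad_E` (n x d) and `grad_M` (list of d x d).
#' @export
rescal_gradients <- function(dataset, model, penalty = 0) {
  check_rescal_dims(dataset, model)
  grads_EM(dataset$adjacency, model$E, model$M, penalty)
}

grads_EM <- function(A, E, M, penalty) {
  grad_E <- 2 * penalty * E
  grad_M <- vector("list", length(A))
  for (k in seq_along(A)) {
    EM <- E %*% M[[k]]
    R <- A[[k]] - EM %*% t(E)
    grad_E <- grad_E - 2 * (R %*% E %*% t(M[[k]]) + t(R) %*% EM)
    grad_M[[k]] <- -2 * t(E) %*% R %*% E + 2 * penalty * M[[k]]
  }
  list(grad_E = grad_E, grad_M = grad_M)
}

# Generic descent loop with best-iterate tracking and early stopping.
# `patience` counts iterations whose loss exceeds the best seen so far
# (cumulative by default, consecutive when `consecutive = TRUE`); the
# best-loss state, not the last, is returned.
descend <- function(state, step_fn, loss_fn, max_iter, patience,
                    consecutive = FALSE) {
  best <- loss_fn(state)
  if (!is.finite(best)) abort("initial loss is not finite")
  trace <- numeric(max_iter + 1L)
  trace[1L] <- best
  best_state <- state
  best_iter <- 0L
  worse <- 0L
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    state <- step_fn(state)
    l <- loss_fn(state)
    if (!is.finite(l)) {
      abort("loss diverged to a non-finite value; try a smaller learning rate")
    }
    trace[it + 1L] <- l
    if (l < best) {
      best <- l
      best_state <- state
      best_iter <- it
      if (consecutive) worse <- 0L
    } else if (l > best) {
      worse <- worse + 1L
      if (worse >= patience) break
    }
  }
  list(state = best_state, loss_trace = trace[seq_len(it + 1L)],
       stopped_at = it, best_iter = best_iter)
}

#' Fit drug embeddings and relation matrices by gradient descent
#'
#' Factorizes the stacked adjacency tensor \eqn{A^{(k)} \approx
#' E M^{(k)} E^T}: one shared embedding row per drug plus one relation
#' matrix per interaction type (a single matrix in single-type mode).
#' Parameters are initialized with seeded Gaussian entries and updated by
#' full-batch gradient descent on [rescal_loss()] at a constant learning
#' rate. The loss is recorded every iteration; training stops at
#' `max_iter` or when `patience` iterations have exceeded the best loss
#' seen so far, and the best-loss iterate is returned.
#'
#' @param dataset A [ddi_dataset()].
#' @param config A [rescal_config()].
#' @param init Optional list with `E` and `M` to use instead of the
#'   seeded random initialization (e.g. for warm starts).
#' @return A `rescal_model`: `E`, `M`, `config`, `loss_trace` (per
#'   iteration, index 1 = initial loss), `converged_at` (last iteration
#'   run) and `best_iter`.
#' @examples
#' sim <- simulate_ddi(n = 16, p = 10, m = 2, d_true = 3, seed = 1)
#' fit <- fit_rescal(sim$dataset, rescal_config(dim = 4, learning_rate = 0.01,
#'                                              penalty = 0, max_iter = 50))
#' tail(fit$loss_trace, 1) < fit$loss_trace[1]
#' @export
fit_rescal <- function(dataset, config = rescal_config(), init = NULL) {
  stopifnot(inherits(dataset, "ddi_dataset"), inherits(config, "rescal_config"))
  A <- dataset$adjacency
  n <- n_drugs(dataset)
  m <- n_types(dataset)
  d <- config$dim
  if (is.null(init)) {
    withr::local_seed(config$seed)
    E <- matrix(rnorm(n * d, sd = config$init_scale), n, d)
    M <- lapply(seq_len(m), function(k) {
      matrix(rnorm(d * d, sd = config$init_scale), d, d)
    })
  } else {
    E <- init$E
    M <- init$M
    stopifnot(nrow(E) == n, ncol(E) == d, length(M) == m)
  }
  lr <- config$learning_rate
  pen <- config$penalty
  step_fn <- function(state) {
    g <- grads_EM(A, state$E, state$M, pen)
    list(E = state$E - lr * g$grad_E,
         M = Map(function(Mk, Gk) Mk - lr * Gk, state$M, g$grad_M))
  }
  loss_fn <- function(state) loss_EM(A, state$E, state$M, pen)
  res <- descend(list(E = E, M = M), step_fn, loss_fn,
                 config$max_iter, config$patience, config$consecutive)
  E_best <- res$state$E
  rownames(E_best) <- dataset$drug_ids
  M_best <- res$state$M
  names(M_best) <- dataset$type_ids
  structure(list(E = E_best, M = M_best, config = config,
                 loss_trace = res$loss_trace,
                 converged_at = res$stopped_at, best_iter = res$best_iter),
            class = "rescal_model")
}

#' @export
print.rescal_model <- function(x, ...) {
  cat("<rescal_model> ", nrow(x$E), " drugs x ", ncol(x$E),
      " dims, ", length(x$M), " relation matrix(es)\n", sep = "")
  cat("  loss: ", format(x$loss_trace[1]), " -> ",
      format(min(x$loss_trace)), " (best at iteration ", x$best_iter,
      " of ", x$converged_at, ")\n", sep = "")
  invisible(x)
}

#' Embed a single-type DDI network by truncated SVD
#'
#' Baseline embedding for occurrence-only prediction: the adjacency
#' matrix is factorized as \eqn{A \approx U_d \Sigma_d V_d^T} and drugs
#' embedded as \eqn{E = U_d \Sigma_d^{1/2}}, so that \eqn{E E^T} is the
#' truncated reconstruction scored with the plain inner product.
#' The relation matrix slot holds the identity, for interface uniformity
#' with [fit_rescal()].
#'
#' @param dataset A single-type [ddi_dataset()] (collapse first if
#'   needed).
#' @param dim Embedding dimension, `1 <= dim <= n`.
#' @return A `rescal_model` with `M = list(identity)`.
#' @export
svd_embed <- function(dataset, dim) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  if (n_types(dataset) != 1L) {
    abort("svd_embed requires a single-type dataset; see collapse_single_type()")
  }
  n <- n_drugs(dataset)
  if (dim < 1 || dim > n) abort(paste0("dim must be in [1, ", n, "]"))
  s <- svd(dataset$adjacency[[1]], nu = dim, nv = 0)
  E <- s$u %*% diag(sqrt(s$d[seq_len(dim)]), dim)
  rownames(E) <- dataset$drug_ids
  structure(list(E = E, M = list(interacts = diag(dim)),
                 config = NULL, loss_trace = numeric(0),
                 converged_at = NA_integer_, best_iter = NA_integer_),
            class = "rescal_model")
}
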