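#' Fit the attribute-to-embedding bridge by partial least squares
#'
#' New drugs have no edges in the DDI network, so their embeddings cannot
#' be learned from topology. Instead a linear map \eqn{F B = E} is fitted
#' on the drugs that are in the network, regressing their learned
#' embeddings `E_train` on their binary attribute vectors `F_train`.
#' Partial least squares (PLS2, NIPALS algorithm) is used because binary
#' attribute columns are often collinear: both blocks are column-centered
#' and projected onto latent components
#' \eqn{F = T P^T + error_1}, \eqn{E = U Q^T + error_2},
#' extracted one at a time with deflation. The regression coefficient is
#' assembled in the standard PLS2 form \eqn{B = W (P^T W)^{-1} Q^T}
#' (x-weights `W`, x-loadings `P`, y-loadings `Q`); the alternative form
#' \eqn{B = W C^T} built directly from the weight matrices is available
#' via `coef_form = "weights"` for comparison, but only the default
#' satisfies \eqn{F B \approx E} on realizable data.
#'
#' With all extractable components on full-column-rank data the PLS
#' solution coincides with ordinary least squares. If the requested
#' number of components exceeds the extractable rank, extraction stops
#' early with a warning and `n_components` is reduced.
#'
#' @param F_train n_train x p binary attribute matrix (or data frame).
#' @param E_train n_train x d real embedding matrix.
#' @param n_components Number of latent components `c`,
#'   `c <= min(p, n_train - 1)`. Default `min(50, p, n_train - 1)`.
#' @param tol Relative convergence tolerance of the NIPALS inner loop on
#'   the score vector `t`.
#' @param max_inner Maximum inner iterations per component.
#' @param coef_form `"regression"` (default) or `"weights"` (see above).
#' @return A `pls_map` with coefficient matrix `B` (p x d), weights
#'   `x_weights` / `y_weights`, loadings `x_loadings` / `y_loadings`,
#'   scores `x_scores` / `y_scores`, block means `x_mean` / `y_mean`,
#'   `n_components`, and `residual_norms` (Frobenius norms of the two
#'   block residuals).
#' @examples
#' F_tr <- matrix(rbinom(80, 1, 0.4), 20, 4)
#' B_star <- matrix(rnorm(8), 4, 2)
#' fit <- fit_pls_map(F_tr, F_tr %*% B_star, n_components = 4)
#' max(abs(map_new_drugs(fit, F_tr) - F_tr %*% B_star)) < 1e-6
#' @export
fit_pls_map <- function(F_train, E_train, n_components = NULL,
                        tol = 1e-8, max_inner = 500,
                        coef_form = c("regression", "weights")) {
  coef_form <- match.arg(coef_form)
  F_train <- as.matrix(F_train)
  E_train <- as.matrix(E_train)
  storage.mode(F_train) <- "double"
  storage.mode(E_train) <- "double"
  n <- nrow(F_train)
  p <- ncol(F_train)
  d <- ncol(E_train)
  if (nrow(E_train) != n) abort("F_train and E_train must have the same rows")
  if (n < 2) abort("need at least 2 training drugs")
  cmax <- min(p, n - 1L)
  if (is.null(n_components)) n_components <- min(50L, cmax)
  if (n_components < 1 || n_components > cmax) {
    abort(paste0("n_components must be in [1, ", cmax, "]"))
  }

  x_mean <- colMeans(F_train)
  y_mean <- colMeans(E_train)
  Fc <- sweep(F_train, 2, x_mean)
  Ec <- sweep(E_train, 2, y_mean)
  if (all(abs(Fc) < 1e-12)) abort("attribute matrix has zero variance after centering")
  Fres0 <- sqrt(sum(Fc^2))
  Eres0 <- sqrt(sum(Ec^2))

  W <- matrix(0, p, n_components)   # x-weights
  C <- matrix(0, d, n_components)   # y-weights (normalized)
  P <- matrix(0, p, n_components)   # x-loadings
  Q <- matrix(0, d, n_components)   # y-loadings (regression form)
  Tm <- matrix(0, n, n_components)  # x-scores
  U <- matrix(0, n, n_components)   # y-scores
  c_used <- 0L

  for (a in seq_len(n_components)) {
    # degenerate Y block: B complete, all further components are noise
    if (sum(Ec^2) < 1e-24 * max(1, Eres0^2) || sum(Fc^2) < 1e-24) break
    u <- Ec[, which.max(colSums(Ec^2))]
    t_old <- rep(Inf, n)
    t_vec <- NULL
    for (iter in seq_len(max_inner)) {
      w <- crossprod(Fc, u)
      wn <- sqrt(sum(w^2))
      if (wn < 1e-14) break
      w <- w / wn
      t_vec <- Fc %*% w
      q <- crossprod(Ec, t_vec)
      qn <- sqrt(sum(q^2))
      if (qn < 1e-14) break
      q <- q / qn
      u <- Ec %*% q
      if (sqrt(sum((t_vec - t_old)^2)) <= tol * sqrt(sum(t_vec^2))) break
      t_old <- t_vec
    }
    if (is.null(t_vec) || sum(t_vec^2) < 1e-14) break
    tt <- sum(t_vec^2)
    p_load <- crossprod(Fc, t_vec) / tt
    q_load <- crossprod(Ec, t_vec) / tt
    Fc <- Fc - t_vec %*% t(p_load)
    Ec <- Ec - t_vec %*% t(q_load)
    W[, a] <- w
    C[, a] <- q
    P[, a] <- p_load
    Q[, a] <- q_load
    Tm[, a] <- t_vec
    U[, a] <- u
    c_used <- a
  }
  if (c_used == 0L) {
    # constant E block: the best linear predictor is the mean
    B <- matrix(0, p, d)
    keep <- integer(0)
  } else {
    if (c_used < n_components) {
      warn(paste0("extractable rank exhausted: n_components reduced from ",
                  n_components, " to ", c_used))
    }
    keep <- seq_len(c_used)
    W <- W[, keep, drop = FALSE]
    C <- C[, keep, drop = FALSE]
    P <- P[, keep, drop = FALSE]
    Q <- Q[, keep, drop = FALSE]
    Tm <- Tm[, keep, drop = FALSE]
    U <- U[, keep, drop = FALSE]
    B <- switch(coef_form,
      regression = W %*% solve(crossprod(P, W), t(Q)),
      weights = W %*% t(C))
  }
  if (!is.null(colnames(F_train))) rownames(B) <- colnames(F_train)

  structure(list(B = B, x_weights = W, y_weights = C,
                 x_loadings = P, y_loadings = Q,
                 x_scores = Tm, y_scores = U,
                 n_components = c_used, coef_form = coef_form,
                 x_mean = x_mean, y_mean = y_mean,
                 residual_norms = c(x = sqrt(sum(Fc^2)), y = sqrt(sum(Ec^2)))),
            class = "pls_map")
}

#' @export
print.pls_map <- function(x, ...) {
  cat("<pls_map> ", nrow(x$B), " attributes -> ", ncol(x$B),
      " embedding dims, ", x$n_components, " PLS component(s)\n", sep = "")
  cat("  residual norms: F ", format(x$residual_norms[["x"]]),
      ", E ", format(x$residual_norms[["y"]]), "\n", sep = "")
  invisible(x)
}

#' Embed new drugs from their attribute vectors
#'
#' Applies the fitted affine map: `(F_new - x_mean) B + y_mean`, one
#' predicted embedding row per new drug. The prediction depends only on
#' the attribute vector, so drugs with identical attributes receive
#' identical embeddings.
#'
#' @param model A [fit_pls_map()] fit.
#' @param F_new q x p binary attribute matrix for the new drugs (a single
#'   vector is treated as one row).
#' @return q x d matrix of predicted embeddings (row names carried over
#'   from `F_new`).
#' @export
map_new_drugs <- function(model, F_new) {
  stopifnot(inherits(model, "pls_map"))
  if (is.null(dim(F_new))) F_new <- matrix(F_new, nrow = 1)
  F_new <- as.matrix(F_new)
  if (ncol(F_new) != length(model$x_mean)) {
    abort(paste0("F_new has ", ncol(F_new), " columns; model expects ",
                 length(model$x_mean)))
  }
  out <- sweep(F_new, 2, model$x_mean) %*% model$B
  sweep(out, 2, model$y_mean, `+`)
}

#' @export
predict.pls_map <- function(object, newdata, ...) map_new_drugs(object, newdata)
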