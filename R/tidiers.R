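#' Tidiers for fitted objects
#'
#' broom-style accessors. `tidy()` returns the per-observation detail of
#' each object — loss per iteration for an embedding fit, one coefficient
#' per (attribute, embedding dimension) for a PLS map, per-type metrics
#' for a cross-validation run. `glance()` returns a one-row summary.
#'
#' @param x A `rescal_model`, `pls_map` or `ddi_cv` object.
#' @param ... Unused.
#' @return A tibble.
#' @name ddicold-tidiers
NULL

#' @rdname ddicold-tidiers
#' @method tidy rescal_model
#' @export
tidy.rescal_model <- function(x, ...) {
  tibble(iteration = seq_along(x$loss_trace) - 1L, loss = x$loss_trace)
}

#' @rdname ddicold-tidiers
#' @method glance rescal_model
#' @export
glance.rescal_model <- function(x, ...) {
  tibble(n_drugs = nrow(x$E), dim = ncol(x$E), n_types = length(x$M),
         initial_loss = x$loss_trace[1] %||% NA_real_,
         best_loss = if (length(x$loss_trace)) min(x$loss_trace) else NA_real_,
         best_iter = x$best_iter, iterations = x$converged_at)
}

#' @rdname ddicold-tidiers
#' @method tidy pls_map
#' @export
tidy.pls_map <- function(x, ...) {
  B <- x$B
  tibble(attribute = rep(rownames(B) %||% as.character(seq_len(nrow(B))),
                         times = ncol(B)),
         dimension = rep(seq_len(ncol(B)), each = nrow(B)),
         estimate = as.vector(B))
}

#' @rdname ddicold-tidiers
#' @method glance pls_map
#' @export
glance.pls_map <- function(x, ...) {
  tibble(n_attributes = nrow(x$B), dim = ncol(x$B),
         n_components = x$n_components,
         residual_x = x$residual_norms[["x"]],
         residual_y = x$residual_norms[["y"]])
}

#' @rdname ddicold-tidiers
#' @method tidy ddi_cv
#' @export
tidy.ddi_cv <- function(x, ...) x$per_type

#' @rdname ddicold-tidiers
#' @method glance ddi_cv
#' @export
glance.ddi_cv <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "task",
                       values_from = -"task",
                       names_glue = "{tolower(task)}_{.value}")
}
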