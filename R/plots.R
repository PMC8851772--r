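#' Plot the training loss trace of an embedding fit
#'
#' Loss per gradient iteration on a log scale, with the best-loss
#' iterate (the one returned by [fit_rescal()]) marked.
#'
#' @param object A `rescal_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rescal_model
#' @export
autoplot.rescal_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(xintercept = object$best_iter, linetype = "dashed",
                        color = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "reconstruction loss (log scale)",
                  title = "Bilinear factorization training trace") +
    ggplot2::theme_minimal()
}

#' Plot per-type cold-start performance
#'
#' One point per (fold, interaction type), AUC and AUPR side by side,
#' faceted by evaluation task (S1 = new vs existing, S2 = new vs new).
#' Types skipped in a fold (no positives or no training edges) are
#' omitted.
#'
#' @param object A `ddi_cv` result from [run_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddi_cv
#' @export
autoplot.ddi_cv <- function(object, ...) {
  df <- object$per_type |>
    tidyr::pivot_longer(c("auc", "aupr"), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$value,
                                   color = .data$metric)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4),
                        alpha = 0.7) +
    ggplot2::facet_wrap(~.data$task) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "interaction type", y = "score",
                  title = "Per-type cold-start performance",
                  color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
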