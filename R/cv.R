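# One cold-start fold of the full pipeline: train embeddings on the
# existing-drug subnetwork, bridge attributes to embeddings by PLS, map
# the held-out drugs, score S1/S2 pairs, compute per-type metrics.
evaluate_fold <- function(dataset, split, config, n_components = NULL,
                          embedding = c("rescal", "svd"), threshold = 0.5) {
  embedding <- match.arg(embedding)
  if (is.null(dataset$attributes)) abort("dataset has no attributes; attach them first")
  train <- fold_training_dataset(dataset, split)

  empty_types <- dataset$type_ids[vapply(train$adjacency, sum, numeric(1)) == 0]
  if (length(empty_types) > 0L) {
    warn(paste0("type(s) with no training edges in fold ", split$fold, ": ",
                paste(empty_types, collapse = ", "),
                " (dropped from this fold's per-type metrics)"))
  }

  model <- if (embedding == "svd") svd_embed(train, config$dim)
           else fit_rescal(train, config)
  scorer <- if (embedding == "svd") "inner" else "bilinear"

  pls <- fit_pls_map(train$attributes, model$E, n_components = n_components)
  E_new <- map_new_drugs(pls, dataset$attributes[split$new, , drop = FALSE])
  rownames(E_new) <- dataset$drug_ids[split$new]
  E_all <- rbind(model$E, E_new)

  per_task <- lapply(c("S1", "S2"), function(task) {
    idx <- if (task == "S1") split$s1_pairs else split$s2_pairs
    if (nrow(idx) == 0L) return(NULL)
    pairs <- data.frame(drug1 = dataset$drug_ids[idx[, 1]],
                        drug2 = dataset$drug_ids[idx[, 2]],
                        stringsAsFactors = FALSE)
    sc <- score_pairs(E_all, model$M, pairs, scorer = scorer)
    truth <- truth_labels(dataset, split, task)

    per_type <- dplyr::bind_rows(lapply(seq_along(dataset$type_ids), function(k) {
      ty <- dataset$type_ids[k]
      evaluable <- !(ty %in% empty_types)
      col <- if (scorer == "inner") 1L else k
      tibble(fold = split$fold, task = task, type = ty,
             n_pos = sum(truth[, k]), n_pairs = nrow(truth),
             auc = if (evaluable) auc_score(sc$scores[, col], truth[, k]) else NA_real_,
             aupr = if (evaluable) aupr_score(sc$scores[, col], truth[, k]) else NA_real_)
    }))

    if (n_types(dataset) == 1L) {
      # single-type occurrence prediction: thresholded F1, plus the F1 at
      # the training-data-optimal threshold for sensitivity
      tr_pairs_idx <- which(upper.tri(train$adjacency[[1]]), arr.ind = TRUE)
      tr_pairs <- data.frame(drug1 = train$drug_ids[tr_pairs_idx[, 1]],
                             drug2 = train$drug_ids[tr_pairs_idx[, 2]])
      tr_sc <- score_pairs(model$E, model$M, tr_pairs, scorer = scorer)
      tr_lab <- train$adjacency[[1]][tr_pairs_idx]
      thr_opt <- best_f1_threshold(tr_sc$scores[, 1], tr_lab)
      f1 <- f1_binary(sc$scores[, 1], truth[, 1], threshold)
      f1_opt <- f1_binary(sc$scores[, 1], truth[, 1], thr_opt)
      f1_mic <- NA_real_
    } else {
      f1 <- NA_real_
      f1_opt <- NA_real_
      f1_mic <- if (any(rowSums(truth) > 0)) f1_micro(sc$scores, truth) else NA_real_
    }
    list(per_type = per_type,
         fold_row = tibble(fold = split$fold, task = task,
                           auc_mean = mean(per_type$auc, na.rm = TRUE),
                           aupr_mean = mean(per_type$aupr, na.rm = TRUE),
                           f1 = f1, f1_opt = f1_opt, f1_micro = f1_mic,
                           n_types_skipped = sum(is.na(per_type$auc))))
  })
  per_task <- per_task[!vapply(per_task, is.null, logical(1))]
  list(per_type = dplyr::bind_rows(lapply(per_task, `[[`, "per_type")),
       per_fold = dplyr::bind_rows(lapply(per_task, `[[`, "fold_row")),
       model = model, pls = pls)
}

#' Cold-start cross-validation of the full prediction pipeline
#'
#' Drug-wise k-fold evaluation: per fold, the held-out ("new") drugs are
#' removed from the network entirely; embeddings and relation matrices
#' are trained on the remaining existing-drug subnetwork; a PLS map from
#' attributes to embeddings is fitted on the existing drugs; the new
#' drugs are embedded from attributes alone; and every S1 (new-existing)
#' and S2 (new-new) candidate pair is scored against the ground-truth
#' adjacency. AUC and AUPR are computed per interaction type and
#' macro-averaged over the evaluable types (types with no positive test
#' pair, or no training edge in a fold, are skipped, not scored 0).
#' Single-type mode collapses the tensor to occurrence-only prediction
#' and additionally reports thresholded F1; multi-type mode reports
#' micro-averaged F1 over argmax type decisions.
#'
#' @param dataset A [ddi_dataset()] with attributes attached.
#' @param k_folds Number of drug-wise folds (default 10).
#' @param config A [rescal_config()]; one shared configuration is used
#'   for every fold.
#' @param n_components PLS components for the attribute map (default:
#'   chosen by [fit_pls_map()]).
#' @param mode `"multi"` (per-type tensor) or `"single"` (collapsed
#'   occurrence network).
#' @param embedding `"rescal"` (bilinear scores) or `"svd"`
#'   (single-type only, inner-product scores).
#' @param threshold Occurrence threshold for single-type F1.
#' @param seed Seed for the fold assignment.
#' @return A `ddi_cv` object with tibbles `per_type` (fold x task x type
#'   AUC/AUPR), `per_fold` (macro means and F1 per fold and task) and
#'   `summary` (mean and sd across folds per task), plus the settings.
#'   Use [tidy()], [glance()] and [autoplot()] on it.
#' @examples
#' sim <- simulate_ddi(n = 40, p = 20, m = 2, d_true = 3, seed = 1)
#' cv <- run_cv(sim$dataset, k_folds = 4,
#'              config = rescal_config(dim = 6, learning_rate = 0.005,
#'                                     penalty = 0, max_iter = 150, seed = 1),
#'              seed = 1)
#' glance(cv)
#' @export
run_cv <- function(dataset, k_folds = 10, config = rescal_config(),
                   n_components = NULL, mode = c("multi", "single"),
                   embedding = c("rescal", "svd"), threshold = 0.5,
                   seed = 1) {
  mode <- match.arg(mode)
  embedding <- match.arg(embedding)
  stopifnot(inherits(dataset, "ddi_dataset"))
  if (is.null(dataset$attributes)) abort("dataset has no attributes; attach them first")
  if (mode == "single") dataset <- collapse_single_type(dataset)
  if (embedding == "svd" && mode != "single") {
    abort("svd embedding supports single-type mode only")
  }
  folds <- make_folds(n_drugs(dataset), k_folds, seed)
  results <- lapply(folds, function(split) {
    evaluate_fold(dataset, split, config, n_components, embedding, threshold)
  })
  per_type <- dplyr::bind_rows(lapply(results, `[[`, "per_type"))
  per_fold <- dplyr::bind_rows(lapply(results, `[[`, "per_fold"))
  summary <- per_fold |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(dplyr::across(c("auc_mean", "aupr_mean", "f1",
                                     "f1_opt", "f1_micro"),
                                   list(mean = ~mean(.x, na.rm = TRUE),
                                        sd = ~sd(.x, na.rm = TRUE))),
                     .groups = "drop")
  structure(list(per_type = per_type, per_fold = per_fold, summary = summary,
                 settings = list(k_folds = k_folds, config = config,
                                 n_components = n_components, mode = mode,
                                 embedding = embedding, threshold = threshold,
                                 seed = seed)),
            class = "ddi_cv")
}

#' @export
print.ddi_cv <- function(x, ...) {
  cat("<ddi_cv> ", x$settings$k_folds, "-fold drug-wise cold-start CV, mode = ",
      x$settings$mode, ", embedding = ", x$settings$embedding, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Grid search over embedding hyperparameters
#'
#' Trains one model per (dim, learning rate, penalty) grid point on a
#' validation split's existing-drug subnetwork, runs the attribute map,
#' and scores the held-out S1 pairs by mean per-type AUPR. The argmax
#' configuration is returned; ties are broken toward the smaller penalty,
#' then the smaller learning rate, then grid order. Grid points whose
#' training diverges are excluded; if every point diverges an error is
#' raised.
#'
#' @param dataset A [ddi_dataset()] with attributes.
#' @param split A validation `cold_start_split` from [make_folds()].
#' @param dims,rates,penalties Grid values for the embedding dimension,
#'   learning rate and L2 penalty.
#' @param n_components PLS components passed through to the mapping.
#' @param max_iter,patience,seed Passed to [rescal_config()].
#' @return The winning [rescal_config()], with the full results table as
#'   attribute `"grid"`.
#' @export
grid_search_rescal <- function(dataset, split, dims = 200,
                               rates = c(0.001, 0.01, 0.1),
                               penalties = c(0.001, 0.01, 0.1),
                               n_components = NULL, max_iter = 1000,
                               patience = 3, seed = 1) {
  stopifnot(length(dims) > 0, length(rates) > 0, length(penalties) > 0)
  grid <- expand.grid(dim = dims, learning_rate = rates, penalty = penalties,
                      KEEP.OUT.ATTRS = FALSE)
  score_one <- function(i) {
    cfg <- rescal_config(dim = grid$dim[i], learning_rate = grid$learning_rate[i],
                         penalty = grid$penalty[i], max_iter = max_iter,
                         patience = patience, seed = seed)
    res <- tryCatch(evaluate_fold(dataset, split, cfg, n_components),
                    error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    row <- res$per_fold[res$per_fold$task == "S1", ]
    row$aupr_mean[1]
  }
  grid$s1_aupr <- vapply(seq_len(nrow(grid)), score_one, numeric(1))
  if (all(is.na(grid$s1_aupr))) abort("all grid points diverged")
  ord <- order(-grid$s1_aupr, grid$penalty, grid$learning_rate,
               seq_len(nrow(grid)), na.last = TRUE)
  best <- grid[ord[1], ]
  out <- rescal_config(dim = best$dim, learning_rate = best$learning_rate,
                       penalty = best$penalty, max_iter = max_iter,
                       patience = patience, seed = seed)
  attr(out, "grid") <- as_tibble(grid)
  out
}
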