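#' Build a multi-relational DDI dataset from an edge table
#'
#' Assembles the symmetric binary adjacency tensor of an undirected
#' drug-drug interaction (DDI) network from a long edge table. Each
#' interaction type becomes one \eqn{n \times n} slice; an edge
#' \eqn{(i, j)} of type \eqn{k} sets both \eqn{a^{(k)}_{ij}} and
#' \eqn{a^{(k)}_{ji}} to 1.
#'
#' Drug and type identifiers are arbitrary strings and are indexed in
#' first-appearance order, so the construction is deterministic for a
#' given row order. Input rows `(a, b)` and `(b, a)` denote the same
#' undirected edge; duplicated edges are collapsed idempotently with a
#' warning.
#'
#' @param edges A data frame with columns `drug1`, `drug2` and optionally
#'   `type`. When `type` is absent the network is single-type (`m = 1`).
#' @return A `ddi_dataset`: a list with `drug_ids`, `type_ids`,
#'   `adjacency` (list of symmetric 0/1 matrices, one per type, zero
#'   diagonal), and (once attached) `attributes` / `attribute_ids`.
#' @seealso [read_ddi_edges()], [attach_attributes()],
#'   [collapse_single_type()]
#' @examples
#' edges <- tibble::tibble(drug1 = c("a", "b", "a"),
#'                         drug2 = c("b", "c", "c"),
#'                         type  = c("T1", "T1", "T2"))
#' d <- ddi_dataset(edges)
#' sum(d$adjacency[[1]])  # 4 nonzeros after symmetrization
#' @export
ddi_dataset <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) abort("no edges: the edge table is empty")
  if (!all(c("drug1", "drug2") %in% names(edges))) {
    abort("edge table must have columns 'drug1' and 'drug2'")
  }
  if (!"type" %in% names(edges)) edges$type <- "interacts"
  edges$drug1 <- as.character(edges$drug1)
  edges$drug2 <- as.character(edges$drug2)
  edges$type <- as.character(edges$type)
  bad <- which(is.na(edges$drug1) | is.na(edges$drug2) | is.na(edges$type) |
                 edges$drug1 == "" | edges$drug2 == "")
  if (length(bad) > 0L) {
    abort(paste0("malformed edge row(s): ", paste(bad, collapse = ", ")))
  }
  loops <- which(edges$drug1 == edges$drug2)
  if (length(loops) > 0L) {
    abort(paste0("self-loop not allowed: row ", loops[1], " (",
                 edges$drug1[loops[1]], ", ", edges$drug2[loops[1]], ")"))
  }

  drug_ids <- unique(c(rbind(edges$drug1, edges$drug2)))
  type_ids <- unique(edges$type)
  n <- length(drug_ids)
  i <- match(edges$drug1, drug_ids)
  j <- match(edges$drug2, drug_ids)
  k <- match(edges$type, type_ids)

  key <- paste(k, pmin(i, j), pmax(i, j))
  if (anyDuplicated(key)) {
    warn(paste0(sum(duplicated(key)), " duplicate edge(s) collapsed"))
  }

  adjacency <- lapply(seq_along(type_ids), function(kk) {
    A <- matrix(0, n, n, dimnames = list(drug_ids, drug_ids))
    sel <- k == kk
    A[cbind(i[sel], j[sel])] <- 1
    A[cbind(j[sel], i[sel])] <- 1
    A
  })
  names(adjacency) <- type_ids

  structure(
    list(drug_ids = drug_ids, type_ids = type_ids, adjacency = adjacency,
         attributes = NULL, attribute_ids = NULL),
    class = "ddi_dataset"
  )
}

#' @export
print.ddi_dataset <- function(x, ...) {
  nnz <- vapply(x$adjacency, sum, numeric(1))
  cat("<ddi_dataset> ", length(x$drug_ids), " drugs, ",
      length(x$type_ids), " interaction type(s), ",
      sum(nnz) / 2, " undirected edges\n", sep = "")
  if (!is.null(x$attributes)) {
    cat("  attributes: ", ncol(x$attributes), " binary columns\n", sep = "")
  }
  invisible(x)
}

#' Number of drugs / interaction types in a dataset
#' @param dataset A [ddi_dataset()].
#' @return An integer count.
#' @export
n_drugs <- function(dataset) length(dataset$drug_ids)

#' @rdname n_drugs
#' @export
n_types <- function(dataset) length(dataset$type_ids)

#' Read a DDI edge list from a tab-separated file
#'
#' @param path Path to a TSV with columns drug1, drug2 and, when
#'   `type_column = TRUE`, a third type column.
#' @param type_column Does the file carry a type column? If `FALSE` the
#'   dataset is built single-type.
#' @param header Does the file start with a header row?
#' @return A [ddi_dataset()].
#' @export
read_ddi_edges <- function(path, type_column = TRUE, header = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = header,
                      colClasses = "character", quote = "",
                      comment.char = "", blank.lines.skip = TRUE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        abort("no edges: the edge file is empty")
      }
      abort(paste0("malformed edge file: ", conditionMessage(e)))
    })
  if (nrow(raw) == 0L) abort("no edges: the edge table is empty")
  want <- if (type_column) 3L else 2L
  if (ncol(raw) < want) {
    abort(paste0("malformed edge file: expected ", want,
                 " tab-separated columns, found ", ncol(raw)))
  }
  names(raw)[1:2] <- c("drug1", "drug2")
  if (type_column) names(raw)[3] <- "type" else raw <- raw[, 1:2]
  ddi_dataset(raw[, intersect(c("drug1", "drug2", "type"), names(raw))])
}

#' Write a DDI dataset as a canonical edge list
#'
#' One row per unordered pair per type, with the lower drug index first
#' and rows sorted by (type index, i, j), so writing and re-reading an
#' adjacency tensor is an identity.
#'
#' @param dataset A [ddi_dataset()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ddi_edges <- function(dataset, path) {
  rows <- lapply(seq_along(dataset$type_ids), function(k) {
    idx <- which(upper.tri(dataset$adjacency[[k]]) &
                   dataset$adjacency[[k]] == 1, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    data.frame(drug1 = dataset$drug_ids[idx[, 1]],
               drug2 = dataset$drug_ids[idx[, 2]],
               type = dataset$type_ids[k], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) abort("no edges to write")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach binary drug attributes to a dataset
#'
#' Aligns a drug-attribute table (e.g. binding-protein indicator vectors)
#' to the dataset's drug order. Every drug in the network must have an
#' attribute row; rows for drugs outside the network are dropped.
#'
#' @param dataset A [ddi_dataset()].
#' @param attrs Data frame whose first column is the drug identifier and
#'   whose remaining columns are 0/1 indicators.
#' @return The dataset with `attributes` (matrix, rows in `drug_ids`
#'   order) and `attribute_ids` filled in.
#' @export
attach_attributes <- function(dataset, attrs) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  attrs <- as.data.frame(attrs, stringsAsFactors = FALSE)
  if (ncol(attrs) < 2L) abort("attribute table needs a drug_id column plus >= 1 attribute")
  ids <- as.character(attrs[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate attribute row(s) for drug(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  missing <- setdiff(dataset$drug_ids, ids)
  if (length(missing) > 0L) {
    abort(paste0("drugs missing from the attribute table: ",
                 paste(missing, collapse = ", ")))
  }
  M <- as.matrix(attrs[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  bad <- which(!(M %in% c(0, 1)) | is.na(M))
  if (length(bad) > 0L) {
    rc <- arrayInd(bad[1], dim(M))
    abort(paste0("non-binary attribute cell at drug '", ids[rc[1]],
                 "', column '", colnames(attrs)[-1][rc[2]], "'"))
  }
  M <- M[match(dataset$drug_ids, ids), , drop = FALSE]
  rownames(M) <- dataset$drug_ids
  zero_cols <- colnames(M)[colSums(M) == 0]
  if (length(zero_cols) > 0L) {
    warn(paste0("uninformative all-zero attribute column(s): ",
                paste(zero_cols, collapse = ", ")))
  }
  dataset$attributes <- M
  dataset$attribute_ids <- colnames(M)
  dataset
}

#' Read a drug-attribute TSV and attach it to a dataset
#'
#' The file has a header row of attribute names; the first column is the
#' drug identifier, the remaining columns are 0/1.
#'
#' @inheritParams attach_attributes
#' @param path Path to the attribute TSV.
#' @return The dataset with attributes attached.
#' @export
read_drug_attributes <- function(path, dataset) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  attrs <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, quote = "",
                             comment.char = "", stringsAsFactors = FALSE)
  attach_attributes(dataset, attrs)
}

#' Write a dataset's attribute table as TSV
#'
#' Header row of attribute names, first column `drug_id`, rows in the
#' dataset's drug order — the format [read_drug_attributes()] reads.
#'
#' @param dataset A [ddi_dataset()] with attributes attached.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_drug_attributes <- function(dataset, path) {
  if (is.null(dataset$attributes)) abort("dataset has no attributes")
  out <- data.frame(drug_id = dataset$drug_ids,
                    dataset$attributes, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse a multi-type dataset to a single-type network
#'
#' The single-type adjacency has an edge wherever any interaction type
#' connects a pair: the union over type slices. Used for occurrence-only
#' (binary) DDI prediction, where one relation matrix is learned.
#'
#' @param dataset A [ddi_dataset()].
#' @return A single-type `ddi_dataset` over the same drugs, with
#'   attributes carried over.
#' @export
collapse_single_type <- function(dataset) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  A <- Reduce(`+`, dataset$adjacency)
  A <- (A > 0) * 1
  dataset$adjacency <- list(interacts = A)
  dataset$type_ids <- "interacts"
  dataset
}

#' @method as_tibble ddi_dataset
#' @export
as_tibble.ddi_dataset <- function(x, ...) {
  rows <- lapply(seq_along(x$type_ids), function(k) {
    idx <- which(upper.tri(x$adjacency[[k]]) & x$adjacency[[k]] == 1,
                 arr.ind = TRUE)
    tibble(drug1 = x$drug_ids[idx[, 1]], drug2 = x$drug_ids[idx[, 2]],
           type = x$type_ids[k])
  })
  dplyr::bind_rows(rows)
}

# ---- model artifact serialization -------------------------------------

.ddicold_artifact_version <- 1L

#' Save / load model artifacts
#'
#' Lossless round-trip serialization for fitted objects (embedding models,
#' attribute-mapping models, cold-start splits, datasets):
#' `load_ddi_model(save_ddi_model(x, path))` reproduces every matrix
#' bit-exactly. A format version and the object class are stored and
#' checked on load.
#'
#' @param x Object to save.
#' @param path File path for the artifact.
#' @return `save_ddi_model()` returns `path` invisibly; `load_ddi_model()`
#'   returns the restored object.
#' @export
save_ddi_model <- function(x, path) {
  saveRDS(list(format = "ddicold-artifact",
               version = .ddicold_artifact_version,
               class = class(x), object = x),
          path, version = 3)
  invisible(path)
}

#' @rdname save_ddi_model
#' @export
load_ddi_model <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("corrupt or unreadable artifact: ", path))
  })
  if (!is.list(raw) || !identical(raw$format, "ddicold-artifact")) {
    abort(paste0("not a ddicold artifact: ", path))
  }
  if (raw$version > .ddicold_artifact_version) {
    abort(paste0("artifact version ", raw$version,
                 " is newer than supported version ",
                 .ddicold_artifact_version))
  }
  raw$object
}
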