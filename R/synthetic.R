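#' Power-law interaction-type frequency profile
#'
#' Real DDI corpora are strongly type-imbalanced: a handful of
#' pharmacological types account for most interactions while the tail is
#' sparse. This helper returns per-type target edge densities decaying as
#' \eqn{(k)^{-\alpha}} for type rank \eqn{k}, scaled so the densest type
#' equals `ceiling`.
#'
#' @param m Number of interaction types.
#' @param alpha Power-law exponent (`alpha = 0` gives equal densities).
#' @param ceiling Density of the most frequent type.
#' @return Numeric vector of length `m`, monotone nonincreasing.
#' @examples
#' type_frequency_profile(5, alpha = 1, ceiling = 0.2)
#' @export
type_frequency_profile <- function(m, alpha = 1, ceiling = 0.2) {
  stopifnot(m >= 1, alpha >= 0, ceiling > 0, ceiling < 1)
  d <- seq_len(m)^(-alpha)
  d * (ceiling / d[1])
}

#' Generate an attribute-linked synthetic DDI dataset with ground truth
#'
#' Emulates the generative model behind attribute-based cold-start DDI
#' prediction: binary drug attributes `F` (i.i.d. Bernoulli), a linear
#' attribute-to-embedding map `true_B`, latent embeddings
#' `true_E = F true_B + noise`, and per-type bilinear scores
#' \eqn{S^{(k)} = \frac{1}{2}(E M^{(k)} E^T + (E M^{(k)} E^T)^T)} that are
#' binarized at per-type density targets. Because the network topology is
#' (up to noise) a deterministic function of the attributes, a pipeline
#' that learns embeddings from topology and maps attributes onto them can
#' in principle recover the generating structure — which is exactly what
#' the tests exploit.
#'
#' Binarization takes, per type, the top `round(density * n_pairs)`
#' off-diagonal pairs by score, so the requested imbalance profile is met
#' to within one cell exactly. Score ties straddling that cutoff would
#' make the density unreachable and raise an error.
#'
#' @param n Number of drugs (>= 4).
#' @param p Number of binary attributes (>= `d_true`).
#' @param m Number of interaction types.
#' @param d_true Latent dimension of the generating embeddings.
#' @param densities Per-type target edge densities in (0, 1); defaults to
#'   [type_frequency_profile()] of `m` types.
#' @param noise_sd Standard deviation of the Gaussian noise added to
#'   `F true_B`; `0` gives exactly attribute-determined embeddings.
#' @param attr_prob Bernoulli rate of attribute indicators (sparse binary
#'   vectors, default 0.1).
#' @param seed Integer seed; fixes every random draw.
#' @return A list with `dataset` (a [ddi_dataset()] with attributes
#'   attached) and `truth` (class `ddi_ground_truth`: `true_B`, `true_M`,
#'   `true_E`, `noise_sd`, `thresholds`).
#' @examples
#' sim <- simulate_ddi(n = 20, p = 12, m = 2, d_true = 3, seed = 1)
#' sim$dataset
#' @export
simulate_ddi <- function(n, p, m, d_true = 8,
                         densities = type_frequency_profile(m),
                         noise_sd = 0, attr_prob = 0.1, seed) {
  stopifnot(n >= 4, p >= d_true, m >= 1, length(densities) == m,
            all(densities > 0), all(densities < 1), noise_sd >= 0)
  withr::local_seed(seed)

  drug_ids <- sprintf("D%03d", seq_len(n))
  attr_ids <- sprintf("P%03d", seq_len(p))

  F_mat <- matrix(rbinom(n * p, 1, attr_prob), n, p,
                  dimnames = list(drug_ids, attr_ids))
  # every drug gets a distinct, nonempty attribute profile: an all-zero
  # row would map to the mean embedding only, and duplicated rows give
  # duplicated noiseless embeddings whose tied scores break binarization
  for (tries in 1:100) {
    bad <- which(rowSums(F_mat) == 0 | duplicated(F_mat))
    if (length(bad) == 0L) break
    F_mat[bad, ] <- matrix(rbinom(length(bad) * p, 1, attr_prob),
                           length(bad), p)
  }
  if (any(rowSums(F_mat) == 0 | duplicated(F_mat))) {
    abort("could not draw distinct nonempty attribute rows; increase p or attr_prob")
  }

  true_B <- matrix(rnorm(p * d_true), p, d_true)
  true_E <- F_mat %*% true_B
  if (noise_sd > 0) true_E <- true_E + matrix(rnorm(n * d_true, sd = noise_sd), n, d_true)
  true_M <- lapply(seq_len(m), function(k) matrix(rnorm(d_true * d_true), d_true, d_true))

  off <- upper.tri(matrix(0, n, n))
  n_pairs <- sum(off)
  thresholds <- numeric(m)
  adjacency <- vector("list", m)
  for (k in seq_len(m)) {
    S <- true_E %*% true_M[[k]] %*% t(true_E)
    S <- (S + t(S)) / 2
    s <- S[off]
    n_edges <- round(densities[k] * n_pairs)
    if (n_edges < 1L || n_edges >= n_pairs) {
      abort(paste0("density ", densities[k], " unreachable for type ", k,
                   " at n = ", n))
    }
    ord <- sort(s, decreasing = TRUE)
    cutoff <- ord[n_edges]
    if (cutoff == ord[n_edges + 1L]) {
      abort(paste0("density ", densities[k],
                   " unreachable: tied scores straddle the cutoff for type ", k))
    }
    thresholds[k] <- cutoff
    A <- matrix(0, n, n, dimnames = list(drug_ids, drug_ids))
    A[off] <- (s >= cutoff) * 1
    A <- A + t(A)
    adjacency[[k]] <- A
  }
  type_ids <- sprintf("T%02d", seq_len(m))
  names(adjacency) <- type_ids

  dataset <- structure(
    list(drug_ids = drug_ids, type_ids = type_ids, adjacency = adjacency,
         attributes = F_mat, attribute_ids = attr_ids),
    class = "ddi_dataset"
  )
  truth <- structure(
    list(true_B = true_B, true_M = true_M, true_E = true_E,
         noise_sd = noise_sd, thresholds = thresholds),
    class = "ddi_ground_truth"
  )
  list(dataset = dataset, truth = truth)
}
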