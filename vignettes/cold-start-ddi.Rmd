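---
title: "Cold-start DDI prediction: model, mapping and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cold-start DDI prediction: model, mapping and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddicold)
```

## The problem

A drug–drug interaction (DDI) corpus is a network: nodes are drugs,
edges are known pharmacological interactions, and each edge carries a
reaction type ("anticoagulant activities increase", and so on). Two
features of such corpora shape everything in this package:

* **Cold start.** A newly approved drug has no edges. Network-topology
  embeddings are undefined for it, yet it is precisely the drug whose
  interactions one most wants to predict. We distinguish task **S1**
  (new drug vs. a drug in the network) from task **S2** (two new
  drugs).
* **Type imbalance.** A handful of reaction types dominates the corpus
  while the tail is very sparse; some types can have *no* positive test
  pair in a given evaluation split.

The package's answer is a three-stage pipeline: learn embeddings of
in-network drugs from the interaction tensor; learn a linear bridge from
per-drug binary attributes (binding-protein indicators) to those
embeddings; embed new drugs through the bridge and score pairs
bilinearly.

## Stage 1 — bilinear tensor factorization

With $m$ types over $n$ drugs we stack the symmetric 0/1 adjacency
matrices $A^{(k)}$ into a tensor and factorize
$A^{(k)} \approx E M^{(k)} E^{\mathsf T}$, with shared drug embeddings
$E \in \mathbb R^{n\times d}$ and one $d \times d$ relation matrix per
type (one matrix in single-type mode, where the tensor is first
collapsed by `collapse_single_type()` into an occurrence network).
Training minimizes

$$
l \;=\; \sum_k \bigl\|A^{(k)} - E M^{(k)} E^{\mathsf T}\bigr\|_F^2
\;+\; \lambda\Bigl(\|E\|_F^2 + \sum_k \|M^{(k)}\|_F^2\Bigr),
$$

which makes three commitments worth stating explicitly:

* **Zeros are observed negatives.** Every tensor cell enters the
  squared loss. At corpus scale (a thousand-odd drugs) the pair universe
  is enumerable, and the evaluation protocol likewise keeps all
  candidate negatives, so training and evaluation agree on the
  closed-world reading.
* **The penalty is L2 on both blocks.** A single coefficient $\lambda$
  regularizes $E$ and all $M^{(k)}$ jointly; it is the standard
  regularizer for this model class and keeps the grid search
  one-dimensional in $\lambda$.
* **The optimizer is full-batch gradient descent** at a constant
  learning rate, with analytic gradients
  ($R^{(k)} = A^{(k)} - E M^{(k)} E^{\mathsf T}$):
  $\nabla_E = \sum_k(-2R^{(k)}EM^{(k)\mathsf T} - 2R^{(k)\mathsf T}EM^{(k)}) + 2\lambda E$
  and $\nabla_{M^{(k)}} = -2E^{\mathsf T}R^{(k)}E + 2\lambda M^{(k)}$.
  Tuning a learning rate (rather than using alternating least squares)
  is what makes the early-stopping rule below meaningful.

**Initialization** is i.i.d. Gaussian with standard deviation
`init_scale` (default 0.1), fully determined by `seed`.

**Early stopping.** The loss is recorded every iteration. Training
stops at `max_iter` or as soon as `patience` (default 3) iterations
have produced a loss *greater than the best seen so far*. The counter
is cumulative by default — three worse losses anywhere stop training —
with a consecutive-counting variant behind `consecutive = TRUE`.
Either way the returned parameters are the **best-loss iterate**, never
the last one, so early stopping can only help the training objective.
A side effect worth knowing: a wildly excessive learning rate is
usually caught by this rule (three immediate deteriorations) and
returns the near-initialization iterate; only if the loss overflows to
a non-finite value before that does `fit_rescal()` raise an error
advising a smaller rate.

**Defaults.** `dim = 200` suits a corpus of ~1300 drugs; the examples
and tests in this package run at `dim` 3–16 on synthetic data where the
generating rank is 8 or less. Learning rate and penalty default to
0.001 and 0.01, the scale at which the 100-drug test corpora train
stably; `grid_search_rescal()` searches the classical
$\{0.001, 0.01, 0.1\}^2$ grid against a validation split's S1 AUPR when
a dataset needs its own setting, breaking ties toward the smaller
penalty, then the smaller rate.

## Stage 2 — attributes to embeddings by PLS

New drugs need embeddings without edges. We fit the linear map
$FB = E$ on the *existing* drugs only and apply it to new drugs'
attribute vectors. Binding-protein indicator columns are strongly
collinear (protein families co-occur), which rules out plain least
squares as ill-conditioned in general; partial least squares projects
both blocks onto latent components
$F = TP^{\mathsf T} + \mathrm{error}_1$,
$E = UQ^{\mathsf T} + \mathrm{error}_2$
and regresses through them.

Implementation choices, all visible in `fit_pls_map()`:

* **NIPALS PLS2**, components extracted one at a time; the inner loop
  iterates $w \propto F^{\mathsf T}u$, $t = Fw$,
  $q \propto E^{\mathsf T}t$, $u = Eq$ until the relative change of $t$
  falls below $10^{-8}$ (at most 500 inner iterations), then deflates
  both blocks by the $t$ component.
* **Centering, no scaling.** Both blocks are column-centered;
  binary indicators already share a scale, and the embedding block's
  scale is meaningful, so variance-scaling would only inject noise.
* **The regression coefficient** is the standard PLS2 form
  $B = W(P^{\mathsf T}W)^{-1}Q^{\mathsf T}$, the unique form under
  which full-component PLS on full-column-rank data reproduces the
  least-squares solution (and hence $FB \approx E$ on realizable data).
  The weight-product form $B = WC^{\mathsf T}$ sometimes quoted for
  PLS is kept available via `coef_form = "weights"` for comparison,
  but it does not satisfy that consistency check and is not the
  default.
* **Component count** is unprincipled to fix globally; the default is
  `min(50, p, n_train − 1)`, and the CV driver accepts `n_components`
  explicitly. If the extractable rank runs out earlier, extraction
  stops with a warning and the count is reduced.
* **Degenerate inputs.** A zero-variance attribute block is an error; a
  constant embedding block yields $B = 0$ with all predictions at the
  mean; exactly duplicated attribute columns are harmless — at full
  extractable rank the fitted prediction is the least-squares
  projection onto the attribute column space, which duplication does
  not change.

Prediction is affine: `map_new_drugs()` returns
$(F_{\text{new}} - \mu_F)B + \mu_E$. It depends on attributes only, so
identical attribute vectors give identical embeddings.

## Stage 3 — scoring and type calls

The learned $M^{(k)}$ is not constrained symmetric but the network is
undirected, so the pair-level score is orientation-symmetrized:
$\tfrac12(E_iM^{(k)}E_j^{\mathsf T} + E_jM^{(k)}E_i^{\mathsf T})$,
equivalently the bilinear form under $\tfrac12(M^{(k)}+M^{(k)\mathsf T})$.
Scores are used raw — no sigmoid — because the training loss
reconstructs 0/1 entries, putting scores naturally on that scale; the
default occurrence threshold is therefore 0.5, configurable everywhere
it is used, and the single-type evaluator additionally reports F1 at
the training-data-optimal threshold as a sensitivity check. The
predicted type of a pair is the argmax over type columns, ties broken
toward the smallest type index. For the SVD baseline (single-type
only), drugs are embedded as $U_d\Sigma_d^{1/2}$ and scored by the
inner product, so ranking equals ranking by the truncated
reconstruction $EE^{\mathsf T}$.

## Evaluation protocol

`make_folds()` splits *drugs* (never edges) into near-equal groups by a
seeded permutation; fold $f$ holds out group $f$ as new drugs. Per
fold, `run_cv()`:

1. restricts the tensor to existing × existing (the training view —
   `audit_leakage()` re-derives every fold and counts entries touching
   a held-out drug, which must be zero);
2. trains the factorization on that subnetwork (one shared
   configuration across folds);
3. fits the PLS bridge on the existing drugs' attributes and learned
   embeddings;
4. embeds the held-out drugs from attributes alone;
5. scores **all** S1 and S2 candidate pairs — every non-edge is a
   negative, no subsampling;
6. computes AUC (Mann–Whitney with half-credit ties) and AUPR (average
   precision over the unique-score step curve) per type, macro-averages
   them over *evaluable* types, and pools argmax type decisions into
   micro-F1 (multi-type) or thresholded F1 (single-type).

Types with no positive test pair, or no training edge in a fold, are
**skipped, not scored zero** — scoring them zero would conflate "not
measurable in this split" with "predicted badly", which matters under
heavy type imbalance where tail types routinely vanish from S2 pair
sets. S1 and S2 are reported separately throughout.

## The synthetic generator

`simulate_ddi()` exists so that every pipeline stage is testable
without any external corpus, and it mirrors the model's own generative
assumptions: attributes $F$ are i.i.d. Bernoulli (default rate 0.1,
emulating sparse binding-protein vectors); a Gaussian matrix
$B^\ast$ maps them to latent embeddings
$E^\ast = FB^\ast + \varepsilon$, $\varepsilon \sim N(0,
\sigma^2)$; per-type Gaussian relation matrices give symmetric score
matrices that are binarized at per-type densities. Specifics:

* **Imbalance** comes from `type_frequency_profile()`: densities decay
  as $k^{-\alpha}$ ($\alpha = 1$ by default) from a ceiling of 0.2,
  matching the qualitative shape of real corpora where the first few
  types dominate.
* **Binarization is exact top-$k$**: per type, the $\lfloor
  \text{density} \times \binom n2 \rceil$ highest-scoring pairs become
  edges, so requested densities are met to within one cell. Score ties
  straddling the cutoff would make the target unreachable and raise an
  error rather than silently shifting the density.
* **Attribute rows are distinct and nonempty** (resampled under the
  seed until they are): an all-zero row could only ever map to the mean
  embedding, and with $\sigma = 0$ duplicated rows give duplicated
  embeddings whose structural score ties break exact binarization.
* **The noiseless limit is reachable.** With $\sigma = 0$ and
  $p \ge d_{\text{true}}$ the topology is a deterministic function of
  the attributes through a linear map — exactly the situation the
  pipeline assumes — so recovery there is a meaningful correctness
  check. Default $d_{\text{true}} = 8$ is deliberately below the
  embedding dimensions used in tests (16) so the model class contains
  the truth.

What the generator does **not** emulate: correlated attribute structure
(real binding-protein families co-occur), degree heterogeneity beyond
what the bilinear scores induce, multi-label types with structured
co-occurrence, and any text- or chemistry-derived signal. Passing the
synthetic recovery tests therefore shows the pipeline is *correct and
self-consistent*, not that it will reach any particular performance on
a real corpus.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the full pipeline at 120
drugs × 60 attributes × 5 types (generating rank 8, embedding dimension
16, 10-fold CV; the multi-seed S1-vs-S2 trend check uses 5 folds over 5
seeds), sizes at which cold-start structure is comfortably
recoverable while the whole suite stays in the minutes range on one
CPU. Other conventions collected in one place:

* every stochastic step (generation, initialization, fold assignment)
  is driven by an explicit seed argument and restores the caller's RNG
  state (`withr`), so identical configurations give bit-identical
  artifacts;
* loss traces must stay finite — divergence is an error, never a NaN in
  a report;
* AUC needs at least one positive and one negative, AUPR at least one
  positive; otherwise the type is reported `NA` and marked skipped;
* F1 with no predicted and no true positives is defined as 0 with a
  warning;
* model artifacts are RDS containers with a format version and the
  object class embedded; `load_ddi_model()` refuses foreign or
  newer-versioned files.

## Known limitations

* The mapping is linear by design; systematically nonlinear
  attribute–embedding relationships will cap S1/S2 performance no
  matter how good the factorization is.
* S2 compounds mapping error from both ends of a pair and is expected
  to trail S1 — the package reproduces this ordering on synthetic data,
  and it should be anticipated on real corpora too.
* Full-batch gradients over a dense tensor are comfortable to a few
  thousand drugs; beyond that a sparse or sampled training scheme would
  be needed.
* Grid search re-trains one model per grid point on a single validation
  split (not per fold), trading a little selection variance for a large
  constant-factor saving.
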