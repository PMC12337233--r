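---
title: "Weighted voting and cluster-routed model selection for frozen QA predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted voting and cluster-routed model selection for frozen QA predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llmsynergy)
```

## The setting

The package combines the answers of `M` *frozen* base predictors on
multiple-choice questions. Each predictor has already been run — its answers
sit in an instance × model table — and cannot be re-trained, re-prompted or
queried for probabilities. All the ensemble can learn is *how much to trust
each model*, and, in the dynamic variant, *where* to trust it. This setting
is typical of LLM panels on medical QA benchmarks, where inference is
expensive and is done once per model, but it applies to any committee of
fixed categorical classifiers.

Two consequences of the setting shape the design:

* Only hard labels are available, so the combiner is a weighted plurality
  vote over option labels, not probability averaging.
* The base models' error rates are *static*: nothing the ensemble does
  changes what any model answers. Weight learning is therefore an explicit
  function of measured error rates rather than a sequential re-training loop.

## The boosting-weighted vote

Weights start equal, `w_j = 1/M`. For model `j`, the training error `E_j` is
the fraction of training instances it answers incorrectly; an abstention
(the sentinel `"__ABSTAIN__"`, used for unparseable model output) counts as
incorrect and casts no vote. The model's adjustment is the log-odds of it
being correct,

$$\alpha_j = \tfrac{1}{2}\log\frac{1-E_j'}{E_j'},$$

with `E_j'` the error clamped into `[eps, 1 - eps]`. Per pass every weight
receives `w_j <- w_j + lr * alpha_j`; negatives are clipped to zero and the
vector renormalized to the simplex. Training stops when the training
accuracy of the weighted vote moves by less than `convergence_tol` over two
consecutive passes, or at `max_passes`.

With all clamped errors below 0.5 this iteration has a closed-form limit:
the normalized weights converge geometrically to
$\alpha_j / \sum_k \alpha_k$ (the update is an affine contraction on the
simplex with that fixed point). The test suite checks the limit directly at
500 passes against a fixed error vector. Models at or above chance-on-their
-own-scale (`E >= 0.5`) get non-positive adjustments and are driven to
weight zero — the clip is what keeps the vote well defined rather than a
styling choice.

An exponential margin loss, $L=\sum_i \exp(-\sum_j w_j c_{ij})$ with
$c_{ij}=\pm 1$ encoding correctness, is recorded per pass. It is a
monitoring diagnostic of how confidently the weight mass sits on correct
models; it is *not* the optimization objective, and no gradient steps are
taken on it.

### The ambiguous update rule, and the two modes

The additive-per-model update above treats the learned weights as *model*
weights. A boosting narrative can equally be read as reweighting
*instances* — "hard questions should matter more for the next model". Both
readings are implemented: the default `mode = "model_weights"` uses static
per-model errors; `mode = "adaboost_instances"` maintains AdaBoost-style
instance weights `u_i` (initialized `1/N`, multiplied by `exp(alpha_j)` on
each model's mistakes and renormalized after each model's turn) and measures
each model's error under them. With frozen predictors the instance-weighted
mode changes which regions of the data each model's error is measured on,
but not the models themselves; the default mode is the one whose behaviour
is fully characterized by the fixed-point analysis above.

### Voting and tie-breaking

For two options a weighted vote is a signed threshold; for three or more the
only total, order-respecting generalization is the per-option weighted
indicator sum, and that is what is implemented: the winner maximizes
$\sum_j w_j\,\mathbf{1}[h_j(x)=o]$. Ties are broken by the earliest option
in the *instance's* option order — deterministic, reproducible, and honest
about the fact that a tie contains no information. Rows where every model
abstains return the first option and are flagged in a diagnostics attribute
rather than silently scored.

## Cluster-based dynamic selection

The premise is regional competence: different models dominate different
question types. The procedure is

1. embed each *question context* — the question text only, never the
   candidate options, which would leak label structure into the geometry;
2. cluster the training embeddings with k-means;
3. fit an independent boosting vote inside every cluster with at least
   `min_cluster_size` training instances (default 10 — error rates on fewer
   points are noise, and such clusters fall back to the global weights);
4. at inference, route a question to its nearest training centroid and vote
   with that cluster's weights.

Validation questions are routed to training-time centroids, never
re-clustered jointly with training data: re-clustering would let validation
geometry influence the fitted structure and would not match deployment.

### Choosing K

Two criteria are computed per candidate K: the mean silhouette coefficient
(compactness vs. separation, in `[-1, 1]`, singletons scoring 0) and the
within-cluster sum of squares (WCSS) curve for elbow inspection.
`select_k()` returns the silhouette argmax (ties to the smaller K) and warns
when the largest-second-difference elbow disagrees — the elbow is advisory,
silhouette decides. `dms_tune()` then makes the final call the way a
deployed system should: it grids over K (and optionally clustering seeds),
scores each fitted ensemble on held-out validation accuracy, and picks the
winner, ties again to the smaller K. Accuracy decides because cluster
geometry is a means, not the end.

### k-means, precisely

Lloyd iterations with k-means++ seeding, 10 restarts under a single seeded
stream, best final WCSS kept; the fit is a deterministic function of
`(X, K, seed, restarts)`. Distances are Euclidean throughout (silhouette
included). An empty cluster is re-seeded at the point farthest from its
assigned centroid, which cannot increase the objective; the per-iteration
WCSS trace is stored and is asserted non-increasing in the tests. Nearest-
centroid routing breaks exact ties toward the smaller label. The default
search range 2–15 covers the cluster counts one meets on QA benchmarks of
desk scale. The k-means clustering is implemented in the package rather than
delegated so that seeding, restarts, tie rules, the empty-cluster rule and
the iteration trace are all part of the specified, testable contract; the
stock `stats::kmeans` serves as an independent cross-check in the test
suite.

### The embedding contract

Any object with `dimension` and `embed(texts)` works. The built-in
`hash_embedder()` lowercases, tokenizes on non-alphanumerics, hashes tokens
into buckets with an exact-in-doubles polynomial hash, and sums one seeded
Gaussian projection vector per bucket occurrence — deterministic for a
fixed `(dim, seed, buckets)`, requiring no download, and preserving
bag-of-words cluster structure well enough to route cluster-tagged text. It
is a real embedder with a real limitation: it captures token overlap, not
meaning. A mean-pooled transformer encoder (for clinical text, a
clinical-domain BERT at its native 768 dimensions) plugs into the same
interface when semantic routing of natural questions matters.

## The synthetic universes

`synthetic_spec()` describes a generative world: N instances over K latent
clusters (categorical cluster assignment, isotropic Gaussian embeddings
around mutually equidistant centroids), gold labels uniform over the option
set, and model `j` correct on cluster `k` with probability `accuracy[k, j]`,
errors independent across models (optionally correlated through a Gaussian
copula via `error_correlation`) and spread uniformly over the wrong options.
Question texts are cluster-tagged token bags so the hashing embedder
inherits the latent geometry; the exact Gaussian embeddings are also
returned so clustering can be tested with and without the text path.
Everything is byte-identical given the seed.

Three named scenarios fix the study conditions used throughout the tests and
the acceptance script:

| scenario | K | M | per-cluster accuracies | exercises |
|---|---|---|---|---|
| `uniform` | 1 | 4 | all 0.6 | weights stay near-equal |
| `graded` | 1 | 4 | 0.75 / 0.65 / 0.60 / 0.40 | weight-ordering recovery |
| `experts` | 3 | 3 | 0.9 own cluster, 0.3 elsewhere | dynamic routing's gain |

The `experts` geometry uses centroid separation 10 with unit noise in 8
dimensions — separated enough that routing is essentially clean, which is
the regime the method claims to exploit. Default sizes are N = 4000 for the
single-cluster scenarios and N = 6000 for `experts`; at these sizes the
binomial noise on an error rate (about 0.008 at N = 3200 training rows) is
several times smaller than the smallest accuracy gap being resolved (0.05 in
`graded`), so recovery checks measure the method, not the sample.

What the generator deliberately does not emulate: free-text answers and
their parsing failures (abstentions exist only as post-hoc corruption via
`corrupt_abstain()`), prompt sensitivity, option-position biases, and
strongly correlated model errors as the default. Passing tests on these
universes show the machinery is correct and that the dynamic method's
advantage is realizable when regional competence exists; they do not show
that real LLM panels on real benchmarks have cleanly separable competence
regions.

## Numerical choices and degenerate inputs

* **Error clamping**: `eps = 1/(2N)` by default — the adjustment of a
  perfect model is bounded by what is resolvable at sample size N, so a
  flawless model dominates but never produces infinities.
* **Convergence**: `convergence_tol = 1e-4` absolute training accuracy over
  two consecutive passes, `max_passes = 100`. Setting `tol = 0` disables
  early stopping (used by the fixed-point tests).
* **Stratified split**: per-class shuffle under the seed, `floor(ratio·n_c)`
  to train, largest fractional remainders topped up until the global
  `floor(ratio·N)` is met; per-class train counts are within one instance of
  the ratio. Default ratio 0.8, default seed 42.
* **Option labels** are opaque symbols compared by exact, case-sensitive
  string equality.
* Empty question text embeds to the zero vector with a warning; an all-
  identical embedding matrix is rejected by `select_k()`; `K = 1` makes the
  silhouette undefined and is an error in `mean_silhouette()` while
  `dms_fit(k = 1)` degenerates exactly to the global boosting vote (tested
  as an identity).

## Problem sizes

The test suite and the acceptance script run the scenarios at their default
sizes (N = 4000 / 6000, 20-seed repetition for the recovery rates; voting
and silhouette oracles on 1000 and 50 random cases respectively), which a
laptop handles in well under a minute per component.

## Known limitations

* Weights are per-model-per-cluster; there is no per-instance gating, no
  soft cluster membership, and no mixture-of-experts training signal.
* The vote consumes hard labels only; models that could supply calibrated
  probabilities are flattened to their argmax.
* Silhouette computation materializes the full pairwise distance matrix
  (O(N²) memory), which is fine at desk scale and wasteful beyond it.
* The hashing embedder routes by lexical overlap; questions that share words
  but not meaning will co-cluster.
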