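# llmsynergy

Ensemble methods for multiple-choice question answering over **frozen base
predictors** — models (typically zero-shot large language models) whose
categorical answers are cached in a file and never re-trained. Given a QA
dataset and an instance × model table of answers, the package answers the
question practitioners actually face: *how should the votes of several
imperfect, heterogeneous models be combined?* It is aimed at biomedical NLP
groups benchmarking LLM panels on medical QA, but nothing in it is specific
to medicine: any dataset with ordered option labels and any roster of
categorical predictors fits.

Two combiners are provided.

**Boosting-weighted majority vote.** Every model starts at weight
`w_j = 1/M`. From its training error rate `E_j` (fraction of training
instances answered incorrectly; an abstention counts as incorrect) each model
receives the log-odds adjustment

```
alpha_j = 1/2 * log((1 - E_j) / E_j)
```

applied additively per pass (`w_j <- w_j + lr * alpha_j`, negatives clipped,
the vector renormalized) until the training accuracy of the weighted vote
stabilizes. Inference is a weighted plurality vote: the winning option
maximizes `sum_j w_j * 1[h_j(x) = option]`, ties going to the earliest
option in the instance's option order. An exponential margin loss
`L = sum_i exp(-sum_j w_j c_ij)`, with `c_ij = ±1` encoding correctness, is
tracked per pass as a confidence diagnostic.

**Cluster-based dynamic model selection.** Different models are good at
different kinds of questions. The question contexts (never the answer
options) are embedded into fixed-length vectors, clustered with k-means
(K chosen by the highest mean silhouette coefficient, with the elbow of the
within-cluster sum of squares as an advisory cross-check, and finally tuned
by validation accuracy), and a separate boosting-weighted vote is fitted
inside each cluster. At inference a question is routed to its nearest
training centroid and voted with that cluster's own weights; clusters too
small to estimate weights reliably fall back to the global weighting. A
deterministic hashing embedder ships in the package so the whole pipeline
runs offline; any mean-pooled transformer encoder can be plugged in through
the same interface.

A synthetic-universe generator (`scenario()` / `generate_universe()`)
produces datasets, embeddings and prediction matrices with known per-cluster
model accuracies, so every claim the package makes can be measured against
ground truth.

## Worked example

Three models, three latent question clusters; each model is an expert
(accuracy 0.9) on its own cluster and weak (0.3) elsewhere, so each model's
*overall* accuracy is only 0.5:

```r
library(llmsynergy)
universe <- generate_universe(scenario("experts", n_instances = 2000, seed = 11))
split <- stratified_split(universe$dataset, ratio = 0.8, seed = 42)

boost <- boost_fit(universe$dataset, universe$predictions, ids = split$train_ids)
print(boost)
#> <llm_boost> 3 models, trained on 1600 instances (converged after 3 passes)
#>   model_2              weight  37.29%  (error 0.498)
#>   model_3              weight  35.31%  (error 0.501)
#>   model_1              weight  27.40%  (error 0.514)

dms <- dms_fit(universe$dataset, universe$predictions, universe$embeddings,
               k = 3, ids = split$train_ids)

report <- evaluate_ensembles(
  universe$dataset, universe$predictions,
  test_ids = split$validation_ids, train_ids = split$train_ids,
  fits = list(boosting = boost, dynamic = dms),
  embeddings = universe$embeddings
)
print(report)
#> Test set performance (n = 400)
#>   model_1                       51.50%
#>   model_2                       45.75%
#>   model_3                       50.25%
#>   boosting                      57.00%  (+5.50 pts vs best individual)
#>   dynamic                       88.50%  (+37.00 pts vs best individual)
#>   per-cluster breakdown:
#>  cluster   n boosting dynamic
#>        1 146   0.4726  0.8562
#>        2 138   0.4928  0.9420
#>        3 116   0.7845  0.8534
```

The global vote can only edge past the best individual (+5.5 points here):
no single weighting helps when each model's competence is regional. Routing
each question to its cluster's own weights lifts test accuracy to 88.5%,
because inside each cluster the boosting weights collapse onto that
cluster's expert (inspect with `weight_report(dms)` or `coef(dms)`).

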