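# Synthetic QA universes: datasets, embeddings and base-predictor prediction
# matrices with known cluster structure and per-cluster model accuracies, so
# every stage of the ensemble pipeline can be exercised and measured against
# ground truth without any model download.

#' Describe a synthetic QA universe
#'
#' The generative model: each instance belongs to one of `n_clusters` latent
#' question clusters drawn from `cluster_weights`; its embedding is an
#' isotropic Gaussian around the cluster centroid (centroids mutually
#' separated by `centroid_separation`); its gold label is uniform over the
#' option labels; and base model `j` answers an instance of cluster `k`
#' correctly with probability `accuracy[k, j]`, wrong answers falling
#' uniformly on the remaining options. Model errors are independent across
#' models unless `error_correlation > 0`, in which case correctness draws
#' share a per-instance latent through a Gaussian copula.
#'
#' @param n_instances number of instances N.
#' @param n_models number of base models M.
#' @param n_options number of option labels per question (labels `LETTERS`),
#'   at least 2. Default 4.
#' @param n_clusters number of latent clusters K. Default 1.
#' @param accuracy K x M matrix of per-cluster per-model correctness
#'   probabilities (a vector is recycled into one row per cluster).
#' @param cluster_weights K simplex weights. Default uniform.
#' @param embedding_dim embedding dimension d, at least `n_clusters`.
#'   Default 8.
#' @param centroid_separation pairwise Euclidean distance between cluster
#'   centroids. Default 10.
#' @param embedding_noise_sd per-coordinate Gaussian noise around centroids.
#'   Default 1.
#' @param error_correlation pairwise correlation of the latent correctness
#'   draws across models, in `[0, 1)`. Default 0 (independent errors).
#' @param seed integer seed making the generated universe fully
#'   deterministic.
#' @return An object of class `synthetic_spec`.
#' @seealso [scenario()], [generate_universe()]
#' @export
synthetic_spec <- function(n_instances, n_models, n_options = 4L,
                           n_clusters = 1L, accuracy,
                           cluster_weights = NULL, embedding_dim = 8L,
                           centroid_separation = 10, embedding_noise_sd = 1,
                           error_correlation = 0, seed = 1L) {
  if (!is_count(n_instances) || !is_count(n_models) || !is_count(n_clusters)) {
    stop_fmt("n_instances, n_models and n_clusters must be positive integers")
  }
  if (!is_count(n_options) || n_options < 2) {
    stop_fmt("n_options must be an integer >= 2")
  }
  accuracy <- matrix(accuracy, nrow = n_clusters, ncol = n_models,
                     byrow = is.null(dim(accuracy)))
  if (any(accuracy < 0) || any(accuracy > 1)) {
    stop_fmt("accuracy entries must lie in [0, 1]")
  }
  cluster_weights <- cluster_weights %||% rep(1 / n_clusters, n_clusters)
  if (length(cluster_weights) != n_clusters ||
      abs(sum(cluster_weights) - 1) > 1e-9 || any(cluster_weights < 0)) {
    stop_fmt("cluster_weights must be %d nonnegative values summing to 1",
             n_clusters)
  }
  if (embedding_dim < n_clusters) {
    stop_fmt("embedding_dim must be at least n_clusters so centroids can be mutually equidistant")
  }
  if (error_correlation < 0 || error_correlation >= 1) {
    stop_fmt("error_correlation must lie in [0, 1)")
  }
  structure(
    list(n_instances = as.integer(n_instances), n_models = as.integer(n_models),
         n_options = as.integer(n_options), n_clusters = as.integer(n_clusters),
         accuracy = accuracy, cluster_weights = cluster_weights,
         embedding_dim = as.integer(embedding_dim),
         centroid_separation = centroid_separation,
         embedding_noise_sd = embedding_noise_sd,
         error_correlation = error_correlation, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> N = %d, M = %d models, %d options, K = %d clusters (seed %d)\n",
              x$n_instances, x$n_models, x$n_options, x$n_clusters, x$seed))
  cat("  per-cluster accuracies:\n")
  print(round(x$accuracy, 3))
  invisible(x)
}

#' Named study scenarios
#'
#' Three canonical test universes: `"uniform"` — one cluster, four
#' interchangeable models at accuracy 0.6 (weight learning should stay flat);
#' `"graded"` — one cluster, four models at accuracies 0.75 / 0.65 / 0.60 /
#' 0.40 (weight learning should recover the accuracy ordering); `"experts"` —
#' three clusters and three models, each model an expert (accuracy 0.9) on
#' its own cluster and weak (0.3) elsewhere, centroids 10 apart with unit
#' noise (dynamic per-cluster weighting should beat any single global
#' weighting).
#'
#' @param name one of `"uniform"`, `"graded"`, `"experts"`.
#' @param n_instances number of instances; defaults to 4000 for the
#'   single-cluster scenarios and 6000 for `"experts"`.
#' @param seed integer seed.
#' @return A [synthetic_spec()].
#' @export
#' @examples
#' scenario("graded", n_instances = 400, seed = 7)$accuracy
scenario <- function(name = c("uniform", "graded", "experts"),
                     n_instances = NULL, seed = 1L) {
  name <- match.arg(name)
  switch(
    name,
    uniform = synthetic_spec(
      n_instances = n_instances %||% 4000L, n_models = 4L, n_options = 4L,
      n_clusters = 1L, accuracy = c(0.6, 0.6, 0.6, 0.6), seed = seed
    ),
    graded = synthetic_spec(
      n_instances = n_instances %||% 4000L, n_models = 4L, n_options = 4L,
      n_clusters = 1L, accuracy = c(0.75, 0.65, 0.60, 0.40), seed = seed
    ),
    experts = synthetic_spec(
      n_instances = n_instances %||% 6000L, n_models = 3L, n_options = 4L,
      n_clusters = 3L,
      accuracy = matrix(0.3, 3, 3) + diag(0.6, 3),
      centroid_separation = 10, embedding_noise_sd = 1, seed = seed
    )
  )
}

# Mutually equidistant centroids: scaled standard basis vectors e_k, whose
# pairwise distance is sqrt(2) * scale; requires d >= K.
make_centroids <- function(K, d, separation) {
  C <- matrix(0, K, d)
  for (k in seq_len(K)) C[k, k] <- separation / sqrt(2)
  C
}

#' Generate a synthetic QA universe
#'
#' Draws a complete universe — dataset, true cluster labels, embeddings and
#' a prediction matrix — from a [synthetic_spec()]. Question texts are
#' cluster-tagged token bags, so a hashing embedder applied to them inherits
#' the cluster structure; the exact Gaussian embeddings are also returned so
#' clustering can be tested with or without the text path. The result is
#' byte-identical across runs with the same spec.
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `synthetic_universe`: `dataset` (a
#'   [qa_dataset()]), `true_cluster` (integer labels named by id),
#'   `embeddings` (N x d matrix, row names ids), `predictions` (prediction
#'   matrix for models `model_1..model_M`), and `spec`.
#' @export
generate_universe <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  N <- spec$n_instances; M <- spec$n_models; K <- spec$n_clusters
  opts <- LETTERS[seq_len(spec$n_options)]
  ids <- sprintf("q%06d", seq_len(N))
  with_seed(spec$seed, {
    true_cluster <- sample.int(K, N, replace = TRUE, prob = spec$cluster_weights)
    centroids <- make_centroids(K, spec$embedding_dim, spec$centroid_separation)
    embeddings <- centroids[true_cluster, , drop = FALSE] +
      matrix(stats::rnorm(N * spec$embedding_dim, sd = spec$embedding_noise_sd),
             N, spec$embedding_dim)
    rownames(embeddings) <- ids
    gold <- sample(opts, N, replace = TRUE)
    # cluster-tagged token bags: topic tokens from the cluster's vocabulary
    # plus shared filler tokens
    question <- vapply(seq_len(N), function(i) {
      k <- true_cluster[i]
      topic <- sample(sprintf("topic%d_term%02d", k, 1:40), 6L, replace = TRUE)
      filler <- sample(sprintf("common%02d", 1:20), 3L, replace = TRUE)
      paste(c(topic, filler), collapse = " ")
    }, character(1))
    # correctness via a Gaussian copula: rho = 0 gives independent errors
    rho <- spec$error_correlation
    z <- stats::rnorm(N)
    latent <- sqrt(rho) * z + sqrt(1 - rho) *
      matrix(stats::rnorm(N * M), N, M)
    p_correct <- spec$accuracy[true_cluster, , drop = FALSE]
    correct <- stats::pnorm(latent) < p_correct
    answers <- matrix(NA_character_, N, M)
    for (j in seq_len(M)) {
      answers[, j] <- ifelse(correct[, j], gold, NA_character_)
      wrong_rows <- which(!correct[, j])
      if (length(wrong_rows)) {
        answers[wrong_rows, j] <- vapply(wrong_rows, function(i) {
          sample(setdiff(opts, gold[i]), 1L)
        }, character(1))
      }
    }
    dataset <- qa_dataset(ids, question, opts, gold)
    colnames(answers) <- sprintf("model_%d", seq_len(M))
    predictions <- prediction_matrix(answers, dataset)
    names(true_cluster) <- ids
    structure(
      list(dataset = dataset, true_cluster = true_cluster,
           embeddings = embeddings, predictions = predictions, spec = spec),
      class = "synthetic_universe"
    )
  })
}

#' @export
print.synthetic_universe <- function(x, ...) {
  cat(sprintf("<synthetic_universe> N = %d, M = %d, K = %d (seed %d)\n",
              x$spec$n_instances, x$spec$n_models, x$spec$n_clusters,
              x$spec$seed))
  emp <- vapply(seq_len(ncol(x$predictions)), function(j) {
    mean(x$predictions[, j] == x$dataset$gold)
  }, numeric(1))
  cat("  empirical model accuracies:",
      paste(sprintf("%.3f", emp), collapse = ", "), "\n")
  invisible(x)
}

#' Inject abstentions into a prediction matrix
#'
#' Post-hoc corruption utility: each cell independently becomes the abstain
#' sentinel with probability `rate`, emulating unparseable base-model output.
#'
#' @param predictions a prediction matrix.
#' @param rate abstention probability per cell, in `[0, 1]`.
#' @param seed integer seed.
#' @return The corrupted matrix.
#' @export
corrupt_abstain <- function(predictions, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  with_seed(seed, {
    mask <- matrix(stats::runif(length(predictions)) < rate,
                   nrow(predictions), ncol(predictions))
    predictions[mask] <- abstain_label()
    predictions
  })
}

#' Export a synthetic universe to plain-text files
#'
#' Writes `dataset.jsonl`, `predictions.csv`, `embeddings.csv` and
#' `truth.json` (spec parameters plus true cluster labels) into a directory.
#'
#' @param universe a `synthetic_universe`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_universe <- function(universe, dir) {
  stopifnot(inherits(universe, "synthetic_universe"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_qa_dataset(universe$dataset, file.path(dir, "dataset.jsonl"))
  write_predictions(universe$predictions, file.path(dir, "predictions.csv"))
  emb <- data.frame(id = rownames(universe$embeddings), universe$embeddings,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(emb, file.path(dir, "embeddings.csv"), row.names = FALSE)
  spec <- universe$spec
  jsonlite::write_json(
    list(spec = unclass(spec), true_cluster = unname(universe$true_cluster),
         ids = universe$dataset$id),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read an embedding matrix from CSV
#'
#' Expects an `id` column plus numeric columns; rows are aligned to the
#' dataset on `id`.
#'
#' @param path CSV path.
#' @param dataset a [qa_dataset()] defining row order.
#' @return Numeric matrix with instance ids as row names.
#' @export
read_embeddings <- function(path, dataset) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!("id" %in% names(df))) stop_fmt("embedding CSV %s has no 'id' column", path)
  idx <- match(dataset$id, as.character(df$id))
  if (anyNA(idx)) {
    stop_fmt("embedding CSV %s is missing id '%s'", path,
             dataset$id[is.na(idx)][1L])
  }
  X <- as.matrix(df[idx, setdiff(names(df), "id"), drop = FALSE])
  storage.mode(X) <- "double"
  dimnames(X) <- list(dataset$id, NULL)
  X
}
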