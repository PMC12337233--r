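# Cluster-based dynamic model selection: k-means over question-context
# embeddings, one boosting-weighted vote per sufficiently large cluster, a
# global fallback, and validation-driven tuning of K.

#' Fit a cluster-based dynamic model selection ensemble
#'
#' Clusters the training questions' embeddings with k-means, then fits an
#' independent boosting-weighted majority vote (see [boost_fit()]) inside
#' each cluster holding at least `min_cluster_size` training instances, so
#' each cluster obtains its own combination of model weights tailored to its
#' question contexts. A global boosting fit over all training rows always
#' serves as the fallback for small clusters and out-of-support routing. At
#' prediction time each question is routed to its nearest training centroid
#' and voted with that cluster's weights.
#'
#' @param dataset a [qa_dataset()].
#' @param predictions a prediction matrix aligned to `dataset`.
#' @param embeddings numeric matrix of question embeddings with instance ids
#'   as row names (see [embed_questions()]).
#' @param k number of clusters; if a vector of length > 1 it is treated as a
#'   candidate range and the silhouette criterion of [select_k()] picks K.
#' @param config a [boost_config()] shared by every per-cluster fit.
#' @param ids optional training ids; defaults to the whole dataset.
#' @param min_cluster_size clusters with fewer training instances than this
#'   fall back to the global weights. Default 10.
#' @param seed integer seed for the clustering.
#' @param restarts k-means restarts.
#' @return An object of class `llm_dms`: `cluster_model` (a `kmeans_model`),
#'   `states` (named list of per-cluster `llm_boost` fits), `global_state`,
#'   `min_cluster_size`, `model_names`, `config`, `seed`. Supports `print()`,
#'   `coef()` and `predict()`.
#' @export
dms_fit <- function(dataset, predictions, embeddings, k,
                    config = boost_config(), ids = NULL,
                    min_cluster_size = 10L, seed = 42L, restarts = 10L) {
  stopifnot(inherits(dataset, "qa_dataset"))
  ids <- ids %||% dataset$id
  train_ds <- subset_dataset(dataset, ids)
  train_pred <- predictions[ids, , drop = FALSE]
  miss <- setdiff(ids, rownames(embeddings))
  if (length(miss)) stop_fmt("no embedding for id '%s'", miss[1L])
  X <- embeddings[ids, , drop = FALSE]

  if (length(k) > 1L) {
    k <- select_k(X, k_min = min(k), k_max = max(k), seed = seed,
                  restarts = restarts)$best_k
  }
  cluster_model <- kmeans_fit(X, k, seed = seed, restarts = restarts)
  global_state <- boost_fit(train_ds, train_pred, config)

  states <- list()
  for (cl in seq_len(cluster_model$K)) {
    members <- ids[cluster_model$assignments == cl]
    if (length(members) >= min_cluster_size) {
      states[[as.character(cl)]] <-
        boost_fit(dataset, predictions, config, ids = members)
    }
  }
  if (length(states) == 0L) {
    warning("every cluster is below min_cluster_size; the ensemble degenerates to the global weights",
            call. = FALSE)
  }
  structure(
    list(cluster_model = cluster_model, states = states,
         global_state = global_state,
         min_cluster_size = as.integer(min_cluster_size),
         model_names = colnames(train_pred), config = config,
         seed = as.integer(seed)),
    class = "llm_dms"
  )
}

#' @export
print.llm_dms <- function(x, ...) {
  cat(sprintf("<llm_dms> K = %d clusters, %d with dedicated weights (min size %d)\n",
              x$cluster_model$K, length(x$states), x$min_cluster_size))
  for (cl in names(x$states)) {
    w <- x$states[[cl]]$weights
    top <- names(which.max(w))
    cat(sprintf("  cluster %s (n = %d): top model %s at %.1f%%\n",
                cl, x$states[[cl]]$n_train, top, 100 * max(w)))
  }
  cat(sprintf("  global fallback: top model %s at %.1f%%\n",
              names(which.max(x$global_state$weights)),
              100 * max(x$global_state$weights)))
  invisible(x)
}

#' @export
coef.llm_dms <- function(object, ...) {
  out <- rbind(
    global = object$global_state$weights,
    do.call(rbind, lapply(object$states, function(s) s$weights))
  )
  rownames(out) <- c("global", names(object$states))
  out
}

#' @export
plot.llm_dms <- function(x, ...) {
  W <- t(coef(x))
  graphics::barplot(100 * W, beside = TRUE, legend.text = rownames(W),
                    ylab = "weight (%)", xlab = "cluster",
                    main = "Per-cluster model weights", ...)
  invisible(x)
}

# Weight vector used for a routed cluster label (global fallback when the
# cluster has no dedicated state).
dms_state_for <- function(object, cluster_label) {
  object$states[[as.character(cluster_label)]] %||% object$global_state
}

#' Predict answers with a dynamic model selection ensemble
#'
#' Routes every instance to its nearest training-time centroid and applies
#' that cluster's weighted vote (or the global fallback for clusters without
#' dedicated weights).
#'
#' @param object an `llm_dms` fit.
#' @param predictions prediction matrix whose row names select the instances
#'   to answer; columns must match the fitted roster.
#' @param dataset the [qa_dataset()] supplying option orders.
#' @param embeddings embedding matrix covering every requested row.
#' @param explain if `TRUE`, return a provenance data frame instead of a bare
#'   answer vector: columns `id`, `cluster`, `used_global`, `answer`, plus an
#'   attribute `"weights"` holding the exact weight vector applied to each
#'   row. Re-voting with those records reproduces the answers.
#' @param ... unused.
#' @return Named character vector of answers, or the provenance data frame
#'   when `explain = TRUE`.
#' @export
predict.llm_dms <- function(object, predictions, dataset, embeddings,
                            explain = FALSE, ...) {
  if (!identical(colnames(predictions), object$model_names)) {
    stop_fmt("prediction matrix columns do not match the fitted model roster")
  }
  ids <- rownames(predictions)
  miss <- setdiff(ids, rownames(embeddings))
  if (length(miss)) stop_fmt("no embedding for id '%s'", miss[1L])
  ds <- subset_dataset(dataset, ids)
  clusters <- assign_cluster(object$cluster_model,
                             embeddings[ids, , drop = FALSE])
  answers <- character(length(ids))
  used_global <- logical(length(ids))
  W <- matrix(NA_real_, length(ids), length(object$model_names),
              dimnames = list(ids, object$model_names))
  for (cl in sort(unique(clusters))) {
    rows <- which(clusters == cl)
    state <- dms_state_for(object, cl)
    used_global[rows] <- is.null(object$states[[as.character(cl)]])
    W[rows, ] <- matrix(state$weights, length(rows), length(state$weights),
                        byrow = TRUE)
    answers[rows] <- ensemble_answers(
      predictions[rows, , drop = FALSE], state$weights,
      ds$options[rows], ds$option_scheme
    )
  }
  names(answers) <- ids
  if (!explain) return(answers)
  out <- data.frame(id = ids, cluster = clusters, used_global = used_global,
                    answer = unname(answers), stringsAsFactors = FALSE)
  attr(out, "weights") <- W
  out
}

#' Tune the cluster count of a dynamic selection ensemble on validation data
#'
#' Fits one ensemble per candidate `(K, seed)` pair on the training ids and
#' scores each on the validation ids; the configuration with the highest
#' validation accuracy wins, ties resolving to the smaller K and then the
#' smaller seed. Validation questions are routed to the training-time
#' centroids — they are never re-clustered — so no information leaks from
#' validation into the fitted weights.
#'
#' @param dataset a [qa_dataset()].
#' @param predictions prediction matrix aligned to `dataset`.
#' @param embeddings embedding matrix covering train and validation ids.
#' @param split a `split_result` from [stratified_split()] (or any list with
#'   `train_ids` and `validation_ids`).
#' @param k_range integer vector of candidate cluster counts.
#' @param seeds integer vector of clustering seeds to try. Default the single
#'   seed 42.
#' @param config a [boost_config()].
#' @param min_cluster_size passed to [dms_fit()].
#' @param restarts k-means restarts per fit.
#' @return An object of class `dms_tune`: `best` (the winning `llm_dms`,
#'   fitted on the training ids), `k`, `seed`, `validation_accuracy`, and
#'   `report` (one row per configuration).
#' @export
dms_tune <- function(dataset, predictions, embeddings, split, k_range,
                     seeds = 42L, config = boost_config(),
                     min_cluster_size = 10L, restarts = 10L) {
  if (length(k_range) == 0L) stop_fmt("k_range must not be empty")
  if (length(split$validation_ids) == 0L) {
    stop_fmt("the validation split is empty")
  }
  k_range <- sort(unique(as.integer(k_range)))
  seeds <- sort(unique(as.integer(seeds)))
  val_ds <- subset_dataset(dataset, split$validation_ids)
  val_pred <- predictions[split$validation_ids, , drop = FALSE]
  grid <- expand.grid(k = k_range, seed = seeds, KEEP.OUT.ATTRS = FALSE)
  acc <- numeric(nrow(grid))
  n_states <- integer(nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fit <- dms_fit(dataset, predictions, embeddings, k = grid$k[i],
                   config = config, ids = split$train_ids,
                   min_cluster_size = min_cluster_size,
                   seed = grid$seed[i], restarts = restarts)
    ans <- predict(fit, val_pred, val_ds, embeddings)
    acc[i] <- accuracy(ans, val_ds$gold)
    n_states[i] <- length(fit$states)
    fits[[i]] <- fit
  }
  report <- cbind(grid, validation_accuracy = acc,
                  clusters_with_weights = n_states)
  # highest accuracy; ties to smaller K then smaller seed (grid order)
  best_i <- order(-acc, grid$k, grid$seed)[1L]
  structure(
    list(best = fits[[best_i]], k = grid$k[best_i], seed = grid$seed[best_i],
         validation_accuracy = acc[best_i], report = report),
    class = "dms_tune"
  )
}

#' @export
print.dms_tune <- function(x, ...) {
  cat(sprintf("<dms_tune> best K = %d (seed %d), validation accuracy %.2f%%\n",
              x$k, x$seed, 100 * x$validation_accuracy))
  print.data.frame(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize or restore a dynamic selection ensemble as JSON
#'
#' @param object an `llm_dms` fit.
#' @param path file path.
#' @return `read_dms` returns an `llm_dms`; `write_dms` returns `path`
#'   invisibly.
#' @export
write_dms <- function(object, path) {
  stopifnot(inherits(object, "llm_dms"))
  tmp_state <- function(s) list(
    model_names = s$model_names, weights = unname(s$weights),
    errors = unname(s$errors), alphas = unname(s$alphas),
    converged = s$converged, passes = s$passes, n_train = s$n_train,
    eps = s$eps, config = unclass(s$config), history = s$history
  )
  jsonlite::write_json(
    list(
      cluster_model = list(
        K = object$cluster_model$K,
        centroids = object$cluster_model$centroids,
        wcss = object$cluster_model$wcss,
        seed = object$cluster_model$seed,
        restarts = object$cluster_model$restarts
      ),
      states = lapply(object$states, tmp_state),
      global_state = tmp_state(object$global_state),
      min_cluster_size = object$min_cluster_size,
      model_names = object$model_names,
      config = unclass(object$config),
      seed = object$seed
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_dms
#' @export
read_dms <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  mk_config <- function(cfg) boost_config(
    error_clamp_eps = cfg$error_clamp_eps, convergence_tol = cfg$convergence_tol,
    max_passes = cfg$max_passes, learning_rate = cfg$learning_rate,
    mode = cfg$mode
  )
  mk_state <- function(s) {
    w <- as.numeric(s$weights); e <- as.numeric(s$errors)
    a <- as.numeric(s$alphas)
    names(w) <- names(e) <- names(a) <- s$model_names
    structure(
      list(model_names = s$model_names, weights = w, errors = e, alphas = a,
           history = as.data.frame(s$history), converged = s$converged,
           passes = as.integer(s$passes), n_train = as.integer(s$n_train),
           eps = as.numeric(s$eps), config = mk_config(s$config)),
      class = "llm_boost"
    )
  }
  cm <- structure(
    list(K = as.integer(x$cluster_model$K),
         centroids = as.matrix(x$cluster_model$centroids),
         assignments = integer(0), wcss = as.numeric(x$cluster_model$wcss),
         wcss_trace = numeric(0), mean_silhouette = NA_real_,
         seed = as.integer(x$cluster_model$seed),
         restarts = as.integer(x$cluster_model$restarts), iterations = NA_integer_),
    class = "kmeans_model"
  )
  structure(
    list(cluster_model = cm, states = lapply(x$states, mk_state),
         global_state = mk_state(x$global_state),
         min_cluster_size = as.integer(x$min_cluster_size),
         model_names = x$model_names, config = mk_config(x$config),
         seed = as.integer(x$seed)),
    class = "llm_dms"
  )
}
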