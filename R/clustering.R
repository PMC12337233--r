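# Question-context embedding contract, k-means clustering with seeded
# k-means++ restarts, and K selection by mean silhouette with elbow
# confirmation on the within-cluster sum of squares.

#' Deterministic hashing text embedder
#'
#' A lightweight embedder that maps text to a fixed-dimension vector by
#' hashing lowercase word tokens into buckets and summing a seeded Gaussian
#' random-projection vector per bucket occurrence. It is deterministic for a
#' fixed `(dim, seed, buckets)` configuration and requires no model download,
#' which makes the whole clustering pipeline runnable and testable offline.
#' Any encoder that mean-pools transformer hidden states into a fixed-length
#' vector (for example a clinical-domain BERT) can be plugged in instead by
#' supplying an object with the same `name` / `dimension` / `embed` fields.
#'
#' @param dim embedding dimension. Default 768, the usual BERT-base pooled
#'   size.
#' @param seed integer seed for the projection vectors.
#' @param buckets number of hash buckets. Default 4096.
#' @return An object of class `text_embedder` whose `embed` element is a
#'   function mapping a character vector of texts to a `length(texts) x dim`
#'   matrix.
#' @export
#' @examples
#' emb <- hash_embedder(dim = 16, seed = 1)
#' dim(emb$embed(c("first question", "second question")))
hash_embedder <- function(dim = 768L, seed = 1L, buckets = 4096L) {
  if (!is_count(dim) || !is_count(buckets)) {
    stop_fmt("dim and buckets must be positive integers")
  }
  dim <- as.integer(dim); buckets <- as.integer(buckets)
  cache <- new.env(parent = emptyenv())
  bucket_vector <- function(b) {
    key <- as.character(b)
    if (is.null(cache[[key]])) {
      cache[[key]] <- with_seed(derive_seed(seed, b), stats::rnorm(dim)) / sqrt(dim)
    }
    cache[[key]]
  }
  embed <- function(texts) {
    out <- matrix(0, length(texts), dim)
    for (i in seq_along(texts)) {
      toks <- tokenize_text(texts[i])
      if (length(toks) == 0L) next  # zero vector for empty text
      for (b in hash_tokens(toks, buckets)) {
        out[i, ] <- out[i, ] + bucket_vector(b)
      }
    }
    out
  }
  structure(
    list(name = sprintf("hash-%d-%d", dim, seed), dimension = dim,
         seed = as.integer(seed), buckets = buckets, embed = embed),
    class = "text_embedder"
  )
}

# Lowercase word tokenization on non-alphanumeric boundaries.
tokenize_text <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1L]]
  toks[nzchar(toks)]
}

# Polynomial rolling hash of each token into 1..buckets. Intermediate values
# stay below 2^25 so the arithmetic is exact in doubles on every platform.
hash_tokens <- function(tokens, buckets) {
  vapply(tokens, function(tok) {
    h <- 0
    for (code in utf8ToInt(tok)) h <- (h * 31 + code) %% 1048573
    as.integer(h %% buckets) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

#' Embed the question contexts of a dataset
#'
#' Only `question` text is embedded — never the candidate answer options —
#' so the clustering sees the question context alone. Instances with empty
#' question text map to the zero vector with a warning.
#'
#' @param dataset a [qa_dataset()].
#' @param embedder a `text_embedder` (see [hash_embedder()]) or any object
#'   with fields `dimension` and `embed(texts)`.
#' @return Numeric matrix, one row per instance in dataset order, row names
#'   set to instance ids.
#' @export
embed_questions <- function(dataset, embedder) {
  stopifnot(inherits(dataset, "qa_dataset"))
  empty <- !nzchar(trimws(dataset$question))
  if (any(empty)) {
    warning(sprintf("empty question text for id(s) %s: embedded as zero vector",
                    paste(dataset$id[empty], collapse = ", ")), call. = FALSE)
  }
  X <- embedder$embed(dataset$question)
  if (!is.matrix(X) || nrow(X) != length(dataset) ||
      ncol(X) != embedder$dimension) {
    stop_fmt("embedder returned a malformed matrix")
  }
  bad <- which(!apply(X, 1L, function(r) all(is.finite(r))))
  if (length(bad)) {
    stop_fmt("embedder produced non-finite values for id '%s'", dataset$id[bad[1L]])
  }
  rownames(X) <- dataset$id
  X
}

# Squared Euclidean distances between rows of X and rows of C, clamped at 0
# against floating-point cancellation.
sqdist_to_centroids <- function(X, C) {
  D <- matrix(rowSums(X^2), nrow(X), nrow(C)) +
    matrix(rowSums(C^2), nrow(X), nrow(C), byrow = TRUE) -
    2 * X %*% t(C)
  pmax(D, 0)
}

# k-means++ seeding: first centroid uniform, then each next centroid drawn
# with probability proportional to squared distance from the nearest chosen
# centroid. Runs under the caller's RNG state.
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1L] <- sample.int(n, 1L)
  if (K > 1L) {
    d2 <- sqdist_to_centroids(X, X[centers[1L], , drop = FALSE])[, 1L]
    for (k in 2L:K) {
      if (sum(d2) <= 0) {
        pool <- setdiff(seq_len(n), centers[seq_len(k - 1L)])
        centers[k] <- if (length(pool) > 1L) sample(pool, 1L) else pool
      } else {
        centers[k] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, sqdist_to_centroids(X, X[centers[k], , drop = FALSE])[, 1L])
    }
  }
  X[centers, , drop = FALSE]
}

# One Lloyd run from given initial centroids. Returns assignments, centroids,
# final WCSS and the per-iteration WCSS trace (non-increasing by
# construction). An empty cluster is re-seeded at the point currently
# farthest from its assigned centroid.
lloyd_run <- function(X, C, max_iter) {
  n <- nrow(X); K <- nrow(C)
  assign_old <- integer(0)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- sqdist_to_centroids(X, C)
    assignment <- max.col(-D, ties.method = "first")
    # re-seed empty clusters at the worst-served point, then re-assign
    repeat {
      sizes <- tabulate(assignment, K)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      point_d <- D[cbind(seq_len(n), assignment)]
      far <- which.max(point_d)
      C[empty[1L], ] <- X[far, ]
      D <- sqdist_to_centroids(X, C)
      assignment <- max.col(-D, ties.method = "first")
    }
    trace <- c(trace, sum(D[cbind(seq_len(n), assignment)]))
    if (identical(assignment, assign_old)) break
    assign_old <- assignment
    for (k in seq_len(K)) {
      C[k, ] <- colMeans(X[assignment == k, , drop = FALSE])
    }
  }
  D <- sqdist_to_centroids(X, C)
  wcss <- sum(D[cbind(seq_len(n), assignment)])
  list(assignment = assignment, centroids = C, wcss = wcss, trace = trace,
       iterations = length(trace))
}

#' Fit k-means to an embedding matrix
#'
#' Lloyd's algorithm with k-means++ seeding, run `restarts` times under a
#' single seeded stream; the restart with the lowest within-cluster sum of
#' squares (WCSS) wins. The fit is a deterministic function of
#' `(X, K, seed, restarts)`.
#'
#' @param X numeric matrix, one point per row (row names carried through to
#'   assignments).
#' @param K number of clusters, `1 <= K <= nrow(X)`.
#' @param seed integer seed.
#' @param restarts number of k-means++ restarts. Default 10.
#' @param max_iter Lloyd iteration cap per restart. Default 100.
#' @return An object of class `kmeans_model`: `K`, `centroids` (K x d),
#'   `assignments` (integer labels in 1..K, named by row names), `wcss`,
#'   `wcss_trace` (per-iteration WCSS of the winning restart),
#'   `mean_silhouette` (`NA` unless filled by [select_k()]), `seed`,
#'   `restarts`, `iterations`.
#' @export
kmeans_fit <- function(X, K, seed = 42L, restarts = 10L, max_iter = 100L) {
  X <- as.matrix(X)
  if (!is_count(K)) stop_fmt("K must be a positive integer")
  if (K > nrow(X)) stop_fmt("K = %d exceeds the number of points (%d)", K, nrow(X))
  best <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      run <- lloyd_run(X, kmeanspp_init(X, K), max_iter)
      if (is.null(best) || run$wcss < best$wcss) best <- run
    }
    best
  })
  assignments <- best$assignment
  names(assignments) <- rownames(X)
  dimnames(best$centroids) <- NULL
  structure(
    list(K = as.integer(K), centroids = best$centroids,
         assignments = assignments, wcss = best$wcss,
         wcss_trace = best$trace, mean_silhouette = NA_real_,
         seed = as.integer(seed), restarts = as.integer(restarts),
         iterations = best$iterations),
    class = "kmeans_model"
  )
}

#' @export
print.kmeans_model <- function(x, ...) {
  cat(sprintf("<kmeans_model> K = %d, %d points, WCSS = %.4f (seed %d, %d restarts)\n",
              x$K, length(x$assignments), x$wcss, x$seed, x$restarts))
  cat("  cluster sizes:", paste(tabulate(x$assignments, x$K), collapse = ", "), "\n")
  invisible(x)
}

#' Mean silhouette coefficient of a clustering
#'
#' For each point, `a` is its mean Euclidean distance to the other members of
#' its cluster and `b` the smallest mean distance to any other cluster;
#' `s = (b - a) / max(a, b)`. Points in singleton clusters score 0 by
#' convention. Requires at least two clusters. Uses the full pairwise
#' distance matrix, so memory is O(N^2).
#'
#' @param X numeric matrix of points.
#' @param assignments integer cluster labels, one per row of `X`.
#' @return The mean silhouette, in `[-1, 1]`.
#' @export
mean_silhouette <- function(X, assignments) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(assignments) != n) {
    stop_fmt("assignments must have one label per row of X")
  }
  labels <- sort(unique(assignments))
  if (length(labels) < 2L) {
    stop_fmt("the silhouette is undefined for a single cluster")
  }
  D <- as.matrix(stats::dist(X))
  sizes <- table(factor(assignments, levels = labels))
  # mean distance from each point to each cluster, via column sums per group
  sums <- vapply(labels, function(l) rowSums(D[, assignments == l, drop = FALSE]),
                 numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    li <- match(assignments[i], labels)
    ni <- sizes[[li]]
    if (ni == 1L) { s[i] <- 0; next }
    a <- sums[i, li] / (ni - 1L)
    b <- min(sums[i, -li] / as.numeric(sizes[-li]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Choose the number of clusters by silhouette with elbow confirmation
#'
#' Fits k-means for each K in `k_min..k_max` and returns the K with the
#' highest mean silhouette (ties resolve to the smaller K). The
#' within-cluster sum of squares is reported for every K so the elbow can be
#' inspected; the elbow position (largest second difference of the WCSS
#' curve) is computed as an advisory confirmation and a warning is raised
#' when it disagrees with the silhouette winner.
#'
#' @param X numeric matrix of points.
#' @param k_min,k_max search range, `2 <= k_min <= k_max <= nrow(X) - 1`.
#'   Default 2..15.
#' @param seed integer seed shared by every fit.
#' @param restarts k-means restarts per K.
#' @return An object of class `k_selection`: `best_k`, `elbow_k` (`NA` when
#'   the range is too short for a second difference), `report` (data frame of
#'   K, mean silhouette, WCSS), and `models` (the fitted `kmeans_model` per
#'   K, named by K).
#' @export
select_k <- function(X, k_min = 2L, k_max = 15L, seed = 42L, restarts = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!(is_count(k_min) && is_count(k_max) && 2 <= k_min && k_min <= k_max)) {
    stop_fmt("need 2 <= k_min <= k_max")
  }
  if (k_max > n - 1L) stop_fmt("k_max must not exceed N - 1 = %d", n - 1L)
  if (all(apply(X, 2L, function(col) diff(range(col)) == 0))) {
    stop_fmt("all points are identical; no cluster structure to select")
  }
  ks <- seq.int(k_min, k_max)
  models <- vector("list", length(ks))
  sil <- wcss <- numeric(length(ks))
  for (i in seq_along(ks)) {
    fit <- kmeans_fit(X, ks[i], seed = seed, restarts = restarts)
    fit$mean_silhouette <- mean_silhouette(X, fit$assignments)
    models[[i]] <- fit
    sil[i] <- fit$mean_silhouette
    wcss[i] <- fit$wcss
  }
  names(models) <- ks
  best_k <- ks[which.max(sil)]  # which.max takes the first, hence smallest K
  elbow_k <- NA_integer_
  if (length(ks) >= 3L) {
    second_diff <- utils::head(wcss, -2L) - 2 * wcss[2:(length(ks) - 1L)] +
      utils::tail(wcss, -2L)
    elbow_k <- ks[which.max(second_diff) + 1L]
    if (elbow_k != best_k) {
      warning(sprintf("elbow method suggests K = %d but silhouette selects K = %d",
                      elbow_k, best_k), call. = FALSE)
    }
  }
  structure(
    list(best_k = best_k, elbow_k = elbow_k,
         report = data.frame(k = ks, silhouette = sil, wcss = wcss),
         models = models),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> best K = %d by mean silhouette", x$best_k))
  if (!is.na(x$elbow_k)) cat(sprintf(" (elbow at K = %d)", x$elbow_k))
  cat("\n")
  print.data.frame(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Route points to the nearest centroid of a fitted cluster model
#'
#' @param model a `kmeans_model`.
#' @param X a single d-vector or a matrix with d columns.
#' @return Integer cluster label(s) in `1..K`; distance ties resolve to the
#'   smaller label.
#' @export
assign_cluster <- function(model, X) {
  stopifnot(inherits(model, "kmeans_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$centroids)) {
    stop_fmt("points have dimension %d but centroids have dimension %d",
             ncol(X), ncol(model$centroids))
  }
  labels <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    d2 <- rowSums(sweep(model$centroids, 2L, X[i, ])^2)
    labels[i] <- which.min(d2)  # first minimum = smaller label on ties
  }
  labels
}

#' @export
predict.kmeans_model <- function(object, newdata, ...) {
  assign_cluster(object, newdata)
}
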