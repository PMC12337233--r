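# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain loops so they stay independent of the vectorized implementation
# paths they check.

tiny_dataset <- function(n = 4L, options = c("A", "B", "C", "D"),
                         gold = NULL) {
  gold <- gold %||% rep(options, length.out = n)
  qa_dataset(
    id = sprintf("q%02d", seq_len(n)),
    question = sprintf("question number %d about topic %d", seq_len(n),
                       seq_len(n) %% 3),
    options = options,
    gold = gold
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive per-option score enumeration: the voting oracle.
oracle_vote <- function(predicted, weights, options) {
  predicted <- unname(predicted)
  best <- options[1L]
  best_score <- -Inf
  for (o in options) {
    score <- 0
    for (j in seq_along(predicted)) {
      if (identical(predicted[j], o)) score <- score + weights[j]
    }
    if (score > best_score + 1e-15) {  # strict improvement keeps first-tie rule
      best_score <- score
      best <- o
    }
  }
  best
}

# O(N^2) silhouette oracle with explicit per-point loops.
oracle_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      members <- which(labels == l)
      b <- min(b, mean(vapply(members, function(j) d(i, j), numeric(1))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Exhaustive enumeration of every assignment of n points to K clusters,
# returning the minimal WCSS (centroids at cluster means).
oracle_kmeans_wcss <- function(X, K) {
  n <- nrow(X)
  best <- Inf
  grid <- expand.grid(rep(list(seq_len(K)), n))
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) < K) next
    w <- 0
    for (k in seq_len(K)) {
      pts <- X[lab == k, , drop = FALSE]
      ctr <- colMeans(pts)
      w <- w + sum(sweep(pts, 2L, ctr)^2)
    }
    best <- min(best, w)
  }
  best
}

# Best label agreement over all permutations of K cluster labels (K small).
permuted_agreement <- function(found, truth, K) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(K))) {
    best <- max(best, mean(p[found] == truth))
  }
  best
}

# Gaussian blob generator for clustering tests: K centers `sep` apart on
# scaled basis vectors, n points total.
make_blobs <- function(n = 150L, K = 3L, d = 2L, sep = 10, sd = 0.1,
                       seed = 1L) {
  stopifnot(d >= K)
  set.seed(seed)
  labels <- sort(rep_len(seq_len(K), n))
  centers <- matrix(0, K, d)
  for (k in seq_len(K)) centers[k, k] <- sep / sqrt(2)
  X <- centers[labels, , drop = FALSE] + matrix(rnorm(n * d, sd = sd), n, d)
  rownames(X) <- sprintf("p%03d", seq_len(n))
  list(X = X, labels = labels)
}
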