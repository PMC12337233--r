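test_that("the hashing embedder is deterministic and text-driven", {
  emb <- hash_embedder(dim = 32, seed = 5)
  ds <- qa_dataset(
    id = c("q1", "q2", "q3"),
    question = c("what is the dose", "what is the dose", "renal clearance path"),
    options = c("A", "B"), gold = c("A", "B", "A")
  )
  X1 <- embed_questions(ds, emb)
  X2 <- embed_questions(ds, hash_embedder(dim = 32, seed = 5))
  expect_identical(X1, X2)
  expect_identical(dim(X1), c(3L, 32L))
  expect_identical(rownames(X1), ds$id)
  # identical question text gives identical rows; different text differs
  expect_identical(X1[1, ], X1[2, ])
  expect_false(all(X1[1, ] == X1[3, ]))
  # a different seed yields a different projection
  X3 <- embed_questions(ds, hash_embedder(dim = 32, seed = 6))
  expect_false(all(X1 == X3))
})

test_that("empty question text embeds as a zero vector with a warning", {
  ds <- qa_dataset(c("q1", "q2"), c("", "real question"), c("A", "B"),
                   c("A", "B"))
  expect_warning(X <- embed_questions(ds, hash_embedder(dim = 8, seed = 1)),
                 "q1")
  expect_identical(X["q1", ], rep(0, 8))
})

test_that("k-means attains the brute-force optimum on the 4-point toy", {
  X <- matrix(c(0, 0, 0, 1, 10, 10, 10, 11), 4, 2, byrow = TRUE)
  fit <- kmeans_fit(X, 2, seed = 1)
  expect_equal(fit$wcss, 1.0)
  expect_equal(fit$wcss, oracle_kmeans_wcss(X, 2))
  ctr <- fit$centroids[order(fit$centroids[, 1]), ]
  expect_equal(ctr, matrix(c(0, 0.5, 10, 10.5), 2, 2, byrow = TRUE))
  # independent library cross-check
  expect_equal(fit$wcss, stats::kmeans(X, 2, nstart = 10)$tot.withinss)
})

test_that("k-means degenerate cases behave as forced", {
  set.seed(3)
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(kmeans_fit(X, 10, seed = 1)$wcss, 0)
  k1 <- kmeans_fit(X, 1, seed = 1)
  expect_equal(k1$centroids[1, ], colMeans(X))
  expect_error(kmeans_fit(X, 11, seed = 1), "exceeds")
})

test_that("k-means is bit-reproducible and its WCSS trace never increases", {
  set.seed(17)
  for (case in 1:25) {
    n <- sample(10:60, 1)
    d <- sample(2:8, 1)
    K <- sample(2:5, 1)
    X <- matrix(rnorm(n * d), n, d)
    f1 <- kmeans_fit(X, K, seed = case, restarts = 4)
    f2 <- kmeans_fit(X, K, seed = case, restarts = 4)
    expect_identical(f1, f2)
    expect_true(all(diff(f1$wcss_trace) <= 1e-9))
    expect_true(all(f1$assignments %in% seq_len(K)))
    expect_true(all(tabulate(f1$assignments, K) > 0L))
  }
})

test_that("mean silhouette matches the hand-derived toy value", {
  X <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  labels <- c(1, 1, 2, 2)
  # per point: a = 0.1; b = mean distance to the far pair; e.g. for the point
  # at 0, b = (10 + 10.1)/2 = 10.05 and s = 9.95/10.05
  hand <- (9.95 / 10.05 + 9.85 / 9.95) / 2
  expect_equal(mean_silhouette(X, labels), hand, tolerance = 1e-6)
  expect_error(mean_silhouette(X, rep(1, 4)), "single cluster")
})

test_that("mean silhouette agrees with the brute-force oracle and stays bounded", {
  set.seed(23)
  for (case in 1:15) {
    n <- sample(8:60, 1)
    d <- sample(1:4, 1)
    K <- sample(2:4, 1)
    X <- matrix(rnorm(n * d), n, d)
    labels <- sample(seq_len(K), n, replace = TRUE)
    labels[seq_len(K)] <- seq_len(K)  # keep every cluster non-empty
    got <- mean_silhouette(X, labels)
    expect_equal(got, oracle_silhouette(X, labels), tolerance = 1e-9)
    expect_gte(got, -1)
    expect_lte(got, 1)
  }
  # random split of one tight blob scores near zero
  blob <- matrix(rnorm(80, sd = 0.05), 40, 2)
  s <- mean_silhouette(blob, rep(1:2, 20))
  expect_lt(abs(s), 0.2)
})

test_that("singleton clusters contribute zero silhouette", {
  X <- matrix(c(0, 0.2, 0.1, 5), 4, 1)
  labels <- c(1, 1, 1, 2)
  expect_equal(mean_silhouette(X, labels), oracle_silhouette(X, labels),
               tolerance = 1e-12)
})

test_that("silhouette-based selection recovers the true number of blobs", {
  blobs <- make_blobs(n = 150, K = 3, d = 3, sep = 10, sd = 0.1, seed = 1)
  sel <- select_k(blobs$X, k_min = 2, k_max = 6, seed = 42)
  expect_identical(sel$best_k, 3L)
  expect_identical(nrow(sel$report), 5L)
  # duplicated pair of blobs: two groups
  # two true blobs: silhouette picks 2 while the elbow heuristic, computed on
  # a curve that starts at the truth, disagrees and triggers the advisory
  two <- make_blobs(n = 100, K = 2, d = 2, sep = 10, sd = 0.1, seed = 2)
  expect_warning(sel2 <- select_k(two$X, 2, 5, seed = 42), "elbow")
  expect_identical(sel2$best_k, 2L)
})

test_that("selection handles trivial and degenerate ranges", {
  blobs <- make_blobs(n = 60, K = 3, d = 3, seed = 4)
  sel <- suppressWarnings(select_k(blobs$X, 4, 4, seed = 1))
  expect_identical(sel$best_k, 4L)
  expect_identical(nrow(sel$report), 1L)
  same <- matrix(1, 30, 2)
  expect_error(select_k(same, 2, 4), "identical")
})

test_that("cluster recovery on separated blobs is near-perfect", {
  blobs <- make_blobs(n = 150, K = 3, d = 3, sep = 10, sd = 0.1, seed = 9)
  fit <- kmeans_fit(blobs$X, 3, seed = 42)
  expect_gt(permuted_agreement(fit$assignments, blobs$labels, 3), 0.95)
})

test_that("cluster routing is a nearest-centroid scan with a smaller-label tie rule", {
  blobs <- make_blobs(n = 90, K = 3, d = 3, seed = 5)
  fit <- kmeans_fit(blobs$X, 3, seed = 42)
  # a centroid maps to its own label
  for (k in 1:3) {
    expect_identical(assign_cluster(fit, fit$centroids[k, ]), k)
  }
  # midpoint of two centroids: the smaller label wins
  mid <- (fit$centroids[1, ] + fit$centroids[2, ]) / 2
  expect_identical(assign_cluster(fit, mid), 1L)
  # random vectors match an independent scan
  set.seed(6)
  V <- matrix(rnorm(60), 20, 3)
  got <- assign_cluster(fit, V)
  want <- vapply(seq_len(20), function(i) {
    which.min(vapply(1:3, function(k) sum((V[i, ] - fit$centroids[k, ])^2),
                     numeric(1)))
  }, integer(1))
  expect_identical(got, want)
  expect_identical(predict(fit, V), got)
  expect_error(assign_cluster(fit, c(1, 2)), "dimension")
})
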