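test_that("initial weights are equal and sum to one", {
  expect_identical(init_weights(4), rep(0.25, 4))
  expect_identical(init_weights(1), 1)
  w5 <- init_weights(5)
  expect_length(w5, 5)
  expect_equal(sum(w5), 1)
  expect_true(all(w5 == w5[1]))
  expect_error(init_weights(0), "positive integer")
})

test_that("model error counts mismatches and abstains as incorrect", {
  gold <- c("A", "B", "C", "D", "A", "B", "C", "D", "A", "B")
  pred <- gold
  pred[c(2, 5, 9)] <- c("C", "B", "D")
  expect_equal(model_error(gold, gold), 0)
  expect_equal(model_error(pred, gold), 0.3)
  expect_equal(model_error(c("A", abstain_label()), c("A", "B")), 0.5)
  expect_error(model_error(c("A"), c("A", "B")), "equal length")
})

test_that("the log-odds adjustment matches its closed form and properties", {
  expect_identical(alpha_weight(0.5), 0)
  expect_equal(alpha_weight(0.25), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(alpha_weight(0.25), 0.5493061443, tolerance = 1e-9)

  grid <- seq(0.01, 0.99, by = 0.01)
  a <- alpha_weight(grid, eps = 1e-9)
  # antisymmetry about 0.5
  expect_lt(max(abs(a + rev(a))), 1e-12)
  # strictly decreasing
  expect_true(all(diff(a) < 0))
  # clamping keeps the endpoints finite
  expect_true(is.finite(alpha_weight(0, eps = 1e-4)))
  expect_true(is.finite(alpha_weight(1, eps = 1e-4)))
  expect_error(alpha_weight(1.2), "\\[0, 1\\]")
})

test_that("weighted vote scores options and breaks ties by option order", {
  opts <- c("A", "B", "C", "D")
  expect_identical(weighted_vote(c("B", "B", "C"), rep(1 / 3, 3), opts), "B")
  # 0.5 vs 0.5 tie between A and B resolves to the earlier option A
  expect_identical(weighted_vote(c("A", "B", "B"), c(0.5, 0.3, 0.2), opts), "A")
  expect_identical(weighted_vote(c("C", "A", "B"), c(0.6, 0.2, 0.2), opts), "C")
  # abstains contribute no score
  expect_identical(
    weighted_vote(c(abstain_label(), "B", "C"), c(0.9, 0.06, 0.04), opts), "B")
  expect_error(weighted_vote(c("A", "B"), c(1), opts), "equal length")
  expect_error(weighted_vote(c("A", "B"), c(0.5, -0.5), opts), "nonnegative")
})

test_that("weighted vote agrees with exhaustive score enumeration", {
  set.seed(11)
  for (case in 1:200) {
    M <- sample(2:6, 1)
    n_opt <- sample(3:5, 1)
    opts <- LETTERS[1:n_opt]
    preds <- sample(c(opts, abstain_label()), M, replace = TRUE,
                    prob = c(rep(1, n_opt), 0.4))
    w <- runif(M)
    expect_identical(weighted_vote(preds, w, opts),
                     oracle_vote(preds, w, opts))
  }
})

test_that("the exponential margin loss matches its definition", {
  ds <- tiny_dataset(3, gold = c("A", "B", "C"))
  all_right <- prediction_matrix(matrix(c("A", "B", "C", "A", "B", "C"), 3, 2),
                                 ds, c("m1", "m2"))
  expect_equal(exp_margin_loss(all_right, ds$gold, c(0.5, 0.5)), 3 * exp(-1))
  all_wrong <- prediction_matrix(matrix("D", 3, 2), ds, c("m1", "m2"))
  expect_equal(exp_margin_loss(all_wrong, ds$gold, c(0.5, 0.5)), 3 * exp(1))
  split_row <- prediction_matrix(matrix(c("A", "D"), 1, 2),
                                 subset_dataset(ds, "q01"), c("m1", "m2"))
  expect_equal(exp_margin_loss(split_row, "A", c(0.5, 0.5)), 1)
})

test_that("degenerate rosters produce the forced weight vectors", {
  u <- generate_universe(scenario("graded", n_instances = 200, seed = 2))
  # single model: weight 1 regardless of passes
  solo <- u$predictions[, 1, drop = FALSE]
  fit1 <- boost_fit(u$dataset, solo)
  expect_identical(unname(fit1$weights), 1)
  # two identical models: symmetric weights
  twin <- cbind(u$predictions[, 1, drop = FALSE], u$predictions[, 1, drop = FALSE])
  colnames(twin) <- c("a", "b")
  fit2 <- boost_fit(u$dataset, twin)
  expect_equal(unname(fit2$weights[1]), unname(fit2$weights[2]), tolerance = 1e-12)
})

test_that("weights stay on the simplex after every pass", {
  u <- generate_universe(scenario("graded", n_instances = 500, seed = 4))
  fit <- boost_fit(u$dataset, u$predictions,
                   boost_config(convergence_tol = 0, max_passes = 25))
  W <- as.matrix(fit$history[, fit$model_names])
  expect_true(all(W >= 0))
  expect_true(all(abs(rowSums(W) - 1) < 1e-9))
  expect_identical(nrow(W), 25L)
})

test_that("with static errors the weights converge to the normalized adjustments", {
  # fixed error vector realised by a deterministic fixture: model j answers
  # the first round(E_j * N) instances wrongly
  E <- c(0.2, 0.3, 0.4)
  n <- 100L
  ds <- tiny_dataset(n, gold = rep("A", n))
  answers <- sapply(E, function(e) {
    out <- rep("A", n)
    out[seq_len(round(e * n))] <- "B"
    out
  })
  colnames(answers) <- paste0("m", 1:3)
  pm <- prediction_matrix(answers, ds)
  fit <- boost_fit(ds, pm,
                   boost_config(error_clamp_eps = 1e-6, convergence_tol = 0,
                                max_passes = 500))
  expect_equal(unname(fit$errors), E)
  target <- fit$alphas / sum(fit$alphas)
  expect_lt(max(abs(fit$weights - target)), 1e-3)
})

test_that("training recovers the accuracy ordering of graded synthetic models", {
  u <- generate_universe(scenario("graded", n_instances = 2000, seed = 1))
  sp <- stratified_split(u$dataset, 0.8, 42)
  fit <- boost_fit(u$dataset, u$predictions, ids = sp$train_ids)
  expect_identical(order(fit$weights, decreasing = TRUE), 1:4)
  expect_true(fit$converged)
  expect_identical(colnames(u$predictions), fit$model_names)
})

test_that("one-hot weights reproduce the base model exactly", {
  u <- generate_universe(scenario("graded", n_instances = 300, seed = 6))
  fit <- boost_fit(u$dataset, u$predictions)
  fit$weights <- stats::setNames(c(0, 1, 0, 0), fit$model_names)
  ans <- predict(fit, u$predictions, u$dataset)
  expect_identical(unname(ans), unname(u$predictions[, 2]))
  expect_equal(accuracy(ans, u$dataset$gold),
               accuracy(u$predictions[, 2], u$dataset$gold))
})

test_that("equal weights reduce prediction to a plurality vote", {
  u <- generate_universe(scenario("graded", n_instances = 200, seed = 8))
  fit <- boost_fit(u$dataset, u$predictions)
  fit$weights <- stats::setNames(init_weights(4), fit$model_names)
  ans <- predict(fit, u$predictions, u$dataset)
  manual <- vapply(seq_len(200), function(i) {
    oracle_vote(u$predictions[i, ], rep(0.25, 4), u$dataset$options[[i]])
  }, character(1))
  expect_identical(unname(ans), manual)
})

test_that("the ensemble is at least as accurate as the best single model", {
  # conditionally independent predictors, each better than chance
  spec <- synthetic_spec(n_instances = 4000, n_models = 4, n_options = 4,
                         accuracy = c(0.7, 0.6, 0.55, 0.5), seed = 31)
  u <- generate_universe(spec)
  fit <- boost_fit(u$dataset, u$predictions)
  best_single <- max(vapply(1:4, function(j) {
    accuracy(u$predictions[, j], u$dataset$gold)
  }, numeric(1)))
  ens <- accuracy(predict(fit, u$predictions, u$dataset), u$dataset$gold)
  expect_gte(ens, best_single - 0.005)
})

test_that("prediction rejects a mismatched model roster and flags silent rows", {
  u <- generate_universe(scenario("graded", n_instances = 50, seed = 9))
  fit <- boost_fit(u$dataset, u$predictions)
  shuffled <- u$predictions[, c(2, 1, 3, 4)]
  expect_error(predict(fit, shuffled, u$dataset), "roster")

  gagged <- u$predictions
  gagged[1, ] <- abstain_label()
  expect_warning(ans <- predict(fit, gagged, u$dataset), "abstained")
  expect_identical(unname(ans[1]), u$dataset$options[[1]][1])
  expect_identical(attr(ans, "all_abstain"), u$dataset$id[1])
})

test_that("the adaboost-instances mode trains and favors the stronger models", {
  u <- generate_universe(scenario("graded", n_instances = 2000, seed = 12))
  fit <- boost_fit(u$dataset, u$predictions,
                   boost_config(mode = "adaboost_instances", max_passes = 20))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_identical(unname(which.max(fit$weights)), 1L)
  expect_lt(fit$weights["model_4"], fit$weights["model_1"])
})

test_that("a fitted ensemble survives JSON serialization", {
  u <- generate_universe(scenario("graded", n_instances = 100, seed = 13))
  fit <- boost_fit(u$dataset, u$predictions)
  path <- withr::local_tempfile(fileext = ".json")
  write_boost(fit, path)
  back <- read_boost(path)
  expect_equal(back$weights, fit$weights)
  expect_equal(back$alphas, fit$alphas)
  expect_identical(predict(back, u$predictions, u$dataset),
                   predict(fit, u$predictions, u$dataset))
})
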