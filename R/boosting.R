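# Boosting-based weighted majority vote over a fixed roster of frozen base
# predictors. One weight per model is learned from its training error via the
# log-odds adjustment alpha = 0.5 * log((1 - E) / E); inference is a weighted
# plurality vote over option labels.

#' Configuration for boosting-based weight learning
#'
#' @param error_clamp_eps clamp applied to model error rates before the
#'   log-odds formula, keeping them inside `[eps, 1 - eps]`. `NULL` (default)
#'   means `1 / (2 * N)` at fit time, so a perfect model on N instances gets
#'   the largest finite adjustment representable at that sample size.
#' @param convergence_tol absolute training-accuracy change below which a
#'   pass counts as stable; training stops after two consecutive stable
#'   passes. Default `1e-4`. Set to 0 to always run `max_passes` passes.
#' @param max_passes maximum number of weight-update passes. Default 100.
#' @param learning_rate positive factor scaling each additive weight update.
#'   Default 1.
#' @param mode `"model_weights"` (default): per pass, every model's weight is
#'   increased by `learning_rate * alpha_j` computed from its static training
#'   error, negatives are clipped to zero and the vector renormalized.
#'   `"adaboost_instances"`: additionally maintains AdaBoost-style instance
#'   weights, so each model's error is measured on the instances its
#'   predecessors found hard.
#' @return An object of class `boost_config`.
#' @export
boost_config <- function(error_clamp_eps = NULL, convergence_tol = 1e-4,
                         max_passes = 100L, learning_rate = 1,
                         mode = c("model_weights", "adaboost_instances")) {
  mode <- match.arg(mode)
  if (!is.null(error_clamp_eps)) {
    if (!is.numeric(error_clamp_eps) || error_clamp_eps <= 0 ||
        error_clamp_eps >= 0.5) {
      stop_fmt("error_clamp_eps must lie in (0, 0.5)")
    }
  }
  if (!is.numeric(convergence_tol) || convergence_tol < 0) {
    stop_fmt("convergence_tol must be nonnegative")
  }
  if (!is_count(max_passes)) stop_fmt("max_passes must be a positive integer")
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop_fmt("learning_rate must be positive")
  }
  structure(
    list(error_clamp_eps = error_clamp_eps, convergence_tol = convergence_tol,
         max_passes = as.integer(max_passes), learning_rate = learning_rate,
         mode = mode),
    class = "boost_config"
  )
}

#' Equal initial model weights
#'
#' @param M number of base models, a positive integer.
#' @return Numeric vector of length `M`, all entries `1 / M`.
#' @export
#' @examples
#' init_weights(4)
init_weights <- function(M) {
  if (!is_count(M)) stop_fmt("M must be a positive integer")
  rep(1 / M, M)
}

#' Training error rate of one base model
#'
#' The fraction of instances the model answers incorrectly; an abstain counts
#' as incorrect.
#'
#' @param predicted character vector of a model's answers.
#' @param gold character vector of gold labels, same length.
#' @return The error fraction in `[0, 1]`.
#' @export
model_error <- function(predicted, gold) {
  if (length(predicted) != length(gold)) {
    stop_fmt("predicted and gold must have equal length")
  }
  if (length(gold) == 0L) stop_fmt("cannot compute an error rate on 0 instances")
  mean(predicted != gold)
}

#' Log-odds weight adjustment from an error rate
#'
#' Computes `alpha = 0.5 * log((1 - E') / E')` where `E'` is the error
#' clamped into `[eps, 1 - eps]`. The adjustment is the log-odds of the model
#' being correct: positive when the model beats coin-flipping on its own
#' error scale (`E < 0.5`), zero at `E = 0.5`, negative beyond.
#'
#' @param error error rate(s) in `[0, 1]`; vectorized.
#' @param eps clamp bound in (0, 0.5).
#' @return The adjustment(s) `alpha`.
#' @export
#' @examples
#' alpha_weight(0.25)        # 0.5 * log(3)
#' alpha_weight(0.5)         # exactly 0
alpha_weight <- function(error, eps = 1e-6) {
  if (any(!is.finite(error)) || any(error < 0) || any(error > 1)) {
    stop_fmt("error must lie in [0, 1]")
  }
  if (!is.numeric(eps) || eps <= 0 || eps >= 0.5) {
    stop_fmt("eps must lie in (0, 0.5)")
  }
  e <- pmin(pmax(error, eps), 1 - eps)
  0.5 * log((1 - e) / e)
}

#' Weighted plurality vote over one instance
#'
#' Each model casts its weight for the option it predicted; abstains cast
#' nothing. The option with the highest summed weight wins; ties are broken
#' by the earliest position in the instance's option order. If every model
#' abstains the first option is returned and the caller is expected to flag
#' the instance (see [predict.llm_boost()]).
#'
#' @param predicted character vector of M model answers for one instance.
#' @param weights numeric vector of M nonnegative model weights.
#' @param options the instance's ordered option labels.
#' @return The winning option label.
#' @export
#' @examples
#' weighted_vote(c("A", "B", "B"), c(0.5, 0.3, 0.2), c("A", "B", "C", "D"))
weighted_vote <- function(predicted, weights, options) {
  if (length(predicted) != length(weights)) {
    stop_fmt("predicted and weights must have equal length")
  }
  if (any(weights < 0)) stop_fmt("weights must be nonnegative")
  scores <- vapply(options, function(o) sum(weights[predicted == o]), numeric(1))
  options[which.max(scores)]
}

# Vectorized vote over all rows of a prediction matrix sharing one option
# scheme. Returns the winning label per row; ties resolve to the earliest
# option because max.col(ties.method = "first") scans columns in option order.
vote_rows <- function(predictions, weights, options) {
  scores <- matrix(0, nrow(predictions), length(options))
  for (k in seq_along(options)) {
    scores[, k] <- (predictions == options[k]) %*% weights
  }
  options[max.col(scores, ties.method = "first")]
}

# Vote over rows with per-instance option schemes (slow path).
vote_rows_generic <- function(predictions, weights, options_list) {
  vapply(seq_len(nrow(predictions)), function(i) {
    weighted_vote(predictions[i, ], weights, options_list[[i]])
  }, character(1))
}

ensemble_answers <- function(predictions, weights, dataset_options, scheme) {
  if (!is.null(scheme)) {
    vote_rows(predictions, weights, scheme)
  } else {
    vote_rows_generic(predictions, weights, dataset_options)
  }
}

#' Exponential margin loss of a weighted ensemble
#'
#' A monitoring diagnostic of ensemble confidence: with correctness encodings
#' `c_ij = +1` when model `j` answers instance `i` correctly and `-1`
#' otherwise (abstain counts as incorrect), the per-instance margin is
#' `m_i = sum_j w_j c_ij` and the loss is `sum_i exp(-m_i)`. It shrinks as
#' weight mass concentrates on models that are correct.
#'
#' @param predictions character prediction matrix (instances x models).
#' @param gold gold labels, one per row.
#' @param weights model weights.
#' @return The nonnegative loss.
#' @export
exp_margin_loss <- function(predictions, gold, weights) {
  if (nrow(predictions) != length(gold) || ncol(predictions) != length(weights)) {
    stop_fmt("predictions, gold and weights have inconsistent shapes")
  }
  correct <- predictions == gold  # abstain sentinel never equals a gold label
  margins <- (2 * correct - 1) %*% weights
  sum(exp(-margins))
}

#' Fit a boosting-weighted majority vote ensemble
#'
#' Learns one nonnegative weight per base model from the model's training
#' error rate. Per pass, each model receives the additive log-odds adjustment
#' `learning_rate * alpha_j` with `alpha_j = 0.5 * log((1 - E'_j) / E'_j)`;
#' negative weights are clipped to zero and the vector renormalized to sum 1.
#' Training stops when the training accuracy of the weighted vote changes by
#' less than `convergence_tol` over two consecutive passes, or at
#' `max_passes`. Because the base predictors are frozen, their error rates
#' are static in the default `"model_weights"` mode; the
#' `"adaboost_instances"` mode re-measures each model's error under
#' AdaBoost-style instance weights instead.
#'
#' @param dataset a [qa_dataset()].
#' @param predictions a prediction matrix aligned to `dataset` (see
#'   [prediction_matrix()] / [read_predictions()]).
#' @param config a [boost_config()].
#' @param ids optional character vector of training ids; defaults to the full
#'   dataset. Pass `train_ids` from [stratified_split()] to respect a split.
#' @return An object of class `llm_boost` with components `model_names`,
#'   `weights` (normalized, named), `errors`, `alphas`, `history` (one row
#'   per pass: training accuracy, exponential margin loss, weight vector),
#'   `converged`, `passes`, `n_train` and `config`. Supports `print()`,
#'   `summary()`, `coef()`, `predict()` and `plot()`.
#' @seealso [predict.llm_boost()], [weight_report()]
#' @export
boost_fit <- function(dataset, predictions, config = boost_config(), ids = NULL) {
  stopifnot(inherits(dataset, "qa_dataset"), inherits(config, "boost_config"))
  if (!is.null(ids)) {
    dataset <- subset_dataset(dataset, ids)
    predictions <- predictions[ids, , drop = FALSE]
  }
  n <- length(dataset)
  if (n == 0L) stop_fmt("the training set is empty")
  M <- ncol(predictions)
  if (M < 1L) stop_fmt("at least one base model is required")
  model_names <- colnames(predictions)
  gold <- dataset$gold
  eps <- config$error_clamp_eps %||% (1 / (2 * n))

  wrong <- predictions != gold              # abstain != gold always
  errors <- colMeans(wrong)
  alphas <- alpha_weight(errors, eps)

  w <- init_weights(M)
  lr <- config$learning_rate
  hist_acc <- numeric(0)
  hist_loss <- numeric(0)
  hist_w <- matrix(NA_real_, 0, M, dimnames = list(NULL, model_names))
  u <- rep(1 / n, n)  # instance weights, used only in adaboost_instances mode
  converged <- FALSE
  pass <- 0L

  while (pass < config$max_passes) {
    pass <- pass + 1L
    if (config$mode == "model_weights") {
      w <- w + lr * alphas
    } else {
      for (j in seq_len(M)) {
        ej <- sum(u * wrong[, j])
        aj <- alpha_weight(ej, eps)
        w[j] <- w[j] + lr * aj
        u <- u * exp(aj * wrong[, j])
        u <- u / sum(u)
      }
    }
    w <- pmax(w, 0)
    if (sum(w) == 0) w <- init_weights(M) else w <- w / sum(w)

    answers <- ensemble_answers(predictions, w, dataset$options,
                                dataset$option_scheme)
    acc <- mean(answers == gold)
    hist_acc <- c(hist_acc, acc)
    hist_loss <- c(hist_loss, exp_margin_loss(predictions, gold, w))
    hist_w <- rbind(hist_w, w)

    if (pass >= 3L) {
      d1 <- abs(hist_acc[pass] - hist_acc[pass - 1L])
      d2 <- abs(hist_acc[pass - 1L] - hist_acc[pass - 2L])
      if (d1 < config$convergence_tol && d2 < config$convergence_tol) {
        converged <- TRUE
        break
      }
    }
  }

  history <- data.frame(pass = seq_len(pass), accuracy = hist_acc,
                        loss = hist_loss)
  history <- cbind(history, as.data.frame(hist_w))
  names(w) <- names(errors) <- names(alphas) <- model_names
  structure(
    list(model_names = model_names, weights = w, errors = errors,
         alphas = alphas, history = history, converged = converged,
         passes = pass, n_train = n, eps = eps, config = config),
    class = "llm_boost"
  )
}

#' @export
print.llm_boost <- function(x, ...) {
  cat(sprintf("<llm_boost> %d models, trained on %d instances (%s after %d passes)\n",
              length(x$weights), x$n_train,
              if (x$converged) "converged" else "stopped", x$passes))
  w <- sort(x$weights, decreasing = TRUE)
  for (m in names(w)) {
    cat(sprintf("  %-20s weight %6.2f%%  (error %.3f)\n",
                m, 100 * w[m], x$errors[m]))
  }
  invisible(x)
}

#' @export
summary.llm_boost <- function(object, ...) {
  out <- data.frame(
    model = object$model_names,
    error = unname(object$errors),
    alpha = unname(object$alphas),
    weight = unname(object$weights),
    percent = unname(100 * object$weights),
    stringsAsFactors = FALSE
  )
  attr(out, "converged") <- object$converged
  attr(out, "passes") <- object$passes
  class(out) <- c("summary.llm_boost", "data.frame")
  out
}

#' @export
print.summary.llm_boost <- function(x, ...) {
  cat(sprintf("Boosting-weighted majority vote (%s, %d passes)\n",
              if (attr(x, "converged")) "converged" else "max passes reached",
              attr(x, "passes")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.llm_boost <- function(object, ...) object$weights

#' @export
plot.llm_boost <- function(x, ...) {
  graphics::barplot(100 * sort(x$weights, decreasing = TRUE),
                    ylab = "weight (%)", las = 2,
                    main = "Ensemble model weights", ...)
  invisible(x)
}

#' Predict answers with a fitted boosting ensemble
#'
#' Applies the learned weighted plurality vote row by row. Instances on which
#' every model abstained receive the first option of their scheme and are
#' reported in the `"all_abstain"` attribute of the result.
#'
#' @param object an `llm_boost` fit.
#' @param predictions a prediction matrix whose columns match the fit's model
#'   roster; its row names select and order the instances to answer.
#' @param dataset the [qa_dataset()] supplying each instance's option order.
#' @param ... unused.
#' @return Named character vector of predicted option labels (names are
#'   instance ids), with attribute `"all_abstain"` listing ids where no model
#'   voted.
#' @export
predict.llm_boost <- function(object, predictions, dataset, ...) {
  if (!identical(colnames(predictions), object$model_names)) {
    stop_fmt("prediction matrix columns do not match the fitted model roster")
  }
  ds <- subset_dataset(dataset, rownames(predictions))
  answers <- ensemble_answers(predictions, object$weights, ds$options,
                              ds$option_scheme)
  names(answers) <- ds$id
  silent <- rowSums(predictions != abstain_label()) == 0L
  if (any(silent)) {
    attr(answers, "all_abstain") <- ds$id[silent]
    warning(sprintf("%d instance(s) received no vote (all models abstained); %s",
                    sum(silent), "defaulted to the first option"),
            call. = FALSE)
  }
  answers
}

#' Serialize or restore a fitted boosting ensemble as JSON
#'
#' @param object an `llm_boost` fit.
#' @param path file path.
#' @return `read_boost` returns an `llm_boost`; `write_boost` returns `path`
#'   invisibly.
#' @export
write_boost <- function(object, path) {
  stopifnot(inherits(object, "llm_boost"))
  jsonlite::write_json(
    list(model_names = object$model_names,
         weights = unname(object$weights),
         errors = unname(object$errors),
         alphas = unname(object$alphas),
         converged = object$converged, passes = object$passes,
         n_train = object$n_train, eps = object$eps,
         config = unclass(object$config),
         history = object$history),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_boost
#' @export
read_boost <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- boost_config(
    error_clamp_eps = x$config$error_clamp_eps,
    convergence_tol = x$config$convergence_tol,
    max_passes = x$config$max_passes,
    learning_rate = x$config$learning_rate,
    mode = x$config$mode
  )
  w <- as.numeric(x$weights); e <- as.numeric(x$errors)
  a <- as.numeric(x$alphas)
  names(w) <- names(e) <- names(a) <- x$model_names
  structure(
    list(model_names = x$model_names, weights = w, errors = e, alphas = a,
         history = as.data.frame(x$history), converged = x$converged,
         passes = as.integer(x$passes), n_train = as.integer(x$n_train),
         eps = as.numeric(x$eps), config = cfg),
    class = "llm_boost"
  )
}
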