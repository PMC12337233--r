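# Evaluation harness: accuracy, individual-versus-ensemble comparison with a
# strict train/test leakage guard, and weight reporting.

#' Exact-match accuracy
#'
#' The sole evaluation metric: the fraction of instances whose predicted
#' option label equals the gold label. Precision/recall-style metrics are
#' deliberately not offered — they are sensitive to option reordering on
#' multiple-choice tasks.
#'
#' @param predicted character vector of predicted labels.
#' @param gold character vector of gold labels, same length.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' accuracy(c("A", "B", "D", "D"), c("A", "B", "C", "D"))
accuracy <- function(predicted, gold) {
  if (length(predicted) != length(gold)) {
    stop_fmt("predicted and gold must have equal length")
  }
  if (length(gold) == 0L) stop_fmt("cannot score 0 instances")
  mean(predicted == gold)
}

#' Compare individual base models against fitted ensembles on a test set
#'
#' Scores every base model and every supplied ensemble fit on the same test
#' rows and reports percentage-point gains over the best individual model.
#' The test ids must be disjoint from the train and validation ids — any
#' overlap is an error, never a warning, so accidental leakage cannot
#' produce a number.
#'
#' @param dataset a [qa_dataset()].
#' @param predictions prediction matrix aligned to `dataset`.
#' @param test_ids ids to score on.
#' @param train_ids,validation_ids ids used during fitting/tuning; asserted
#'   disjoint from `test_ids`.
#' @param fits named list of fitted ensembles (`llm_boost` and/or `llm_dms`
#'   objects); names label the report rows.
#' @param embeddings embedding matrix, required when any fit is an
#'   `llm_dms`.
#' @return An object of class `synergy_eval`: `per_model_accuracy`,
#'   `ensemble_accuracies`, `deltas` (percentage points over the best
#'   individual), `n_test`, and `per_cluster_breakdown` (per-cluster n and
#'   per-method accuracy, when a dynamic fit is present).
#' @export
evaluate_ensembles <- function(dataset, predictions, test_ids,
                               train_ids = character(),
                               validation_ids = character(),
                               fits = list(), embeddings = NULL) {
  stopifnot(inherits(dataset, "qa_dataset"))
  leaked <- intersect(test_ids, c(train_ids, validation_ids))
  if (length(leaked)) {
    stop_fmt("leakage guard: %d test id(s) also appear in train/validation (first: '%s')",
             length(leaked), leaked[1L])
  }
  if (length(test_ids) == 0L) stop_fmt("test_ids must not be empty")
  test_ds <- subset_dataset(dataset, test_ids)
  test_pred <- predictions[test_ids, , drop = FALSE]
  gold <- test_ds$gold

  per_model <- vapply(colnames(test_pred), function(m) {
    accuracy(test_pred[, m], gold)
  }, numeric(1))
  best_individual <- max(per_model)

  ens_acc <- numeric(0)
  method_answers <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    ans <- if (inherits(fit, "llm_dms")) {
      if (is.null(embeddings)) {
        stop_fmt("fit '%s' needs embeddings for cluster routing", nm)
      }
      predict(fit, test_pred, test_ds, embeddings)
    } else if (inherits(fit, "llm_boost")) {
      predict(fit, test_pred, test_ds)
    } else {
      stop_fmt("fit '%s' is neither llm_boost nor llm_dms", nm)
    }
    method_answers[[nm]] <- ans
    ens_acc[nm] <- accuracy(ans, gold)
  }
  deltas <- 100 * (ens_acc - best_individual)

  breakdown <- NULL
  dms_fits <- Filter(function(f) inherits(f, "llm_dms"), fits)
  if (length(dms_fits) > 0L) {
    cm <- dms_fits[[1L]]$cluster_model
    clusters <- assign_cluster(cm, embeddings[test_ids, , drop = FALSE])
    rows <- lapply(sort(unique(clusters)), function(cl) {
      sel <- clusters == cl
      row <- data.frame(cluster = cl, n = sum(sel))
      for (nm in names(method_answers)) {
        row[[nm]] <- accuracy(method_answers[[nm]][sel], gold[sel])
      }
      row
    })
    breakdown <- do.call(rbind, rows)
  }

  structure(
    list(per_model_accuracy = per_model, ensemble_accuracies = ens_acc,
         deltas = deltas, n_test = length(test_ids),
         per_cluster_breakdown = breakdown),
    class = "synergy_eval"
  )
}

#' @export
print.synergy_eval <- function(x, ...) {
  cat(sprintf("Test set performance (n = %d)\n", x$n_test))
  for (m in names(x$per_model_accuracy)) {
    cat(sprintf("  %-28s %6.2f%%\n", m, 100 * x$per_model_accuracy[m]))
  }
  for (m in names(x$ensemble_accuracies)) {
    cat(sprintf("  %-28s %6.2f%%  (%+.2f pts vs best individual)\n",
                m, 100 * x$ensemble_accuracies[m], x$deltas[m]))
  }
  if (!is.null(x$per_cluster_breakdown)) {
    cat("  per-cluster breakdown:\n")
    print.data.frame(x$per_cluster_breakdown, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Tabulate ensemble weights as percentages
#'
#' Renders the learned model weights of a boosting fit, or of every cluster
#' of a dynamic selection fit (plus the global fallback), as percentages.
#' Within each weighting the percentages sum to 100.
#'
#' @param fit an `llm_boost` or `llm_dms` object.
#' @return A data frame with columns `cluster` (`"global"` for a plain
#'   boosting fit), `model`, `weight` and `percent`.
#' @export
weight_report <- function(fit) UseMethod("weight_report")

#' @export
weight_report.llm_boost <- function(fit) {
  data.frame(cluster = "global", model = fit$model_names,
             weight = unname(fit$weights),
             percent = unname(100 * fit$weights),
             stringsAsFactors = FALSE)
}

#' @export
weight_report.llm_dms <- function(fit) {
  blocks <- lapply(names(fit$states), function(cl) {
    s <- fit$states[[cl]]
    data.frame(cluster = cl, model = s$model_names,
               weight = unname(s$weights), percent = unname(100 * s$weights),
               stringsAsFactors = FALSE)
  })
  rbind(weight_report(fit$global_state), do.call(rbind, blocks))
}

#' Serialize an evaluation report
#'
#' Writes the full-precision report as JSON and, optionally, a Markdown
#' table rendered from the same object at two decimal places.
#'
#' @param report a `synergy_eval`.
#' @param path JSON output path.
#' @param markdown_path optional Markdown output path.
#' @return `path`, invisibly.
#' @export
write_eval <- function(report, path, markdown_path = NULL) {
  stopifnot(inherits(report, "synergy_eval"))
  jsonlite::write_json(
    list(per_model_accuracy = as.list(report$per_model_accuracy),
         ensemble_accuracies = as.list(report$ensemble_accuracies),
         deltas = as.list(report$deltas), n_test = report$n_test,
         per_cluster_breakdown = report$per_cluster_breakdown),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  if (!is.null(markdown_path)) {
    lines <- c("| method | accuracy (%) | gain (pts) |",
               "|---|---|---|")
    for (m in names(report$per_model_accuracy)) {
      lines <- c(lines, sprintf("| %s | %.2f | |", m,
                                100 * report$per_model_accuracy[m]))
    }
    for (m in names(report$ensemble_accuracies)) {
      lines <- c(lines, sprintf("| %s | %.2f | %+.2f |", m,
                                100 * report$ensemble_accuracies[m],
                                report$deltas[m]))
    }
    writeLines(lines, markdown_path)
  }
  invisible(path)
}
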