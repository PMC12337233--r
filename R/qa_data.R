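# Domain containers and file I/O for multiple-choice QA data: datasets,
# cached prediction matrices from frozen base models, and the stratified
# train/validation split every downstream method consumes.

#' Construct a multiple-choice QA dataset
#'
#' A dataset is an ordered collection of question instances, each with a
#' unique id, free-text question (the "question context"), an ordered set of
#' distinct option labels, and a gold label drawn from those options. Option
#' order matters: it defines tie-breaking during weighted voting.
#'
#' @param id character vector of unique instance ids.
#' @param question character vector of question texts.
#' @param options either a character vector (a shared option scheme for all
#'   instances) or a list of character vectors, one per instance.
#' @param gold character vector of gold labels, each contained in the
#'   corresponding instance's options.
#' @return An object of class `qa_dataset` with fields `id`, `question`,
#'   `options` (list of per-instance option vectors), `gold`, and
#'   `option_scheme` (the shared scheme, or `NULL` if options differ).
#' @export
#' @examples
#' qa_dataset(
#'   id = c("q1", "q2"),
#'   question = c("First question?", "Second question?"),
#'   options = c("A", "B", "C", "D"),
#'   gold = c("A", "C")
#' )
qa_dataset <- function(id, question, options, gold) {
  id <- as.character(id)
  question <- as.character(question)
  gold <- as.character(gold)
  n <- length(id)
  if (n == 0L) stop_fmt("a qa_dataset must contain at least one instance")
  if (length(question) != n || length(gold) != n) {
    stop_fmt("id, question and gold must have equal length")
  }
  if (anyDuplicated(id)) {
    stop_fmt("duplicate instance id: '%s'", id[duplicated(id)][1L])
  }
  if (!is.list(options)) options <- rep(list(as.character(options)), n)
  if (length(options) != n) {
    stop_fmt("options must be a shared character vector or a list of length %d", n)
  }
  options <- lapply(options, as.character)
  for (i in seq_len(n)) {
    opts <- options[[i]]
    if (length(opts) < 2L) {
      stop_fmt("instance '%s' has fewer than 2 options", id[i])
    }
    if (anyDuplicated(opts)) {
      stop_fmt("instance '%s' has duplicated option labels", id[i])
    }
    if (!(gold[i] %in% opts)) {
      stop_fmt("gold label '%s' of instance '%s' is not among its options",
               gold[i], id[i])
    }
  }
  scheme <- options[[1L]]
  uniform <- all(vapply(options, function(o) identical(o, scheme), logical(1)))
  structure(
    list(
      id = id, question = question, options = options, gold = gold,
      option_scheme = if (uniform) scheme else NULL
    ),
    class = "qa_dataset"
  )
}

#' @export
length.qa_dataset <- function(x) length(x$id)

#' @export
print.qa_dataset <- function(x, ...) {
  cat(sprintf("<qa_dataset> %d instances\n", length(x)))
  if (!is.null(x$option_scheme)) {
    cat("  options:", paste(x$option_scheme, collapse = " / "), "\n")
  } else {
    cat("  options: per-instance schemes\n")
  }
  k <- min(3L, length(x))
  for (i in seq_len(k)) {
    q <- x$question[i]
    if (nchar(q) > 50) q <- paste0(substr(q, 1, 47), "...")
    cat(sprintf("  %s [gold %s] %s\n", x$id[i], x$gold[i], q))
  }
  if (length(x) > k) cat(sprintf("  ... and %d more\n", length(x) - k))
  invisible(x)
}

#' Subset a QA dataset by instance id
#'
#' @param dataset a [qa_dataset()].
#' @param ids character vector of ids to keep, in the requested order.
#' @return A `qa_dataset` restricted to `ids`.
#' @export
subset_dataset <- function(dataset, ids) {
  stopifnot(inherits(dataset, "qa_dataset"))
  idx <- match(ids, dataset$id)
  if (anyNA(idx)) stop_fmt("unknown instance id: '%s'", ids[is.na(idx)][1L])
  qa_dataset(dataset$id[idx], dataset$question[idx],
             dataset$options[idx], dataset$gold[idx])
}

#' Read a QA dataset from JSONL or CSV
#'
#' The canonical format is JSON Lines: one object per line with keys `id`,
#' `question`, `options` (array of labels) and `gold`. The CSV dialect is
#' UTF-8, comma-delimited with a header row and columns `id`, `question`,
#' `options` (labels joined by `|`) and `gold`.
#'
#' @param path path to the file.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @return A [qa_dataset()] preserving file order.
#' @export
read_qa_dataset <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fmt("dataset file not found: %s", path)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(
        jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
        error = function(e) stop_fmt("parse error at line %d of %s: %s",
                                     i, path, conditionMessage(e))
      )
      miss <- setdiff(c("id", "question", "options", "gold"), names(rec))
      if (length(miss)) {
        stop_fmt("record at line %d of %s is missing field(s): %s",
                 i, path, paste(miss, collapse = ", "))
      }
      recs[[i]] <- rec
    }
    qa_dataset(
      id = vapply(recs, function(r) as.character(r$id), character(1)),
      question = vapply(recs, function(r) as.character(r$question), character(1)),
      options = lapply(recs, function(r) as.character(r$options)),
      gold = vapply(recs, function(r) as.character(r$gold), character(1))
    )
  } else {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
    miss <- setdiff(c("id", "question", "options", "gold"), names(df))
    if (length(miss)) {
      stop_fmt("CSV %s is missing column(s): %s", path, paste(miss, collapse = ", "))
    }
    qa_dataset(df$id, df$question, strsplit(df$options, "|", fixed = TRUE),
               df$gold)
  }
}

#' Write a QA dataset to JSONL or CSV
#'
#' @inheritParams read_qa_dataset
#' @param dataset a [qa_dataset()].
#' @return `path`, invisibly.
#' @export
write_qa_dataset <- function(dataset, path, format = c("jsonl", "csv")) {
  stopifnot(inherits(dataset, "qa_dataset"))
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(seq_along(dataset$id), function(i) {
      jsonlite::toJSON(
        list(id = dataset$id[i], question = dataset$question[i],
             options = dataset$options[[i]], gold = dataset$gold[i]),
        auto_unbox = TRUE
      )
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- data.frame(
      id = dataset$id, question = dataset$question,
      options = vapply(dataset$options, paste, character(1), collapse = "|"),
      gold = dataset$gold, stringsAsFactors = FALSE
    )
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Construct a prediction matrix of cached base-model answers
#'
#' One categorical answer per (instance, model) cell, aligned to the dataset's
#' instance order. Every cell must be one of the corresponding instance's
#' option labels or the abstain sentinel (see [abstain_label()]).
#'
#' @param answers character matrix, instances in rows and models in columns.
#' @param dataset the [qa_dataset()] the rows align to.
#' @param model_names optional character vector of model names; defaults to
#'   `colnames(answers)`.
#' @return A validated character matrix with instance ids as row names and
#'   model names as column names.
#' @export
prediction_matrix <- function(answers, dataset, model_names = colnames(answers)) {
  stopifnot(inherits(dataset, "qa_dataset"))
  answers <- as.matrix(answers)
  storage.mode(answers) <- "character"
  if (is.null(model_names) || anyDuplicated(model_names)) {
    stop_fmt("model names must be present and distinct")
  }
  if (nrow(answers) != length(dataset)) {
    stop_fmt("prediction matrix has %d rows but the dataset has %d instances",
             nrow(answers), length(dataset))
  }
  colnames(answers) <- as.character(model_names)
  rownames(answers) <- dataset$id
  sentinel <- abstain_label()
  for (i in seq_len(nrow(answers))) {
    ok <- answers[i, ] %in% c(dataset$options[[i]], sentinel)
    if (!all(ok)) {
      j <- which(!ok)[1L]
      stop_fmt("prediction '%s' for (id '%s', model '%s') is not a valid option",
               answers[i, j], dataset$id[i], colnames(answers)[j])
    }
  }
  answers
}

#' Read a prediction matrix from CSV
#'
#' Expects a header row with an `id` column plus one column per model, and one
#' row per dataset instance. Rows are joined to the dataset on `id`, so file
#' row order is irrelevant.
#'
#' @param path path to the CSV file.
#' @param dataset the [qa_dataset()] the predictions belong to.
#' @return A validated prediction matrix aligned to `dataset` order.
#' @export
read_predictions <- function(path, dataset) {
  stopifnot(inherits(dataset, "qa_dataset"))
  if (!file.exists(path)) stop_fmt("prediction file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (!("id" %in% names(df))) stop_fmt("prediction CSV %s has no 'id' column", path)
  models <- setdiff(names(df), "id")
  if (length(models) == 0L) stop_fmt("prediction CSV %s names no models", path)
  idx <- match(dataset$id, df$id)
  if (anyNA(idx)) {
    stop_fmt("prediction CSV %s is missing instance id '%s'",
             path, dataset$id[is.na(idx)][1L])
  }
  prediction_matrix(as.matrix(df[idx, models, drop = FALSE]), dataset,
                    model_names = models)
}

#' Write a prediction matrix to CSV
#'
#' @param predictions a prediction matrix (see [prediction_matrix()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  df <- data.frame(id = rownames(predictions), predictions,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Stratified train/validation split
#'
#' Splits a dataset into train and validation id sets, stratified by gold
#' label so that the answer-option distribution is preserved in both parts.
#' Each gold class is shuffled under a seeded generator and the first
#' `floor(ratio * n_class)` instances go to train; classes with the largest
#' fractional remainders then receive one extra train instance each until the
#' global train size reaches `floor(ratio * N)`. The result is a
#' deterministic function of `(dataset, ratio, seed)`.
#'
#' @param dataset a [qa_dataset()].
#' @param ratio fraction of instances assigned to train, in (0, 1). Default 0.8.
#' @param seed integer seed. Default 42.
#' @return An object of class `split_result`: a list with `train_ids`,
#'   `validation_ids`, `ratio` and `seed`.
#' @export
#' @examples
#' ds <- qa_dataset(paste0("q", 1:10), rep("?", 10), c("A", "B"),
#'                  rep(c("A", "B"), 5))
#' sp <- stratified_split(ds, ratio = 0.8, seed = 42)
#' length(sp$train_ids)  # 8
stratified_split <- function(dataset, ratio = 0.8, seed = 42L) {
  stopifnot(inherits(dataset, "qa_dataset"))
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1) {
    stop_fmt("ratio must lie strictly between 0 and 1")
  }
  n <- length(dataset)
  classes <- sort(unique(dataset$gold))
  target <- floor(ratio * n)
  shuffled <- with_seed(seed, {
    lapply(classes, function(cl) sample(dataset$id[dataset$gold == cl]))
  })
  names(shuffled) <- classes
  n_class <- vapply(shuffled, length, integer(1))
  base <- floor(ratio * n_class)
  remainder <- ratio * n_class - base
  extra <- target - sum(base)
  take <- base
  if (extra > 0) {
    # deterministic remainder ordering: largest remainder first, class name
    # breaking ties
    ord <- order(-remainder, classes)
    bump <- ord[seq_len(extra)]
    take[bump] <- take[bump] + 1L
  }
  train_ids <- unlist(lapply(seq_along(classes), function(k) {
    shuffled[[k]][seq_len(take[k])]
  }), use.names = FALSE)
  train_ids <- dataset$id[dataset$id %in% train_ids]
  validation_ids <- setdiff(dataset$id, train_ids)
  structure(
    list(train_ids = train_ids, validation_ids = validation_ids,
         ratio = ratio, seed = as.integer(seed)),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> train %d / validation %d (ratio %.2f, seed %d)\n",
              length(x$train_ids), length(x$validation_ids), x$ratio, x$seed))
  invisible(x)
}

#' Read or write a split as JSON
#'
#' The split file records `seed`, `ratio`, `train_ids` and `validation_ids`.
#'
#' @param split a `split_result` from [stratified_split()].
#' @param path file path.
#' @return `read_split` returns a `split_result`; `write_split` returns
#'   `path` invisibly.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_result"))
  jsonlite::write_json(
    list(seed = split$seed, ratio = split$ratio,
         train_ids = split$train_ids, validation_ids = split$validation_ids),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(
    list(train_ids = as.character(x$train_ids),
         validation_ids = as.character(x$validation_ids),
         ratio = as.numeric(x$ratio), seed = as.integer(x$seed)),
    class = "split_result"
  )
}
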