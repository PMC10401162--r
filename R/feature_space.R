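#' @keywords internal
"_PACKAGE"

#' Recognized task stages
#'
#' Stage labels a task's embedding snapshot may carry: before pretraining
#' (`"randomly_initialized"`), after multimodal pretraining (`"pretrained"`),
#' after task fine-tuning (`"fine_tuned"`), or `"unspecified"`.
#'
#' @format Character vector of length 4.
#' @export
FEATURE_STAGES <- c("randomly_initialized", "pretrained", "fine_tuned",
                    "unspecified")

validate_embedding_matrix <- function(values, what = "embeddings") {
  if (!is.matrix(values) || !is.numeric(values))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop(what, " must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(values)))
    stop(what, " contains non-finite entries", call. = FALSE)
  invisible(values)
}

#' Create a task embedding set
#'
#' Bundles one task's sample embeddings (an m x d numeric matrix, rows are
#' samples) with its identifier and, optionally, the training stage the
#' snapshot was taken at.
#'
#' @param task_id Non-empty character scalar naming the task.
#' @param embeddings Numeric matrix, m samples x d dimensions, all entries
#'   finite. Row names, when present, are kept as sample identifiers.
#' @param stage One of [FEATURE_STAGES]; defaults to `"unspecified"`.
#' @return An object of class `task_embedding_set`.
#' @examples
#' task_embedding_set("stability", matrix(rnorm(20), 5, 4))
#' @export
task_embedding_set <- function(task_id, embeddings, stage = "unspecified") {
  if (!is.character(task_id) || length(task_id) != 1L || !nzchar(task_id) ||
      is.na(task_id))
    stop("task_id must be a non-empty character scalar", call. = FALSE)
  stage <- match.arg(stage, FEATURE_STAGES)
  if (is.data.frame(embeddings)) embeddings <- as.matrix(embeddings)
  storage.mode(embeddings) <- "double"
  validate_embedding_matrix(embeddings,
                            sprintf("embeddings for task '%s'", task_id))
  structure(list(task_id = task_id, stage = stage, embeddings = embeddings),
            class = "task_embedding_set")
}

#' @export
print.task_embedding_set <- function(x, ...) {
  cat(sprintf("<task_embedding_set> '%s' [%s]: %d samples x %d dims\n",
              x$task_id, x$stage, nrow(x$embeddings), ncol(x$embeddings)))
  invisible(x)
}

#' Create a feature space from task embedding sets
#'
#' A feature space is an ordered collection of K >= 1 tasks whose embeddings
#' share a common dimension d; it is the object the representation measure
#' scores.
#'
#' @param ... `task_embedding_set` objects, or a single list of them.
#' @return An object of class `feature_space`: a named list of tasks with
#'   unique `task_id`s, all of equal embedding dimension.
#' @examples
#' fs <- feature_space(
#'   task_embedding_set("a", matrix(rnorm(8), 2, 4)),
#'   task_embedding_set("b", matrix(rnorm(12), 3, 4)))
#' n_tasks(fs)
#' @export
feature_space <- function(...) {
  tasks <- list(...)
  if (length(tasks) == 1L && is.list(tasks[[1L]]) &&
      !inherits(tasks[[1L]], "task_embedding_set"))
    tasks <- tasks[[1L]]
  if (length(tasks) < 1L)
    stop("a feature space needs at least one task", call. = FALSE)
  ok <- vapply(tasks, inherits, logical(1L), "task_embedding_set")
  if (!all(ok))
    stop("all elements must be task_embedding_set objects", call. = FALSE)
  ids <- vapply(tasks, `[[`, character(1L), "task_id")
  if (anyDuplicated(ids))
    stop("duplicate task_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  dims <- vapply(tasks, function(t) ncol(t$embeddings), integer(1L))
  if (length(unique(dims)) != 1L)
    stop("all tasks must share one embedding dimension; found d in {",
         paste(sort(unique(dims)), collapse = ", "), "}", call. = FALSE)
  names(tasks) <- ids
  structure(tasks, class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> K = %d tasks, d = %d dimensions\n",
              length(x), embedding_dim(x)))
  for (t in x)
    cat(sprintf("  %-20s %-20s m = %d\n", t$task_id,
                paste0("[", t$stage, "]"), nrow(t$embeddings)))
  invisible(x)
}

#' @rdname feature_space
#' @param fs A `feature_space`.
#' @export
n_tasks <- function(fs) length(fs)

#' @rdname feature_space
#' @export
embedding_dim <- function(fs) ncol(fs[[1L]]$embeddings)

#' @rdname feature_space
#' @export
task_ids <- function(fs) unname(vapply(fs, `[[`, character(1L), "task_id"))

tsv_num_fmt <- function(x) sprintf("%.15g", x)

#' Write a feature space to disk
#'
#' Two on-disk layouts are supported. `"tsv"` is a human-inspectable
#' tab-separated table with header `sample_id`, `task_id`, `stage`, then
#' `e1..ed`; numeric values are written with 15 significant digits, so a
#' roundtrip preserves at least 12. `"rds"` is a binary container (one array
#' per task plus its task_id/stage attributes, serialized with base R) whose
#' roundtrip is bitwise exact.
#'
#' @param fs A valid `feature_space`.
#' @param path Output file path.
#' @param format `"tsv"` or `"rds"`.
#' @return Invisibly, `path`.
#' @seealso [read_feature_space()]
#' @export
write_feature_space <- function(fs, path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(fs, "feature_space"))
  if (format == "rds") {
    payload <- list(
      container = "otfrm_feature_space",
      version = 1L,
      tasks = lapply(unclass(fs), function(t)
        list(task_id = t$task_id, stage = t$stage, values = t$embeddings)))
    ok <- tryCatch({saveRDS(payload, path, version = 3L); TRUE},
                   error = function(e) e)
    if (!isTRUE(ok))
      stop("cannot write '", path, "': ", conditionMessage(ok), call. = FALSE)
    return(invisible(path))
  }
  d <- embedding_dim(fs)
  header <- paste(c("sample_id", "task_id", "stage", paste0("e", seq_len(d))),
                  collapse = "\t")
  rows <- unlist(lapply(unclass(fs), function(t) {
    m <- nrow(t$embeddings)
    sid <- rownames(t$embeddings)
    if (is.null(sid)) sid <- sprintf("%s_s%d", t$task_id, seq_len(m))
    vapply(seq_len(m), function(i)
      paste(c(sid[i], t$task_id, t$stage, tsv_num_fmt(t$embeddings[i, ])),
            collapse = "\t"),
      character(1L))
  }), use.names = FALSE)
  ok <- tryCatch({writeLines(c(header, rows), path); TRUE},
                 error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write '", path, "': ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a feature space from disk
#'
#' Parses the tabular or binary layout written by [write_feature_space()].
#' Rows of the tabular format are grouped by `task_id` in order of first
#' appearance; row order within a task is preserved. A missing `stage`
#' column defaults every task to `"unspecified"`. Malformed rows (wrong
#' field count, non-numeric embedding entries, duplicated
#' `(task_id, sample_id)` pairs) raise a parse error naming the offending
#' line.
#'
#' @param path Input file path.
#' @param format `"tsv"` or `"rds"`.
#' @return A `feature_space`.
#' @export
read_feature_space <- function(path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "rds") {
    payload <- readRDS(path)
    if (!is.list(payload) ||
        !identical(payload$container, "otfrm_feature_space"))
      stop("'", path, "' is not a feature-space container", call. = FALSE)
    tasks <- lapply(payload$tasks, function(t)
      task_embedding_set(t$task_id, t$values, t$stage))
    return(feature_space(tasks))
  }
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("parse error in '", path, "': need a header and at least one data row",
         call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  has_stage <- "stage" %in% header
  fixed <- c("sample_id", "task_id", if (has_stage) "stage")
  if (!identical(header[seq_along(fixed)], fixed))
    stop("parse error in '", path, "' line 1: header must start with ",
         paste(fixed, collapse = ", "), call. = FALSE)
  d <- length(header) - length(fixed)
  if (d < 1L)
    stop("parse error in '", path, "' line 1: no embedding columns",
         call. = FALSE)
  n <- length(lines) - 1L
  sample_id <- character(n); task_id <- character(n); stage <- character(n)
  values <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    ln <- i + 1L
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(header))
      stop(sprintf("parse error in '%s' line %d: expected %d fields, found %d",
                   path, ln, length(header), length(f)), call. = FALSE)
    sample_id[i] <- f[[1L]]
    task_id[i] <- f[[2L]]
    stage[i] <- if (has_stage) f[[3L]] else "unspecified"
    v <- suppressWarnings(as.numeric(f[(length(fixed) + 1L):length(f)]))
    if (anyNA(v))
      stop(sprintf("parse error in '%s' line %d: non-numeric embedding value",
                   path, ln), call. = FALSE)
    values[i, ] <- v
  }
  key <- paste(task_id, sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    ln <- which(duplicated(key))[1L] + 1L
    stop(sprintf(
      "parse error in '%s' line %d: duplicate (task_id, sample_id) pair",
      path, ln), call. = FALSE)
  }
  tasks <- lapply(unique(task_id), function(id) {
    sel <- task_id == id
    st <- unique(stage[sel])
    if (length(st) != 1L)
      stop(sprintf("parse error in '%s': task '%s' has conflicting stages",
                   path, id), call. = FALSE)
    emb <- values[sel, , drop = FALSE]
    rownames(emb) <- sample_id[sel]
    task_embedding_set(id, emb, st)
  })
  feature_space(tasks)
}
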