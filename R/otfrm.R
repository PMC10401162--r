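#' Mean pairwise cosine similarity within one task
#'
#' The intra-task similarity of a task with samples `x_1..x_m` is the mean
#' cosine similarity over all m(m-1)/2 unique sample pairs,
#' `2 / (m (m - 1)) * sum_{i<j} cos(x_i, x_j)`; it lies in `[-1, 1]` and
#' needs at least two samples.
#'
#' @param task A `task_embedding_set` or embedding matrix (rows = samples,
#'   no zero rows).
#' @return A scalar in `[-1, 1]`.
#' @examples
#' intra_task_similarity(rbind(c(1, 0), c(1, 0)))  # 1
#' @export
intra_task_similarity <- function(task) {
  X <- as_embedding_rows(task, "task")
  m <- nrow(X)
  if (m < 2L)
    stop("intra-task similarity is undefined for fewer than 2 samples ",
         "(normalization divides by m*(m-1))", call. = FALSE)
  S <- cosine_similarity_cross(X, X)
  (sum(S) - sum(diag(S))) / (m * (m - 1))
}

guard_positive <- function(x, guard, what) {
  if (!is.finite(x) || x <= guard)
    stop(sprintf(
      "ill-conditioned ratio: %s = %.6g is not above the positivity guard %g",
      what, x, guard), call. = FALSE)
  x
}

fs_pairwise_w <- function(fs, config) {
  K <- n_tasks(fs)
  D <- matrix(0, K, K, dimnames = list(task_ids(fs), task_ids(fs)))
  if (K == 1L) return(D)
  for (k in seq_len(K - 1L)) for (l in (k + 1L):K) {
    w <- wasserstein_p(fs[[k]], fs[[l]], config)
    D[k, l] <- w; D[l, k] <- w
  }
  D
}

#' Pairwise task-distance matrix
#'
#' The K x K symmetric matrix of p-Wasserstein distances (cosine ground
#' cost) between every pair of tasks in a feature space; the diagonal is 0.
#'
#' @param fs A `feature_space` with K >= 2 tasks.
#' @param config An [ot_config()].
#' @return A symmetric K x K numeric matrix with task ids as dimnames.
#' @export
pairwise_distance_matrix <- function(fs, config = ot_config()) {
  stopifnot(inherits(fs, "feature_space"))
  if (n_tasks(fs) < 2L)
    stop("pairwise distances need at least 2 tasks", call. = FALSE)
  fs_pairwise_w(fs, config)
}

#' Mean OT similarity of one task to all others
#'
#' `1/(K-1) * sum_{l != k} (1 - W_p(C_k, C_l))`: the average
#' optimal-transport similarity between the inspected task and every other
#' task in the feature space.
#'
#' @param task_id Which task to inspect.
#' @param fs A `feature_space` with K >= 2 tasks.
#' @param config An [ot_config()].
#' @return A scalar in `[-1, 1]`.
#' @export
inter_task_similarity <- function(task_id, fs, config = ot_config()) {
  stopifnot(inherits(fs, "feature_space"))
  if (!task_id %in% task_ids(fs))
    stop("unknown task_id: ", task_id, call. = FALSE)
  if (n_tasks(fs) < 2L)
    stop("inter-task similarity is undefined for a single-task space",
         call. = FALSE)
  others <- setdiff(task_ids(fs), task_id)
  sims <- vapply(others, function(l)
    ot_similarity(fs[[task_id]], fs[[l]], config), numeric(1L))
  mean(sims)
}

#' Representation-measure score of one task
#'
#' The ratio of the task's intra-task similarity to its inter-task
#' similarity. A larger score means a tighter task cluster that is better
#' separated from the other tasks. The denominator must exceed a small
#' positivity guard; a near-zero or negative inter-task similarity raises an
#' error carrying both components.
#'
#' @inheritParams inter_task_similarity
#' @param guard Positivity guard for the denominator (default 1e-8).
#' @return A positive scalar.
#' @seealso [otfrm()] for all tasks at once.
#' @export
otfrm_score <- function(task_id, fs, config = ot_config(), guard = 1e-8) {
  intra <- intra_task_similarity(fs[[task_id]])
  inter <- inter_task_similarity(task_id, fs, config)
  guard_positive(inter, guard,
                 sprintf("inter-task similarity of '%s' (intra = %.6g)",
                         task_id, intra))
  intra / inter
}

#' Score a whole feature space
#'
#' Computes, for every task, the intra-task similarity, the inter-task
#' similarity, and their ratio (the representation-measure score), together
#' with the full pairwise task-distance matrix, all under one transport
#' configuration.
#'
#' @param fs A `feature_space` with K >= 2 tasks sharing one embedding
#'   dimension.
#' @param config An [ot_config()]; the default uses the entropic solver at
#'   `epsilon = 0.1`, order `p = 1`, uniform marginals.
#' @param guard Positivity guard for the score denominator.
#' @return An object of class `otfrm_report` with components `per_task`
#'   (data frame: task_id, stage, m, intra_sim, inter_sim, otfrm),
#'   `pairwise_distance` (K x K matrix of W_p values) and `config`.
#' @examples
#' fs <- generate_feature_space(synthetic_space_spec(K = 3, m = 20, d = 8,
#'                                                   delta = 4, seed = 1))
#' rep <- otfrm(fs)
#' summary(rep)
#' @export
otfrm <- function(fs, config = ot_config(), guard = 1e-8) {
  stopifnot(inherits(fs, "feature_space"))
  K <- n_tasks(fs)
  if (K < 2L)
    stop("the representation measure needs at least 2 tasks", call. = FALSE)
  D <- fs_pairwise_w(fs, config)
  ids <- task_ids(fs)
  intra <- vapply(fs, intra_task_similarity, numeric(1L))
  inter <- vapply(seq_len(K), function(k) mean(1 - D[k, -k]), numeric(1L))
  for (k in seq_len(K))
    guard_positive(inter[k], guard,
                   sprintf("inter-task similarity of '%s' (intra = %.6g)",
                           ids[k], intra[k]))
  per_task <- data.frame(
    task_id = ids,
    stage = vapply(fs, `[[`, character(1L), "stage"),
    m = vapply(fs, function(t) nrow(t$embeddings), integer(1L)),
    intra_sim = unname(intra),
    inter_sim = inter,
    otfrm = unname(intra) / inter,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_task = per_task, pairwise_distance = D, config = config),
            class = "otfrm_report")
}

#' @export
print.otfrm_report <- function(x, digits = 4L, ...) {
  cat(sprintf("<otfrm_report> K = %d tasks, solver = %s (p = %g, eps = %g)\n",
              nrow(x$per_task), x$config$solver, x$config$p,
              x$config$epsilon))
  df <- x$per_task
  df$intra_sim <- signif(df$intra_sim, digits)
  df$inter_sim <- signif(df$inter_sim, digits)
  df$otfrm <- signif(df$otfrm, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.otfrm_report <- function(object, ...) {
  structure(list(report = object), class = "summary.otfrm_report")
}

#' @export
print.summary.otfrm_report <- function(x, ...) {
  r <- x$report
  print(r)
  cat("\nPairwise W_p distances:\n")
  print(round(r$pairwise_distance, 4L))
  cat(sprintf("\nMean score: %.4g (range %.4g - %.4g)\n",
              mean(r$per_task$otfrm), min(r$per_task$otfrm),
              max(r$per_task$otfrm)))
  invisible(x)
}

#' @export
as.data.frame.otfrm_report <- function(x, ...) x$per_task

#' @export
plot.otfrm_report <- function(x, ...) {
  graphics::barplot(x$per_task$otfrm, names.arg = x$per_task$task_id,
                    las = 2L, ylab = "score (intra / inter)", ...)
  invisible(x)
}

#' Stage-wise transferability comparison
#'
#' Given feature-space snapshots of the same tasks at the randomly
#' initialized (RI), pretrained (PT) and fine-tuned (FT) stages, computes
#' each task's representation-measure score at each stage plus the PT/RI
#' and FT/PT ratios, the stage-to-stage transferability gains.
#'
#' @param snapshots Named list with elements `randomly_initialized`,
#'   `pretrained` and `fine_tuned`, each a `feature_space` over the same
#'   task ids.
#' @param config An [ot_config()].
#' @param guard Positivity guard applied to every ratio denominator.
#' @return An object of class `otfrm_stage_comparison`: a data frame with
#'   columns task_id, otfrm_RI, otfrm_PT, otfrm_FT, ratio_PT_over_RI,
#'   ratio_FT_over_PT.
#' @export
stage_comparison <- function(snapshots, config = ot_config(), guard = 1e-8) {
  need <- c("randomly_initialized", "pretrained", "fine_tuned")
  if (!is.list(snapshots) || !all(need %in% names(snapshots)))
    stop("snapshots must be a named list with stages ",
         paste(need, collapse = ", "), call. = FALSE)
  ids <- lapply(snapshots[need], function(fs) sort(task_ids(fs)))
  if (!identical(ids[[1L]], ids[[2L]]) || !identical(ids[[1L]], ids[[3L]]))
    stop("all stages must contain the same task_ids", call. = FALSE)
  scores <- lapply(snapshots[need], function(fs) {
    r <- otfrm(fs, config, guard)$per_task
    stats::setNames(r$otfrm, r$task_id)
  })
  tid <- sort(names(scores[[1L]]))
  ri <- scores$randomly_initialized[tid]
  pt <- scores$pretrained[tid]
  ft <- scores$fine_tuned[tid]
  for (k in seq_along(tid)) {
    guard_positive(ri[k], guard, sprintf("otfrm_RI of '%s'", tid[k]))
    guard_positive(pt[k], guard, sprintf("otfrm_PT of '%s'", tid[k]))
  }
  out <- data.frame(task_id = tid, otfrm_RI = unname(ri),
                    otfrm_PT = unname(pt), otfrm_FT = unname(ft),
                    ratio_PT_over_RI = unname(pt / ri),
                    ratio_FT_over_PT = unname(ft / pt),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_task = out, config = config),
            class = "otfrm_stage_comparison")
}

#' @export
print.otfrm_stage_comparison <- function(x, digits = 4L, ...) {
  cat("<otfrm_stage_comparison> RI -> PT -> FT scores and ratios\n")
  df <- x$per_task
  for (cn in setdiff(names(df), "task_id")) df[[cn]] <- signif(df[[cn]], digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.otfrm_stage_comparison <- function(x, ...) x$per_task

spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(NA_real_)
  sum(dx * dy) / den
}

#' Rank correlation between task distance and adaptation outcome
#'
#' Spearman's rho between pairwise task distances and the corresponding
#' adaptation performance changes, computed from scratch: average-rank
#' transform of both vectors followed by the Pearson product-moment formula
#' on the ranks. A negative rho means adaptation degrades as tasks grow
#' farther apart.
#'
#' @param distances Numeric vector of pairwise W_p values.
#' @param deltas Numeric vector of adaptation performance changes, same
#'   length (>= 3).
#' @return A list `(rho, n)`.
#' @export
adaptability_correlation <- function(distances, deltas) {
  stopifnot(is.numeric(distances), is.numeric(deltas))
  if (length(distances) != length(deltas))
    stop("distances and deltas must have equal length", call. = FALSE)
  n <- length(distances)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(distances) || anyNA(deltas))
    stop("inputs must not contain NA", call. = FALSE)
  if (length(unique(distances)) == 1L || length(unique(deltas)) == 1L)
    stop("correlation undefined for a constant input vector", call. = FALSE)
  list(rho = spearman_rho(distances, deltas), n = n)
}

#' Rank candidate transfer sources for a target task
#'
#' Orders the other tasks of a feature space by ascending W_p distance to
#' the target. Because adaptation performance correlates negatively with
#' task distance, the closest task is the best predicted transfer source.
#' Ties are broken lexicographically by task id.
#'
#' @param target Task id of the transfer target.
#' @param fs A `feature_space` with K >= 2 tasks.
#' @param config An [ot_config()].
#' @return Character vector of the K - 1 other task ids, best source first,
#'   with the distances as the `distances` attribute.
#' @export
rank_transfer_sources <- function(target, fs, config = ot_config()) {
  stopifnot(inherits(fs, "feature_space"))
  if (!target %in% task_ids(fs))
    stop("unknown target task: ", target, call. = FALSE)
  if (n_tasks(fs) < 2L)
    stop("ranking sources needs at least 2 tasks", call. = FALSE)
  others <- setdiff(task_ids(fs), target)
  d <- vapply(others, function(l)
    wasserstein_p(fs[[target]], fs[[l]], config), numeric(1L))
  ord <- order(d, others)
  structure(others[ord], distances = unname(d[ord]))
}
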