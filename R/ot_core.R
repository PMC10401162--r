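#' Optimal-transport configuration
#'
#' Collects every tunable of the transport computations so that the task
#' similarity, pairwise-distance and stage-comparison views of a feature
#' space all use one consistent setting.
#'
#' @param p Wasserstein order, a real >= 1. The ground cost is the cosine
#'   distance raised to `p`; the reported distance is the transport cost to
#'   the power 1/p. Default 1.
#' @param epsilon Entropic regularization strength for the Sinkhorn solver
#'   (> 0). Default 0.1.
#' @param max_iter Maximum Sinkhorn iterations. Default 10000.
#' @param marginal_tol Maximum allowed deviation of the returned plan's
#'   row/column sums from the prescribed marginals. Default 1e-9.
#' @param solver `"sinkhorn"` (entropic, default) or `"exact"`
#'   (transportation simplex; small instances only).
#' @param subsample_cap Tasks with more samples than this are subsampled
#'   (seeded, without replacement) before transport, since the cost matrix
#'   is O(m*n). Default 2000.
#' @param seed Integer seed driving the subsampling stream. Default 1.
#' @return An object of class `ot_config`.
#' @examples
#' ot_config(solver = "exact")
#' @export
ot_config <- function(p = 1, epsilon = 0.1, max_iter = 10000L,
                      marginal_tol = 1e-9,
                      solver = c("sinkhorn", "exact"),
                      subsample_cap = 2000L, seed = 1L) {
  solver <- match.arg(solver)
  stopifnot(is.numeric(p), length(p) == 1L, p >= 1,
            is.numeric(max_iter), max_iter >= 1,
            is.numeric(marginal_tol), marginal_tol > 0,
            is.numeric(subsample_cap), subsample_cap >= 2)
  if (solver == "sinkhorn" && (!is.numeric(epsilon) || epsilon <= 0))
    stop("epsilon must be > 0 for the sinkhorn solver", call. = FALSE)
  structure(list(p = as.numeric(p), epsilon = as.numeric(epsilon),
                 max_iter = as.integer(max_iter),
                 marginal_tol = as.numeric(marginal_tol), solver = solver,
                 subsample_cap = as.integer(subsample_cap),
                 seed = as.integer(seed)),
            class = "ot_config")
}

#' @export
print.ot_config <- function(x, ...) {
  cat(sprintf(
    "<ot_config> solver = %s, p = %g, epsilon = %g, max_iter = %d,\n",
    x$solver, x$p, x$epsilon, x$max_iter))
  cat(sprintf("            marginal_tol = %g, subsample_cap = %d, seed = %d\n",
              x$marginal_tol, x$subsample_cap, x$seed))
  invisible(x)
}

as_embedding_rows <- function(X, what = "X") {
  if (inherits(X, "task_embedding_set")) X <- X$embeddings
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, nrow = 1L)
  if (is.data.frame(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  validate_embedding_matrix(X, what)
  X
}

row_norms <- function(X) sqrt(rowSums(X * X))

check_nonzero_rows <- function(X, what) {
  nrm <- row_norms(X)
  if (any(nrm < 1e-12))
    stop("zero-norm vector in ", what,
         " (row ", which(nrm < 1e-12)[1L], "): cosine distance undefined",
         call. = FALSE)
  nrm
}

cosine_similarity_cross <- function(X, Y) {
  nx <- check_nonzero_rows(X, "X")
  ny <- check_nonzero_rows(Y, "Y")
  S <- tcrossprod(X / nx, Y / ny)
  pmin(pmax(S, -1), 1)
}

#' Cosine-distance cost matrix
#'
#' Entry (i, j) is `(1 - cos(x_i, y_j))^p`, the ground cost used by all
#' transport computations; entries lie in `[0, 2^p]`.
#'
#' @param X,Y Numeric matrices (or `task_embedding_set`s) with a common
#'   column dimension; rows are samples. Zero-norm rows are rejected.
#' @param p Cost exponent (Wasserstein order), >= 1.
#' @return An m x n matrix of costs.
#' @examples
#' cosine_distance_matrix(rbind(c(1, 0)), rbind(c(0, 1)))  # 1
#' @export
cosine_distance_matrix <- function(X, Y, p = 1) {
  X <- as_embedding_rows(X, "X"); Y <- as_embedding_rows(Y, "Y")
  if (ncol(X) != ncol(Y))
    stop("X and Y must share the embedding dimension", call. = FALSE)
  stopifnot(is.numeric(p), length(p) == 1L, p >= 1)
  D <- 1 - cosine_similarity_cross(X, Y)
  if (p != 1) D <- D^p
  D
}

check_weights <- function(w, len, what) {
  if (is.null(w)) return(rep(1 / len, len))
  stopifnot(is.numeric(w), length(w) == len)
  if (any(w < 0) || !all(is.finite(w)))
    stop(what, " must be nonnegative and finite", call. = FALSE)
  s <- sum(w)
  if (abs(s - 1) > 1e-8)
    stop(what, " must sum to 1 (probability simplex)", call. = FALSE)
  w / s
}

logsumexp_rows <- function(M) {
  # ties.method = "first" keeps this free of RNG side effects
  idx <- max.col(M, ties.method = "first")
  mx <- M[cbind(seq_len(nrow(M)), idx)]
  mx + log(rowSums(exp(M - mx)))
}

#' Entropic optimal transport via log-domain Sinkhorn
#'
#' Solves `min_pi <C, pi> - epsilon * H(pi)` over couplings with marginals
#' `a` and `b` (`H` the entropy), using log-domain iterations that remain
#' stable at small `epsilon`. The returned cost is the sharp transport cost
#' `sum(C * pi)` under the entropic plan, with the entropy term excluded, so
#' the cost converges to the unregularized optimum as `epsilon` shrinks.
#'
#' @param C Cost matrix (m x n), finite entries.
#' @param a,b Marginal weight vectors in the probability simplex; `NULL`
#'   (default) means uniform.
#' @param config An [ot_config()]; `epsilon`, `max_iter` and `marginal_tol`
#'   are honoured.
#' @return A list of class `coupling_plan`: `plan` (m x n, nonnegative, row
#'   sums `a`, column sums `b` within `marginal_tol`), `cost`, `a`, `b`,
#'   `iterations`, `converged`.
#' @details At small `epsilon` the iteration is warm-started through an
#'   epsilon-scaling schedule (anneal the regularization downward, reusing
#'   the dual potentials), which cuts the iteration count by orders of
#'   magnitude without changing the solution.
#' @examples
#' sp <- sinkhorn_plan(matrix(c(0, 1, 1, 0), 2, 2))
#' sp$cost
#' @export
sinkhorn_plan <- function(C, a = NULL, b = NULL, config = ot_config()) {
  stopifnot(is.matrix(C), is.numeric(C), all(is.finite(C)))
  m <- nrow(C); n <- ncol(C)
  a <- check_weights(a, m, "a"); b <- check_weights(b, n, "b")
  loga <- log(a); logb <- log(b)
  tol <- config$marginal_tol
  tC <- t(C)
  run <- function(eps, f, g, maxit, tol) {
    err <- Inf; it <- 0L; P <- NULL
    while (it < maxit) {
      it <- it + 1L
      f <- eps * (loga - logsumexp_rows(sweep(-C, 2L, g, "+") / eps))
      g <- eps * (logb - logsumexp_rows(sweep(-tC, 2L, f, "+") / eps))
      # after the g-update column sums are exact; row residual drives stopping
      P <- exp(sweep(sweep(-C, 1L, f, "+"), 2L, g, "+") / eps)
      err <- max(abs(rowSums(P) - a))
      if (err <= tol) break
    }
    list(f = f, g = g, P = P, err = err, it = it)
  }
  f <- numeric(m); g <- numeric(n)
  it <- 0L
  eps <- config$epsilon
  if (eps < 0.05) {                # anneal from a mild regularization
    e <- 1
    while (e > 4 * eps) {
      res <- run(e, f, g, min(500L, config$max_iter), max(tol, 1e-6))
      f <- res$f; g <- res$g; it <- it + res$it
      e <- e / 4
    }
  }
  res <- run(eps, f, g, max(config$max_iter - it, 1L), tol)
  it <- it + res$it
  P <- res$P; err <- res$err
  converged <- err <= tol
  if (!converged) {
    if (err > 10 * tol)
      stop(sprintf(
        "sinkhorn did not converge in %d iterations (marginal residual %.3e)",
        config$max_iter, err), call. = FALSE)
    warning(sprintf(
      "sinkhorn stopped at max_iter = %d with marginal residual %.3e",
      config$max_iter, err), call. = FALSE)
  }
  structure(list(plan = P, cost = sum(C * P), a = a, b = b,
                 iterations = it, converged = converged),
            class = "coupling_plan")
}

#' @export
print.coupling_plan <- function(x, ...) {
  cat(sprintf("<coupling_plan> %d x %d, cost = %.6g, %d iterations%s\n",
              nrow(x$plan), ncol(x$plan), x$cost, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# Northwest-corner initial basic feasible solution: exactly m + n - 1 basic
# cells (degenerate zero-value cells included when a row and column close
# simultaneously).
nw_corner_basis <- function(a, b) {
  m <- length(a); n <- length(b)
  arem <- a; brem <- b
  nb <- m + n - 1L
  bi <- integer(nb); bj <- integer(nb); bv <- numeric(nb)
  i <- 1L; j <- 1L
  for (k in seq_len(nb)) {
    v <- min(arem[i], brem[j])
    bi[k] <- i; bj[k] <- j; bv[k] <- v
    arem[i] <- arem[i] - v; brem[j] <- brem[j] - v
    if (i == m && j == n) break
    if (arem[i] <= brem[j] && i < m) i <- i + 1L else j <- j + 1L
  }
  list(i = bi, j = bj, v = bv)
}

# Duals u, v with u[1] = 0 solved over the basis spanning tree.
modi_duals <- function(basis, C, m, n) {
  u <- rep(NA_real_, m); v <- rep(NA_real_, n)
  u[1L] <- 0
  repeat {
    changed <- FALSE
    for (k in seq_along(basis$i)) {
      i <- basis$i[k]; j <- basis$j[k]
      if (!is.na(u[i]) && is.na(v[j])) { v[j] <- C[i, j] - u[i]; changed <- TRUE }
      else if (is.na(u[i]) && !is.na(v[j])) { u[i] <- C[i, j] - v[j]; changed <- TRUE }
    }
    if (!anyNA(u) && !anyNA(v)) break
    if (!changed) stop("degenerate basis: disconnected spanning tree",
                       call. = FALSE)
  }
  list(u = u, v = v)
}

# Unique alternating cycle created by adding cell (i0, j0) to the basis
# tree: path from row node i0 to column node j0 through basic cells.
modi_cycle <- function(basis, i0, j0, m, n) {
  # nodes: rows 1..m, columns m+1..m+n; edges are basic cells
  adj <- vector("list", m + n)
  for (k in seq_along(basis$i)) {
    r <- basis$i[k]; c <- m + basis$j[k]
    adj[[r]] <- c(adj[[r]], k); adj[[c]] <- c(adj[[c]], k)
  }
  target <- m + j0
  parent_edge <- integer(m + n); parent_node <- integer(m + n)
  seen <- logical(m + n)
  queue <- i0; seen[i0] <- TRUE
  while (length(queue)) {
    node <- queue[[1L]]; queue <- queue[-1L]
    if (node == target) break
    for (k in adj[[node]]) {
      other <- if (node <= m) m + basis$j[k] else basis$i[k]
      if (!seen[other]) {
        seen[other] <- TRUE
        parent_edge[other] <- k; parent_node[other] <- node
        queue <- c(queue, other)
      }
    }
  }
  if (!seen[target]) stop("basis tree disconnected", call. = FALSE)
  edges <- integer(0L)
  node <- target
  while (node != i0) {
    edges <- c(edges, parent_edge[node])
    node <- parent_node[node]
  }
  rev(edges)
}

#' Exact Kantorovich optimal transport (small instances)
#'
#' Solves the unregularized linear program `min_pi sum(C * pi)` subject to
#' the marginal constraints, with a transportation-simplex solver
#' (northwest-corner start, MODI pivoting). Intended as the exact reference
#' for small problems; instances with `m * n > 10000` are refused.
#'
#' @inheritParams sinkhorn_plan
#' @param return_plan Also return the optimal coupling.
#' @return The minimal transport cost, or (with `return_plan = TRUE`) a list
#'   `(cost, plan)`.
#' @examples
#' exact_ot(matrix(c(1, 0, 0, 1), 2, 2))  # 0: anti-diagonal permutation
#' @export
exact_ot <- function(C, a = NULL, b = NULL, return_plan = FALSE) {
  stopifnot(is.matrix(C), is.numeric(C), all(is.finite(C)))
  m <- nrow(C); n <- ncol(C)
  if (m * n > 10000)
    stop("instance too large for the exact solver (m*n = ", m * n,
         " > 10000); use the sinkhorn solver", call. = FALSE)
  a <- check_weights(a, m, "a"); b <- check_weights(b, n, "b")
  if (m == 1L || n == 1L) {
    plan <- outer(a, b)
    cost <- sum(C * plan)
    return(if (return_plan) list(cost = cost, plan = plan) else cost)
  }
  basis <- nw_corner_basis(a, b)
  tol <- 1e-12 * max(1, max(abs(C)))
  max_pivots <- 200L * (m + n)
  for (pivot in seq_len(max_pivots)) {
    duals <- modi_duals(basis, C, m, n)
    red <- C - outer(duals$u, duals$v, "+")
    red[cbind(basis$i, basis$j)] <- 0
    best <- which.min(red)
    if (red[best] >= -tol) break
    i0 <- row(C)[best]; j0 <- col(C)[best]
    cyc <- modi_cycle(basis, i0, j0, m, n)
    # orient the path: edges alternate -,+,-,... after the entering +edge
    sign_minus <- seq_along(cyc) %% 2L == 1L
    minus_edges <- cyc[sign_minus]
    theta <- min(basis$v[minus_edges])
    leave <- minus_edges[which.min(basis$v[minus_edges])]
    basis$v[cyc] <- basis$v[cyc] + ifelse(sign_minus, -theta, theta)
    basis$i[leave] <- i0; basis$j[leave] <- j0; basis$v[leave] <- theta
    if (pivot == max_pivots)
      stop("transportation simplex failed to converge", call. = FALSE)
  }
  plan <- matrix(0, m, n)
  plan[cbind(basis$i, basis$j)] <- basis$v
  cost <- sum(C * plan)
  if (return_plan) list(cost = cost, plan = plan) else cost
}

maybe_subsample <- function(X, config, stream) {
  m <- nrow(X)
  if (m <= config$subsample_cap) return(X)
  idx <- with_stream_seed(config$seed, stream,
                          sample.int(m, config$subsample_cap))
  X[sort(idx), , drop = FALSE]
}

transport_cost <- function(C, a, b, config) {
  if (config$solver == "exact") exact_ot(C, a, b)
  else sinkhorn_plan(C, a, b, config)$cost
}

#' p-Wasserstein distance between two embedding sets
#'
#' Cosine-distance ground cost raised to `config$p`, transported between the
#' two empirical measures (uniform weights unless `a`/`b` given), and the
#' optimal cost taken to the power `1/p`.
#'
#' @param A,B Embedding matrices (rows = samples) or `task_embedding_set`s
#'   of equal dimension.
#' @param config An [ot_config()].
#' @param a,b Optional marginal weights (simplex vectors).
#' @return A nonnegative scalar in `[0, 2]`.
#' @examples
#' wasserstein_p(rbind(c(1, 0)), rbind(c(0, 1)), ot_config(solver = "exact"))
#' @export
wasserstein_p <- function(A, B, config = ot_config(), a = NULL, b = NULL) {
  A <- as_embedding_rows(A, "A"); B <- as_embedding_rows(B, "B")
  A <- maybe_subsample(A, config, "subsample_A")
  B <- maybe_subsample(B, config, "subsample_B")
  C <- cosine_distance_matrix(A, B, config$p)
  cost <- transport_cost(C, a, b, config)
  max(cost, 0)^(1 / config$p)
}

#' Optimal-transport similarity of two embedding sets
#'
#' Defined as `1 - W_p(A, B)` with the cosine-distance ground cost, so that
#' identical sets score 1 and orthogonal singletons score 0; values lie in
#' `[-1, 1]`.
#'
#' @inheritParams wasserstein_p
#' @return A scalar in `[-1, 1]`.
#' @examples
#' ot_similarity(rbind(c(1, 0)), rbind(c(1, 0)), ot_config(solver = "exact"))
#' @export
ot_similarity <- function(A, B, config = ot_config(), a = NULL, b = NULL) {
  1 - wasserstein_p(A, B, config, a, b)
}
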