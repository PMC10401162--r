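# Independent oracles used across the suite; each is deliberately naive and
# shares no code with the implementation it checks.

# All permutations of 1..n (n <= 7), recursively.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (k in seq_len(n)) {
    q <- append(p, n, after = k - 1L)
    out[[length(out) + 1L]] <- q
  }
  out
}

# Exact OT for a square cost matrix with uniform marginals: by Birkhoff's
# theorem the optimum is attained at a permutation coupling, so enumerate.
perm_ot <- function(C) {
  n <- nrow(C)
  stopifnot(n == ncol(C), n <= 7L)
  min(vapply(all_perms(n), function(p)
    mean(C[cbind(seq_len(n), p)]), numeric(1L)))
}

# Average ranks by counting, no call to rank().
counting_ranks <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1L))
}

# Spearman rho: counting ranks then textbook product-moment quotient.
brute_spearman <- function(x, y) {
  r <- counting_ranks(x); s <- counting_ranks(y)
  num <- sum((r - mean(r)) * (s - mean(s)))
  num / sqrt(sum((r - mean(r))^2) * sum((s - mean(s))^2))
}

# Confusion counts and metrics recomputed by explicit looping.
brute_binary_metrics <- function(truth, pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] && pred[i]) tp <- tp + 1L
    else if (!truth[i] && !pred[i]) tn <- tn + 1L
    else if (!truth[i] && pred[i]) fp <- fp + 1L
    else fn <- fn + 1L
  }
  den <- function(x) if (x == 0) NA_real_ else x
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       precision = tp / den(tp + fp),
       recall = tp / den(tp + fn),
       mcc = {
         d <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
         if (d == 0) NA_real_ else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(d)
       })
}

# Run code under a named generator substream (internal package mechanism).
with_stream_seed_test <- function(seed, stream, expr)
  otfrm:::with_stream_seed(seed, stream, expr)

# Random embedding matrix with no zero rows.
rand_embeddings <- function(m, d) {
  X <- matrix(stats::rnorm(m * d), m, d)
  X[abs(rowSums(X)) < 1e-9, 1L] <- 1
  X
}

# Random valid feature space.
rand_feature_space <- function(K = 3L, d = 4L, m_range = 2:6,
                               stages = "unspecified") {
  feature_space(lapply(seq_len(K), function(k)
    task_embedding_set(sprintf("t%02d", k),
                       rand_embeddings(sample(m_range, 1L), d),
                       sample(stages, 1L))))
}

# Random valid annotated sequence (arbitrary spans, non-overlapping per kind).
rand_annotated_sequence <- function(id = "s1", L = sample(20:60, 1L)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  sq <- paste(sample(aa, L, replace = TRUE), collapse = "")
  ents <- do.call(rbind, lapply(c("motif", "domain", "region"), function(kd) {
    n_sp <- sample(0:3, 1L)
    if (n_sp == 0L) return(NULL)
    free <- rep(TRUE, L)
    rows <- list()
    for (i in seq_len(n_sp)) {
      len <- sample(1:8, 1L)
      ok <- which(vapply(seq_len(max(L - len + 1L, 0L)), function(s)
        all(free[s:(s + len - 1L)]), logical(1L)))
      if (!length(ok)) next
      s <- if (length(ok) == 1L) ok else sample(ok, 1L)
      free[s:(s + len - 1L)] <- FALSE
      rows[[length(rows) + 1L]] <-
        data.frame(start = s, end = s + len - 1L,
                   category = sprintf("Cat%d", sample(5L, 1L)), kind = kd,
                   stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }))
  annotated_sequence(sq, ents, sequence_id = id)
}
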