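AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Specification of a synthetic Gaussian-cluster feature space
#'
#' Describes K isotropic Gaussian task clusters in d dimensions. `sigma` is
#' the within-task spread measured as the RMS distance of a sample from its
#' cluster mean (per-coordinate standard deviation `sigma / sqrt(d)`), and
#' `delta` is the pairwise distance between cluster means in units of
#' `sigma` — so `delta = 0` is a fully mixed space and growing `delta`
#' progressively separates the tasks, emulating the feature-space picture
#' of an embedding model before pretraining, after pretraining and after
#' fine-tuning.
#'
#' @param K Number of tasks (>= 1).
#' @param m Samples per task (>= 2).
#' @param d Embedding dimension (>= 2).
#' @param delta Between-task mean separation in units of `sigma` (>= 0).
#' @param sigma Within-task RMS spread (> 0). Default 1.
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the spec including the seed.
#' @return An object of class `synthetic_space_spec`.
#' @export
synthetic_space_spec <- function(K = 6L, m = 50L, d = 16L, delta = 1,
                                 sigma = 1, seed = 1L) {
  stopifnot(is.numeric(K), K >= 1, is.numeric(m), m >= 2,
            is.numeric(d), d >= 2, is.numeric(delta), delta >= 0,
            is.numeric(sigma), sigma > 0, is.numeric(seed))
  structure(list(K = as.integer(K), m = as.integer(m), d = as.integer(d),
                 delta = as.numeric(delta), sigma = as.numeric(sigma),
                 seed = as.integer(seed)),
            class = "synthetic_space_spec")
}

#' @export
print.synthetic_space_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_space_spec> K = %d, m = %d, d = %d, delta = %g, sigma = %g, seed = %d\n",
    x$K, x$m, x$d, x$delta, x$sigma, x$seed))
  invisible(x)
}

# Cluster means: a common center of norm sigma (feature spaces of trained
# and untrained networks alike are not centered at the origin, so
# within-task cosine similarity stays well defined even in the fully mixed
# delta = 0 space) plus unit-norm separation directions, orthonormalized
# via Gram-Schmidt when K <= d so that scaling by delta*sigma/sqrt(2)
# gives an exact pairwise mean distance of delta*sigma (a common offset
# leaves pairwise distances untouched); plain unit-norm projections
# otherwise (approximate separation).
cluster_means <- function(spec) {
  dirs <- with_stream_seed(spec$seed, "means",
                           matrix(stats::rnorm(spec$d * spec$K), spec$d))
  ctr <- with_stream_seed(spec$seed, "center", stats::rnorm(spec$d))
  ctr <- ctr / sqrt(sum(ctr^2)) * spec$sigma
  if (spec$K + 1L <= spec$d) {
    # separation directions orthogonal to the center (and to each other):
    # cross-task mean inner products stay at ||center||^2 > 0, so tasks
    # separate without ever becoming anti-aligned
    Q <- qr.Q(qr(cbind(ctr, dirs)))[, 1L + seq_len(spec$K), drop = FALSE]
  } else {
    Q <- sweep(dirs, 2L, sqrt(colSums(dirs^2)), "/")
  }
  sweep(t(Q) * (spec$delta * spec$sigma / sqrt(2)), 2L, ctr, "+")
}

#' Generate a synthetic feature space
#'
#' Draws `m` samples per task from K isotropic Gaussian clusters whose
#' unit-norm mean directions are held fixed for a given seed and scaled so
#' cluster means sit at pairwise distance `delta * sigma` (exact when
#' `K <= d`). Samples with norm below 1e-9 are resampled so cosine
#' similarity is always defined. Deterministic given the spec.
#'
#' @param spec A [synthetic_space_spec()].
#' @param stage Stage label stamped on every task.
#' @param stream Substream name; snapshots generated under different stream
#'   names share mean directions but draw independent within-cluster noise.
#' @return A `feature_space` with tasks `task1..taskK`.
#' @examples
#' fs <- generate_feature_space(synthetic_space_spec(K = 3, m = 10, d = 8,
#'                                                   delta = 2, seed = 7))
#' @export
generate_feature_space <- function(spec, stage = "unspecified",
                                   stream = "feature_space") {
  stopifnot(inherits(spec, "synthetic_space_spec"))
  mu <- cluster_means(spec)
  sd_coord <- spec$sigma / sqrt(spec$d)
  tasks <- with_stream_seed(spec$seed, paste0(stream, "_samples"), {
    lapply(seq_len(spec$K), function(k) {
      X <- matrix(stats::rnorm(spec$m * spec$d, sd = sd_coord), spec$m)
      X <- sweep(X, 2L, mu[k, ], "+")
      for (tries in 1:100) {
        bad <- row_norms(X) < 1e-9
        if (!any(bad)) break
        X[bad, ] <- matrix(stats::rnorm(sum(bad) * spec$d, sd = sd_coord),
                           ncol = spec$d) + rep(mu[k, ], each = sum(bad))
      }
      task_embedding_set(sprintf("task%d", k), X, stage)
    })
  })
  feature_space(tasks)
}

#' Generate stage snapshots with increasing task separation
#'
#' Produces three feature spaces over the same task ids — the randomly
#' initialized, pretrained and fine-tuned stages — that share cluster mean
#' directions but use increasing separations `deltas`, so the tasks
#' progressively pull apart exactly as the stage-wise transferability
#' analysis assumes.
#'
#' @param spec A [synthetic_space_spec()]; its `delta` is ignored in favour
#'   of `deltas`.
#' @param deltas Numeric vector of three non-decreasing separations
#'   (RI <= PT <= FT). Default `c(0, 1, 4)`.
#' @return Named list of three `feature_space` objects
#'   (`randomly_initialized`, `pretrained`, `fine_tuned`).
#' @seealso [stage_comparison()]
#' @export
generate_stage_snapshots <- function(spec, deltas = c(0, 1, 4)) {
  stopifnot(inherits(spec, "synthetic_space_spec"))
  if (length(deltas) != 3L || any(deltas < 0) || is.unsorted(deltas))
    stop("deltas must be three non-decreasing separations (RI <= PT <= FT)",
         call. = FALSE)
  stages <- c("randomly_initialized", "pretrained", "fine_tuned")
  out <- lapply(seq_along(stages), function(s) {
    sp <- spec; sp$delta <- deltas[[s]]
    generate_feature_space(sp, stage = stages[[s]],
                           stream = paste0("stage_", stages[[s]]))
  })
  stats::setNames(out, stages)
}

place_spans <- function(L, lengths) {
  occupied <- rep(FALSE, L)
  out <- matrix(integer(0), ncol = 2L)
  for (len in lengths) {
    placed <- FALSE
    for (trylen in seq(len, 1L)) {
      ok <- vapply(seq_len(L - trylen + 1L), function(s)
        !any(occupied[s:(s + trylen - 1L)]), logical(1L))
      if (any(ok)) {
        pos <- which(ok)   # sample() treats a length-1 vector as 1:n
        s <- if (length(pos) == 1L) pos else sample(pos, 1L)
        occupied[s:(s + trylen - 1L)] <- TRUE
        out <- rbind(out, c(s, s + trylen - 1L))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("generation error: cannot pack the requested spans into a ",
           "sequence of length ", L, call. = FALSE)
  }
  out
}

#' Generate a long-tailed annotated corpus
#'
#' Random amino-acid sequences carrying motif/domain/region spans whose
#' category frequencies follow a Zipf law (`P(rank r) ~ r^-zipf_exponent`),
#' emulating the heavy long tail of real annotation category counts. Spans
#' are valid and non-overlapping within each kind; output is deterministic
#' given the seed.
#'
#' @param n_sequences Number of sequences.
#' @param length_range Two-element integer range of sequence lengths.
#' @param zipf_exponent Zipf tail exponent, > 1. Default 2.
#' @param n_categories Categories per annotation kind.
#' @param seed Integer seed.
#' @param max_spans_per_kind Upper bound on spans of one kind per sequence
#'   (drawn uniformly from 0..max). Default 3.
#' @return A list: `sequences` (list of [annotated_sequence()]) and
#'   `counts` (named vector of category occurrence counts).
#' @export
generate_annotated_corpus <- function(n_sequences, length_range = c(50L, 200L),
                                      zipf_exponent = 2, n_categories = 20L,
                                      seed = 1L, max_spans_per_kind = 3L) {
  stopifnot(n_sequences >= 1, length(length_range) == 2L,
            length_range[1L] >= 5, length_range[2L] >= length_range[1L],
            n_categories >= 1, max_spans_per_kind >= 0)
  if (zipf_exponent <= 1)
    stop("zipf_exponent must be > 1", call. = FALSE)
  probs <- seq_len(n_categories)^(-zipf_exponent)
  probs <- probs / sum(probs)
  kind_label <- c(motif = "Motif", domain = "Domain", region = "Region")
  sequences <- with_stream_seed(seed, "annotated_corpus", {
    lapply(seq_len(n_sequences), function(i) {
      L <- sample(length_range[1L]:length_range[2L], 1L)
      sq <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
      ents <- do.call(rbind, lapply(ENTITY_KINDS, function(kd) {
        n_sp <- sample(0:max_spans_per_kind, 1L)
        if (n_sp == 0L) return(NULL)
        lens <- sample(1:10, n_sp, replace = TRUE)
        pos <- place_spans(L, lens)
        cats <- sample(n_categories, n_sp, replace = TRUE, prob = probs)
        data.frame(start = pos[, 1L], end = pos[, 2L],
                   category = sprintf("%s%d", kind_label[[kd]], cats),
                   kind = kd, stringsAsFactors = FALSE)
      }))
      annotated_sequence(sq, ents, sequence_id = sprintf("seq%04d", i))
    })
  })
  all_cats <- unlist(lapply(sequences, function(s) s$entities$category))
  counts <- if (length(all_cats)) table(all_cats) else table(character(0))
  list(sequences = sequences,
       counts = stats::setNames(as.numeric(counts), names(counts)))
}

#' Simulate adaptation outcomes from task distances
#'
#' Emulates the contract that adaptation performance declines as tasks grow
#' farther apart: each outcome is `slope * distance + N(0, noise_sd^2)`.
#' Deterministic given the seed.
#'
#' @param distances Numeric vector of pairwise task distances.
#' @param slope Linear trend; the distance-adaptability analysis expects a
#'   negative slope. Default -1.
#' @param noise_sd Outcome noise standard deviation (>= 0). Default 0.1.
#' @param seed Integer seed.
#' @return Numeric vector of adaptation performance changes, same length.
#' @seealso [adaptability_correlation()]
#' @export
simulate_adaptation_outcomes <- function(distances, slope = -1,
                                         noise_sd = 0.1, seed = 1L) {
  stopifnot(is.numeric(distances), is.numeric(slope),
            is.numeric(noise_sd), noise_sd >= 0)
  with_stream_seed(seed, "adaptation",
                   slope * distances +
                     stats::rnorm(length(distances), sd = noise_sd))
}
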