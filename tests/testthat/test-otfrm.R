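exact_cfg <- ot_config(solver = "exact")

test_that("intra-task similarity enumerates unique pairs", {
  expect_equal(intra_task_similarity(rbind(c(1, 0), c(2, 0), c(3, 0))), 1)
  expect_equal(intra_task_similarity(rbind(c(1, 0), c(0, 1))), 0)
  X <- rbind(c(1, 0), c(0, 1), c(1, 1) / sqrt(2))
  expect_equal(intra_task_similarity(X), (0 + sqrt(2) / 2 + sqrt(2) / 2) / 3,
               tolerance = 1e-12)
  expect_error(intra_task_similarity(rbind(c(1, 0))), "fewer than 2")
})

three_singletons <- feature_space(
  task_embedding_set("t1", rbind(c(1, 0))),
  task_embedding_set("t2", rbind(c(0, 1))),
  task_embedding_set("t3", rbind(c(1, 1) / sqrt(2))))

test_that("inter-task similarity averages OT similarities over other tasks", {
  fs2 <- feature_space(task_embedding_set("a", rbind(c(1, 0), c(0, 1))),
                       task_embedding_set("b", rbind(c(1, 0), c(0, 1))))
  expect_equal(inter_task_similarity("a", fs2, exact_cfg), 1)

  fs_orth <- feature_space(task_embedding_set("a", rbind(c(1, 0))),
                           task_embedding_set("b", rbind(c(0, 1))))
  expect_equal(inter_task_similarity("a", fs_orth, exact_cfg), 0)

  expect_equal(inter_task_similarity("t3", three_singletons, exact_cfg),
               sqrt(2) / 2, tolerance = 1e-9)
  expect_error(inter_task_similarity(
    "a", feature_space(task_embedding_set("a", matrix(1, 2, 2))), exact_cfg),
    "single-task")
  expect_error(inter_task_similarity("zz", fs2, exact_cfg), "unknown task")
})

test_that("the score is the intra/inter ratio with a guarded denominator", {
  # all tasks identical: intra = inter = 1, score 1
  X <- rbind(c(1, 1), c(2, 2))
  fs_same <- feature_space(task_embedding_set("a", X),
                           task_embedding_set("b", X))
  expect_equal(otfrm_score("a", fs_same, exact_cfg), 1)

  # task3 duplicated on the diagonal direction: intra 1, inter sqrt(2)/2
  fs3 <- feature_space(
    task_embedding_set("t1", rbind(c(1, 0), c(1, 0))),
    task_embedding_set("t2", rbind(c(0, 1), c(0, 1))),
    task_embedding_set("t3", rbind(c(1, 1) / sqrt(2), c(1, 1) / sqrt(2))))
  expect_equal(otfrm_score("t3", fs3, exact_cfg), sqrt(2), tolerance = 1e-9)

  # near-orthogonal space drives inter to ~0: the ratio must error, not blow up
  fs_orth <- feature_space(
    task_embedding_set("a", rbind(c(1, 0), c(1, 0))),
    task_embedding_set("b", rbind(c(0, 1), c(0, 1))))
  expect_error(otfrm_score("a", fs_orth, exact_cfg), "ill-conditioned ratio")
})

test_that("otfrm() reports all per-task components consistently", {
  set.seed(21)
  fs <- generate_feature_space(synthetic_space_spec(K = 4, m = 12, d = 6,
                                                    delta = 3, seed = 21))
  rep <- otfrm(fs, exact_cfg)
  expect_s3_class(rep, "otfrm_report")
  expect_equal(rep$per_task$task_id, unname(task_ids(fs)))
  # components recomputed through the standalone operations
  for (k in seq_len(4)) {
    id <- rep$per_task$task_id[k]
    expect_equal(rep$per_task$intra_sim[k], intra_task_similarity(fs[[id]]),
                 tolerance = 1e-12)
    expect_equal(rep$per_task$inter_sim[k],
                 inter_task_similarity(id, fs, exact_cfg), tolerance = 1e-9)
  }
  expect_equal(rep$per_task$otfrm,
               rep$per_task$intra_sim / rep$per_task$inter_sim)
  expect_true(all(abs(rep$per_task$intra_sim) <= 1))
  expect_true(all(abs(rep$per_task$inter_sim) <= 1))
  df <- as.data.frame(rep)
  expect_named(df, c("task_id", "stage", "m", "intra_sim", "inter_sim",
                     "otfrm"))
})

test_that("pairwise distances are symmetric, zero-diagonal, oracle-exact", {
  fs2 <- feature_space(task_embedding_set("a", rbind(c(1, 0), c(0, 1))),
                       task_embedding_set("b", rbind(c(1, 0), c(0, 1))))
  expect_equal(pairwise_distance_matrix(fs2, exact_cfg),
               matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))

  fs_orth <- feature_space(task_embedding_set("a", rbind(c(1, 0))),
                           task_embedding_set("b", rbind(c(0, 1))))
  D <- pairwise_distance_matrix(fs_orth, exact_cfg)
  expect_equal(D["a", "b"], 1)

  set.seed(3)
  fs <- rand_feature_space(K = 3L, d = 4L, m_range = 6L)
  D <- pairwise_distance_matrix(fs, exact_cfg)
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 3), task_ids(fs)), tolerance = 1e-12)
  for (k in 1:2) for (l in (k + 1):3) {
    C <- cosine_distance_matrix(fs[[k]]$embeddings, fs[[l]]$embeddings)
    expect_equal(D[k, l], exact_ot(C), tolerance = 1e-12)
  }
})

test_that("stage comparison computes per-stage scores and ratios", {
  spec <- synthetic_space_spec(K = 3, m = 15, d = 8, seed = 5)
  fs <- generate_feature_space(spec)
  same <- list(randomly_initialized = fs, pretrained = fs, fine_tuned = fs)
  sc <- stage_comparison(same, exact_cfg)
  expect_equal(sc$per_task$ratio_PT_over_RI, rep(1, 3))
  expect_equal(sc$per_task$ratio_FT_over_PT, rep(1, 3))

  snaps <- generate_stage_snapshots(spec, c(0, 1, 4))
  sc <- stage_comparison(snaps)
  expect_true(all(sc$per_task$otfrm_RI <= sc$per_task$otfrm_PT))
  expect_true(all(sc$per_task$otfrm_PT <= sc$per_task$otfrm_FT))

  expect_error(stage_comparison(same[c("randomly_initialized", "pretrained")]),
               "named list with stages")
  # mismatched task sets across stages
  other <- generate_feature_space(synthetic_space_spec(K = 4, m = 15, d = 8,
                                                       seed = 5))
  expect_error(stage_comparison(list(randomly_initialized = fs,
                                     pretrained = fs, fine_tuned = other)),
               "same task_ids")
})

test_that("the in-house rank correlation matches a counting-rank oracle", {
  d <- c(0.1, 0.4, 0.9, 1.3)
  expect_equal(adaptability_correlation(d, -d * 2 + 1)$rho, -1)
  expect_error(adaptability_correlation(c(1, 2, 3), c(5, 5, 5)), "constant")
  expect_error(adaptability_correlation(1:3, 1:4), "equal length")
  expect_error(adaptability_correlation(1:2, 2:1), "at least 3")
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    x <- round(runif(n), 1)  # rounding forces ties
    y <- round(rnorm(n), 1)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
    expect_equal(adaptability_correlation(x, y)$rho, brute_spearman(x, y),
                 tolerance = 1e-14)
  }
})

test_that("simulated outcomes recover a sign-correct, strong correlation", {
  distances <- with_stream_seed_test(2, "distances", runif(30, 0, 2))
  deltas <- simulate_adaptation_outcomes(distances, slope = -1,
                                         noise_sd = 0.1, seed = 2)
  rho <- adaptability_correlation(distances, deltas)$rho
  expect_lt(rho, -0.9)
  # slope zero leaves only noise: near-zero correlation at n = 200
  d2 <- seq(0.01, 2, length.out = 200)
  noise <- simulate_adaptation_outcomes(d2, slope = 0, noise_sd = 1, seed = 4)
  expect_lt(abs(adaptability_correlation(d2, noise)$rho), 0.2)
})

test_that("transfer sources are ranked by ascending distance to the target", {
  fs2 <- feature_space(task_embedding_set("a", rbind(c(1, 0))),
                       task_embedding_set("b", rbind(c(0, 1))))
  expect_equal(as.character(rank_transfer_sources("a", fs2, exact_cfg)), "b")

  # three tasks at increasing angles from the target direction
  fs4 <- feature_space(
    task_embedding_set("target", rbind(c(1, 0))),
    task_embedding_set("near", rbind(c(cos(0.2), sin(0.2)))),
    task_embedding_set("mid", rbind(c(cos(0.8), sin(0.8)))),
    task_embedding_set("far", rbind(c(0, 1))))
  expect_equal(as.character(rank_transfer_sources("target", fs4, exact_cfg)),
               c("near", "mid", "far"))

  set.seed(9)
  fs <- rand_feature_space(K = 4L, d = 4L, m_range = 5L)
  ord <- rank_transfer_sources(task_ids(fs)[1L], fs, exact_cfg)
  D <- pairwise_distance_matrix(fs, exact_cfg)
  expect_equal(as.character(ord),
               names(sort(D[1, -1])))
  expect_equal(attr(ord, "distances"), unname(sort(D[1, -1])),
               tolerance = 1e-12)
  expect_error(rank_transfer_sources("nope", fs, exact_cfg), "unknown target")
})
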