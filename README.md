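# otfrm

Quantifying how well a learned protein representation separates downstream
tasks — and which tasks will transfer well to each other — with an
optimal-transport-based feature-space representation measure.

## The problem

When one embedding model (pretrained on protein sequence, structure and
function data) serves many downstream tasks, each task's samples occupy a
region of the shared feature space. A representation is well formed for a
task when that task's samples cluster tightly while staying separated from
the other tasks' samples, and the degree to which pretraining and
fine-tuning improve this organization is the model's *transferability* to
the task. `otfrm` makes this quantitative:

* **OT similarity between two tasks** (the distributional view): with
  samples `x_i` from task `C_k` and `y_j` from task `C_l`, and the
  cosine-distance ground cost `C_ij = (1 - cos(x_i, y_j))^p`, the
  p-Wasserstein distance is `W_p = (min_pi <C, pi>)^(1/p)` over couplings
  `pi` with the two empirical marginals, and
  `OT_sim(C_k, C_l) = 1 - W_p`. The minimization is solved exactly (a
  transportation simplex, small instances) or with entropic regularization
  (log-domain Sinkhorn, `eps = 0.1` by default).
* **The representation measure** for task `k` in a K-task space:

  ```
            intra_sim(k)         2/(m_k (m_k - 1)) * sum_{i<j} cos(x_i, x_j)
  score_k = ------------  =  ------------------------------------------------
            inter_sim(k)         1/(K - 1) * sum_{l != k} OT_sim(C_k, C_l)
  ```

  Both components lie in [-1, 1]; a larger score means a tighter,
  better-separated task distribution.
* **Transfer guidance**: pairwise `W_p` distances between tasks correlate
  negatively with adaptation performance, so candidate source tasks are
  ranked by ascending distance to the target.

The package also implements the surrounding toolkit: BIOES tag encoding of
protein motif/domain/region annotations with long-tail category merging
into `Other`, the equalized focal loss family for long-tailed
classification, the standard evaluation metrics (RMSE, Pearson R, accuracy,
precision, recall, MCC), and seeded synthetic generators so every analysis
runs without external data.

## Worked example

```r
library(otfrm)

spec <- synthetic_space_spec(K = 4, m = 40, d = 16, delta = 3, seed = 42)
fs <- generate_feature_space(spec)
report <- otfrm(fs)          # entropic solver, eps = 0.1, p = 1
summary(report)
```

```
<otfrm_report> K = 4 tasks, solver = sinkhorn (p = 1, eps = 0.1)
 task_id       stage  m intra_sim inter_sim otfrm
   task1 unspecified 40    0.8448    0.1738 4.860
   task2 unspecified 40    0.8656    0.1726 5.015
   task3 unspecified 40    0.8601    0.1667 5.159
   task4 unspecified 40    0.8512    0.1719 4.951

Pairwise W_p distances:
       task1  task2  task3  task4
task1 0.0000 0.8036 0.8149 0.8600
task2 0.8036 0.0000 0.8697 0.8090
task3 0.8149 0.8697 0.0000 0.8153
task4 0.8600 0.8090 0.8153 0.0000

Mean score: 4.996 (range 4.86 - 5.159)
```

Each task's samples have mean within-task cosine similarity ~0.85
(`intra_sim`) but only ~0.17 mean OT similarity to the other tasks
(`inter_sim`), so every score is ~5: the four synthetic clusters, drawn at
separation `delta = 3` within-cluster spreads, are tight and well
separated. Ranking transfer sources for `task1` sorts the others by
ascending transport distance:

```r
rank_transfer_sources("task1", fs)
#> [1] "task2" "task3" "task4"
#> attr(,"distances") 0.8035596 0.8149008 0.8600034
```

Stage-wise dynamics (`generate_stage_snapshots()` + `stage_comparison()`)
reproduce the qualitative transferability pattern: scores grow from the
randomly initialized through the pretrained to the fine-tuned stage, and
the PT/RI and FT/PT ratios quantify each step's gain.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/otfrm.R simulate embeddings --delta 4 --K 3 --out run1
Rscript inst/cli/otfrm.R otfrm run1/embeddings.tsv --out run1
Rscript inst/cli/otfrm.R bioes encode inst/extdata/synthetic_toy_annotations.tsv --out run1
```

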