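---
title: "Methods: an optimal-transport measure of feature-space organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an optimal-transport measure of feature-space organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otfrm)
```

## The measure

A multi-task feature space is a collection of K tasks, each an $m_k \times
d$ matrix of sample embeddings in one shared dimension. The package scores
each task by the ratio of how tightly its own samples cluster to how
similar its distribution is to the other tasks' distributions.

**Intra-task similarity** is the mean cosine similarity over all unique
sample pairs within the task,

$$\mathrm{intra}(k) = \frac{2}{m_k (m_k - 1)} \sum_{i < j}
\cos(x_i, x_j),$$

which requires $m_k \ge 2$ (the normalization is undefined at $m_k = 1$,
and the package raises an error rather than guessing).

**Inter-task similarity** compares whole distributions. With the
cosine-distance ground cost $c(x, y) = (1 - \cos(x, y))^p$, the
p-Wasserstein distance between the empirical measures of tasks $C_k$ and
$C_l$ is $W_p = \mathrm{OT}(\alpha, \beta)^{1/p}$, where $\mathrm{OT}$
minimizes $\langle C, \pi\rangle$ over couplings $\pi$ with the two
sample-weight vectors as marginals. The OT similarity is $1 - W_p$, and

$$\mathrm{inter}(k) = \frac{1}{K - 1}\sum_{l \ne k}
\bigl(1 - W_p(C_k, C_l)\bigr).$$

Cosine distance is the natural ground metric for high-dimensional
embeddings, and its similarity/distance duality ($\mathrm{sim} = 1 -
\mathrm{dist}$) puts both components on the same $[-1, 1]$ scale.

**The score** is $\mathrm{intra}(k) / \mathrm{inter}(k)$: larger means a
tighter task cluster that is further from the rest of the space. The ratio
is only meaningful for a positive denominator; when $\mathrm{inter}(k)$
falls below a guard of $10^{-8}$ (tasks anti-aligned with the rest of the
space, or an exactly orthogonal toy configuration), the package raises an
error carrying both components instead of returning a signed infinity.

## Solving the transport problem

Two solvers stand behind every distance:

* **Exact** (`solver = "exact"`): a transportation simplex
  (northwest-corner initial basis, MODI pivoting with the most-negative
  reduced cost entering and ties broken by index). It is intended for
  small instances and refuses problems with $mn > 10^4$. Degenerate pivots
  keep explicit zero-value basic cells so the basis stays a spanning tree.
* **Sinkhorn** (default): entropy-regularized transport,
  $\min_\pi \langle C, \pi\rangle - \varepsilon H(\pi)$, iterated in the
  log domain so small $\varepsilon$ stays numerically stable. Below
  $\varepsilon = 0.05$ the iteration is warm-started through an
  epsilon-scaling schedule (anneal $\varepsilon$ downward by factors of 4
  from 1, carrying the dual potentials), which cuts iteration counts by
  orders of magnitude. Iteration stops when the worst marginal residual
  drops below `marginal_tol`; hitting `max_iter` first raises a warning,
  or an error when the residual still exceeds ten times the tolerance.

Two conventions deserve a note. First, the entropic term enters with the
standard entropy-favoring sign (the formulation the Sinkhorn algorithm
solves); writings of the objective sometimes flip the sign of the $H(\pi)$
term, but only this convention yields the classical scaling iteration.
Second, the reported cost is the *sharp* transport cost $\langle C,
\pi^\ast\rangle$ under the entropic plan, with the entropy term excluded:
this keeps the self-distance at zero in the $\varepsilon \to 0$ limit and
preserves the $W_p$ semantics of the distance.

Defaults, all configurable through `ot_config()`:

| parameter | default | why |
|---|---|---|
| `p` | 1 | order of the distance; 1 keeps costs on the raw cosine-distance scale (the analyses here are order-agnostic) |
| `epsilon` | 0.1 | regularization used for routine scoring; smooth, fast, and close enough to exact for ranking purposes |
| `marginal_tol` | 1e-9 | plan feasibility at default epsilon; for very small epsilon a looser 1e-6 is appropriate (feasibility error of that size moves the cost by far less than the entropic bias) |
| `max_iter` | 10000 | ample at default epsilon (tens of iterations typical) |
| marginals | uniform | empirical measures with equal weights; weighted marginals are accepted but non-default |
| `subsample_cap` | 2000 | the cost matrix is $O(mn)$ memory; larger tasks are subsampled without replacement under a seeded, named random stream |

The exact solver doubles as the test oracle for the entropic one: on random
cosine-cost instances with $m, n \le 8$ the two costs agree to well under
$10^{-3}$ at $\varepsilon = 10^{-3}$, and the exact solver itself is
checked against full permutation enumeration (the optimum of a square
uniform-marginal problem sits at a permutation coupling).

## Stage dynamics, adaptability, source ranking

`stage_comparison()` scores the same task set at the randomly initialized
(RI), pretrained (PT) and fine-tuned (FT) snapshots and reports the PT/RI
and FT/PT ratios — the per-task transferability gains of each training
step. Ratio denominators pass through the same positivity guard as the
score itself.

`adaptability_correlation()` relates pairwise task distances to adaptation
outcomes with Spearman's rank correlation, computed in-house (average-rank
transform, then the product-moment quotient on the ranks) so the statistic
can be verified against a brute-force counting-rank oracle in the tests.
Constant inputs make the statistic undefined and raise an error.

`rank_transfer_sources()` orders candidate source tasks by ascending
$W_p$ distance to the target — closest first, following the negative
distance-adaptability relationship — with lexicographic tie-breaks for
reproducibility.

## The synthetic generator

`generate_feature_space()` draws K isotropic Gaussian clusters in $d$
dimensions. Its geometry encodes three deliberate choices:

* **`sigma` is the RMS within-cluster radius** (per-coordinate standard
  deviation $\sigma/\sqrt{d}$), so `delta` — the pairwise distance between
  cluster means in units of `sigma` — measures separation relative to
  cluster spread independently of dimension. Had `sigma` been the
  per-coordinate deviation, the same `delta` would become negligible
  relative to the noise ball as $d$ grows and "separation" would lose its
  meaning.
* **A shared center**: all cluster means sit on a common offset of norm
  `sigma` from the origin. Real network activations, trained or not, are
  not centered at the origin and have positive mean cosine similarity; a
  zero-centered space would make intra-task similarity hover at $0 \pm$
  noise and the score's denominator guard fire spuriously at `delta = 0`.
* **Separation orthogonal to the center**: the mean directions are
  orthonormalized against the center (and each other) when $K + 1 \le d$,
  so cross-task mean inner products stay at $\lVert c\rVert^2 > 0$ for
  every `delta` — tasks separate without ever becoming anti-aligned — and
  the pairwise mean distance is exactly `delta * sigma`. For $K + 1 > d$
  the directions fall back to plain unit-norm projections and the
  separation is approximate.

`generate_stage_snapshots()` reuses the same center and directions across
the three stages (it is one model's feature space throughout) and draws
independent within-cluster noise per stage, with separations `c(0, 1, 4)`
by default: fully mixed at initialization, mildly organized after
pretraining, strongly separated after fine-tuning.

What the generator does *not* emulate: anisotropic or manifold-structured
embedding geometry, task-size imbalance, heavy-tailed sample norms, or
inter-task correlation structure beyond the shared center. Passing tests
on these fixtures therefore demonstrate the correctness and qualitative
behaviour of the measure, not its numerical values on any real model's
feature space.

Every generator derives its draws from one integer seed through named
substreams (one stream per output kind), so adding a generator never
shifts another's sequence, and the caller's RNG state is left untouched.
Samples with norm below $10^{-9}$ are resampled so cosine similarity is
always defined.

`generate_annotated_corpus()` produces random amino-acid sequences with
motif/domain/region spans whose category frequencies follow a Zipf law
(exponent > 1), the long-tailed regime the category-merging and equalized
focal loss machinery exists for. Span packing is rejection-free (spans are
placed into remaining gaps, shrinking if needed) and errors only when a
sequence cannot hold the requested spans at all.

## Annotation encoding

BIOES tags mark each residue as **B**egin/**I**nside/**E**nd of a
multi-residue entity, **S**ingle for a one-residue entity, or **O**utside.
Coordinates are 1-based inclusive, matching UniProt feature conventions;
spans of the same kind must not overlap, while different kinds (motif,
domain, region) live on separate tag tracks and may overlap freely — the
category vocabulary is kind-qualified (`Motif1`, `Domain2`), so a combined
single-track mode exists but is not the default. `decode_bioes()` enforces
the tag grammar (every non-O run is `S` or `B (I)* E` with one category)
and names the offending position on violation; encode/decode roundtrip
identity is property-tested on generated corpora.

`merge_long_tail()` maps categories observed fewer than `min_count` times
to the sentinel `Other`, keeping the mapping for encode-time lookup. The
threshold is data- and snapshot-dependent, so it is a required argument
with no privileged default; reproducing any particular published category
count is out of scope.

## Losses and evaluation metrics

The equalized focal loss for category $j$ with confidence $p_t$ is

$$-\,\alpha_t\,\frac{\gamma_b + \gamma_v^j}{\gamma_b}\,
(1 - p_t)^{\gamma_b + \gamma_v^j} \log p_t, \qquad
\gamma_v^j = s\,(1 - g_j),$$

with $g_j \in [0, 1]$ the category's balance value (1 = balanced). With
all $g_j = 1$ it reduces exactly to the plain focal form with unit weight
— a property the tests exercise — and the weighting factor is
non-increasing in $g_j$, up-weighting rare categories. $\alpha_t$ defaults
to 1 and $g_j$ is supplied by the caller (e.g. from a running tracker
during training); confidences are clamped at $10^{-12}$ before the
logarithm. The multitask pretraining combination (cross-entropy plus
equalized focal term) is exposed as a weighted sum with unit default
weights.

Evaluation metrics follow the standard formulas (RMSE; Pearson's R;
accuracy, precision, recall, MCC from confusion counts). A metric whose
denominator is zero is reported as `NA` — explicitly undefined — never as
a silent zero, which would corrupt comparisons on degenerate folds.
Multiclass inputs are binarized one-vs-rest with per-class and
macro-averaged summaries.

## Problem sizes and determinism

The test-suite and acceptance-script study conditions are: 6 tasks, 50
samples per task, 16 dimensions for the stage-dynamics analysis
(separations 0/1/4); 50 random instances with $m, n \le 8$ for the
solver-agreement check; 30 distance/outcome pairs (slope $-1$, noise sd
0.25) for the rank-correlation analysis; 1000 generated sequences for the
encode/decode roundtrip. These sizes give stable statistics while keeping
a full run in well under a minute. All randomness flows from explicit
seeds; `scripts/acceptance.R --seed N` is bit-reproducible for a given N.

## Known limitations

* The score is undefined when the mean OT similarity to other tasks is
  non-positive; the package errors rather than extrapolating.
* The exact solver is for small instances only; large tasks rely on
  subsampling plus entropic transport, whose cost carries an
  $O(\varepsilon)$ bias relative to the exact optimum.
* Synthetic fixtures are Gaussian; conclusions about real embedding
  spaces require the user's own embeddings through
  `read_feature_space()`.
* The package quantifies and ranks transferability; it does not perform
  the alternating source/target fine-tuning itself (that requires trained
  models and their training loops).
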