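---
title: "Methods: network inference with per-gene neural regressors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network inference with per-gene neural regressors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regnann)
```

## The model

`regnann` infers an undirected gene network from an expression matrix
(samples in rows, genes in columns). The core idea is to ask, for every gene
separately, *how well do this gene's levels predict everyone else's?* — and to
read the answer off a trained regressor rather than off a pairwise statistic.

For a network of $N$ genes, gene $g$ gets a one-to-many multilayer perceptron

$$y_k = \tanh\Big(\sum_{i=1}^{H} w^{out}_{ik}\, \tanh(w^{in}_i\, x)\Big),
\qquad k = 1, \dots, N-1,$$

with no bias terms and $H = \lceil\sqrt{N-1}\rceil$ hidden units. Each
expression sample contributes one training pattern: input $x$ is gene $g$'s
value, targets are the other genes' values. Weights are fit by online
back-propagation with momentum,

$$\Delta w(t) = -\eta\,\nabla E + \alpha\,\Delta w(t-1),
\qquad E = \tfrac12 \sum_k (y_k - t_k)^2,$$

visiting the patterns in a freshly shuffled order each epoch.

After training, the regressor is **probed** at $x = 1$ — maximal expression on
the $[-1, 1]$ scale — and the $N-1$ outputs are taken as the interaction
estimates of gene $g$ with every other gene. `infer_network()` stacks the $N$
probes into an $N \times N$ matrix with a zero diagonal. The matrix is not
symmetric (gene $g$ predicting gene $j$ is a different regression from the
reverse), so `binarize()` scores each unordered pair by
$\max(|c_{gj}|, |c_{jg}|)$ by default and keeps pairs strictly above the
threshold; `mean` and `signed_max` combiners and non-absolute scoring are
available. `majority_vote()` repeats the whole inference `n_runs` times from
derived seeds and keeps links that appear in strictly more than
`vote_fraction` of the runs.

## Parameters and their defaults

`learning_params()` collects the training knobs:

* `learning_rate = 0.01`, `momentum = 0.8` — small-step online training with
  heavy momentum; stable across the package's benchmark sizes. A learning rate
  of exactly 0 is allowed and makes training a no-op (useful for inspecting
  initializations).
* `epochs = 200` — enough for the desk-scale problems below to converge; the
  per-epoch mean error is retained on the fitted object (`glance()`).
* `hidden = NULL` — defaults to $\lceil\sqrt{N-1}\rceil$, a deliberately small
  capacity that regularizes the per-gene regression.
* `init_scale = 0.1` — uniform initialization in $\pm 0.1$, keeping the
  $\tanh$ units in their linear regime at the start.
* `seed` — gene $g$ trains under seed `seed + g`, so rows of the inferred
  matrix are independent of execution order, and majority-vote run $r$ uses
  `seed + (r-1) * N`. All randomness (initialization and epoch shuffles) is
  drawn from R's RNG; the C++ inner loop is purely deterministic.

Because every activation is $\tanh$, inputs and targets must live in
$[-1, 1]$: `infer_network()` refuses unbounded input and points at
`rescale_linear()`.

## Synthetic benchmarks: what they emulate and what they don't

Real regulatory networks are only partially known, so the package evaluates
against synthetic ground truth:

* **Topologies.** `generate_barabasi()` (preferential attachment; scale-free
  degree distributions like those reported for biological networks) and
  `generate_erdos_renyi()` (a null topology with the same mean degree). Both
  delegate to igraph. `network_density()` uses the convention
  $\text{links}/N^2$ over undirected links.
* **Expression.** `generate_slc()` draws source signals uniformly in
  $[-1, 1]$ and adds one round of linear propagation along the true edges,
  $E = S + S A$. This captures correlated expression across linked genes but
  none of the dynamics, saturation, or measurement noise of real assays — it
  is a best-case generative model, and recovered accuracies should be read as
  upper bounds.
* **Toy motifs.** `toy_spec()` / `generate_toy()` build four 4-gene motifs
  (single, cooperative, multiple, indirect regulation) with threshold gates,
  activation probability `p_active = 0.5`, gate threshold `theta = 0.5` and
  noise amplitude 0.1. Their small size makes the expected correlations
  derivable by hand, which the test suite exploits.

Normalizations beyond the linear rescale: `normalize_statistical()`
(z-score per gene with the population SD; constant genes map to 0 with a
warning) and `discretize_signs()` (signs of successive differences, losing one
row). Inside `run_protocol()` unbounded schemes are linearly remapped into
$[-1, 1]$ after the fact so the regressors stay valid.

## Evaluation conventions

Predictions are scored over unordered gene pairs (the diagonal is ignored).
`recall()`, `precision()` and `mcc()` all return 0 when their denominator is
0 — the standard convention that makes null comparisons well defined. MCC is
the headline score because the link/no-link classes are heavily imbalanced at
biological densities.

`eval_curve()` sweeps the binarization threshold from 0 to the maximum pair
strength and reports two areas:

* `auc_pr` — area under precision versus recall;
* `auc_mr` — area under MCC versus recall, rewarding methods whose MCC stays
  high as recall increases.

Numerical choices, stated explicitly:

* Thresholds at which nothing is predicted (TP + FP = 0) stay in the points
  table but are excluded from the integrals; including them would pin every
  curve to (0, 0) and cap a perfect scorer's `auc_mr` at 0.5.
* Duplicate recall values are averaged before trapezoidal integration, and the
  curve is anchored at recall 0 and 1 by extending the nearest observed value.
* An all-zero score matrix degenerates to a single point with zero AUCs and a
  warning.
* `grid_search_threshold()` breaks MCC ties toward the smallest threshold
  (the most inclusive network among equals). `threshold_study()` estimates the
  threshold on random sample-wise train/validation splits so the reported
  validation MCC is not selected on.

## Scale and limitations

Defaults target desk-scale studies — tens of genes, tens to hundreds of
samples — where a full inference takes about a second and benchmark sweeps
finish in minutes. The per-gene regressors are embarrassingly parallel in
principle, but the package runs them serially for exact reproducibility.
Inference quality degrades sharply when samples are scarce relative to genes
(the data-ratio sweep in `run_protocol()` quantifies this), the probe reads a
*marginal* association, so indirect regulation can induce spurious
second-order links, and the method infers association strength, not causal
direction.
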