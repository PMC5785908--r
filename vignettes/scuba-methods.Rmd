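---
title: "Methods: positive-unlabelled multiple kernel learning for gene prioritization"
author: "scuba package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positive-unlabelled multiple kernel learning for gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scuba)
```

# The problem

Given a set of genes $\mathcal G$, a small positive set $\mathcal P$ of
known disease genes ($m = |\mathcal P|$) and a large candidate set
$\mathcal U = \mathcal G \setminus \mathcal P$ ($n = |\mathcal U|$), gene
prioritization ranks the candidates by their likelihood of association
with the disease.  Two features of the task shape the method:

* **Positive-unlabelled structure.**  Only $\mathcal P$ is trusted.
  Candidates are *unlabelled*, not negative — some of them are precisely
  the undiscovered disease genes we want to rank highly.
* **Strong imbalance.**  $m$ is typically tens of genes while $n$ may be
  the genome, so anything costing more than linear work in $n$ per
  kernel is impractical.

Evidence about gene relatedness lives in heterogeneous sources —
protein–protein interaction graphs, co-expression, pathway
co-membership — each naturally expressed as an undirected gene network.
The package converts every source into several positive semi-definite
node-similarity matrices (graph node kernels) and learns a convex
combination of them together with a ranking function, following the
guilt-by-association principle.

# Graph node kernels

For a network with adjacency $A$, degree matrix $D$ and Laplacian
$L = D - A$, four kernel families are available (`medk()`, `mdk()`,
`rlk()`, `diffusion_kernel()`):

| family | formula | parameter (unitless) | default grid |
|---|---|---|---|
| MEDK | $\exp(\beta M)$, $M = I - L/N$ | diffusion strength $\beta \ge 0$ | $\{0.01, 0.04, 0.07\}$ |
| MDK | $Z(t)Z(t)^\top$, $Z(t)=\frac1t\sum_{\tau=1}^{t}P^\tau$, $P = D^{-1}A$ | steps $t \in \mathbb N_{\ge 1}$ | $\{2, 4, 6\}$ |
| RLK | $(I+\alpha L)^{-1}$ | regularization $\alpha \ge 0$ | $\{1, 10, 100\}$ |
| heat diffusion | $\exp(-\beta L)$ | $\beta \ge 0$ | $\{0.01, 0.04, 0.07\}$ |

MEDK replaces the adjacency matrix of classical exponential diffusion by
the Markov-type matrix $M = I - L/N$, whose rows sum to one; this
removes the hub bias that makes plain diffusion favour high-degree
genes.  The published description of this kernel does not pin down the
exact Markov normalization, so the package fixes the symmetric choice
$M = I - L/N$ (equivalently $(A - D + N I)/N$), which keeps the
exponent symmetric and the kernel PSD by construction.  MDK compares
$t$-step random-walk diffusion patterns; RLK counts paths of all lengths
with geometric damping and is the normalized random-walk-with-restart
model.

Both matrix exponentials are computed by spectral decomposition of the
symmetric exponent (`eigen(symmetric = TRUE)`), RLK by a direct solve of
the SPD system; the results are symmetrized to remove round-off
asymmetry.  Computation is dense and targets networks up to a few
thousand genes.

**Normalization.**  Kernels from different sources live on different
scales, so `kernel_bank()` cosine-normalizes every kernel to unit
diagonal ($K'_{ij} = K_{ij}/\sqrt{K_{ii}K_{jj}}$) before combination by
default (`normalize = FALSE` turns this off).  Genes that are isolated
under MDK have an identically zero kernel row and hence zero diagonal;
the bank leaves those rows at zero rather than failing, while the
exported `cosine_normalize()` treats a nonpositive diagonal as an error
because a standalone kernel with an uninformative gene usually signals
an input problem.

**Degenerate inputs.**  Self-loops are dropped (with a warning),
duplicate edges collapse to the maximum weight, and weighted adjacency
is accepted everywhere with degrees defined as weighted row sums.
Zero-degree genes get an all-zero MDK transition row — the random walker
vanishes — so isolated genes have similarity zero to everything rather
than an arbitrary self-loop.

# The learning model

Let $K^s = \sum_{r=1}^R K_r$ be the summed training kernel, partitioned
into blocks $K^+$ (positive–positive), $K^{+-}$ and $K^-$.  The balanced
margin-distribution problem (`solve_easymkl()`) is

$$\min_{\gamma \in \Gamma}\; (1-\lambda)\,\gamma^\top Y K^s Y \gamma
  + \lambda\, \gamma^\top \gamma,$$

where $\Gamma$ constrains the positive and negative parts of $\gamma$ to
unit simplices and $Y = \mathrm{diag}(y)$.  $\gamma$ picks one point in
each class's convex hull; $\lambda = 0$ gives the hard-margin
nearest-points solution and $\lambda = 1$ the class centroids.

In the positive-unlabelled setting the two classes deserve different
regularization: the unlabelled class is noisy, and in the limit of
maximal uncertainty its weights should not be trusted at all.  The
package therefore pins $\gamma_- = u = (1/n, \dots, 1/n)$ — the
infinite-regularization solution for the unlabelled block — and solves
only for $\gamma_+$ over the $m$-simplex (`solve_scuba()`):

$$\min_{\gamma_+ \in \Delta_m}\; \gamma_+^\top K^+ \gamma_+
  - 2\,\gamma_+^\top c + \lambda_+\, \gamma_+^\top \gamma_+,
  \qquad c = K^{+-} u .$$

Only the $m \times m$ block and one $m$-vector per kernel enter the
objective, so the solve costs $O(m^2 R)$ — quadratic in the number of
positives and independent of $n$.  `scuba_blocks()` performs the single
streaming pass over the bank that extracts $K^+_r$, $c_r$ (the row-mean
of $K^{+-}_r$) and the scalar $d_r = u^\top K^-_r u$; at most one full
kernel is in memory alongside the accumulators.

**Two-stage fit** (`scuba_fit()`):

1. solve the problem above on the unweighted sum $K^s$;
2. convert the solution into kernel weights
   $\eta_r \propto (Y\gamma)^\top K_r (Y\gamma) \ge 0$, normalized to
   sum to one (the published formula omits the transposes; the quadratic
   form is the only dimensionally consistent reading).  The scalar
   $d_r$ completes the quadratic form for the uniform unlabelled part;
3. re-solve on the weighted combination $K^* = \sum_r \eta_r K_r$ to get
   the final $\gamma^*$.

Exactly two solves are performed; the procedure is not iterated further.
A candidate $g_i$ is then scored by
$s_i = \sum_j y_j \gamma^*_j K^{*}_{ij}$ — its weighted similarity to
the positive representative point minus its mean similarity to the
candidates — and candidates are ranked by decreasing score with
lexicographic gene-ID tie-breaking, which makes rankings reproducible to
the byte.

# The solver

Both optimization problems are convex quadratic programs over (products
of) probability simplices.  They are solved by projected gradient
descent: Euclidean projection onto the simplex via the sort-based
algorithm, backtracking line search on the quadratic upper bound, step
growth on acceptance, and termination when the objective decrease drops
below $10^{-10}$ or after $10^4$ iterations.  Any stationary point of a
convex QP is a global optimum, and the test suite checks the attained
objective against an independent active-set QP solver on random
instances.  Two analytic shortcuts: $m = 1$ returns $\gamma_+ = 1$
immediately, and $\lambda_+ = \infty$ returns the uniform distribution
(it is also the correct limit: the $\ell_1$ distance between
$\gamma_+$ and uniform decreases monotonically in $\lambda_+$).

With $\lambda_+ = 0$ and rank-deficient kernels the optimum need not be
unique; any minimizer is acceptable and tests compare objectives, not
argmins.

# Tunable parameters

* `kernels` — families and grids per source; default MEDK
  $\{0.01, 0.04, 0.07\}$, i.e. $H = 3$ kernels per source.  More kernels
  per source widen the model space but add parameters to learn; a
  moderate $H$ keeps over-fitting in check.
* `lambda` — the positive-class regularization $\lambda_+ \in
  [0, \infty]$.  `"auto"` selects it by k-fold cross-validation over the
  grid $\{0, 0.1, \dots, 1\}$: the positive set is split into folds,
  the model refit on the retained positives (candidates unchanged), and
  held-out positives are scored against the fold's candidate pool; the
  grid value with the best mean held-out AUC wins, ties going to the
  smaller value.  The grid is used literally as $\lambda_+$ values even
  though $\lambda_+$'s natural range is $[0, \infty)$, matching the
  published protocol.  The fold count is not fixed by that protocol;
  the package defaults to $k = 5$, reducing to $m$ when $m < 5$.
* `normalize` — cosine normalization toggle (on by default; whether the
  original experiments normalized before combination is unstated).
* `universe` — sources are aligned to the intersection of their node
  sets by default, mirroring pre-aligned published datasets; union
  alignment with zero-padding is available.

Candidate genes already present in the training $\mathcal U$ are scored
transductively with the fitted model — they *are* the unlabelled
training genes, and the genome-wide protocol scores exactly that set.

# Evaluation protocols

`loocv_protocol()` implements the class-based protocol: for each disease
class, $\mathcal P$ is the class, $\mathcal U$ is a seeded sample of
out-of-class disease genes of size $\lceil m/2 \rceil$ (disease genes
are better studied, so out-of-class disease genes are the safest
pseudo-candidates); every training gene is held out in turn, the model
refit, and the held-out gene scored against all genes associated to no
disease.  Its *decision score* is the fraction of that pool it strictly
outranks (ties do not count — the pessimistic, deterministic
convention).  Pooled across classes, the mean decision score equals the
ROC area of held-out versus pool scores, which the tests verify against
a pairwise-comparison oracle at $10^{-9}$.

`rank_metrics()` summarizes normalized ranks (rank divided by ranking
size) from independent prioritizations: median, mean, standard
deviation, TPR at the 5/10/30 % thresholds and the averaged AUC, where a
test gene ranked $r$ of $n$ contributes $(n-r)/(n-1)$ — the fraction of
the other candidates it outranks.  Statistical comparisons use
`hanley_mcneil()` (1982 independent-curves standard error; the 1983
correlated correction needs a correlation estimate that the protocol
does not provide) and `paired_rank_test()`, a two-sided Wilcoxon
signed-rank test that drops zero differences and uses the exact
sign-flip permutation null (dynamic programming over the observed,
possibly tied, ranks) up to 25 pairs, the continuity-corrected normal
approximation beyond.

# Synthetic data: what it does and does not show

`simulate_planted_network()` draws a planted-module graph: a module of
`module_size` genes connected with probability `p_in` against a
background of density `p_out`.  `simulate_multisource()` draws several
independent views sharing the module (optionally rewired), plus an
optional matched-density pure-noise source; a single master seed feeds
per-source substreams so adding sources never perturbs earlier draws.
`split_positives()` reveals part of the module as $\mathcal P$ and hides
the rest among the candidates, reproducing the PU setup exactly.

The reference study conditions used throughout the tests and the
acceptance script are 300 genes, a module of 20, `p_in = 0.3`,
`p_out = 0.02` and 10 revealed positives with the MEDK bank ($H = 3$) —
a desk-scale instance with module degrees (≈ 6 within-module plus ≈ 6
background edges) that are realistic for functional gene networks while
leaving recovery genuinely noisy.  Under these conditions the hidden
module genes are recovered with mean AUC well above chance, the
recovery AUC decays towards 0.5 as `p_in` approaches `p_out`, and the
learned kernel weights put more mass on the signal-carrying source than
on the matched-density noise source.

These generators emulate community structure only.  They do not emulate
scale-free degree distributions, edge-weight heterogeneity, ascertainment
bias (better-studied genes having more edges), or correlated noise
across sources — all present in real interactome data.  Passing the
synthetic benchmarks therefore demonstrates the correctness and the
qualitative behaviour of the machinery, not the published performance
levels on curated disease collections, which depend on external datasets
outside this package's scope.

# Problem sizes and runtime

The test suite and acceptance script run at deliberately modest sizes —
kernels on graphs of 10–300 nodes, 20-replicate simulation studies, and
a scaling check with $m = 20$ positives against candidate pools of 500
and 5 000 (where the fit, measured on precomputed block summaries, is
insensitive to the pool size by design).  Dense kernel computation is
the only step that grows faster than linearly in the gene count; on a
single core, a 300-gene bank of three kernels builds in well under a
second, and a few thousand genes remain comfortable.

# Known limitations

* Dense kernels: genome-scale graphs (tens of thousands of nodes) need
  landmark or sparse approximations that are out of scope here.
* Exact string matching of gene identifiers; no namespace translation.
* The two-stage fit uses exactly one weight update; fully iterated
  alternation might improve $\eta$ on some instances but is not part of
  the published procedure.
* Kernel-weight differences between informative and uninformative
  sources are small in absolute terms when kernels are near-identity
  (small diffusion parameters): $\eta$ discriminates reliably in sign
  but not dramatically in magnitude.
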