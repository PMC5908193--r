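---
title: "Variance-driven multitask clustering: model, solver and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-driven multitask clustering: model, solver and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scVDMC)
```

## The problem

Single-cell RNA-seq experiments on related populations — biological
replicates, donors, or patient/control pairs — contain the same cell types,
expressed through the same marker genes, but shifted and rescaled by
technical batch effects and population-specific biology. Pooling the cells
and clustering once lets those shifts dominate (cells group by sample of
origin); clustering each population alone squanders the shared structure and
fails on small samples. This package clusters all populations *jointly*
while keeping population-specific cluster centers, and selects the shared
marker genes *inside* the clustering objective rather than as a
preprocessing step.

## Model

Each domain (population) $d = 1, \dots, D$ is a matrix
$X^{(d)} \in \mathbb{R}^{m \times n^{(d)}}$ of log-scale expression, all
domains sharing one gene index of length $m$. The model estimates, per
domain, centers $U^{(d)} \in \mathbb{R}^{m \times k}$ and one-hot
assignments $V^{(d)} \in \{0,1\}^{n^{(d)} \times k}$, plus one global binary
marker-selection vector $B \in \{0,1\}^m$ with $\sum_i B_i = \lambda$. With
$D_B = \mathrm{diag}(B)$ the objective is

$$
\min \;
\frac12 \sum_d \bigl\| D_B \bigl( X^{(d)} - U^{(d)} V^{(d)\top} \bigr)
\bigr\|_F^2
\;-\; w \sum_d B^\top \mathrm{Var}\!\left(U^{(d)}\right)
\;+\; \alpha \sum_{i,j} B_i \, \mathrm{Var}\!\left(Y^{(i,j)}\right),
$$

where $\mathrm{Var}(U^{(d)})$ stacks the population variance of each center
row (how far apart gene $i$'s $k$ centers sit — rewarding separation), and
$Y^{(i,j)} = (U^{(1)}_{ij}, \dots, U^{(D)}_{ij})$ stacks one center entry
across domains, so the $\alpha$ term penalizes cross-domain disagreement of
matched clusters. Both variances are the centering quadratic forms
$\frac1k u \Psi u^\top$ and $\frac1D y^\top \Phi y$ with
$\Psi = I_k - \frac1k \mathbf{1}\mathbf{1}^\top$,
$\Phi = I_D - \frac1D \mathbf{1}\mathbf{1}^\top$.

The model assumes: a common number of clusters $k$ in every domain; a
common marker set of known size $\lambda$; and that cross-domain variation
is captured by center displacement (not, say, cluster-specific rescaling).

## Alternating solver

Each iteration performs three exact block minimizations:

1. **Selection.** At fixed $U, V$ the objective is linear in $B$: each gene
   gets the coefficient
   $c_i = \frac12\sum_d \|X^{(d)}_{i,:} - U^{(d)}_{i,:}V^{(d)\top}\|^2
   - w \sum_d \mathrm{Var}(U^{(d)}_{i,:})
   + \alpha \sum_j \mathrm{Var}(Y^{(i,j)})$, and the $\lambda$ smallest
   coefficients win (a sort solves the cardinality-constrained binary
   program exactly; ties go to the lowest gene index).
2. **Assignment.** Per domain, each cell joins the nearest center in
   squared Euclidean distance over the selected genes only; ties go to the
   lowest cluster index. If a cluster empties, the largest cluster is
   randomly split in half (repeatedly, until all $k$ are populated).
3. **Centers.** Per domain and selected gene, the row subproblem is
   quadratic with the $k \times k$ Hessian
   $H = V^{(d)\top}V^{(d)} - \frac{2w}{k}\Psi
   + \frac{2\alpha}{D}\Phi_{dd} I_k$, shared across genes; one
   factorization solves all rows. Non-selected genes do not enter the
   objective; their rows are maintained as per-cluster means so that they
   re-enter the selection step with current coefficients.

With $D = 1$, $\alpha = 0$, $w = 0$, $\lambda = m$ the iteration is exactly
Lloyd's k-means, which the test suite asserts per-iteration against an
independent Lloyd implementation.

### The center-update scaling

The closed-form center update is derived here directly from the objective
above: its $\alpha$-dependent coefficients are $\frac{2\alpha}{D}$. An
alternative form in circulation carries an extra factor $k$ in those
coefficients ($\frac{2\alpha k}{D}$), which does not arise when
differentiating this objective; it is available behind
`alpha_scaling = "printed"` for comparison, and the corresponding bound is
`w_upper_bound_printed()`. The default update is validated in the tests by
numerical gradients and an independent numerical minimizer (both must agree
to $10^{-6}$).

### How large may w be?

$H$ must stay positive semi-definite or the center update is no longer a
minimizer. Gershgorin's circle theorem gives a sufficient condition in
terms of the smallest cluster size $c_{\min}$:

$$
w \le \frac{k^2 c_{\min}}{4(k-1)}
      + \frac{\alpha k^2 (D-1)}{2 D^2 (k-1)} .
$$

`w_upper_bound_implemented()` evaluates this; with $c_{\min} = 1$ it is the
loose bound valid for any non-empty clustering. The bound matters in
practice: beyond it, the separation reward can *manufacture* center
variance through degenerate partitions. The extreme case is a singleton
cluster — one outlying cell becomes its own center, the center variance
explodes, and the objective rewards it. The solver therefore

* clamps the center-update weight to $0.95\times$ the bound realized for
  the current cluster sizes (with a warning), so every update stays a
  well-posed minimization;
* prefers, among the iterates it visits and among restarts, solutions whose
  partition keeps the user's $w$ inside the realized bound — partitions
  with clusters small enough to violate it are treated as out-of-regime;
* returns the best iterate visited rather than the last one. Under
  monotone descent these coincide; when the empty-cluster split perturbs
  the trajectory, the best iterate is the honest summary of the run.

`suggest_w()` encodes the recommended operating point: 75% of the bound at
$c_{\min} = 2$. That value sits *above* the $c_{\min}=1$ bound — so
singleton partitions are out-of-regime and disfavored — and *below* the
$c_{\min}=2$ bound, so every non-degenerate update is well-posed.

### Initialization and restarts

The solver starts from pooled k-means over all domains (k-means++ seeding,
Lloyd iterations, best of 10 seedings by within-cluster sum of squares).
With `nstart > 1`, restarts alternate between pooled k-means over **all**
genes and pooled k-means over the most variable genes
($\min(m, \max(50, 2\lambda))$ of them). The screened variant exists
because, when informative genes are a tiny fraction of $m$, the all-gene
pool's distances are noise-dominated and every all-gene restart can land in
the same uninformative basin; variance screening is the standard simple
selector in this field and reliably reaches marker-driven basins. The best
restart wins by (regime-validity, objective).

### Convergence

"Converged" means the selection vector $B$ is unchanged *and* the relative
objective decrease falls below `tol` (default $10^{-6}$), capped at
`max_iter` (default 100). The objective trace is recorded after every
iteration. Because selection, assignment and center updates are exact block
minimizations, the trace is non-increasing as long as the empty-cluster
split never fires; the split is a random repair, not a descent step, so a
trace can tick upward in the iteration where it rescues an empty cluster.
On clustered data with $w$ below the loose bound this is rare; on
structureless data with $k$ close to $n$ it can recur, which is why the
convergence property tests draw their instances from the simulator (the
method's operating regime) rather than from unstructured noise.

The whole run is driven by one RNG stream seeded from `seed`
(initialization, restarts, empty-cluster splits), so fits are bitwise
reproducible.

## Choosing the hyperparameters

* **$\lambda$** (marker count) is domain knowledge — the number of genes
  expected to separate the cell types. It is not selected automatically.
* **$k$** via the elbow statistic $T_s = \sum_d \|D_B(X^{(d)} -
  U^{(d)}V^{(d)\top})\|_F^2$ (`elbow_statistic()`), scanned over candidate
  $k$ with `elbow_scan()` (10 repeats per $k$ by default) and read at the
  bend of the curve.
* **$w$** from `suggest_w()` as above, always below the Gershgorin bound.
* **$\alpha$** by scanning a grid (default 0, 0.5, 1, 2, 5, 10, 20) with
  `alpha_scan()` and watching the total cross-domain center disagreement
  (`alpha_diagnostic()`: summed Euclidean distances between same-index
  centers of every domain pair, on the selected genes). The diagnostic
  falls as $\alpha$ grows; the suggested $\alpha$ is the smallest one
  within 10% of the plateau — the operationalization of "increase until the
  difference stops changing much". PCA projections of centers are useful
  for eyeballing the same thing, but the selection rule works in the full
  selected-gene space; projection is cosmetic.

## The synthetic benchmark

`simulate_multidomain()` generates the geometry the method is built for:
$k_{\text{true}}$ cell types separated **only** in a small marker subspace
(default: 2 marker genes out of 1000, placed at indices 1–2), hundreds of
label-independent noise genes, and per-domain corruption — an orthogonal
rotation over the leading `mixing_dims` coordinates (default 3: the two
markers plus one noise gene), per-gene rescaling drawn from
`rescale_range`, additive Gaussian noise, and a global non-negativity
shift. Defaults: three domains of 33/33/34 cells, four cell types,
`cluster_spread` 0.4, `center_scale` 4, `noise_sd` 0.2, rescaling in
(0.9, 1.1).

Design choices worth knowing:

* **Distributions are Gaussian** for cluster spread and noise — the
  simplest model producing the intended geometry. The generator makes no
  attempt at scRNA-seq count realism (no dropout, library-size variation,
  or negative-binomial noise); conclusions from it concern the geometry of
  multitask clustering, not count-level properties of real data.
* **True centers are rejection-sampled** until mutually separated (min
  pairwise distance ≥ `center_scale`) *and* spread along every marker
  coordinate (per-coordinate sd ≥ `center_scale`/2, spread ratio between
  coordinates ≥ 0.7). Without the spread conditions, a draw can put nearly
  all center variance on one marker; the other marker then genuinely
  carries little signal and "marker recovery" is not a meaningful ask of
  any method — the model's optimum legitimately prefers quantizing the one
  strong marker.
* **Rotations are bounded-angle** by default: a composition of random
  Givens rotations over the mixed coordinates with angles uniform in
  $\pm$`max_angle` (default $\pi/12$). A fully Haar-uniform rotation
  (available via `rotation = "haar"`) makes the mixed coordinates
  statistically exchangeable — under it, *no* method can prefer the planted
  markers over the mixed noise gene more than 1 time in 3, so planted-marker
  recovery is only a well-posed benchmark under partial rotation. The
  bounded rotation still misaligns the domains enough that pooled k-means
  visibly degrades (mean ARI ≈ 0.85 vs ≈ 1.0 for the multitask fit in the
  shipped experiment).

## Evaluation

`clustering_error()` is the misclassification fraction after optimally
matching predicted to true clusters on the confusion matrix
(maximum-weight bipartite matching; with unequal cluster counts the
unmatched clusters count fully as errors). `adjusted_rand_index()` is the
Hubert–Arabie chance-corrected index. Both are verified in the tests
against brute-force oracles (all $k!$ matchings; the closed-form ARI
formula).

## Preprocessing

The filters mirror standard scRNA-seq practice on log2(FPKM+1) matrices:
`log_transform()` ($\log_2(x+1)$), `filter_low_expression_genes()` (pooled
mean below 1.5, strict), `filter_cells_min_genes()` (fewer than 2000
expressed genes), `filter_uniform_genes()` (constant within any single
domain), `filter_genes_min_cells()` (detected in fewer than 3 cells).
"Expressed" means strictly positive; all boundaries are strict
inequalities, so values exactly at a threshold survive. Every filter
returns a log that reconciles the before/after dimensions, and filters are
idempotent. `exclude_genes_iterative()` implements the confounder loop:
fit, and while any top-ranked selected marker is on an exclusion list
(e.g. cell-cycle genes), drop those genes and refit.

## Problem sizes in the shipped tests and experiment

The acceptance experiment runs 20 replicates of the default simulation
(100 cells × 1000 genes each), fitting at $\lambda \in \{2, 10, 20\}$ with
10 restarts, against pooled and separated k-means — about a minute of
compute. Property tests use small random instances (up to $m = 50$,
$n \le 75$ cells, $D \le 3$) where brute-force oracles (exhaustive subset
search, permutation matching, numerical minimizers) are exact and fast.

## Known limitations

* One global $k$ for all domains: a cell type absent from one population
  forces that domain to split another cluster. Per-domain $k^{(d)}$ is out
  of scope.
* Hard assignments only; no soft/fractional memberships.
* Cluster correspondence across domains is positional (column $j$ matches
  column $j$), maintained by the $\alpha$ coupling and the shared pooled
  initialization, not by an explicit matching step. With $\alpha = 0$ and
  separate initializations the columns would be arbitrary.
* The $\lambda$-constraint is exact cardinality, not a sparsity penalty;
  $\lambda$ must come from prior knowledge.
* The empty-cluster split is a heuristic repair; it can locally increase
  the objective (see Convergence above).
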