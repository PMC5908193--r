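# scVDMC — variance-driven multitask clustering of single-cell RNA-seq data

Clustering tool for studies that profile **several related single-cell
populations** — biological replicates, multiple donors, or patient/control
pairs — where the same cell types recur in every population but technical
biases and sample-specific biology shift their expression. Pooling all cells
and clustering once lets those shifts dominate (cells cluster by sample
origin); clustering each sample separately wastes the shared signal and
fails at small sample sizes. This package clusters all populations jointly,
with population-specific cluster centers, and selects the shared marker
genes *inside* the clustering objective.

## The model

For domains (populations) `d = 1..D` with expression matrices
`X(d) (m genes × n(d) cells)`, the method estimates per-domain centers
`U(d) (m × k)`, one-hot assignments `V(d) (n(d) × k)` and one global binary
marker-selection vector `B` with `sum(B) = λ`, minimizing

    ½ Σ_d ‖D_B (X(d) − U(d) V(d)ᵀ)‖²_F          reconstruction on selected genes
    − w Σ_d Bᵀ Var(U(d))                          reward within-domain center separation
    + α Σ_{i,j} B_i Var(Y(i,j))                   penalize cross-domain center disagreement

where `D_B = diag(B)`, `Var(U(d))` is the vector of per-gene population
variances across the `k` centers, and `Y(i,j)` stacks center entry `(i,j)`
across the `D` domains. The objective is solved by alternating exact block
updates: a sort solves the cardinality-constrained selection, nearest-center
assignment solves `V(d)`, and one `k × k` linear system per domain solves
all center rows at once. A Gershgorin bound on the center-subproblem Hessian
(`w_upper_bound_implemented()`) tells how large the separation weight `w`
may be; `suggest_w()` returns a safe default. The number of clusters is
chosen with an elbow scan of the within-cluster sum of squares, and `α` with
a center-disagreement diagnostic. See the methods vignette
(`vignettes/scvdmc-methods.Rmd`) for the full account.

Also included: pooled and separated k-means baselines with variance-based
gene selection, best-matching error and adjusted Rand index metrics,
standard preprocessing filters (log2(x+1), low-expression genes, low-count
cells, uniform genes, rarely detected genes, iterative confounder-gene
exclusion), a synthetic multi-population generator with planted markers,
readers/writers for dense TSV and MatrixMarket/10x-style matrices, and a
command-line interface (`inst/cli/scvdmc.R`).

## Worked example

Simulate the canonical benchmark — three populations (33/33/34 cells),
1000 genes, four cell types separated only in two planted marker genes,
corrupted per population by rotation, rescaling and noise — then fit with
`k = 4`, `λ = 2`:

```r
library(scVDMC)

sim <- simulate_multidomain(simulation_config(seed = 11))
ds  <- sim$dataset
ds
#> <multidomain_dataset> 1000 genes, 3 domain(s): domain_1 (n=33), domain_2 (n=33), domain_3 (n=34)

w <- suggest_w(ds, k = 4, alpha = 1)   # 2.444: 75% of the c_min=2 PSD bound
fit <- scvdmc(ds, k = 4, lambda = 2, w = w, alpha = 1, seed = 11, nstart = 10)
fit
#> <scvdmc_fit> k = 4, lambda = 2, w = 2.444444, alpha = 1
#>   3 domain(s), 3 iteration(s), converged
#>   final objective: -156.8104
#>   markers: gene_0001, gene_0002

evaluate_clustering(fit$labels, sim$truth$labels)
#>     domain   n error ari
#> 1 domain_1  33     0   1
#> 2 domain_2  33     0   1
#> 3 domain_3  34     0   1
#> 4   pooled 100     0   1
```

The fit recovers both planted markers (`gene_0001`, `gene_0002`) and every
cell's type exactly (best-matching error 0, adjusted Rand index 1, per
domain and pooled). Pooled k-means on the same data reaches mean ARI 0.905
— the rotation and rescaling misalign the populations enough that pooling
mixes cell types, which is precisely the gap the multitask coupling closes.

On real data, start from `read_domain()` (dense TSV or MatrixMarket with
gene/barcode sidecars), `align_gene_index()` to intersect gene indices, the
`filter_*` functions for cleaning, `elbow_scan()` to pick `k`, and
`alpha_scan()` to pick `α`. `write_results()` exports assignments, ranked
markers, centers, the objective trace and a JSON run report.

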