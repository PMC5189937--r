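# sctipping

Early-warning analysis of critical state transitions (tipping points) in
single-cell expression ensembles.

## The problem

When a multipotent progenitor commits to a lineage, the attractor that
stabilizes its gene expression program must first destabilize and
vanish — a bifurcation of the gene-regulatory network's dynamics.
Classical early-warning statistics for such transitions (rising
fluctuation amplitude, slowing relaxation, growing autocorrelation)
need a continuous time series of the system state, which destructive
single-cell profiling cannot provide. This package is for
transcriptomics researchers who instead have *snapshot ensembles*:
an `n` cells × `m` genes matrix **X**(t) at a few discrete time points
along a differentiation time course.

## The index

From each snapshot the package computes the critical-transition index

```
I_C(t) = ⟨|R(g_i, g_j)|⟩ / ⟨R(S^k, S^l)⟩
```

the mean absolute Pearson correlation over all gene-vector pairs,
divided by the mean Pearson correlation over all cell-state-vector
pairs. Approaching a tipping point, cells diversify (denominator falls)
and align along the exit direction (numerator rises), so `I_C` rises
toward a maximum near the critical transition. The package adds
bootstrap standard errors, a one-sided permutation test of the index
against marginal-preserving randomized data, gene-subsampling
robustness, per-cell dispersion, and profile dissimilarity (1 − R with
resampling uncertainty).

Around the index sit the working parts of a full pipeline:

* **qPCR preprocessing** — raw quantification cycles with technical
  replicates → LOD filtering, triplicate medians, delta-Cq
  normalization to log2 expression, floor imputation of non-detects.
* **State space** — PCA projection of all time points in one frame and
  a quasi-potential landscape `U = −log(p + 1)` over smoothed cell
  density (Gaussian filter, σ = 2 grid cells by default).
* **Bifurcation simulator** — a stochastic two-master
  mutual-inhibition/self-activation circuit (Hill exponent 4) with
  linear downstream readouts, driven through a pitchfork-like
  bifurcation by a slowly stepped control parameter; includes attractor
  classification (progenitor / intended / rebellious / undecided),
  relaxation-time measurement against the Jacobian-eigenvalue
  prediction, and a pinned 500-cell benchmark scenario.

## Worked example

```r
library(sctipping)

ens <- default_scenario(seed = 1)   # 500 cells x 12 genes, 4 snapshots
print(ens)
#> simulation_ensemble: 4 snapshots x 500 cells x 12 genes
#>   t0 (mu = 1.000): progenitor=500
#>   t1 (mu = 0.880): intended=6, progenitor=477, undecided=17
#>   t2 (mu = 0.820): intended=173, progenitor=282, undecided=45
#>   t3 (mu = 0.700): intended=467, rebellious=26, undecided=7

X <- as_expression_matrix(ens)
ic_timecourse(X, B_sem = 0)
#>   time_point n_cells n_genes mean_cell_cell mean_abs_gene_gene        ic sem
#> 1         t0     500      12      0.9489981          0.1437414 0.1514664  NA
#> 2         t1     500      12      0.9018697          0.4923434 0.5459140  NA
#> 3         t2     500      12      0.7193869          0.8818209 1.2257950  NA
#> 4         t3     500      12      0.8016708          0.8748595 1.0912951  NA
```

Reading the table: while the control parameter ramps toward the
bifurcation (t0 → t2), the average cell–cell correlation drops from
0.95 to 0.72 (the ensemble spreads in the flattening attractor basin)
and the average absolute gene–gene correlation climbs from 0.14 to 0.88
(cells align along the exit direction). Their ratio `I_C` rises
eight-fold and peaks at t2 — the snapshot just above the tipping point —
then relaxes at t3 once cells have committed. At t3, 26 of 500 cells
(5.2%) sit in the *rebellious* attractor, the fate opposite to the one
the instructive bias favored. Significance of the elevated index:

```r
t2 <- subset_cells(X, cells = grepl("^t2_", cell_ids(X)))
permutation_null(t2, B = 199, seed = 42)
#> permutation null (per-gene permutation across cells, B = 199)
#>   I_C = 1.2258, log I_C = 0.2036, p = 0.005
```

A command-line wrapper with subcommands `preprocess`, `ic`, `simulate`
and `landscape` is installed at
`system.file("cli", "sctipping.R", package = "sctipping")`.

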