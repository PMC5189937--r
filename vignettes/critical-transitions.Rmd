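---
title: "Detecting critical state transitions in single-cell expression ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting critical state transitions in single-cell expression ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctipping)
```

## The model behind the index

A differentiating cell population is treated as a statistical ensemble of
replicate dynamical systems. Each cell carries a state vector
$\mathbf{x}(t)$ of $m$ transcript abundances governed by its
gene-regulatory network (GRN); stable cell types are attractors of that
dynamics, and lineage commitment is a bifurcation: a slowly drifting
control parameter $\mu$ deforms the quasi-potential landscape until the
progenitor attractor flattens and vanishes, and cells drop
discontinuously into a committed attractor.

Two statistical signatures precede that tipping point in the
$n \times m$ snapshot matrix $\mathbf{X}(t)$:

* the mean Pearson correlation between cell state vectors,
  $\langle R(S^k, S^l)\rangle$, **falls** — the weakening restoring force
  lets noise spread the cells out;
* the mean absolute Pearson correlation between gene vectors,
  $\langle |R(g_i, g_j)|\rangle$, **rises** — cells align along the exit
  direction (the reaction coordinate), so previously independent genes
  co-vary.

Their ratio is the critical-transition index

$$
I_C(t) \;=\; \frac{\langle |R(g_i, g_j)| \rangle}{\langle R(S^k, S^l) \rangle},
$$

which rises toward a maximum as the ensemble approaches the transition.
Only the *change* of $I_C$ along a time course is meaningful; its
absolute value depends on the gene panel. The numerator uses absolute
values because both correlated and anti-correlated gene pairs signal
coordination; the denominator is signed, exactly as the index is
defined. The theory asserts the rise toward the transition, not a fall
afterwards (post-transition ensembles straddle several attractors and
the ergodicity assumption lapses), so all tests in this package assert
the rise only.

### Assumptions

* Cells are independent replicates of the same dynamical system — no
  cell–cell communication, no population structure other than the
  metadata groups.
* The gene panel participates in (or at least reflects) the transition;
  a panel of purely bystander genes dilutes the signal.
* The ensemble sits in (or near) a quasi-steady state at each sampling
  time, so the snapshot stands in for the unobservable time series.
* The cell–cell mean must be positive: ensembles with no common
  orientation make the ratio meaningless, and `compute_ic()` refuses
  them rather than returning a sign-flipped index.

## Uncertainty, significance, robustness

**SEM.** Cells are the sampling unit, so the standard error of $I_C$ is
a bootstrap over cells (resample with replacement, recompute, report the
replicate standard deviation; `B_sem = 200` by default).

**Permutation test.** `permutation_null()` destroys the correlation
structure by permuting each gene's values independently across cells,
preserving every gene's marginal. Under this null the gene–gene average
collapses to its sampling floor while the cell–cell average (driven by
the static gene-mean profile) stays high, so the null index sits *below*
the observed one whenever real coordination exists. The test statistic
is therefore the one-sided $\log I_C$ — larger is more extreme, the
direction the index moves toward a transition. An absolute two-sided
deviation statistic would invert the test on structured data, because
the null itself deviates strongly downward from 1. The p-value uses the
add-one correction $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1+B)$
and is conservative (super-uniform) by construction.

**Gene subsampling.** `gene_subsample_robustness()` recomputes $I_C$ on
random gene subsets. When the panel shares a transition signal, the
spread of $I_C$ across draws shrinks as the subset grows — the behavior
expected when scaling from tens to thousands of genes.

## Preprocessing single-cell qPCR data

Raw quantification cycles (Cq; lower = more transcript) pass through:

1. **Replicate collapsing** — technical replicates at or beyond the
   assay's limit of detection (LOD) are discarded; the median of the
   survivors is kept; all-failing (cell, gene) pairs become non-detects.
   Filtering precedes the median because the LOD is defined per
   replicate (positive amplification of the most diluted standard).
2. **Delta-Cq normalization** — per cell, the reference is the mean Cq
   of its detected housekeeping (control) genes; expression is
   `reference − Cq`, so one PCR cycle is one log2 unit. Cells with no
   detected control gene, or no detected target gene at all, are
   dropped with a counted message.
3. **Non-detect imputation** — non-detects are imputed at
   `reference − (LOD + floor_margin)` (default margin 1 cycle), i.e.
   just below the least detectable level, and flagged in a detection
   mask. Imputing (rather than dropping) keeps the correlation matrices
   complete on a consistent cell set; the floor guarantees every imputed
   value sits below every detected value of the same gene in the same
   cell's reference frame.

Control genes are identified by explicit role labels, never by name
matching, and are excluded from all correlation statistics by default
(overridable). Input dialect is comma- or tab-delimited, sniffed from
the header line, with case-insensitive column names — published Cq
tables ship as spreadsheet exports in both flavors.

## State-space visualization

`pca_project()` fits one PCA to all cells concatenated across time
points (per-group fits would make coordinates incomparable). Scaling to
unit gene variance is off by default: delta-Cq units are cycles for
every gene, already comparable. Component signs are fixed by making each
component's largest-magnitude loading positive, so projections are
deterministic.

`quasipotential()` bins the first two coordinates on a `grid_size²`
lattice (default 50, data range padded 10%), smooths the counts with a
Gaussian filter of width `sigma` in grid-cell units (default 2), and
elevates the density to $U = -\log(p + 1)$, placing empty space at base
level 0 and attractors in wells. Smoothed *counts* rather than a
normalized density keep the wells visibly deep. The kernel is truncated
at radius $4\sigma$ and renormalized where the grid boundary clips it,
so total smoothed mass equals the cell count exactly (a tested
invariant). The landscape is a visual guide to attractor structure; it
makes no claim about how the landscape deforms during the bifurcation.

## The synthetic benchmark ensemble

Because the index's claims concern ensembles near a bifurcation, the
package ships a generator whose ground truth is known. The model is the
canonical two-master fate-decision circuit — mutual inhibition plus
self-activation with Hill kinetics (exponent 4, threshold 0.5, unit
production and decay) — with the bifurcation parameter $\mu$ scaling
self-activation:

$$
\dot x = \mu\,\frac{x^4}{S^4 + x^4} + \frac{S^4}{S^4 + y^4} - x + b_x,
\qquad
\dot y = \mu\,\frac{y^4}{S^4 + y^4} + \frac{S^4}{S^4 + x^4} - y + b_y .
$$

At $\mu = 1$ the system is tristable: a central co-expression attractor
(the progenitor) flanked by two committed branches. Lowering $\mu$
annihilates the central attractor in a pitchfork-like bifurcation
(numerically at $\mu_c = 0.7745$ for the symmetric circuit). A small
instructive bias (an extra production term on one master; positive
values feed $x$, negative feed $y$) tilts the pitchfork into its
imperfect form: the favored branch is the *intended* fate, and cells
that reach the other branch — noise beating instruction — are
*rebellious*. With bias 0.04, $\mu_c = 0.8115$. Ten downstream genes
read the masters out linearly with additive noise, giving a 12-gene
panel in which the masters' coordination propagates realistically.

Integration is Euler–Maruyama (default `dt = 0.01`) with additive
Gaussian noise and a reflecting boundary at zero concentration; each
cell consumes its own seeded noise stream (derived per cell and stage),
so ensembles are bit-reproducible and a cell's trajectory does not
depend on how many other cells are simulated. Snapshots are reported as
`log2(value + 1)` expression with attractor labels from nearest-stable-
fixed-point classification (Newton root finding on the master
subsystem; capture radius 25% of the smallest inter-attractor
distance, outside which a cell is *undecided*).

`default_scenario()` pins the study configuration: 500 cells, 12 genes,
bias 0.04, noise 0.08, snapshots at $\mu = 1.00, 0.88, 0.82, 0.70$
(t0–t3, with t2 just above $\mu_c$ and t3 past it), 15 time units per
stage after a 25-unit burn-in. These values were chosen once, as the
smallest configuration that sits clearly in the three regimes
(stable progenitor / near-critical / committed): the noise is small
enough that the progenitor ensemble stays tight (cell–cell correlation
near 0.95) yet large enough that a few percent of cells defect to the
non-intended branch. On this scenario the analysis reproduces the full
early-warning phenomenology — falling cell–cell correlation, rising
gene–gene correlation, $I_C$ maximal at t2, a nonzero rebellious
minority — and the noise-free variant exhibits critical slowing down:
relaxation times match the linearized prediction
$\log(1/\text{threshold})/|\mathrm{Re}\,\lambda_{\max}|$ within a few
percent and grow strictly as $\mu \downarrow \mu_c$.

### What the generator does not emulate

Real single-cell data add layers the benchmark deliberately omits:
technical dropout correlated with expression level, cell-cycle and
cell-size covariates, doublets, batch effects, cell–cell communication,
and GRNs far richer than two masters with linear readouts. Passing
tests on the benchmark therefore demonstrate that the statistics behave
as the theory predicts *when the generating process is a bifurcating
ensemble* — not that any particular real dataset is one.

## Numerical choices

* Pearson correlation of a zero-variance vector is undefined; all its
  pairs are dropped from averages and counted, never substituted by 0
  (which would bias the means toward null).
* Duplication of every cell leaves gene–gene correlations exactly
  unchanged but mixes unit self-pairs into the cell–cell mean
  ($m' = (2m(n-1)+1)/(2n-1)$ by pair counting); the index is exactly
  duplication-invariant only for fully collinear ensembles and
  asymptotically otherwise — tests assert the exact algebra.
* Per-cell CV is computed in a positive affine frame (the matrix is
  shifted so its minimum is +1, shift recorded) with the population
  (divide-by-n) standard deviation; it is a dispersion descriptor, not
  an estimator.
* Profile dissimilarity (1 − R with gene-resampling sd, default 30% of
  genes × 10,000 draws) applies the same gene subset to both profiles
  per draw; zero-variance subsets are redrawn with a cap.
* Fixed points come from damped multi-start Newton iteration on an
  8 × 8 grid over $[0,3]^2$ with finite-difference Jacobians; roots are
  deduplicated at 1e-6 and stability read off the Jacobian eigenvalues.
* Non-convergent relaxation runs are reported right-censored (`Inf`
  with an attribute), not as errors.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely from generated
data at desk scale: the 500-cell pinned scenario (about 7 s to
simulate), 20 seeds for each phenomenology property, 1,000-cell
two-stage ensembles for the bias sweep (integration step 0.02 there,
where only the basin outcome matters), 200 null draws at B = 199 for
p-value calibration, and 1,000 random matrices up to 8 × 8 against the
brute-force correlation oracle. These sizes keep every property
estimate's Monte-Carlo error well inside its asserted margin.

## Worked example

```{r example, eval = FALSE}
ens <- default_scenario(seed = 1)
X <- as_expression_matrix(ens)
ic_timecourse(X, B_sem = 0)
#>   time_point n_cells n_genes mean_cell_cell mean_abs_gene_gene        ic sem
#> 1         t0     500      12      0.9489981          0.1437414 0.1514664  NA
#> 2         t1     500      12      0.9018697          0.4923434 0.5459140  NA
#> 3         t2     500      12      0.7193869          0.8818209 1.2257950  NA
#> 4         t3     500      12      0.8016708          0.8748595 1.0912951  NA
```

The index rises eight-fold from t0 to t2 (the snapshot just above the
tipping point) while the cell–cell mean falls and the gene–gene mean
rises, then relaxes as cells settle into the committed attractors.

## Known limitations

* The index needs tens of cells per group and a positively oriented
  ensemble; heterogeneous pools straddling several attractors can push
  the denominator toward zero and inflate the index.
* The permutation null preserves gene marginals only; heavy-tailed
  technical noise shared across genes (e.g. per-cell capture
  efficiency) is not removed by it and should be normalized out first.
* The simulator's attractor labels come from the master subspace alone;
  downstream genes are diagnostic readouts, not dynamical players.
* The landscape visualization compresses all time points into one
  static surface and should not be read as the bifurcating potential.
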