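---
title: "Differential network enrichment analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential network enrichment analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnea)
```

## Overview

`dnea` compares the *connectivity* of the metabolome or lipidome between
two biological conditions, not just the per-metabolite abundances.  The
pipeline has three stages:

1. **Joint network estimation.** Both conditions' partial-correlation
   networks (PCNs) are estimated simultaneously by stability-selected
   nodewise regression with a cross-condition penalty, so edges shared
   by the conditions borrow strength while condition-specific
   (differential) edges can still be detected.
2. **Consensus clustering.** The union of the two networks is clustered
   into stable, densely connected subnetworks; these data-driven modules
   replace curated pathways, which cover lipids and secondary
   metabolites poorly.
3. **Topology-aware enrichment.** Each subnetwork is tested for
   differential enrichment with a mixed linear model whose design is
   the network influence matrix, so both mean shifts and connectivity
   changes contribute to the statistic.

Feature aggregation (for panels with many near-redundant species),
balanced subsampling (for grossly imbalanced group sizes), and
group-lasso association of subnetworks with a continuous phenotype
extend the core pipeline.

## Partial correlation networks and joint estimation

For a precision matrix $\Omega = \Sigma^{-1}$, the partial correlation
between features $i$ and $j$ given all others is
$\rho_{ij} = -\omega_{ij} / \sqrt{\omega_{ii}\,\omega_{jj}}$.  An edge
$i\!-\!j$ is present when $\rho_{ij} \neq 0$.  Nodewise (neighborhood)
regression estimates the edge set of column $j$ from a sparse regression
of $x_j$ on all other columns.

With two conditions the two regressions for the same predictor are
coupled.  For node $j$ the package minimizes

$$
\sum_{k=1}^{2} \frac{1}{2 n_k}\,\bigl\lVert x^{(k)}_j - X^{(k)}_{-j}
b^{(k)} \bigr\rVert_2^2
  + \lambda \sum_{m \neq j} \Bigl[ \alpha\, \lVert (b^{(1)}_m, b^{(2)}_m)
  \rVert_1 + (1-\alpha)\sqrt{2}\, \lVert (b^{(1)}_m, b^{(2)}_m)
  \rVert_2 \Bigr],
$$

a sparse-group penalty over the condition pair.  The 2-norm term selects
shared structure jointly; the elementwise term (weight `mix`
$= \alpha$, default 0.5) permits within-pair sparsity so that an edge
can appear in one condition only.  A pure 2-norm group penalty would
select each edge in *both* conditions or neither — the component
coefficients of an active group are almost never exactly zero — which
would make differential edges undetectable by construction; this is why
the elementwise term is part of the default.  Supports are symmetrized
per condition by the AND rule (an edge needs support from both endpoint
regressions), which is conservative and stabilizes the downstream
clustering.

The solver is block coordinate descent with majorize–minimize group
updates (the group's quadratic term is majorized by its largest
eigenvalue, giving a closed-form sparse-group proximal step), written in
C++.  The same solver implements the phenotype group lasso.

### Penalty selection and stability selection

The penalty $\lambda$ is chosen once, on the full standardized data, as
the grid value minimizing a BIC-type score
$\sum_k \sum_j [\, n_k \log(\mathrm{RSS}_{jk}/n_k) + \log(n_k)\,
\mathrm{df}_{jk} \,]$ over a default grid of 20 log-spaced values from
$\lambda_{\max}$ (the smallest penalty with empty supports, computed
exactly from the sparse-group entry condition) down to
$0.01\,\lambda_{\max}$.  Holding $\lambda$ fixed across subsamples is
standard stability-selection practice; per-iteration reselection is
available (`lambda_per_iteration = TRUE`) but slower and not the
default.

Stability selection repeats the fit on `n_iterations` (default 500)
random subsamples — 50% of each group without replacement, or the
balanced draw below — and records per condition the selection frequency
$P_k(i,j)$ of every edge.  Edges with $P_k(i,j) > \tau$ (default 0.9)
form the condition-$k$ network.

### Balanced subsampling for imbalanced designs

When one group is much larger (say 100 vs 674 samples), the larger
group's network is estimated with far more power and comes out much
denser, which confounds the comparison of connectivity.  With $n_{\min}$
the smaller group's size, each iteration draws

* $\mathrm{round}(\alpha\, n_{\min})$ samples from the larger group
  without replacement ($\alpha = 1.3$), and
* $\mathrm{round}(\beta\, n_{\min})$ distinct samples from the smaller
  group plus $\mathrm{round}((1-\beta)\, n_{\min})$ resampled ones
  ($\beta = 0.9$), keeping some randomness in the smaller group.

Rounding is half-away-from-zero so the documented sizes are exact for
the usual parameter values.  The recommended operating point
$\alpha = 1.3$, $\beta = 0.9$, $\tau = 0.9$ is the default.  On a
60-vs-600 synthetic design this reduces the larger group's edge count at
$\tau$ relative to plain 50% subsampling; the effect is informative only
when the smaller group sits near its detection boundary (the package's
imbalanced validation scenario uses within-block partial correlations of
0.25 for this reason — with strong signal both settings saturate at the
true edge set and the comparison ties).

### Weighted re-estimation of partial correlations

On the thresholded support, each node's neighborhood regression is
re-fit with per-predictor penalty factors $1 - P_k(i,j)$ — the selection
probabilities act as weights, so fully stable edges are fit by (nearly)
least squares.  The regression coefficients and residual variances are
assembled into a precision estimate
($\hat\omega_{jj} = 1/\hat\sigma_j^2$,
$\hat\omega_{ij} = -\hat\beta_{ij}\hat\omega_{jj}$, symmetrized by
averaging) and converted to partial correlations by the closed form
above.  Off-support entries are exactly zero.  A node of degree
$\geq n_k - 1$ makes the refit unidentifiable and is an error.

## Consensus clustering

Clustering operates on the union graph (edges present in either
condition, weight $\max_k |\rho^{(k)}_{ij}|$), so differential edges
cannot split a subnetwork by construction.  Each of `n_runs` (default
50) runs keeps a random 80% of the union edges and applies weighted
Louvain modularity maximization; the consensus matrix $C$ records
co-clustering frequencies.  The final partition refines an
average-linkage tree on $1 - C$ at the shallowest cut in which every
cluster's mean internal consensus reaches 0.5, then splits each cluster
into connected components of $\{C > 0.5\}$.  The shallowest-sufficient
cut is used deliberately: the naive rule "maximize mean within-cluster
consensus" is degenerate (it always prefers shattering the graph into
tight pairs).  Components smaller than `min_size` (default 5) are left
unassigned — singletons and tiny fragments are not meaningful modules —
and subnetwork ids are ordered by descending size.

Chain-like modules (sparse blocks) are often split into stable halves
rather than recovered whole: Louvain legitimately partitions a long
weak chain, and the consensus machinery preserves whatever is stable
across perturbations.  Clique-like modules are recovered exactly.

## Topology-aware enrichment (NetGSA-style)

Each condition network is converted to an influence matrix.  The
undirected graph is oriented by a fixed node ordering (input feature
order): $A_k$ carries edge weights from earlier to later nodes
(strictly lower triangular after ordering), and
$\Lambda_k = (I - A_k)^{-1}$ accumulates each node's upstream
propagated effects.  If the symmetric weight matrix has spectral radius
$\geq 1$ it is rescaled to $0.95/\text{spectral radius}$ first.  Rows
are normalized to unit Euclidean norm; an empty network gives
$\Lambda = I$.

The mixed linear model per sample in condition $k$ is
$Y = \Lambda_k \beta_k + \Lambda_k \gamma + \varepsilon$ with random
effect $\gamma \sim N(0, \sigma^2_g I)$ and noise
$\varepsilon \sim N(0, \sigma^2_\varepsilon I)$, so
$\mathrm{Var}(Y) = \sigma^2_g \Lambda_k \Lambda_k' +
\sigma^2_\varepsilon I$.  The two variance components are shared across
conditions and estimated by REML, profiled in the eigenbasis of
$\Lambda_k \Lambda_k'$ (the covariance is diagonal there, so the
deviance is a cheap sum; optimization is quasi-Newton with a
Nelder–Mead fallback for the flat ridge that arises when the components
are unidentifiable, e.g. $\Lambda = I$).

For a subnetwork $S$ with indicator $\ell_S$, the test is
$H_0\!: \ell_S'\Lambda_1\beta_1 = \ell_S'\Lambda_2\beta_2$ — the
indicator propagated through the influence matrices.  With the GLS
estimate $\hat\beta_k = \Lambda_k^{-1}\bar Y_k$ the contrast reduces to
$\ell_S'(\bar Y_2 - \bar Y_1)$ with model variance
$\sum_k \ell_S' \hat V_k \ell_S / n_k$; degrees of freedom are
Satterthwaite-approximated from the REML Fisher information (with a
pseudo-inverse when the two components are confounded).  Two limit
behaviors pin the construction down:

* $\Lambda_1 = \Lambda_2 = I$ recovers the classical pooled two-sample
  contrast on subnetwork means exactly;
* with *shared* baseline effects $\beta$ but different topologies, the
  propagated means $\Lambda_k \beta$ differ, so connectivity changes
  alone drive rejections — the situation where individual metabolites
  are not significantly differential but the subnetwork is.

That second behavior is also how the package's power validation is
simulated: data are generated under the model above with a common
$\beta$ and edges present in one condition only.  Note that if two
groups have *literally identical mean vectors* (plain multivariate
normal sampling with equal means), no mean-contrast statistic has
power; the differential-edge phenomenon requires shared baseline
effects propagated through different networks.

P-values are two-sided and adjusted across subnetworks by
Benjamini–Hochberg; subnetworks of fewer than 2 nodes are skipped with
a warning.  Per-feature statistics in the node table are Welch t-tests
with BH adjustment, with the sign of the group-2 minus group-1 mean as
the direction.

## Preprocessing and feature aggregation

Intensities are natural-log transformed (any fixed base only rescales
autoscaled data, so downstream results are invariant) and autoscaled
per feature to mean 0, sample standard deviation 1 (denominator
$n - 1$).  Missing values are rejected at import: no imputation is
defined here, so users must pre-impute.

Aggregation addresses panels where features far outnumber samples.  The
similarity measure is the *correlation profile distance*
$d(i,j) = 1 - \mathrm{cor}(r_i, r_j)$, where $r_i$ is feature $i$'s
vector of Pearson correlations with all other features, excluding
entries $i$ and $j$ themselves (self-correlations are constant 1 and
dilute the profile).  It is computed on log-transformed,
*non-autoscaled* data and requires at least 4 features.  Three modes:

* **data-driven** — complete-linkage hierarchical clustering on
  $d$, cut at the `tolerance`; complete linkage guarantees every merged
  pair is within the tolerance.
* **knowledge-driven** — features sharing a chemical class label merge
  unconditionally; unlisted features stay singletons.
* **hybrid** — data-driven merging within each class, so only
  chemically similar features with similar profiles merge; the result
  always refines the knowledge partition.

Merged features take the per-sample *median* of their members;
aggregated ids are the class label (knowledge modes) or the
concatenation of member ids (data mode), singletons keeping their
original id.  `tolerance_scan()` reports the effective feature count
over a tolerance grid (non-increasing by construction) and recommends
the smallest scanned tolerance with features $\leq$ samples.

## Group-lasso phenotype association

Subnetworks are ranked by association with a continuous phenotype
(e.g. gestation-normalized infant birth weight) by the group lasso

$$
\min_\beta \; \frac{1}{2N}\bigl\lVert y - \textstyle\sum_l X_l \beta_l
\bigr\rVert_2^2 + \lambda \sum_l w_l \lVert \beta_l \rVert_2,
$$

with whole subnetworks entering or leaving together.  The group weights
are $w_l = \sqrt{p_l}$ by default — the convention of standard
group-lasso solvers — with literal $w_l = p_l$ available
(`weights = "literal"`).  The path is 100 log-spaced values from
$\lambda_{\max} = \max_l \lVert X_l' y\rVert_2 / (N \sqrt{p_l})$ down
to $10^{-3}\lambda_{\max}$.  A group's *entry penalty* (the largest
path value at which its block is nonzero) measures association
strength; over 500 subsamples of 80% of the samples the package reports
the median entry penalty, the resulting rank, the frequency of entering
within the top quartile of the path, and the frequency of entering
first.  Enrichment significance is *not* an input to this ranking.

One calibration subtlety: because the path is anchored at
$\lambda_{\max}$ of the same data, the spuriously best group of a pure
noise dataset enters near the top of the path on essentially every
resample — within one dataset, "enters early" is not a null-calibrated
quantity.  Across fresh noise datasets, however, no fixed group is
persistently the first entrant; that is the property the tests check.

## Synthetic data generator

`simulate_two_group()` defines the validation conditions: features are
organized into precision blocks, group 2 loses the differential blocks'
edges and gains mean shifts on selected nodes, and draws are
exponentiated so the pipeline's log transform recovers Gaussianity.
Within-block topology is a *chain* (tridiagonal precision) by default
because it realizes the requested partial correlation exactly;
equicorrelated "full" blocks are limited to
$\rho < 1/(\text{block size}-1)$ (a full block of 10 cannot reach
$\rho = 0.3$) and error when infeasible.  Blocks whose minimum
eigenvalue falls below 0.1 are diagonally loaded with a warning, which
shrinks the realized partial correlations.  The optional phenotype is
the sum of one block's Gaussian-scale features plus normal noise.

The reference validation design is p = 50 features in 5 chain blocks of
10 at partial correlation 0.3, 300 samples per group, one differential
block and a 1-sd mean shift on 5 nodes; presets mimic a small
imbalanced metabolomics cohort (163 features, 30 vs 41) and a large
imbalanced cohort (200 features, 100 vs 674).  What the generator does
*not* emulate: instrument noise and heteroscedasticity, batch effects,
missingness, and non-Gaussian abundance distributions — passing tests
demonstrate correctness of the estimators under the stated model, not
robustness to those artifacts.

## Numerical choices and problem sizes

* Coordinate-descent convergence: max coefficient change below 1e-6
  (support estimation) or 1e-9 (final group-lasso fits), KKT residuals
  verified to 1e-6 in the tests.
* Stability selection defaults to 500 iterations; the validation suite
  uses 100–500 depending on the scenario, sizes chosen so the full
  suite completes in about a minute on one CPU.
* REML uses log-parametrized L-BFGS-B with a Nelder–Mead fallback;
  Satterthwaite covariance uses a singular-value pseudo-inverse with a
  1e-10 relative cutoff.
* Ties in consensus component ordering break by smallest node index;
  subnetwork ids are 1-based, 0 meaning unassigned.
* All randomness flows through R's RNG; pipeline stages derive their
  seeds from the single run seed, so one integer reproduces a run
  bit-for-bit.

## Known limitations

* Exactly two conditions; no covariate adjustment inside the model
  (adjust upstream), no survival or binary phenotypes in the
  association module.
* The node ordering of the influence matrix is the input feature order;
  a different ordering changes $\Lambda$ (not the tested contrast's
  null behavior).  It is exposed as an argument.
* Selection probabilities of borderline edges carry data-level
  asymmetries between exchangeable groups; interpret $P$ near the
  threshold with care.
* Consensus clustering may split sparse chain-like modules into stable
  halves; interpret subnetwork boundaries together with the edge list.
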