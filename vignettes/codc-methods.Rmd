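---
title: "Copula-based differential coexpression: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copula-based differential coexpression: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(codc)
```

## The model

Classical differential-coexpression scores compare a gene pair's
*correlation coefficients* between two conditions,
$\mathrm{DC}_{ij} = |\rho_{ij}^{(1)} - \rho_{ij}^{(2)}|$. A single
coefficient, however, compresses the whole dependence structure into one
number: it misses changes in the *shape* of the dependence and, when used
for ranking, prefers a pair moving from $0.2$ to $0.7$ (score $0.5$) over a
pair flipping from $-0.2$ to $+0.2$ (score $0.4$), although the sign flip
is arguably the more interesting biology.

`codc` instead compares the pair's *joint distributions*. By Sklar's
theorem any bivariate distribution factors into its two marginals and a
copula $C:[0,1]^2\to[0,1]$ carrying all the dependence. With unknown
marginals the natural estimate is the empirical copula: transform each
profile to its scaled ranks (pseudo-observations, `pseudo_observations()`),

$$\hat F(y) = \tfrac{1}{m}\textstyle\sum_j 1\{y_j \le y\},$$

and count lower-left quadrants,

$$\hat C(u, v) = \tfrac{1}{m}\textstyle\sum_j
  1\{\hat F_1(y_{1j}) \le u,\; \hat F_2(y_{2j}) \le v\}.$$

The differential-coexpression score of a pair is the two-sample
Kolmogorov–Smirnov distance between its tumor-condition and
normal-condition empirical copulas:

$$\mathrm{DC}(g_i, g_j) =
  \sup_{u,v}\ |\hat C^{\mathrm{tumor}}(u,v) - \hat C^{\mathrm{normal}}(u,v)|.$$

Because ranks are invariant under strictly increasing transforms, the score
is *exactly* unchanged by any per-gene monotone rescaling (log, power,
affine) of the data — the property that makes it robust to normalization
choices and to noise that preserves ordering. For strictly *decreasing*
transforms applied identically to both conditions the score can only grow;
both properties are enforced as exact regression tests.

## Computing the supremum

Both copula estimates are lower-quadrant step functions, so the supremum of
their difference is attained on the product grid of the pooled jump
coordinates. The default evaluator (`eval_mode = "pooled"`) computes both
CDFs on exactly that grid with a two-dimensional cumulative histogram
($O(m + g^2)$) and is therefore exact, not approximate. Evaluating only at
the observed pseudo-observation *pairs* — a tempting shortcut — can miss
the attaining corner and demonstrably breaks the decreasing-transform
inequality, which is why it is not offered. A regular-lattice mode
(`"grid"`) exists as an independent cross-check; it agrees with the exact
sup to within grid resolution.

One consequence deserves emphasis: since every copula lies between the
Fréchet–Hoeffding bounds $\max(u+v-1,0) \le C \le \min(u,v)$, whose
pointwise gap peaks at $1/2$, the bivariate sup-distance between *any* two
copulas is at most $0.5$ (attained in the limit by a comonotone vs a
countermonotone pair — an executable test in this package). Detection
thresholds such as $0.56$ or $0.6$, which practitioners have used with this
method, are only meaningful on the scale of the classical one-dimensional
two-sample K–S statistic applied to the two vectors of copula values (the
`d` statistic of `ks.test`), which ranges over $[0,1]$. That reading is
available as `eval_mode = "values_1d"`; the recovery experiment uses it so
that the conventional $0.6$ threshold selects a nonempty set. The two
scales order pairs very similarly; only absolute thresholds differ.

The decreasing-transform inequality holds exactly when the two conditions
have equal sample counts (the matched-pair design guarantees this); with
unequal counts the two pseudo-observation grids differ and the inequality
holds only up to $O(1/m)$.

## Preprocessing

Raw counts pass through three steps, each a common practice for UMI-style
RNA-seq matrices:

* `filter_low_expression()` keeps genes with count $> 2$ in at least $4$
  samples (both configurable; the inequality is strict).
* `normalize_counts()` scales each sample by its total and multiplies by
  the median total, so all normalized samples share the median library
  size.
* `select_variable_genes()` ranks genes by dispersion (variance/mean)
  standardized within equal-occupancy mean-expression bins. The binning
  (default 20 bins) and the median/MAD standardization are robustness
  choices: dispersion grows with expression, and MAD-based scaling keeps a
  single outlying gene from distorting its bin. When a bin's MAD is zero
  the mean absolute deviation is used, and a zero-mean gene has dispersion
  defined as 0. Default selection size is 2000 genes.
* `log2_fold_change()` (pseudocount 1 by default) is provided as the
  transcriptional-response representation of the paired design. The copula
  score itself is computed on the per-condition matrices, because the score
  is defined on the tumor and normal profiles separately; the fold-change
  matrix is exposed for visualization and downstream feature building.

## Modules, eigengenes, enrichment

The score matrix converts to a dissimilarity $d = 1 - \mathrm{DC}$
(`copula_distance_matrix()`), which average-linkage (UPGMA) clustering cuts
into modules (`detect_modules()`). The cut is an explicit user parameter —
either a module count `k` or a dendrogram height; published module counts
on real cohorts are dataset-specific settings, not defaults. Modules
smaller than `min_size` (default 5) are merged, smallest first, into the
nearest cluster by average inter-cluster distance; the merge rule is ours
and is deterministic.

`module_eigengene()` summarizes a module as the leading principal component
of the members' standardized profiles (unit norm, sign aligned with the
mean member profile — the usual coexpression-network convention; the sign
is otherwise arbitrary). Constant genes are dropped from the PCA with a
warning. `eigengene_network()` correlates eigengenes within each condition
separately and composes the display matrix with normal correlations above
the diagonal and tumor correlations below — sign flips across the diagonal
are module-level differential coexpression.

Module annotation is deliberately database-free: gene sets arrive as GMT
files (`read_gmt()`), the universe defaults to the genes actually scored
(not the genome — using the genome would inflate every p-value), and
`hypergeom_enrich()` reports the upper-tail hypergeometric p-value with
Benjamini–Hochberg correction across all tests performed. The descriptive
`pathway_score()` is the fold enrichment $n/m$, with $n$ the fraction of
the module occupied by pathway genes and $m$ the pathway's background rate
in the universe. The phrase "fraction of the pathway genes" admits a second
reading — the fraction of the *pathway* captured by the module — kept
behind `mode = "set_fraction"`. `ccdf_pathway_scores()` summarizes a run by
how often a module's *best* score clears a threshold; the per-module
reduction to the maximum is our choice of aggregate.

## The simulation toolkit

`simulate_paired_expression()` draws each gene i.i.d. Gaussian per
condition, except for genes named in `pair_specs`, which are drawn jointly
with a controlled — by default *exactly realized* — sample correlation per
condition (`correlated_pair()`, built on `MASS::mvrnorm(empirical = TRUE)`).
Means and variances are free per gene and condition; since the score is
rank-based, they are immaterial to it, and the defaults are standard normal
profiles. The default cohort size is 51 matched pairs per condition, a
typical matched tumor/normal cohort. Ground truth — pairs with
$|\rho^{(n)}-\rho^{(t)}| > 0.5$ *and* opposite correlation signs — is fixed
on the clean draw before any noise is added.

What the generator emulates: paired two-condition designs, heterogeneous
per-gene scales, controlled pairwise dependence and its change between
conditions, additive Gaussian measurement noise (`inject_noise()`, with a
relative mode that expresses the level as a fraction of the data's pooled
standard deviation). What it does not emulate: count noise and dropout,
library-size variation, non-Gaussian marginals (the score would not care —
that is the point of ranks — but preprocessing behavior on such data is not
exercised), correlation *networks* beyond disjoint planted pairs, and
batch effects. Passing simulation tests therefore demonstrates the method's
statistical behavior, not the end-to-end behavior on raw sequencing data.

Three experiments mirror the method's validation studies, at desk scale:

* `concordance_experiment()` — a 21-point correlation grid from $-1$ to
  $+1$ (step 0.1; the grid is a parameter), two *independent*
  exact-correlation draws per grid value per repetition, K–S distance for
  every cell of the grid × grid matrix. Independence of the row and column
  draws keeps the diagonal honest (identical draws would give exactly 0).
  Default $n = 100$ observations per draw; the packaged checks run 20
  repetitions and verify that mean distance increases with the correlation
  gap (Spearman $\ge 0.9$) and that the diagonal median stays below 0.1.
* `stability_experiment()` — score clean data, score noise-injected data,
  and report the fraction of threshold-selected pairs that survive. The
  packaged checks use 30 genes, 50 pairs per condition, 5 planted pairs,
  noise levels $\{0, 0.5, 1\}$ and thresholds $0.1\ldots0.4$, averaged over
  10 seeds.
* `recovery_experiment()` — plant 10 strong sign-flip pairs
  ($\rho = +0.9 \to -0.9$) among 50 genes, perturb the tumor matrix at
  increasing noise, detect at threshold 0.6 on the `values_1d` scale, and
  report the recovered fraction of ground truth. Averaged over 10 seeds,
  recovery decreases monotonically in noise.

These sizes are the package's reference problem sizes: large enough for the
trends to be stable across seeds, small enough to run in seconds.

## The density diagnostic

`beta_kernel_density()` smooths the copula with a product of beta kernels —
each kernel mode-matched at its data point, so all mass stays inside the
unit square and no boundary correction is needed. For density estimation
the pseudo-observations are rescaled by $m/(m+1)$ to keep them off the
corner $(1,1)$, where the kernel shape degenerates. `bandwidth = "auto"`
minimizes a plug-in approximation of the asymptotic mean integrated squared
error: the squared-bias integral uses as reference density a Frank copula
fitted by inverting the sample Kendall $\tau$ (Debye-function inversion),
the variance term is the leading $O(1/(mh))$ interior expression, and the
minimization is a golden-section search over $[1/m,\ m^{-1/5}]$. The
estimate is a visualization aid only; no score depends on it.

## Numerical choices, in one place

* Ties in ranks: average ranks, everywhere.
* Pseudo-observations normalized by $1/m$ (so the maximum is 1) for CDF
  work; rescaled by $m/(m+1)$ only inside density estimation.
* KS sup evaluated exactly on the pooled product grid; lattice and 1-d
  modes as cross-checks/alternative scale.
* Pair lists are sorted by score descending with lexicographic gene-name
  tie-breaks, so outputs are reproducible byte for byte.
* All-pairs scoring precomputes ranks per gene and condition; results are
  identical to independent per-pair calls (tested).
* Cluster labels are renumbered in order of first appearance; small-module
  merging proceeds smallest-first.
* Every stochastic routine takes a `seed` and restores the caller's RNG
  state; equal seeds give bit-identical output.

## Known limitations

* The bivariate sup-distance saturates at 0.5; users comparing against
  absolute thresholds from the literature should use the `values_1d` scale.
* With very small samples ($m \lesssim 15$) the copula grid is coarse and
  scores are strongly quantized; the package refuses $m < 3$ and leaves
  judgement for small $m$ to the user.
* Average-linkage clustering with ties in the dissimilarity can depend on
  input order; in practice scores computed from data are tie-free almost
  surely.
* The enrichment module consumes user-supplied gene sets only; it does not
  fetch or version pathway databases.
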