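---
title: "Methods: multivariate polygenic scores from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate polygenic scores from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmashrss)
```

## The model

`mrmashrss` fits the multivariate multiple regression

$$Y = XB + E, \qquad E \sim \mathcal{MN}_{n \times r}(0, I_n, V),$$

where $Y$ collects $r$ phenotypes on $n$ individuals, $X$ holds genotype
dosages at $p$ variants, $B$ is the $p \times r$ matrix of effects, and $V$
is the residual covariance across phenotypes. Rows of $B$ (the effects of
one variant across all phenotypes) are exchangeable draws from a mixture of
$r$-variate normals,

$$b_j \mid w_0, S_0 \sim \sum_{k=1}^{K} w_{0,k}\, N_r(0, S_{0,k}),$$

whose covariance components encode patterns of cross-phenotype effect
sharing — a null component, independent effects, equal effects,
phenotype-specific effects, partial sharing at several correlations, and
data-driven patterns estimated from strong signals — each crossed with a
grid of scales. The weights $w_0$ (and optionally $V$) are estimated from
the data by empirical Bayes, so the prior adapts to the trait architecture.

The likelihood depends on the data only through the sufficient statistics
$X^\top X$, $X^\top Y$, and $Y^\top Y$, which is what makes a
summary-statistics version possible: with per-variant marginal effects
$\hat\beta_{jt}$, standard errors $s_{jt}$, the GWAS sample size $n$, and an
LD correlation matrix $R$, the package reconstructs

$$d_{jt} = \frac{y_t^\top y_t}{s_{jt}^2 (n-2) + \hat\beta_{jt}^2}, \qquad
  X^\top Y_{jt} = \hat\beta_{jt}\, d_j, \qquad
  X^\top X = D^{1/2} R\, D^{1/2},$$

under the convention that phenotypes are variance-standardized
($y_t^\top y_t = n-1$) and genotypes centered. $X^\top Y$ is exact; $X^\top
X$ is exact only when $R$ comes from the GWAS sample itself and is an
approximation for reference-panel LD. The per-phenotype $d_{jt}$ coincide
under complete sample overlap; the package collapses them by their median
and reports their dispersion as a QC symptom (`qc_consistency()`), since
disagreement indicates sample non-overlap or unit mismatches.

## Inference

The posterior over $B$ is approximated by coordinate-ascent variational
inference with a fully factorized family over variants. Each sweep visits
every variant, forms the residualized single-variant estimate
$\hat b_j = (T_j + d_j \bar b_j)/d_j$ from the running residual
cross-products $T = X^\top Y - X^\top X \bar B$, and applies the exact
conjugate mixture update

$$\Sigma_{1k} = S_{0k}(S_{0k} + V/d_j)^{-1}(V/d_j), \quad
  \mu_{1k} = S_{0k}(S_{0k} + V/d_j)^{-1}\hat b_j, \quad
  \gamma_{jk} \propto w_{0k}\, N(\hat b_j; 0, S_{0k} + V/d_j),$$

with responsibilities normalized in log space. The
$S_0(S_0 + V/d)^{-1}$ factorization means rank-deficient components (the
null, singletons, rank-1 data-driven matrices) need no inversion of $S_0$.
Internally each sweep whitens by $V = LL^\top$ and eigendecomposes the
whitened components once, so the per-variant, per-component work is a pair
of $r \times r$ matrix–vector products — this is exactly equivalent to the
textbook update and is what makes the inner loop (implemented in C++) fast.

After each sweep the mixture weights are updated by their closed-form
M-step ($w_{0k} = \frac1p\sum_j \gamma_{jk}$), and, when $Y^\top Y$ is
available, the residual covariance by
$V = E_q[(Y-XB)^\top(Y-XB)]/n$, symmetrized and eigenvalue-floored at
$10^{-8}$. Both are exact ascent steps on the evidence lower bound (ELBO),
so the per-sweep ELBO trace is nondecreasing; the fitter treats any
decrease beyond $10^{-8}$ relative as an internal error rather than noise.
The ELBO itself is accumulated during the sweep through the local-evidence
identity $-KL_j = \log \tilde p(\hat b_j) - E_q[\log N(\hat b_j; b_j,
V/d_j)]$, which is exact because the KL term of variant $j$ depends only on
$q_j$. In the single-variant conjugate case the ELBO equals the exact log
marginal likelihood, which the test suite verifies against a closed form,
and with a single normal component the fixed point satisfies the Bayesian
ridge normal equations — these two oracles pin the algebra down
independently of the implementation.

Convergence is declared when the relative ELBO change drops below `tol`
(default $10^{-6}$; `max_iter` 500). The update order is fixed ascending by
default for reproducibility; a seeded per-sweep shuffle is available
(`update_order = "shuffled"`). Genomes are fitted one chromosome (one LD
block-set) at a time; polygenic scores add across chromosome fits
(`pgs_score()` accepts a list of per-chromosome fits).

### Residual covariance and $Y^\top Y$

$Y^\top Y$ is optional. It is required only to estimate $V$ (and for the
absolute value of the ELBO — without it the trace is reported up to an
additive constant). Under the standardized convention the package fills its
off-diagonal with $(n-1)\,\widehat{\mathrm{cor}}(Y)$, where the phenotype
correlation is estimated from the z-score correlation across null-ish
variants ($\max_t |z| < 2$) — the usual summary-level stand-in. When the
exact phenotype cross-products are available (as when the analyst computed
the GWAS themselves), supply them via `yty_mode = "supplied"`: a
*mis-estimated* $Y^\top Y$ combined with `update_V = TRUE` can destabilize
the fit for strongly genetically correlated phenotypes, because the V
update differences two large, inconsistent quantities. With no $Y^\top Y$
at all, the engine runs with $V$ fixed at a diagonal plug-in
$1 - \hat h^2_t$, where $\hat h^2_t = p(\overline{z^2} - 1)/(n \bar\ell)$
is the LD-score-corrected chi-square heritability estimate, clipped to
$[0, 0.9]$, with an identity fallback.

### Initialization for dense architectures

Empirical-Bayes weight updates are known to over-shrink highly polygenic
traits. The package implements the two-step guard: LD-prune to a
semi-independent subset (`ld_prune()`, greedy, default $r^2 \le 0.1$,
visiting variants in decreasing max $|z|$); estimate the mixture weights on
that subset ignoring LD (`fit_mash_weights()`, EM on the weights with
per-variant error covariance $\mathrm{diag}(s_j^2)$ — cross-phenotype error
correlation is deliberately ignored at this step); reset the null weight to
0.5 and rescale the rest (`rescale_null()`), compensating the null-weight
underestimate that comes from fitting on a small pruned subset; then hand
the weights to the engine with updates confined to the first 10 sweeps
(`mr_mash_control(w0_max_updates = 10)`). The 0.5 and the 10 are exposed
as configuration.

A caveat we established empirically at desk scale ($n \approx 2000$): with
$B$ initialized at zero, the first ten sweeps *raise* the null weight
(every responsibility starts near the null before effects grow in), so the
frozen constrained fit ends with a larger null weight than the
unconstrained fit, whose weights recover as signal accumulates — the
opposite of the biobank-scale motivation. At this scale the over-shrinkage
signature appears instead as weight mass on near-zero-variance scale
components. The mechanics of the constraint (freeze at 0, $k$, or
`max_iter` sweeps) are tested exactly; the directional benefit of the
initialization is a large-sample phenomenon that these desk-scale
simulations do not reproduce, and we document rather than assert it.

## The synthetic-data generator

The simulator exists so that every stage is testable without any data
download. It emulates, at desk scale, the statistical structure of a
biobank simulation study:

* **Genotypes** (`simulate_genotypes()`): latent Gaussian AR(1) along the
  variant axis (lag-one correlation `ld_decay`, default 0.9), thresholded
  twice per variant at Hardy–Weinberg quantiles for a MAF drawn uniformly
  from `maf_range` (default 0.05–0.5), giving 0/1/2 dosages with tunable
  banded LD; genetic-map positions accumulate exponential gaps with mean
  `map_density_cm` (default 0.01 cM). This reproduces local LD decay and a
  cM coordinate, but not human demography, allele-frequency spectra, or
  long-range LD; passing tests on it says nothing about those features of
  real data.
* **Effects** (`simulate_effects()`): `n_causal` variants drawn uniformly;
  six sharing scenarios — equal effects across phenotypes ($h^2_g = 0.5$),
  mostly null (phenotype 1 only, others $h^2_g = 0$), shared-but-unequal
  effects in subgroups \{1,2,3\} vs \{4,5\} chosen by a fair coin
  (within-group effect correlation `rho_share = 0.8`, a value the study
  design leaves open; $h^2_g$ 0.3/0.3/0.3/0.5/0.5), a low-heritability
  variant ($h^2_g = 0.2$), high polygenicity (10× the causal variants), and
  more phenotypes ($r = 10$). Effect sizes are normal — the distribution
  family is a documented choice.
* **Phenotypes** (`simulate_phenotypes()`): effect columns are rescaled so
  the in-sample ratio $\mathrm{Var}(Xb_t)/(\mathrm{Var}(Xb_t) +
  \sigma^2_{e,t})$ hits the target $h^2_g$ exactly with
  $\sigma^2_{e,t} = 1 - h^2_{g,t}$; residuals are multivariate normal with
  identity cross-phenotype correlation by default (also left open by the
  study design). Exact in-sample enforcement is the cleaner testing
  contract than calibrating the effect-size variance; the realized
  $\mathrm{Var}(G)/\mathrm{Var}(Y)$ then differs from the target only
  through residual sampling noise.
* **Scans and robustness** (`gwas_scan()`, `mcar_mask()`,
  `compute_ld()`): single-variant regressions with intercept per phenotype
  (each phenotype rank-inverse-normal transformed with the Blom offset
  before scanning), missing-completely-at-random phenotype masking with the
  $2^r - 1$ nonempty patterns drawn uniformly for a chosen fraction of
  individuals, and LD from a (possibly external, e.g. 503-individual)
  reference panel with optional banded or block-diagonal structure.

Default desk-scale sizes keep the causal fraction's order of magnitude from
the biobank design it mirrors: 2,000 training individuals, 2,000 variants,
50 causal variants (full scale: 105,000 / 595,071 / 5,000). The heavy
checks in the test suite and the acceptance script use these sizes — 20
replicates of each scenario for generator calibration, and 20 replicates of
the joint-vs-single-phenotype comparison — chosen so the whole suite runs
on one CPU in well under half an hour.

## Numerical choices and degenerate inputs

* Banding retains entries *at* the window distance; only pairs strictly
  more than `window_cm` apart (or on different chromosomes) are zeroed.
  Ties in map positions are allowed.
* Banding a *sample* LD matrix can make the rebuilt $X^\top X$ indefinite;
  at reference-panel sizes of a few hundred to a few thousand this visibly
  degrades the fit (the test suite demonstrates the external-panel
  degradation directionally). Block-diagonal structure is the safer
  truncation, and the pipelines here default to dense in-sample LD, for
  which recovery is exact.
* Prior components are validated symmetric PSD with an eigenvalue floor of
  $-10^{-10}$; duplicate components (within $10^{-12}$) are merged, with
  their weights summed, to prevent degenerate weight EM. The null
  component is always present and always first.
* Zero-variance predictions evaluate to $R^2 = 0$ by convention, so
  null-prior fits score cleanly; the accuracy metric is the $R^2$ of the
  regression of true on predicted phenotype, which is invariant to affine
  transforms of the prediction and bounded in expectation by $h^2_g$.
* Zero-variance genotype columns, missing values on the individual-level
  path, non-simplex weights, non-PSD components, and inconsistent
  variant sets all fail fast with named errors rather than propagating.
* `fit_mash_weights()` warns and returns current weights if its EM hits
  `max_iter` (default 1000); its objective trace is attached for
  inspection.

## Known limitations

* The engine assumes complete sample overlap across phenotypes; summary
  statistics computed per phenotype on different complete cases (the MCAR
  robustness scenario) violate its likelihood, deliberately — that is the
  misspecification being studied, not a supported analysis mode.
* Case-control phenotypes, per-variant sample-size heterogeneity
  (meta-analysis summary statistics), allele harmonization against
  reference panels, and imputation of missing phenotypes are out of scope.
* The data-driven covariance step implements rank-1 PCA candidates plus
  fixed-iteration extreme-deconvolution refinement; richer factorization
  approaches exist and can be supplied as custom components via
  `mixture_prior()`.
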