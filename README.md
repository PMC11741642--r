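# mrmashrss

Multivariate polygenic scores from GWAS summary statistics by variational
empirical Bayes.

## What this package does, and for whom

Polygenic scores predict a phenotype from genotype dosages using weights
estimated from genome-wide association data. When several phenotypes are
genetically correlated, modelling them *jointly* and learning the pattern
of effect sharing across them improves the weights for all of them — but
the individual-level data needed for joint modelling are rarely shareable.
`mrmashrss` is for quantitative geneticists who have only **summary data**:
per-variant marginal effect sizes and standard errors from single-variant
GWAS scans of each phenotype, plus a linkage-disequilibrium (LD)
correlation matrix.

The model is the Bayesian multivariate multiple regression

```
Y = X B + E,   E ~ MN(0, I_n, V),     b_j ~ Σ_k w0_k N_r(0, S0_k)
```

with a mixture-of-multivariate-normals prior on each variant's effects
across the `r` phenotypes. The mixture components `S0_k` encode sharing
patterns (null, equal, phenotype-specific, partially shared, data-driven),
and the weights `w0` — and optionally the residual covariance `V` — are
estimated from the data by maximizing the evidence lower bound (ELBO), so
the prior adapts to the trait architecture. Because the likelihood depends
on the data only through the sufficient statistics `X'X`, `X'Y`, `Y'Y`,
the model can be fitted from summary statistics: `X'Y` is recovered
exactly from effect sizes, standard errors and the sample size, and `X'X`
from the LD matrix (exactly for in-sample LD, approximately for a
reference panel). Fitting from summary statistics with in-sample LD gives
the same result as fitting from the individual-level data — a property the
test suite asserts to `1e-6`.

The package also ships a scenario simulator (LD-structured genotypes,
six effect-sharing scenarios, GWAS scans, missing-phenotype and
external-LD robustness settings) so every stage is testable at desk scale
without any data download.

## Worked example

Simulate a five-phenotype study in which every causal variant has the same
effect on all phenotypes (heritability 0.5), run the per-variant GWAS
scans, rebuild the sufficient statistics, fit, and score a held-out test
set:

```r
library(mrmashrss)

sim <- simulate_scenario("equal_effects", n_train = 2000, n_test = 1000,
                         p = 2000, n_causal = 50, seed = 1)

# summary data: per-variant scans of quantile-normalized phenotypes + LD
gwas <- gwas_scan(sim$X_train, sim$Y_train, quantile_norm = TRUE)
ld   <- compute_ld(sim$X_train, sim$positions_cm, sim$chrom)

# phenotype cross-products from the training sample (used to estimate V)
Yq  <- apply(sim$Y_train, 2, quantile_normalize)
ss  <- recover_suffstats(gwas, ld, yty_mode = "supplied",
                         YtY = crossprod(scale(Yq, scale = FALSE)))

prior <- mixture_prior(scale_expand(canonical_covs(5),
                                    default_scale_grid(gwas, length = 5)))
fit <- mr_mash_rss(ss, prior = prior)
fit
#> Multivariate summary-statistics regression fit
#>   p = 2000 variants, r = 5 phenotypes, K = 51 prior components
#>   120 sweeps, converged; final ELBO -11024.69
#>   fitted null weight: 0.09551

round(evaluate_r2(sim$Y_test, predict(fit, sim$X_test)), 3)
#> pheno1 pheno2 pheno3 pheno4 pheno5
#>  0.560  0.481  0.519  0.482  0.502
```

The per-phenotype numbers are the R² of regressing the true test
phenotypes on the scores — the standard accuracy metric for polygenic
scores, whose ceiling in expectation is the simulated heritability (0.5
here; scores near the ceiling reflect the equal-effects scenario, where
the multivariate prior pools all five phenotypes' evidence for every
variant). The fitted null weight is the prior mass on the no-effect
component; under LD much of the null mass lands on the small-variance
scale components instead, so it underestimates the true null fraction.
For comparison, running the same engine on each phenotype separately
(`r = 1`) gives a mean R² of about 0.467 over 5 such simulations, against
0.500 for the joint fit — the gap is the value of modelling the sharing.

For highly polygenic traits, initialize the weights on LD-pruned variants
and restrict weight updates to the first sweeps:

```r
prior0 <- mash_init_weights(gwas, ld, prior)   # null weight reset to 0.5
fit0   <- mr_mash_rss(ss, prior = prior0,
                      control = mr_mash_control(w0_max_updates = 10))
```

See the methods vignette (`vignettes/mrmashrss-methods.Rmd`) for the model,
the update equations, all tunable parameters, and what the simulator does
and does not emulate.

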