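# grcca

Group-regularized canonical correlation analysis (GRCCA) for linking bulk
transcriptomic expression to diagnosis and exposure covariates, with the
full supporting pipeline: count filtering, normalization and covariate
residualization, multiple correspondence analysis (MCA) of categorical
toxicology exposures, weighted co-expression module detection, permutation
and bootstrap inference, a per-feature differential-expression comparison
arm, and rank- and overlap-based gene set enrichment.

## The problem

Case–control differential expression treats genes one at a time and often
fails to align with genetic risk loci; co-expression module analysis
collapses each module to a single eigengene and discards most variance.
Psychiatric disorders in particular are marked by subtle, coordinated shifts
across many co-expressed genes, confounded by medication and recreational
drug exposure. GRCCA addresses both limitations: it finds a single pair of
latent variables — one in expression space, one in covariate space — whose
correlation is maximal, while a group-structured penalty lets whole
co-expression modules move together instead of fitting each gene freely.

## The model

Given column-standardized expression `X` (samples × features), covariates
`Y` (samples × covariates: diagnosis indicators against a control baseline
plus selected toxicology MCA dimensions), and a module assignment `g(i)`
per feature, the first canonical pair solves

```
maximize   w_x' C_xy w_y
subject to w_x' R w_x = 1,   w_y' C_yy w_y = 1
R = lambda (I - B) + mu B
```

where `B` averages weights within modules, `lambda = 1 - 1/p` shrinks
within-module deviations heavily, and `mu = 0.1` shrinks module mean
weights lightly. Because `I - B` and `B` are orthogonal projections,
`R^{-1/2}` is analytic and the problem reduces to an SVD of a whitened
cross-covariance. The retained variance fraction `f` of the transformed
expression matrix is selected by permutation over a grid (0.1–1.0 by 0.1).
Inference: a permutation test of the latent correlation
(`p = (1 + #{null ≥ obs}) / (1 + n_perm)`), bootstrap Z-scores for every
weight, and structure correlations `r_x = cor(X, LV_x)`,
`r_y = cor(Y, LV_y)` with BH-adjusted t-test p-values. A feature is called
significant when `|Z| ≥ 2` and its `r_x` FDR < 0.05.

## Worked example

Everything below runs on simulated data with known ground truth — a
negative-binomial count matrix with 8 planted co-expression modules, a
standardized shift of 1.0 on the latent factors of modules 1–2 in the SCZ
group, and 17 diagnosis-correlated ternary toxicology exposures.

```r
library(grcca)

cf <- simulation_config(n_per_group = c(Control = 45, SCZ = 45), n_genes = 600,
                        module_sizes = rep(60, 8), effect_modules = 1:2,
                        effect_size = 1, seed = 42)
sim  <- simulate_dataset(cf)
expr <- normalize_transform(filter_min_counts(sim$counts))

tox  <- sim$samples[, grep("^tox", names(sim$samples))]
mres <- select_dimensions(mca(impute_unknown(tox)))
Y <- cbind(diagnosis_indicators(sim$samples$diagnosis), mca_scores(mres))
X <- t(expr)
groups <- sim$truth$true_modules[colnames(X)]

sel <- optimize_variance_fraction(X, Y, groups, n_perm = 199, seed = 1)
fit <- fit_grcca(X, Y, groups, f = sel$chosen_f)
fit
#> GRCCA fit: n = 90 , p = 600 , q = 11
#> latent correlation 0.7089 at f = 1.00 (89 components); lambda = 0.998333, mu = 0.1
#> top covariate: SCZ (r_y = 0.926)

permutation_test(X, Y, groups, f = sel$chosen_f, n_perm = 999, seed = 2)$perm_p
#> [1] 0.001
fit <- bootstrap_z(X, Y, groups, fit, n_boot = 200, seed = 3)
sig <- significant_features(fit)
head(sig[sig$significant, c("feature_id", "r", "fdr", "Z")], 5)
#>    feature_id     r      fdr    Z
#> 35      g0035 0.704 5.93e-12 7.90
#> 1       g0001 0.650 1.27e-09 7.79
#> 52      g0052 0.643 1.73e-09 7.98
#> 56      g0056 0.630 4.24e-09 7.92
#> 10      g0010 0.625 5.38e-09 7.68
```

The permutation p reaches its floor of 0.001 (999 permutations), SCZ is by
far the strongest covariate on the latent variable (`r_y = 0.93`), 153
features pass the dual significance criteria, and 75% of them lie in the
two planted effect modules. The per-feature differential-expression arm
agrees with the multivariate result:

```r
dge <- fit_dge(expr, sim$samples, mca_scores(mres))
compare_to_grcca(dge, fit)$correlation
#> [1] 0.79
```

`run_pipeline(pipeline_config(simulate = cf, ...), outdir)` executes the
same stages end to end — including module detection from the expression
itself, GSEA against module gene sets, and hypergeometric overlap — and
writes every intermediate table plus a `manifest.json` with parameters,
per-stage seeds and output checksums; re-running with the same
configuration reproduces all outputs bitwise.

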