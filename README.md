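# gklreg

Shrinkage estimation for gamma regression under multicollinearity.

## The problem

Gamma regression models a positive, right-skewed response — a biological
activity in a QSAR study, an insurance severity, a health-care cost —
through a log-linear mean: each `y_i` is gamma with mean
`θ_i = exp(x_i'β)` and variance `φ·θ_i²`, where `φ` is the dispersion.
When the predictor columns are nearly collinear (correlated molecular
descriptors are the canonical case), the maximum likelihood estimator
(MLE) of `β` is unstable: the weighted cross-product matrix
`D = X'ŴX`, `Ŵ = diag(θ̂²)`, has tiny eigenvalues and the estimator's
variance blows up along the corresponding directions.

`gklreg` implements the MLE and three biased estimators that trade a
small bias for a large variance reduction, with
`D_k = I + kD⁻¹`, `R_k = I − kD⁻¹`, `F_d = (D+I)⁻¹(D+dI)`:

* **GRE** — gamma ridge: `β̂_GRE = D_k⁻¹ β̂`, filter `γ_j/(γ_j+k)` on the
  rotated coordinates `α̂ = P'β̂` of the eigen system `D = P diag(γ) P'`;
* **GLE** — gamma Liu: `β̂_GLE = F_d β̂`, filter `(γ_j+d)/(γ_j+1)`;
* **GKL** — gamma Kibria–Lukman, a single-parameter ridge-type estimator
  with double shrinkage: `β̂_GKL = D_k⁻¹ R_k β̂`, filter
  `(γ_j−k)/(γ_j+k)`.

Around them the package provides the analytic matrix-MSE risk of each
estimator (`risk_summary()` and the eigenvalue forms `mse_mle()`,
`mse_gre()`, `mse_gle()`, `mse_gkl()`, e.g.
`MSE_GKL(k) = φ Σ_j (γ_j−k)²/(γ_j(γ_j+k)²) + 4k² Σ_j α_j²/(γ_j+k)²`),
data-driven biasing-parameter selectors (`select_k_gre()`,
`select_d_gle()`, `select_k_gkl()`), sufficient-condition superiority
checks with direct positive-definiteness verdicts (`gkl_vs_mle()`,
`gkl_vs_gre()`, `gkl_vs_gle()`), collinearity diagnostics
(`condition_number()`), and a Monte-Carlo engine that rebuilds the
standard collinear-design simulation study (`sim_cell()`, `sim_grid()`).

## Worked example

Sixty observations on four predictors with pairwise correlation
`0.99² ≈ 0.98`, unit-norm true coefficients, dispersion 0.5:

```r
library(gklreg)
set.seed(42)
X <- sim_design(60, 4, rho = 0.99)
colnames(X) <- paste0("x", 1:4)
beta <- sim_coef(4, "eigvec-max", X = X)
dat <- data.frame(y = sim_response(X, beta, phi = 0.5), X)

fit <- gklreg(y ~ . - 1, data = dat, estimator = "gkl")
summary(fit)
#> Estimator: GKL  (k = 0.2501 )
#>
#> Coefficients:
#>    Estimate Std. Error
#> x1  0.29838      0.144
#> x2 -0.63371      0.064
#> x3  2.06088      0.087
#> x4  0.01349      0.050
#>
#> Dispersion (Pearson): 0.3486
#> Condition index of X'WX: 137.1
#> Estimated MSE (plug-in): 0.03583
#> Convergence: yes in 5 iterations
```

The fit warns that the condition index 137 (sqrt convention, threshold
30) signals severe multicollinearity. The selected biasing parameter
`k = 0.25` is the median of the per-coordinate optima
`k_j = φ̂/(2α̂_j² + φ̂/γ_j)`. A side-by-side comparison of all
estimators, mirroring the classical application table (coefficients,
then the `d/k` row, then the plug-in estimated MSE row):

```r
estimator_report(y ~ . - 1, dat)
#>                        MLE   GRE-k   GLE-d GKL-kmin  GKL-k2
#> x1                  0.2744  0.2802  0.2777   0.2802  0.2984
#> x2                 -0.6318 -0.6322 -0.6320  -0.6322 -0.6337
#> x3                  2.0775  2.0735  2.0752   2.0735  2.0609
#> x4                  0.0185  0.0173  0.0178   0.0173  0.0135
#> d/k                     NA  0.1185  0.9267   0.0593  0.2501
#> est. MSE (plug-in)  0.0379  0.0372  0.0375   0.0372  0.0358
#>
#> Dispersion (Pearson): 0.3486   Condition index: 137.1
```

Every shrinkage column lowers the plug-in risk below the MLE's 0.0379,
GKL with the k2 rule the most. The theory's sufficient condition for GKL
beating the MLE can be checked at any `(φ, D, β, k)`; at the
conservative `k_min = 0.0593` it certifies superiority:

```r
gkl_vs_mle(fit$dispersion, fit$mle$D, coef(fit$mle), k = 0.0593)
#> Superiority check: GKL vs MLE
#>   sufficient condition: TRUE  (quadratic form = 0.8149 )
#>   direct MMSE-difference p.d.: TRUE
```

Monte-Carlo comparison over a grid of sample sizes, collinearity levels
and dispersions (long-format data frame of empirical MSEs per estimator
with Monte-Carlo standard errors):

```r
tab <- sim_grid(n = c(20, 50, 200), p = c(4, 7),
                rho = c(0.95, 0.99, 0.999), phi = c(0.5, 1),
                reps = 1000, seed = 42)
```

A thin command-line wrapper over the same functions lives in
`inst/scripts/gklreg-cli.R` (subcommands `fit`, `simulate`, `risk`; run
with `help` for usage).

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch, the empirical
mean-squared-error summaries of selected Monte-Carlo cells (the MLE,
ridge, Liu and Kibria–Lukman estimators with their data-driven
parameters, 1000 replicates per cell) and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`. The methods vignette
(`vignettes/gamma-shrinkage.Rmd`) documents the estimators, the selector
conventions, the synthetic world and the package's design decisions.
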