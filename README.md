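# clrgee

Cluster-robust variance estimation for conditional logistic regression
(CLR), with the Monte Carlo machinery to study **how clustering rules
affect the reliability of that variance** in habitat-selection and
step-selection analyses.

## The problem

Step/habitat selection models compare each *used* animal location with
the locations *available* at the same moment: a stratum of `N`
locations containing exactly one use. CLR estimates the selection
coefficients `β` from the within-stratum softmax

    P(y_ji = 1 | X_j) = exp(β'x_ji) / Σ_i' exp(β'x_ji')

Telemetry data are temporally autocorrelated and animals differ from
one another, so the model-based ("naive") covariance
`B = (Σ_k D_k' V_k⁻¹ D_k)⁻¹` is biased. Generalized estimating
equations repair it with the sandwich
`cov(β̂) = B (Σ_k U_k U_k') B`, where `U_k` is the score contribution
of cluster `k` — **provided the clusters really are independent**.
Practitioners partition their data into clusters in wildly different
ways (one animal per cluster, split animals, 14–450 clusters); this
package measures what those choices do to the variance estimates.

It provides:

* `fit_clr()`, `naive_variance()`, `robust_variance()` — the estimator
  (Newton–Raphson on the GEE score under an independence working
  structure, naive and cluster-robust sandwich covariances);
* `sim_config()`, `simulate_dataset()` — a generator of correlated
  matched case–control data: cluster-level random intercepts/slopes
  (heterogeneity `σ_H²`) and AR(1) coefficient paths (autocorrelation
  `ρ`);
* `destructive_sample()`, `unbalance()`,
  `estimate_decorrelation_lag()` — the re-clustering schemes whose
  consequences are under study;
* `run_scenario()`, `true_variance()`, `ratio_summary()`,
  `default_grid()` — the Monte Carlo harness benchmarking both
  estimators against the empirical sampling variance `V_T` of `β̂`
  through the ratios `V_R/V_T` and `V_N/V_T`;
* `clr_cli()` — a `fit` / `simulate` / `scenario` / `grid` command-line
  layer (wrapper script in `inst/scripts/clrgee.R`).

## Worked example

```r
library(clrgee)

cfg <- sim_config(K = 30, sigma_H2 = 0.5, rho = 0.3, seed = 5)
d   <- simulate_dataset(cfg)        # 30 clusters x 20 strata x 10 locations
fit <- fit_clr(d)
fit
#> Conditional logistic regression (GEE, independence working structure)
#>   600 strata in 30 cluster(s); loglik = -1353.8476; converged in 4 iter (|score| = 2.18e-12)
#>    estimate naive_se robust_se
#> x1   0.3694   0.0622   0.13713
#> x2   0.2764   0.0612   0.09841
```

The naive and robust standard errors disagree (0.062 vs 0.137): the
heterogeneity and autocorrelation in this dataset violate the
independence the naive estimator assumes, and the sandwich corrects
for it. A small Monte Carlo run quantifies which one to trust:

```r
res <- run_scenario(cfg, "balanced", R = 100)
res
#> Scenario: K = 30, S = 20, P = 2, rho = 0.3, sigma_H2 = 0.5, balanced
#>   replicates: 100 requested, 0 failed
#>       V_T ratio_R  R_lo  R_hi ratio_N  N_lo  N_hi mean_beta
#> x1 0.0126   0.963 0.920 1.006   0.317 0.315 0.319      0.55
#> x2 0.0124   0.908 0.862 0.954   0.313 0.311 0.315      0.35
```

With one animal per cluster and `K = 30`, the robust ratio `V_R/V_T`
is statistically indistinguishable from 1 while the naive estimator
underestimates the true variance threefold (ratio ≈ 0.32): the
between-animal heterogeneity and temporal autocorrelation in this
scenario make the independence-based variance far too optimistic.
`destructive_sample()` and
`unbalance()` let you rerun the same experiment under split-animal or
unequal-monitoring designs, and `estimate_decorrelation_lag()` supplies
the stratum lag a destructive split must drop.

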