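# drcif

Doubly robust estimation of treatment-specific marginal cumulative
incidence curves for competing-risks data.

## The problem

In observational time-to-event studies with competing events (say,
disease recurrence, second tumor and death), the crude per-arm
Aalen–Johansen cumulative incidence curves do not have a causal
interpretation when treatment choice depends on patient characteristics:
covariate imbalance confounds the comparison. `drcif` estimates the
*marginal* counterfactual cumulative incidence
`I_k^z(t) = P(T^z ≤ t, Δ^z = k)` — the incidence of event type `k` by time
`t` had everyone received arm `z` — by four estimators:

* **crude** — per-arm Aalen–Johansen
  `Î_k(t) = Σ_{t_j ≤ t} Ŝ(t_j−) d_k(t_j)/n(t_j)` (no adjustment; biased
  under confounding);
* **ipw** — the weighted Aalen–Johansen with unstabilized inverse
  probability-of-treatment weights `w_i = 1/[Z_i ê(X_i) + (1−Z_i)(1−ê(X_i))]`
  from a logistic propensity model `ê(X) = P(Z=1|X)`;
* **or** — outcome regression: cause-specific Cox models for each event
  type (treating other causes as censored), individual curves built by the
  discrete product-integral from Breslow baseline hazards, standardized
  over the empirical covariate distribution (g-formula):
  `Î_OR,k^z(t) = n⁻¹ Σ_i Î_k(t, X_i, z)`;
* **dr** — the augmented-IPW estimator

  ```
  Î_DR,k^z(t) = n⁻¹ Σ_i [ y*_ik(t)·1{Z_i=z} − Î_k(t,X_i,z)·(1{Z_i=z} − P̂_i^z) ] / P̂_i^z
  ```

  where `y*_ik(t) = n·Î_k(t) − (n−1)·Î_k^{−i}(t)` are jackknife
  pseudo-values of the pooled-sample Aalen–Johansen CIF, standing in for
  the censored event indicator `1{T_i ≤ t, Δ_i = k}`. The estimator is
  consistent if *either* the propensity model *or* the outcome model is
  correctly specified (double robustness).

Pointwise uncertainty comes from a subject-level bootstrap that refits all
nuisance models within each resample. A simulation engine generates
confounded competing-risks data under four misspecification scenarios with
an exact quadrature truth oracle, so bias and RMSE of all four estimators
can be measured.

## Worked example

```r
library(drcif)

# confounded competing-risks data: 2 causes, 3 confounders
d <- simulate_crisk(scenario_config(1, N = 2000, seed = 42))

fit <- adjcif(Surv(time, status) ~ treatment + x1 + x2 + x3,
              data = as.data.frame(d), treatment = "treatment",
              method = c("crude", "dr"), times = c(0.4, 0.8),
              boot = 100, seed = 1)
print(fit)
#> Adjusted marginal cumulative incidence curves
#>   n = 2000 subjects, 2 event types; methods: crude, dr
#>   evaluation times: 2 point(s) in [ 0.4 , 0.8 ]
#>   bootstrap: B = 100 ( 0 replicate(s) discarded )
#>   crude at t = 0.8: I_1^{z=0} = 0.2933, I_1^{z=1} = 0.3989, I_2^{z=0} = 0.5982, I_2^{z=1} = 0.2752
#>   dr at t = 0.8: I_1^{z=0} = 0.4456, I_1^{z=1} = 0.2881, I_2^{z=0} = 0.4466, I_2^{z=1} = 0.4082
```

The crude curves say treatment *increases* cause-1 incidence
(0.40 treated vs 0.29 control); after doubly robust adjustment the
ordering flips (0.29 vs 0.45) — the confounders drive both treatment
choice and risk. The oracle `true_cif(scenario_config(1), 0.8)` gives the
true marginal cause-1 incidence as 0.4414 (control) vs 0.2709 (treated).

Covariate balance before/after weighting:

```r
balance_table(d, fit_propensity(d))
#>   covariate smd_unweighted smd_weighted flag_unweighted flag_weighted degenerate
#> 1        x1      0.6348064  -0.01087000            TRUE         FALSE      FALSE
#> 2        x2     -0.5902975   0.04497141            TRUE         FALSE      FALSE
#> 3        x3      0.8014658  -0.05550369            TRUE         FALSE      FALSE
```

A bias/RMSE study over repeated simulations:

```r
run_study(1, M = 50, N = 4000, times = 0.8,
          methods = c("crude", "ipw", "or", "dr"), seed = 7)
```

A command-line front end with `estimate`, `balance`, `simulate` and
`study` subcommands is installed at
`system.file("cli", "adjcif.R", package = "drcif")`.

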