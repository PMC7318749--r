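# platformtrial

Design engine and Monte Carlo simulator for a Bayesian, outcome-adaptive,
biomarker-driven platform trial in metastatic castration-resistant
prostate cancer (mCRPC).

Trial statisticians and methodologists can use it to exercise the full
decision machinery of such a design — and to estimate its operating
characteristics by simulation, which for platform trials cannot be
obtained analytically.

## The design

Patients are profiled for four binary markers (AR, DRD, TP53, TEfus),
defining 2^4 = 16 mutually exclusive **subgroup combinations** (the
randomization strata) and five overlapping **biomarker signatures** at
which treatments are evaluated: all patients, TP53-&AR- double wild-type,
TP53+, DRD+, TEfus+ (prevalences 1, 0.5, 0.37, 0.19, 0.32).

Progression-free survival (PFS) is modelled as Weibull with fixed shape k
and a Gamma(α₀ = 10, β₀ = 80) prior on the rate λ — conjugate, so with d
events and exposure Σtᵢᵏ the posterior is
Gamma(α₀ + d, β₀ + Σtᵢᵏ) with no MCMC. Each treatment's evidence within a
signature is its probability of superiority over the concurrent control,

P(λ_T < λ_C) = I_x(α_T, α_C),  x = β_T / (β_T + β_C),

with I the regularized incomplete beta function.

The platform runs in calendar months: Poisson accrual (7/month), 10%
non-evaluable patients routed to an observational arm, fixed equal
randomization until 50 patients have accrued across active arms, then
control-protected adaptive randomization (control probability never below
any single arm's). Monthly interims graduate a (treatment, signature)
pair at P ≥ 85% with ≥ 20 treated patients and consistent member-subgroup
performance, drop it at P ≤ 15%, or cap the signature at 150 patients.
Graduates enter a nested 1:1 confirmatory trial analyzed with a one-sided
log-rank test at α = 0.15, so a 30% screening error bound composes to an
overall type-I error of 0.30 × 0.15 = 4.5%.

## Worked example

```r
library(platformtrial)

# the calibrated population model reproduces the signature prevalences
jp <- calibrate_joint_prevalence()
signature_prevalences(jp)
#>       All TP53-&AR-     TP53+      DRD+    TEfus+
#>      1.00      0.50      0.37      0.19      0.32

# conjugate update and probability of superiority
trt <- posterior_update(prior_spec(), survival_data(c(2, 4, 6), 5))
c(trt$alpha_post, trt$beta_post)
#> [1] 13 97
ctrl <- posterior_update(prior_spec(), survival_data())
prob_superiority(trt, ctrl)
#> [1] 0.4275997

# one full platform trial: 4 drugs x 5 signatures, null effects
res <- run_trial(scenario(), seed = 1)
res
#> Platform trial simulation (seed 1)
#>   months run:   60
#>   patient-lines: 407
#>   pair states:   active=8, capped=6, dropped=5, graduated=1
```

`res$decisions` holds the interim decision history (month, pair,
superiority, treated patients, consistency, decision), `res$patients` the
per-patient ledger, and `res$allocation` the monthly allocation tables.
An effective scenario and its operating characteristics:

```r
scn <- scenario(effects = setNames(10, pair_key("T1", "TP53+")))
rep <- run_replicates(scn, 200, base_seed = 1)
power_and_sample_size(rep, truth_table(scn))
```

which reports the graduation probability of the effective pair and, over
graduating replicates, the mean treated patients, mean participants
(treated + signature-restricted controls), and mean months in the
platform.

A command-line front end for YAML-configured scenarios is installed at
`inst/cli/platformtrial-sim.R` (`run`, `oc`, `validate` subcommands).

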