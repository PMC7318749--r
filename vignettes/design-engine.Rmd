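---
title: "A Bayesian outcome-adaptive biomarker platform design: model, rules, and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian outcome-adaptive biomarker platform design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platformtrial)
```

## The design in brief

`platformtrial` is a design engine and Monte Carlo simulator for a
multi-arm, biomarker-driven platform trial in metastatic
castration-resistant prostate cancer (mCRPC). Patients are profiled for
four binary markers — AR alterations, DNA-repair deficiency (DRD), TP53
inactivation, and the TMPRSS2-ERG fusion (TEfus) — which jointly define
$2^4 = 16$ mutually exclusive *subgroup combinations*. Randomization is
stratified by subgroup; treatments are evaluated at the coarser level of
five overlapping *biomarker signatures* (all patients; TP53- and AR-
double wild-type; TP53+; DRD+; TEfus+). A patient belongs to exactly one
subgroup but possibly several signatures.

The primary endpoint is progression-free survival (PFS). Each
(treatment, signature) pair is compared against the concurrent
standard-of-care control within the signature; pairs graduate to a nested
confirmatory stage on strong evidence of superiority, are dropped for
futility, or are capped when signature accrual reaches its maximum.

## Survival model: conjugate Gamma-Weibull

PFS times are modelled as Weibull with density
$f(t) = k\lambda t^{k-1} e^{-\lambda t^k}$. The shape $k$ is held fixed per
analysis and the rate $\lambda$ receives a Gamma($\alpha_0,\beta_0$) prior.
This is the only reading under which the advertised "no MCMC" posterior is
exact: with $d$ observed events and total exposure
$\sum_i t_i^k$ over all subjects (censored subjects contribute exposure but
no event), the posterior is
$$\lambda \mid \text{data} \sim
  \text{Gamma}\!\Big(\alpha_0 + d,\; \beta_0 + \sum_i t_i^k\Big).$$

Defaults are $\alpha_0 = 10$, $\beta_0 = 80$ — roughly the information of
10 patients — and $k = 1$ (exponential), under which the prior mean PFS is
$\beta_0/\alpha_0 = 8$ months, clinically plausible for mCRPC. Both
$k$ and the hyperparameters are configuration (`prior_spec()`): the
protocol text does not pin the shape, so we expose it rather than guess
beyond the default.

The decision statistic is the probability of superiority
$P(\lambda_T < \lambda_C)$, which for independent Gamma posteriors has the
closed form $I_x(\alpha_T, \alpha_C)$ with
$x = \beta_T/(\beta_T+\beta_C)$, $I$ the regularized incomplete beta
function (`prob_superiority()`). At a common fixed shape this ordering of
rates is equivalent to ordering mean or median PFS. Monte Carlo and
quadrature oracles for this quantity live in the test suite, not the
production path.

```{r superiority}
ctrl <- posterior_update(prior_spec(), survival_data())
trt <- posterior_update(prior_spec(), survival_data(c(9, 14), c(6, 12, 18)))
prob_superiority(trt, ctrl)
```

## Population model: calibrating a joint prevalence

Only signature-level prevalences are given (1, 0.5, 0.37, 0.19, 0.32).
`calibrate_joint_prevalence()` recovers a full joint over the 16 subgroups
with a minimal-assumption product model: TP53, DRD and TEfus marginals are
read off their single-marker signatures; the AR marginal is solved from
$P(\text{AR}{-}\,\&\,\text{TP53}{-}) = 0.5$ assuming AR independent of
TP53, giving $P(\text{AR}{+}) = 1 - 0.5/0.63 \approx 0.206$; all four
markers are then treated as mutually independent. This reproduces every
stated signature prevalence exactly (an analytic identity of the product
construction) while adding no correlation structure the source does not
support. Correlated joints can be supplied to `scenario()` directly.

Signature membership is defined logically from marker status (8 member
subgroups per single-marker signature, 4 for the double wild-type), which
is unambiguous where a rendered membership table would not be.

## Randomization

Within each subgroup, patients are randomized among the control and the
treatments active in at least one signature containing the subgroup.

* **Burn-in.** Until 50 patients (configurable) have accrued across all
  active arms platform-wide, every row is an equal split.
* **Adaptation.** Afterwards, each arm's weight in a subgroup is the
  unweighted mean of its superiority probabilities over the containing
  signatures in which it is still active (the protocol leaves this
  aggregation open; the mean is order-independent and reduces exactly to
  the single-signature case — `max` aggregation is a one-line change in
  `arm_weight()`). The control receives a pseudo-weight equal to the
  largest arm weight, so after normalization the control probability never
  falls below any single arm's — mimicking 1:1 randomization against the
  best arm. With no information (all weights equal) the row is uniform,
  the continuous limit of burn-in.
* Allocation is recomputed at monthly interims, not per patient, and each
  logged row sums to one by construction.

## Decision rules

At each monthly interim, for every active (treatment, signature) pair with
superiority probability $P$:

1. **Graduate** if $P \geq 0.85$, at least 20 patients have been treated
   in the pair, and the treatment is *consistent* across member subgroups:
   every member subgroup with $\geq 3$ treated patients must show
   subgroup-restricted superiority above 0.5. The protocol requires
   "performing well" in all member subgroups without quantifying it; both
   numbers are configuration (`decision_thresholds()`).
2. Otherwise **drop** if $P \leq 0.15$. The minimum-20 rule is attached to
   graduation only (a flag extends it to futility), since early stopping
   for futility is the conservative direction.
3. Otherwise **cap** the pair when signature-level accrual (control plus
   active arms) reaches 150. A capped pair freezes as inconclusive; its
   patients keep being randomized for signatures not yet capped — the
   least destructive reading of a rule the protocol states only as "the
   maximum number of patients in the biomarker signature".
4. Otherwise continue.

Graduated and dropped states are absorbing. A graduating pair opens a
nested confirmatory trial: new patients whose subgroup belongs to the
graduated signature are split 1:1 (strict alternation from a random start)
between the graduated treatment and SOC; the SOC half also remains in the
platform control pool as a comparator for the remaining arms. The
confirmatory comparison itself uses only nested-trial patients and is a
one-sided log-rank test at $\alpha = 0.15$ once an event target is
reached. The protocol gives no confirmatory sample size; the default
target is sized for 80% power against the pair's own scenario effect
(40 events for a truly-null graduation).

## The simulator

`run_trial()` advances calendar time in months — the interim cadence —
with Poisson accrual (default 7 patients/month, the trial's reported
rate). Each new patient draws a subgroup from the calibrated joint; with
probability 0.1 the profile cannot be inferred (undetectable ctDNA,
technical failure, MSI routing are folded into this single probability)
and the patient enters an observational SOC arm, never randomized.

True PFS is Weibull with mean `baseline + effect`, where the effect is
the *maximum* over the patient's containing signatures of the assigned
drug's effects (the protocol never defines composition for overlapping
effective signatures; the maximum is the natural "best applicable
pathway" reading). Control and observational patients first draw a SOC
drug from `control_mix` (uniform by default) and receive that drug's
signature effects — physicians choose without biomarker knowledge, so
under the default scenarios the control mix carries the same effects as
the corresponding active arms.

Upon first progression, patients on active arms may re-enter once
(maximum two randomizations) with profile held fixed; control and
observational patients remain in their arm; a configurable dropout
probability (default 0.1) models discontinuation. Re-randomization
defaults to off for operating-characteristics runs, whose published
summary concerns screening-stage graduation; when on, analyses are
stratified by line, computing superiority per (signature, line) against
the pooled same-stratum control and combining lines weighted by treated
patients.

Everything is reproducible bit-for-bit from (scenario, seed), and
`export_trial()` writes the patient ledger, decision history, allocation
history, and a manifest with the seed.

## Operating characteristics

`run_replicates()` runs seeded replicates (`base_seed + i - 1`) and
aggregates per-pair graduation/drop probabilities, sample sizes, and
durations, always with Monte Carlo standard errors. "Overall type-I
error" is scored as the familywise probability that any truly-null pair
graduates in a replicate; "per-drug" is the marginal for each drug — the
pairing that matches the two-stage arithmetic
`two_stage_type_one(0.30, 0.15) = 0.045`.

Two sample-size readings are reported at graduation: treated patients in
the pair (`mean_n_at_graduation`) and treated plus signature-restricted
control comparators (`mean_participants_at_graduation`). The published
70–95 band can only be the latter: control protection guarantees the
control at least matches the best arm, so 70–95 *treated* patients would
put signature accrual far beyond the 150 cap.

```{r oc, eval = FALSE}
scn <- scenario(effects = setNames(10, pair_key("T1", "TP53+")))
rep <- run_replicates(scn, 200, base_seed = 1)
power_and_sample_size(rep, truth_table(scn))
```

## Default study conditions and problem sizes

Simulation defaults are chosen once as the study conditions: 4 treatments,
each a candidate in all 5 signatures; baseline mean PFS 8 months (the
value implied by the default prior at shape 1); effects spanning 0 to +10
months; accrual 7/month; 10% non-evaluable; 60-month horizon; thresholds
85%/15% with min 20, cap 150, burn-in 50. Acceptance-level checks use 200
replicates per scenario and report Monte Carlo standard errors; the
effective-scenario checks place a +10 or +5 month effect on the TP53+
signature, the mid-prevalence single-marker signature (0.37), chosen once
as representative.

## Numerical choices and degenerate inputs

* Zero-exposure subjects (enrolled at the current interim month) are
  excluded from the update — they carry no likelihood contribution at
  $k \ge 1$ and the data container requires strictly positive times.
* Prior-only posteriors give superiority exactly 0.5; a platform with no
  outcomes therefore randomizes uniformly, continuous with burn-in.
* All-zero adaptive weights fall back to the equal row rather than 0/0.
* A subgroup whose every arm has left (and with no open confirmatory
  trial) routes new patients to the observational arm.
* Ties at thresholds resolve inclusively for graduation ($P \geq$) and
  futility ($P \leq$), matching the rule statements.

## What the simulator does and does not emulate

The generator reproduces the stated marginal prevalence structure, Poisson
accrual at the reported rate, exponential-family PFS, and the full
decision machinery. It does not model calendar-time drift in the patient
mix (a known critique of outcome-adaptive designs), site effects, clonal
evolution of profiles between randomizations, toxicity-driven
discontinuation beyond the flat dropout rate, or data-safety-board
discretion — the engine emits rule-based recommendations, while the
operating trial vests final decisions in its monitoring board. Passing
simulation bands here therefore speaks to the design logic under these
idealized conditions, not to the behavior of any particular clinical
dataset.

A consequence worth stating plainly: with fully automatic monthly
decision application, a naked 85% posterior threshold is examined dozens
of times per pair, and the familywise false-graduation rate under the
null at these desk-scale conditions is substantially higher than the
single-look intuition suggests. The acceptance suite measures and reports
this honestly; tightening it would require design levers (decision
cadence, consistency strictness, explicit alpha-spending) whose original
calibration settings are not public.
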