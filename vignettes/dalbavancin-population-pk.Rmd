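---
title: "Methods: population pharmacokinetics and dosing simulation for single-dose dalbavancin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics and dosing simulation for single-dose dalbavancin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the
decisions behind them: what is estimated, how, under which conventions,
and what the synthetic data can and cannot show.

## The model

Total dalbavancin plasma concentration after an intravenous infusion is
described by a one-compartment model with zero-order input and
first-order elimination. For an individual with volume `V` (L) and
clearance `CL` (L/h), infusion rate `R0 = amount/duration`, duration `D`
and `k = CL/V`:

* during the infusion: `C(t) = R0/CL · (1 − e^{−k t})`
* after it:            `C(t) = C(D) · e^{−k (t − D)}`

Both the concentration and the windowed AUC are evaluated analytically
(the disposition is represented internally as a sum of exponential
terms, which also yields the two-compartment candidate model with the
usual α/β macro-constants). Superposition over dose events is supported
although the study regimen is a single dose, so that spaced repeated
infusions can be explored. The infinite-horizon AUC equals
`amount/CL` exactly, which the test suite uses as an oracle, alongside a
numerical ODE solution that the closed form must match to within 0.1%.

Between-subject variability is log-normal on `V` and `CL`
(`ψ_i = ψ_pop e^{η_i}`, `η ~ N(0, ω²)`, diagonal covariance, no
η-correlation), and residual variability is proportional,
`y = f (1 + b ε)`. Observations below the 1.0 mg/L quantification limit
are flagged on read and excluded from the likelihood — a simple exclusion
rather than a censoring likelihood, defensible here because trough
concentrations in this setting sit far above the limit.

The reference parameter set used for simulation and as generating truth
is `dalbavancin_model()`: `V = 17.9` L, `CL = 0.036` L/h, `ω_V = 0.200`,
`ω_CL = 0.290`, `b = 0.120`. The dispersion entries are interpreted as
standard deviations of the log-parameters; if they were variances, the
simulated spread would roughly double (see the dosing-simulation section
for where this matters).

## Estimation: SAEM

`saem()` maximises the marginal likelihood by stochastic approximation
EM. Design choices:

* **Chain state.** The Markov chains operate on the individual
  log-parameters `φ_i` directly (not on `η_i`): the data likelihood
  depends only on `φ`, so M-step updates of the population location never
  invalidate the cached per-chain predictions. Proposals are
  component-wise Gaussian random walks, two chains per subject by
  default, with per-subject step sizes adapted multiplicatively
  (×1.08 on acceptance, ×0.95 on rejection, stationary near 40%
  acceptance).
* **Phases.** 500 exploration iterations with step size `γ = 1`, then
  200 smoothing iterations with `γ = (k − K₁)^{−0.7}`. During
  exploration the variance components are floored at 95% of their
  previous value per iteration (a simulated-annealing-style guard against
  premature collapse of `ω` or `b`).
* **M-step.** Sufficient statistics are the per-subject chain means of
  `φ` and `φ²` and the summed squared proportional residuals; with a
  covariate model the location update is an ordinary least-squares
  regression of the accumulated `φ` on the covariate design (power
  functions of continuous covariates are linear in log-space).
* **Parameterisation.** Everything is estimated in log space
  (`log V`, `log CL`, `log ω` implicitly through the variance update,
  `b²` through the residual statistic), which enforces positivity.
* **Initialisation.** A naive pooled heuristic: the terminal slope of a
  pooled `log(DV) ~ time` regression gives `k`, its intercept
  back-extrapolates `C(0)` and hence `V = dose/C(0)`; `ω` starts at 0.3
  and `b` at 0.2.
* **No-variability parameters.** Fixing an `ω` at zero via
  `saem_control(fix_omega=)` removes that random effect; if all are
  fixed at zero the model has no latent variables and the package
  switches to direct maximum likelihood (BFGS), which the tests compare
  against an independent nonlinear least-squares fit.
* **Convergence.** A post-hoc slope test on the last 20% of each
  parameter trace flags residual drift; gross drift (>50% of the
  parameter over the tail), collapsed IIV, or non-finite estimates unset
  the `converged` flag, while mild drift is reported as a warning only —
  the usual reading of stochastic EM traces.

Trough-only designs deserve a warning that the package reports rather
than hides: the marginal likelihood is weakly informative about `V`
(around three weeks post-dose the log-concentration sensitivity to `log V`
passes through zero) and can be multimodal, with a degenerate
flat-profile mode (`CL → 0`) and boundary solutions (`ω_V → 0`).
Individual replicate estimates of `V` can therefore deviate substantially
from the generating value even for an exact maximum-likelihood estimator;
medians across replicate cohorts are well-behaved. The default iteration
budget was chosen once (500 + 200) as a balance between tracking the ML
and not wandering between modes on such surfaces.

## Likelihood, information criteria, standard errors

The objective function value (−2 log marginal likelihood) is estimated by
importance sampling: per subject, a multivariate t proposal (df = 4)
centred at the empirical Bayes mode with the conditional-posterior
curvature as scale; the Monte Carlo SE is reported. On toy problems the
test suite checks the estimate against 20-node adaptive Gauss–Hermite
quadrature written independently of the package internals. `AIC = OFV + 2p`;
the corrected BIC uses the mixed penalty convention of SAEM software:
`ln(N_subjects)` per population parameter and `ln(n_obs)` per
residual-error parameter.

Relative standard errors default to Louis' identity evaluated on
posterior samples of the random effects drawn with the fit's own
Metropolis kernel (scores and Hessians of the complete-data
log-likelihood by central finite differences); if the resulting
information matrix is not positive definite the package falls back to a
finite-difference observed information of the adaptive-quadrature
marginal log-likelihood. The method actually used is recorded on the
result. Eta shrinkage is `100 (1 − SD(EBE)/ω)`, undefined when `ω = 0`.

Structural model selection fits each candidate and ranks by BICc, then
AIC, then parameter count; candidates that error out or hard-fail
convergence are excluded with the reason, and RSEs above 50% are flagged
as identifiability pathologies.

## Diagnostics

* **Bootstrap** (`pk_bootstrap()`): subjects resampled with replacement,
  each replicate refitted with the base estimates as initials and a
  reduced iteration budget (150 + 75) — a runtime choice that is a
  documented deviation risk if replicate likelihoods are multimodal.
  Percentile CIs use type-7 quantiles; non-converged replicates are
  dropped and counted, with a warning above 10%.
* **NPDE** (`npde()`): `K = 1000` replicates of each subject's
  observation vector (IIV + residual error), per-subject decorrelation by
  the Cholesky factor of the simulated covariance, then
  `npde = Φ⁻¹((rank + 0.5)/(K + 1))` with ties contributing half a rank.
  The global test combines a t-test of mean zero, a χ² test of unit
  variance and Shapiro–Wilk normality with a Bonferroni factor of 3.
  These conventions (K, tie handling, test battery) are the package's
  own; calibration under the generating model is verified by simulation
  in the test suite.
* **pc-VPC** (`pc_vpc()`): prediction correction
  `pcY = Y · median(PRED_bin)/PRED`, observed 10/50/90th percentiles per
  bin against 90% simulation intervals from 500 replicates; weekly bins
  by default, bins with fewer than two observations merged into a
  neighbour with a message. Percentile and interval choices are
  conventional, not data-derived.
* **GOF** (`gof_table()`): PRED, IPRED, `IWRES = (DV − IPRED)/(b·IPRED)`
  and optionally NPDE per observation.

## Covariate search

Continuous covariates enter as power functions normalised to the cohort
median; sex as a proportional factor. The stepwise procedure adds, at
each forward step, the candidate with the largest OFV drop exceeding
χ²₁(0.05) = 3.84, then removes backwards any covariate whose exclusion
costs less than χ²₁(0.01) = 6.63 — the field-standard thresholds, chosen
here because none are stated for this analysis. Ties are broken by the
larger IIV reduction, then alphabetically. All candidate OFVs are
importance-sampling estimates computed with a common seed (common random
numbers keep ΔOFV noise far below the decision thresholds), and every
tested pair is logged with its ΔOFV, IIV change and decision. The
qualitative "plausibly related" retention criterion cannot be automated;
the log carries a `plausibility` column marked for manual review instead.
The CKD-EPI 2009 equation omits the race coefficient; Cockcroft–Gault
uses the 0.85 female factor.

## Dosing simulation and PTA

`pta_table()` draws `n = 1000` individual `(V, CL)` pairs from the
population model (IIV only — no residual error and no
parameter-uncertainty sampling, the most common convention), computes
each profile's total AUC over the 24-h window `[24·D, 24·D + 24]` hours
after dose start for evaluation days D = 21, 27, 35, converts to unbound
exposure with a fixed scalar `fu = (100 − binding)/100` per scenario
(binding 93/95/97/99%), and reports
`PTA = 100 · #{fAUC0-24/MIC ≥ target}/n` over the MIC grid, flagging
cells ≥ 90% as optimal. The day-window convention is the literal reading
of "day D post-dose"; it is the single most consequential convention in
the package:

* Under it, every reported cell at bindings ≤ 97% reproduces within
  Monte Carlo tolerance, as does the low-MIC part of the 99% column.
* The high-MIC part of the 99%-binding column does **not** reproduce:
  with `fu = 0.01` the typical individual's day-21 fAUC0-24 is
  `0.01 × 711 ≈ 7.1` mg·h/L, below the `50 × 0.25 = 12.5` mg·h/L the
  kill target requires, so PTA is near zero — a different window
  convention, dispersion read as variances, or parameter-uncertainty
  sampling would be needed to raise it, and none is stated. The package
  does not guess; that column is exercised for monotonicity only.

The stasis table is the same computation at target 25 and dominates the
kill table cell-wise by construction. Monte Carlo error follows the
binomial law `SD ≈ √(p(100−p)/n)`, verified empirically in the tests;
1,000 profiles put mid-range cells within about ±1.6 points.

## The synthetic cohort

`generate_pk_dataset()` emulates the modelled study design: 18 subjects;
a single 1,500 mg dose infused over 0.5 h or 2 h (even mix — the two
participating-centre practices); 1–3 samples per subject drawn from
follow-up windows of days 8–14, 18–23 and 26–30 with weights
0.2/0.45/0.35 mirroring the observed trough groups; covariates drawn to
match an elderly, 70%-female cohort with preserved renal function
(eGFR centred near 90 mL/min, serum creatinine back-calculated through
CKD-EPI) and normal albumin. Concentrations are model predictions with
proportional error; values under 1.0 mg/L are flagged BLQ. The generator
records the generating `η` draws as attributes so that simulation studies
can score recovery.

What it does **not** emulate: clinically triggered (informative)
sampling times, assay imprecision structure beyond the proportional
term, measurement-day clustering, or any covariate–parameter
relationship (the generating model is covariate-free, matching the
study's negative covariate analysis). Passing tests on these data
therefore demonstrate estimator correctness under the stated design, not
robustness to the messiness of routine therapeutic drug monitoring.

`cohort_fixture()` is a deterministic, clearly synthetic 20-patient
clinical-outcomes table: the aggregates (sex, joints, the 24 isolates
with 17 CoNS of which 12 *S. epidermidis*, 6 *C. acnes*, 1 *E. faecalis*,
4 polymicrobial, 19/20 second-stage surgeries, one positive second-stage
culture) and the medians/interquartile intervals of age, prior-IV days,
surgery interval and follow-up reproduce the published cohort summary;
patient-level values and isolate MICs are constructed and carry no
patient information. Medians use the mean-of-middle-two convention and
IQIs are type-7 quantiles. `cohort_summary()` computes microbiological
cure as negative second-stage cultures over second-stage surgeries
(18/19 = 94.7%).

## Numerical choices and degenerate inputs

* Internal floor of 10⁻⁴ on ω during sampling (ω = 0 is reported
  exactly when fixed); floor of 10⁻¹² on predicted concentrations inside
  likelihoods; Metropolis steps where both states are impossible
  (−∞ vs −∞) accept, so chains leave impossible regions.
* Proposal scales are per-subject and per-parameter.
* Subjects with no quantifiable observation are excluded from estimation
  with a message; an empty dataset is refused.
* `t2 = Inf` is an explicit sentinel for infinite-horizon AUC.
* Pipeline outputs carry the generating seed and a configuration hash;
  rerunning a configuration is byte-identical.

## Problem sizes in the shipped tests

The test suite works at sizes chosen to exercise every claim with
adequate power: 20 replicate cohorts for parameter recovery and NPDE
calibration; 20 null replicates with an 8-pair candidate set for the
covariate type-I check; 10 structural-selection replicates; bootstrap
checks at 200 resamples across 10 runs plus a 50-resample smoke run; the
grid-search ML oracle on a 50³ log-spaced grid with 15-node quadrature.
The shipped pipeline defaults are the full analysis sizes (1,000
bootstrap resamples, 500 VPC simulations, 1,000 NPDE replicates, 1,000
PTA profiles).

## Known limitations

* Single response, diagonal Ω, proportional error only as the final
  model (additive/combined error and multicompartment structure exist as
  candidates, not as tuned alternatives).
* No censoring likelihood for BLQ data (exclusion only).
* The bootstrap's warm start and reduced budget can understate replicate
  variability on multimodal likelihood surfaces.
* PTA reflects plasma exposure only; site-of-infection (bone) penetration
  is out of scope.
* The stepwise search automates only the quantitative retention criteria.
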