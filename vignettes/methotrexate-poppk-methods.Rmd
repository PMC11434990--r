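---
title: "Methods: population pharmacokinetics of high-dose methotrexate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of high-dose methotrexate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtxpoppk)
```

## The problem

High-dose methotrexate (HDMTX, 12 g/m^2 over a 4-h infusion) is the
backbone of pediatric osteosarcoma chemotherapy, and its toxicity is
managed by therapeutic drug monitoring (TDM): serum concentrations drawn at
nominal 24/48/72/96 h after the end of infusion, compared against protocol
thresholds, and answered with escalating leucovorin (folinic acid) rescue.
`mtxpoppk` packages a complete population-pharmacokinetic workflow for this
setting: a hierarchical two-compartment model with covariates, an
approximate-marginal-likelihood estimator, external-validation metrics,
simulation-based diagnostics, and a forward simulation layer that
anticipates rescue needs under acute kidney injury (AKI).

## The model

Drug disposition follows a two-compartment model with first-order
elimination from the central compartment, parametrized in clearance terms:
micro-constants $k_{10}=CL/V_c$, $k_{12}=Q/V_c$, $k_{21}=Q/V_p$, with
hybrid rate constants $\alpha,\beta$ from
$\alpha+\beta=k_{10}+k_{12}+k_{21}$ and $\alpha\beta=k_{10}k_{21}$. The
central concentration after a constant-rate infusion is the standard
biexponential closed form; multiple infusions superpose.

Individual parameters combine fixed effects, median-normalized covariate
effects and log-normal random effects:

$$CL_i = TVCL \left(\frac{SCr}{0.58}\right)^{\theta_{SCr}}
        e^{\eta_{CL} + \kappa}, \qquad
  V_{c,i} = TVVC \left(\frac{BSA}{1.45}\right)^{\theta_{BSA}} e^{\eta_{Vc}},$$

with $Q$ and $V_p$ at their typical values. $(\eta_{CL},\eta_{Vc})$ are
between-subject effects with full 2x2 covariance $\Omega$ (SDs 19.8% and
13.5%, correlation 0.94 in the packaged final model); $\kappa$ is a
between-occasion effect on clearance redrawn each treatment cycle, all
occasions sharing one variance (SD 15.1%). Observations carry proportional
residual error $y = f(1+\sigma\varepsilon)$, $\sigma$ = 30.9%. The packaged
final parameters are `final_mtx_model()`; printed exponent variances
(0.0391, 0.0228, 0.0181) are read as the variances of $\eta_{CL}$,
$\kappa$ and $\eta_{Vc}$, which is consistent with the reported SDs
(0.198^2, 0.151^2, 0.135^2) — a consistency the test suite checks.

Design choices worth stating explicitly:

* **Time origin.** All dataset times are decimal hours from the start of
  the first infusion. The protocol's nominal "24/48/72/96 h after the end
  of infusion" map to 28/52/76/100 h absolute within a cycle.
* **Correlated BSV.** The 94% CL–Vc correlation is implemented as a full
  2x2 $\Omega$ block (not a shared $\eta$), optimized on an unconstrained
  scale (log SDs, atanh correlation).
* **Occasions.** One $\kappa$ per (subject, cycle), indexed by the observed
  cycle number even when cycles are non-sequential; a single shared
  variance. Cycles two weeks apart carry no meaningful drug over
  (terminal half-life is roughly a day), so each occasion is predicted
  from its own dose; the closed-form kinetics themselves support arbitrary
  multi-dose superposition.
* **Covariates.** SCr and BSA are held piecewise-constant within a cycle at
  the value recorded at the cycle start; within-cycle interpolation is not
  attempted. Reference values (0.58 mg/dL, 1.45 m^2, the cohort medians)
  are stored in the model object, not hard-coded.
* **Degenerate kinetics.** When $\alpha\approx\beta$ the root separation is
  floored at $10^{-8}(\alpha+\beta)$ (an epsilon-perturbation rather than a
  series limit; the induced relative error is below the $10^{-6}$
  equivalence tolerance we verify against the ODE integrator). $Q=0$
  reduces exactly to the one-compartment solution.
* **Positivity of simulated observations.** With $\sigma=0.309$ a normal
  proportional error can produce negative concentrations; simulation
  redraws the deviate until positive (counted in an attribute). The
  observation model used in estimation is untruncated — at the
  concentrations and residual scale of this design the truncation mass is
  small, and the dataset contains no below-quantification values.

## Estimation

`fit_population()` maximizes a subject-level Laplace approximation to the
marginal likelihood in the FOCE-I spirit: the joint $-2\log$ density of a
subject's observations and random effects
$u=(\eta_{CL},\eta_{Vc},\kappa_1..\kappa_K)$ is minimized over $u$ (Newton
with ridge and backtracking, finite-difference derivatives, gradient
tolerance $10^{-8}$), the conditional residual variance uses
$\sigma^2 f(u)^2$ at the current $u$ (the "interaction" convention), and
the subject's contribution is the mode value plus the log-determinant
correction of the inner Hessian. The outer problem runs `nlminb` on the
transformed parameter vector. We do not replicate the exact NONMEM
linearization bit-for-bit; the method class is the same and the package's
own acceptance bar is parameter recovery, not objective-value equality.
Printed objective values from other software are convention-dependent and
are not comparable.

Two numerical points discovered the hard way:

* The inner Laplace step gives the outer objective a small noise floor, so
  `nlminb` frequently stops with "false convergence" *at* the optimum. The
  fitter therefore restarts once from the solution and classifies the fit
  as practically converged when the restart cannot improve the objective
  by more than 0.05.
* Standard errors come from a central-finite-difference Hessian of the
  objective (covariance $2H^{-1}$), delta-transformed to the natural
  scale; RSE% is $100\cdot SE/|\hat\theta|$. Shrinkage is
  $1 - SD(\hat\eta)/\omega$.

Empirical-Bayes (MAP) estimates with fixed population parameters —
the standard "no estimation, posterior modes only" evaluation mode — are
exposed as `map_individual()`, and `predict_conc()` gives population
($u=0$) and individual predictions.

The compiled closed-form/Laplace path is cross-checked in the tests
against an independent pure-R implementation and against pooled nonlinear
least squares in the no-random-effect limit.

### Structural comparison and covariate search

`compare_structures()` refits the dataset under a third compartment or
saturable elimination ($CL/(1+C/K_m)$, which nests the linear model as
$K_m\to\infty$) via deSolve, and flags OFV improvements against chi-square
thresholds — mirroring the usual finding at this sampling design that
neither is supported. `stepwise_covariates()` implements forward inclusion
(largest OFV drop, threshold 3.84, i.e. p<0.05 at df 1) over
median-normalized linear/power/exponential forms, then backward elimination
(threshold 6.63, p<0.01); ties break by candidate order and constant
covariates are skipped with a log entry. Thresholds are arguments, not
constants. One safeguard proved necessary for a calibrated type-I error:
because the outer objective can stall a few points above its optimum, a
candidate refit sometimes "finds" OFV points that are optimization-basin
gains rather than covariate signal. Before accepting a forward step, the
reduced model is therefore refitted warm-started from the winning
candidate's solution, and the OFV drop is re-scored against the best
reduced-model objective seen — a symmetrized likelihood-ratio comparison.

## External validation metrics

`prediction_errors()` computes $PE_i = 100(C_{i,pred}-C_{i,obs})/C_{i,obs}$
and summarizes MPE (mean), MAPE, RMSE ($\sqrt{mean(PE^2)}$), F20 and F30
(percent of $|PE|$ within 20/30%). One deliberate quirk: the source
analysis *defines* MAPE as the median of signed PE, despite the name; the
default follows that printed definition and `mape_absolute = TRUE` gives
the conventional median $|PE|$. The clinical acceptability verdict is
F20 $\ge$ 35%, F30 $\ge$ 50%, $|MPE|\le$ 30% and RMSE $\le$ 30% (MPE is a
signed quantity; the rule is applied to its magnitude).

`vpc()` re-simulates the design and summarizes percentiles per
time-after-infusion bin. Defaults: bins at the nominal monitoring times
with ±3 h windows (observations outside every window are flagged, not
silently dropped), percentiles 5/50/95 with a 10/50/90 preset — both
conventions appear in practice, so both are first-class.
Prediction-corrected VPC is out of scope. `gof_tables()` reports
FOCE-linearized conditional weighted residuals
($V^{-1/2}(y-f(\hat u)+G\hat u)$ with $V = G\Omega G' + diag(\sigma^2
f(\hat u)^2)$), which are approximately standard normal under the correct
model.

## The synthetic cohort

No patient-level data ship with the package; `sample_cohort()` and
`simulate_trial()` generate datasets with the *summary* structure of the
study cohort: 32 patients aged 5–18 (median ~13), weight 13.8–85.5 kg,
height 115–177 cm, baseline SCr log-normal with cohort median ~0.58 mg/dL
truncated to [0.17, 3.2], ~216 cycles in total (mean ~6.75 per patient,
reflecting retrospective missingness of cycles), per-cycle realized dose
truncated-normal around 11.9 g/m^2 in [5.9, 12.9], 2–6 samples per cycle
(median 3, mean ~2.8) at jittered nominal times, and sex-/age-dependent
height-weight growth curves tuned to those ranges. BSA (Haycock), BMI
(Quetelet) and CrCL (Schwartz) are always computed from weight/height/SCr,
never drawn. The Schwartz constants are the original ones (0.55; 0.70 for
adolescent males) because the revised bedside constant cannot reproduce a
cohort CrCL median near 190 mL/min/1.73 m^2; with the packaged mixed-sex
defaults the cohort median lands near 160 — the study's own median is only
matched under the adolescent-male constant, and we chose to keep the
sex-specific constants rather than force the summary statistic.

What the generator does *not* emulate: growth-chart realism beyond
range/median fidelity, co-medication, informative sampling (samples being
added *because* a patient runs toxic), or assay error structure beyond the
proportional model. Passing tests therefore demonstrate internal
consistency of the method on designs like the study's — not external
validity on real patients.

Sampling-time imputation (`impute_sample_time()`) reproduces the
single-imputation rule for missing draw times: subtract the mean
arrival-minus-sampling offset (the study reports 32.5 ± 4.7 min) estimated
from complete records.

## Rescue simulation

`classify_toxicity()` applies the protocol bands (24 h: 10/50 uM; 48 h:
2/5 uM; 72 h: 0.3/1 uM, printed mg/L equivalents 4.5/22.7, 0.9/2.3,
0.1/0.5). Band edges follow the printed table: "target" is strictly below
the lower bound, the moderate band is inclusive at both printed endpoints,
severe strictly above. Classification uses the printed one-decimal mg/L
values (the boundary convention is only self-consistent on that scale),
while `monitoring_complete()` uses the exact 0.3 uM conversion
(0.136332 mg/L). The molecular weight is fixed at 454.44 g/mol, which
reproduces all six printed conversions at one decimal.

`build_aki_scenarios()` scales an age-band reference SCr by 1.5/2.5/3
(low/moderate/high AKI). The reference table itself is not published in
the packaged analysis; the shipped defaults (0.50 mg/dL for 5–10 y,
0.70 mg/dL above 10 y) are literature-based normal values and explicitly an
external assumption — absolute simulated envelopes under AKI are therefore
only qualitatively comparable (monotonicity, threshold crossings), not
numerically. `simulate_rescue_risk()` simulates per-scenario cohorts at
12 g/m^2 and reports envelopes and toxicity probabilities at the end of
infusion and the three checkpoints.

One empirical observation the package surfaces honestly: forward
simulation of the final model for a normo-renal adolescent cohort puts
roughly 7–10% of 24-h concentrations in the moderate-or-worse band,
depending on the seed — noticeably more than the ~1% of *observed*
monitoring samples reported for the study data. The gap traces to the
model's log-normal clearance variability (BSV 19.8% + BOV 15.1%) acting
through the steep post-infusion decay: the elasticity of the 24-h
concentration to clearance is about −4, so modest parameter variability
implies a heavy upper tail that the observed data do not show. The
simulated severe fraction ( > 50 uM) *is* on the ~1% scale. This is a
genuine property of the published parameter set, not an implementation
artifact; the corresponding package check records it.

## Problem sizes and tolerances used by the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
one 32-subject study-scale dataset (~210 cycles, ~570 observations) for
parameter recovery (fixed effects within 15%, covariate exponent and BSV SD
within 25% — consistent with the reported RSEs of 19–36% on those
parameters); 300-replicate VPCs; 600-patient rescue cohorts; and
20-replicate covariate-search experiments at 24 subjects x ~5 cycles
(power) and 12 x 2 (type I error, judged against a 99.5% binomial envelope
of the nominal 5%). Closed-form kinetics are held to 1e-6 relative
agreement with a stiff ODE integration across randomized configurations.
These sizes were chosen so the whole suite runs in minutes on one core
while keeping Monte-Carlo error well inside each tolerance.

## Known limitations

* The estimator is a Laplace approximation; no SAEM/EM alternative, no
  NONMEM control-stream compatibility, and covariance-step replication is
  limited to finite-difference SEs.
* No below-quantification-limit handling (the motivating dataset had none)
  and no dialysis or glucarpidase modelling.
* The published model's own external validation against the real cohort
  cannot be reproduced here because the patient data are not public; the
  package instead validates the *machinery* against simulation oracles.
* Three-compartment and saturable-elimination structures exist as
  comparison candidates, not production paths.
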