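---
title: "Modeling social influence on visual categorization: methods"
author: "dyaddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling social influence on visual categorization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dyaddm)
```

## The scientific problem

In a two-phase dyadic training paradigm, an observer views a Glass pattern
— a field of paired dots (dipoles) whose common orientation rule creates a
global percept between radial (spiral angle 0°) and concentric (90°) — and
judges its category, then rates confidence on a 1–7 scale. The observer is
next shown the choice of a partner on the same stimulus and makes a second
(revised) decision with a second confidence rating. The partner is in fact
an algorithm: its choices are Bernoulli draws from a Boltzmann sigmoid
`P(concentric | x) = 1 / (1 + exp(-a (x - c)))` with slope `a = 0.2`/deg
and a boundary `c` of 45° (unbiased), 60° (biased), or 30°. Training with
a biased partner shifts the observer's own categorization boundary — the
point of subjective equality (PSE) measured in partner-free test phases —
toward the partner's boundary, and the shift persists.

The package implements the full computational pipeline around this
paradigm: the experiment designs, a coordinate-level stimulus generator, a
synthetic observer/cohort generator, psychometric estimation, a ten-model
hierarchical drift-diffusion analysis of the revised decisions, model
validation, and the behavioral indices linking confidence, susceptibility
to social influence, and traits.

## Experiment designs

`buildDesign()` encodes five designs. All share the nine spiral angles
{0, 20, 30, 40, 45, 50, 60, 70, 90}° at 60% signal. Training blocks have
90 trials (10 per angle, five blocks, 450 trials); test phases have 180
trials (20 per angle). `exp1` pairs the observer with the unbiased (45°)
partner, `exp2` and the `control` experiment with the biased (60°)
partner (`control` with peer-absent feedback), `exp3` trains individually
with no feedback, and `exp4` prepends 2–4 sessions of individual training
with error feedback (5 × 180 trials per session) before dyadic training
with a 30° or 60° partner. Trial order is a uniformly random within-block
permutation from a per-(subject, block) seed derived from the master seed;
no further constraints (such as excluding immediate angle repeats) are
imposed, since none are part of the protocol description. The
clockwise/counterclockwise handedness of patterns is a per-subject label
that enters no computation.

## Stimulus geometry

`generatePattern()` produces dipole center positions and orientations
inside a 7.7° square aperture; signal dipoles are oriented at the local
radial direction plus the spiral angle, noise dipoles uniformly at random.
Two free interpretations had to be fixed:

* *Dot density 3%* is read as (number of dots × dot area) / aperture
  area = 0.03 with 2.3 × 2.3 arcmin dots, giving
  `round(0.03 (7.7·60 / 2.3)^2 / 2)` = 605 dipoles. The denominator is
  configurable through `glassGeometry()`.
* Dipoles whose partner dot would leave the aperture are redrawn
  (rejection), keeping the dipole count exact.

Both position and orientation of noise dipoles are redrawn on every call
(a fresh pattern per trial). No rasterization or display model is
included, and observer behavior is generated by the decision model, not
from the dipole field.

## The synthetic observer

Observers are drift-diffusion agents. A Wiener process with unit noise
starts at `z·a` between boundaries 0 (concentric) and `a` (radial) and
drifts at rate `v`; the first boundary reached is the choice, the
absorption time plus `t0` is the response time (stimulus coding: upper
boundary = radial).

* **Initial decision**: `v = v0 + v_stim (boundary_c - angle)/45`,
  unbiased start (`z = 0.5`). `boundary_c` is the observer's internal
  category boundary.
* **Revised decision**: with personal information `P` (initial confidence
  signed by the initial choice, `P = choice · conf/7` ∈ [-1, 1]) and
  social information `S` (partner choice ±1; 0 when no partner),
  `v = v0 + v_stim·stim + v_personal·P + v_social·S` and
  `z = logistic(z0 + z_personal·P + z_social·S)`.
  The logistic link keeps the starting point in (0, 1) and is centered so
  that `z = 0.5` when the linear predictor vanishes.
* **Confidence** is not part of the diffusion model; the generator uses a
  stand-in: `conf = clamp(round(1 + 6·logistic(g·e + ε)), 1, 7)` with
  evidence strength `e = |angle - boundary_c|/45`, gain `g`, and Gaussian
  noise ε. This mechanism is an explicit modeling assumption — how humans
  produce confidence ratings is not observable from this design — and its
  parameters are population-level configuration. The alternative scaling
  of the personal code, `(conf-1)/6` instead of `conf/7`, is available via
  `conf_mapping = "zero_based"`.
* **Boundary assimilation.** The within-trial diffusion model does not by
  itself move the observer's internal boundary, yet the paradigm's
  signature is a persistent pre/post PSE shift. The generator therefore
  updates `boundary_c` after each dyadic training trial by exponential
  assimilation toward the partner boundary at rate κ per trial
  (`assimilation_rate`, default 0.002, halved under peer-absent
  feedback). Over 450 trials this yields a shift of roughly
  `(1 - (1-κ)^450) ≈ 0.59` of the 15° boundary discrepancy, i.e. about
  9°, the magnitude scale reported for biased dyadic training. Setting
  κ = 0 recovers a pure within-trial model.

Population defaults (`observerPopulation()`) are independent normals.
The covariate sensitivities default to the group-level posterior means
estimated for biased-partner training — `v_personal` 1.36, `v_social`
0.45, `z_personal` 0.10, `z_social` 0.14 — with `preset = "unbiased"`
switching to the unbiased-partner means (0.96, 0.33, 0.33, 0.30). The
structural parameters (`a` ≈ 2, `t0` ≈ 0.3 s, `v_stim` ≈ 2.7,
`boundary_c` ≈ 45° ± 2°) were chosen once so that the simulated initial
decisions produce psychometric slopes near 0.12–0.15/deg and revised RTs
almost entirely under 3.5 s (the analysis cutoff), i.e. a cohort that
looks like a typical naive group on this task. Trait scores
(`aq_social_skill`, `extraversion`) are drawn with a configurable
correlation (|r| = 0.35 by default) to each observer's generating
perceptual bias `v_social - v_personal`, negative for the AQ social-skill
score and positive for extraversion, so the mediation structure exists in
synthetic cohorts by construction.

What the generator does *not* emulate: perceptual learning of sensitivity
(slopes are stationary), sequential dependencies beyond the boundary
update, lapses/contaminant responses (the analysis nevertheless retains
its 5% outlier mixture), deception/debriefing content, and item-level
questionnaire responses. Passing tests on synthetic cohorts therefore
demonstrate the *estimators'* correctness under the assumed generative
structure, not the truth of that structure for human data.

## Psychometric estimation

`fitPsychometric()` fits the Boltzmann sigmoid by binomial maximum
likelihood (a least-squares-on-proportions objective is available for
comparison). The model deliberately has no lapse parameters, matching the
two-parameter sigmoid used for both the partner algorithm and the
analysis. The optimizer is L-BFGS-B from nine starts (`c` ∈ {30, 45, 60},
`|a|` ∈ {0.05, 0.2, 0.5}, slope sign taken from the empirical trend);
cleanly converged starts are preferred, then likelihood, with ties broken
toward the smallest `|c - 45|`. Complete separation (all responses one
category) yields a flagged, non-converged fit with no boundary. PSE
confidence intervals use a seed-controlled parametric bootstrap (500
replicates by default, off unless requested). `pseShift()` is the signed
difference of two converged boundaries; `blockwisePse()` tracks the
boundary across training blocks.

## The hierarchical drift-diffusion analysis

Only revised decisions are modeled (`fitHierarchical()` keeps rows with a
revised RT; `filterTrials()` first removes revised RTs above 3.5 s). The
likelihood of a (choice, RT) pair is the Wiener first-passage-time
density, computed with the small-time/large-time series and an adaptive
switch (standardized truncation error below 1e-10, well under the 1e-7
density target), mixed with a 5% uniform contaminant spread over the
observed RT range with half mass per boundary — the contaminant's exact
form is a package choice, as only the outlier probability is conventional.

Ten model variants (`buildModelSpace()`) differ in whether the starting
point and/or drift rate depend on personal and/or social information;
drift always depends on the stimulus code (angle mapped linearly to +1 at
0° and -1 at 90°). Model 1 is the baseline, model 10 the full model.

Subject-level parameters (log `a`, log `t0`, `v0`, `v_stim`, free
covariate sensitivities, `z0` and free `z` regressions on the logit
scale) are drawn from normal group distributions. Priors are
weakly-informative documented constants: group means normal with centers
(log 2, log 0.3, 0, …) and scales (1, 1, 3, 3, 3, 3, 2, 2, 2); group SDs
half-normal with scales 0.5 (log-scale and z parameters) or 1 (drift
parameters). Coefficients reported on the starting point are
linear-predictor (logit-scale) quantities; interpreting them on the
probability scale would change magnitudes, which is why the package never
reports them transformed.

Sampling is adaptive Metropolis-within-Gibbs: component-wise random-walk
updates per subject parameter (proposal scales tuned toward 44%
acceptance during burn-in), conjugate Gibbs updates for group means, and
log-scale random-walk updates for group SDs. The default configuration
mirrors a conventional long single-run regime (50,000 samples, burn-in
10,000, thinning 10) but runs two chains and computes split-Rhat on the
group-level draws; a fit is flagged non-converged when any split-Rhat
exceeds 1.05, and downstream validation refuses flagged fits unless
overridden. `mcmcConfig(profile = "fast")` (2,000 samples, burn-in 500,
thinning 2) is the reduced profile used throughout the test suite.

DIC is `D̄ + pD` with `pD = D̄ - D(θ̄)`, where the deviance is evaluated at
the posterior means of the subject-level parameters (subject-level
focus), recomputable from the stored traces and hence invariant to draw
order.

## Validation

* `posteriorPredictiveCheck()` regenerates datasets from posterior draws
  (2,000 by default) with trial covariates fixed and compares mean
  revised RT and switch probability across the four trial types — high/low
  initial confidence × agreement/disagreement. The confidence split is at
  each subject's own mean (ties to "high"); a grand-mean split is behind a
  flag. Regeneration uses the Wiener process without the outlier
  component.
* `parameterRecovery()` simulates datasets (10 by default) from known
  subject-level parameters, refits, and reports generating-vs-estimated
  correlations and bias; parameters below correlation 0.5 are flagged.
  Refits with failing diagnostics are flagged rather than silently
  dropped (only erroring refits are dropped and counted), so reduced
  configurations remain inspectable.
* `crossValidateBoundary()` simulates cohorts under the 45° and 60°
  partners and fits psychometric curves to the simulated revised choices.
* `gridDeltaPse()` maps the change of PSE over two 2-D grids — drift
  dependencies (v_personal 0.5–2 by 0.15 × v_social 0–0.8 by 0.08) with
  the starting-point dependencies at zero, and the starting-point twin
  with the drift dependencies at zero — under the 60° partner, 10,000
  trials per angle per cell by default, one shared generating observer
  per grid so that only the varied sensitivities differ. The two grids
  are kept separate (varying v- and z-dependencies jointly would
  confound the comparison the grids exist to make). Because only choices
  enter a psychometric fit, cells are simulated from the closed-form
  Wiener choice probabilities (exact for the choice marginal) rather than
  by path simulation, which makes the default grid tractable.

## Behavioral indices

`switchTable()` (2 × 2 switch probabilities; empty cells are missing, not
zero), `confidenceDynamics()` (initial/revised confidence by stay/switch
under disagreement), `metacognitiveSensitivity()` (OLS slope of
confidence on accuracy coded correct = 0, incorrect = 1, boundary-angle
trials = 0.5; note this coding makes *better* metacognition *more
negative*, a sign convention the package preserves exactly rather than
resolves), `socialSusceptibility()` (per-subject regression of z-scored
signed revised confidence on z-scored signed initial confidence and the
±0.5-coded partner choice; z-scoring is within subject; SSI = β_social −
β_personal), `biasIndices()` (v_social − v_personal and z_social −
z_personal from full-model subject posterior means), and `mediate()`
(bias-corrected — BC, not BCa; no acceleration term — percentile
bootstrap for the indirect effect a×b, 5,000 resamples by default,
significant when the 95% CI excludes zero). Trials at the physical
boundary have no correct answer; the 0.5 coding applies only to the
metacognition regression, and such trials are excluded from
accuracy-based switch analyses while still entering confidence analyses.

## Numerical choices and degenerate inputs

Seed fan-out uses a multiplicative-congruential hash (`splitSeed()`) so
every stage, subject, and block has an independent reproducible stream
below 2^31. Diffusion paths use Euler–Maruyama at dt = 1 ms with a 10 s
cap; uncapped paths are resampled and counted (< 1e-6 of trials at
default parameters). The drift-free limit of the choice probability is
returned analytically as `z`. `t ≤ t0` yields zero density, not an
error; the outlier mixture keeps the posterior proper even for extreme
proposals. Psychometric fits flag separation instead of guessing a
boundary.

## Problem sizes in the test suite

The packaged tests run every stage at sizes chosen to exercise the full
code path while staying desk-scale: cohorts of 3–8 subjects for unit
tests; parameter recovery of the drift sensitivities at 20 subjects × 450
training trials with the fast MCMC profile; the ten-model DIC comparison
at 8 subjects with 1,500-iteration chains; grids at 3 × 3 cells × 1,500
trials per angle; mediation calibration over 200 null replicates of
n = 40 with 400 bootstrap resamples. Default arguments everywhere retain
the full-scale values.

## Known limitations

* The confidence generator is a stand-in; recovered confidence-linked
  quantities (metacognitive sensitivity, SSI) validate the estimators,
  not a psychological theory of confidence.
* The boundary-assimilation rule is phenomenological. A learning model
  of *why* the boundary shifts (e.g. reinforcement or Bayesian belief
  updating) is out of scope; the 15° full-conformity shift serves only
  as an analytic reference point.
* No inter-trial variability parameters (sv, sz, st0) are included in
  the diffusion models, matching the ten-model space.
* Group comparisons beyond the defined indices (omnibus ANOVA machinery,
  post-hoc tests) are deliberately left to standard tools.
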