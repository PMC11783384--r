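# dyaddm

Simulation and analysis of **two-phase dyadic training** experiments on
visual categorization, for researchers in psychophysics and computational
cognitive modeling.

An observer categorizes a Glass pattern (radial vs. concentric, spiral
angle 0–90°), rates confidence (1–7), sees a partner's choice on the same
stimulus, then decides and rates again. The "partner" is an algorithm
whose choices follow a Boltzmann sigmoid

```
P(concentric | x) = 1 / (1 + exp(-a (x - c)))
```

with slope `a = 0.2`/deg and boundary `c` = 45° (unbiased), 60° or 30°
(biased). Training with a biased partner shifts the observer's own
categorization boundary — the point of subjective equality (PSE) — toward
the partner's.

The package provides the full computational pipeline:

* **Designs & stimuli** — the five experiment protocols
  (`buildDesign()`), exact stimulus schedules (`enumerateTrials()`), and
  coordinate-level Glass-pattern dipole fields (`generatePattern()`).
* **Synthetic cohorts** — drift-diffusion observers with confidence and
  trait scores, paired with Boltzmann-policy partners
  (`simulateCohort()`, `observerPopulation()`).
* **Psychometrics** — binomial-MLE Boltzmann fits, PSE, slope, bootstrap
  CIs, block-wise trajectories, PSE shifts (`fitPsychometric()`,
  `pseShift()`, `blockwisePse()`).
* **Hierarchical drift-diffusion analysis** — ten model variants in which
  the starting point `z` and/or drift rate `v` of the revised decision
  depend on *personal information* (signed initial confidence) and
  *social information* (the partner's choice):

  ```
  v = v0 + v_stim·stim + v_personal·P + v_social·S
  z = logistic(z0 + z_personal·P + z_social·S)
  ```

  fitted by adaptive Metropolis-within-Gibbs with a Wiener
  first-passage-time likelihood plus a 5% uniform outlier mixture, and
  compared by DIC (`fitHierarchical()`, `buildModelSpace()`,
  `computeDic()`).
* **Validation** — posterior predictive checks, parameter recovery,
  partner-boundary cross-validation, and ΔPSE parameter grids
  (`posteriorPredictiveCheck()`, `parameterRecovery()`,
  `crossValidateBoundary()`, `gridDeltaPse()`).
* **Behavioral indices** — switch-probability tables, confidence
  dynamics, metacognitive sensitivity, the social susceptibility index
  (β_social − β_personal), perceptual/response bias indices
  (v_social − v_personal, z_social − z_personal), and bias-corrected
  bootstrap mediation (`switchTable()`, `metacognitiveSensitivity()`,
  `socialSusceptibility()`, `biasIndices()`, `mediate()`).
* **Orchestration** — `runPipeline()` runs
  simulate → filter → fit → compare → indices from one config
  (a reduced example lives at `inst/extdata/exp2-small.yaml`);
  `makeFixtures()` writes the deterministic toy tables used in tests.

See the methods vignette (`vignettes/dyadic-training-ddm.Rmd`) for the
model, priors, generator assumptions, and numerical choices.

## Worked example

Simulate a biased-feedback cohort (6 observers, 60° partner), measure the
boundary shift, and fit the full drift-diffusion model to the revised
decisions:

```r
library(dyaddm)
design <- buildDesign("exp2")
trials <- simulateCohort(design, n_subjects = 6, master_seed = 11)

pre  <- fitPhase(trials, "pretest")
post <- fitPhase(trials, "posttest")
pseShift(pre, post)
#> Boltzmann fit: slope a = 0.1129 /deg, PSE c = 42.22 deg
#> Boltzmann fit: slope a = 0.1197 /deg, PSE c = 51.79 deg
#> PSE shift: 9.57
```

The pretest boundary sits near the physical midpoint (45°); after 450
dyadic training trials with the biased partner the posttest boundary has
moved ~10° toward 60°. Switching behavior shows the conformity signature
— observers switch far more often when the partner disagrees, and less
when initially confident:

```r
summary(switchTable(filterTrials(trials[trials$phase == "training", ])$trials))
#>   confidence agreement   p_switch
#> 1       high     agree 0.012
#> 2        low     agree 0.042
#> 3       high  disagree 0.269
#> 4        low  disagree 0.382
```

The hierarchical fit of the full model (reduced MCMC profile) recovers
positive effects of both information sources on the drift rate:

```r
train <- filterTrials(trials[trials$phase == "training", ])$trials
fit <- fitHierarchical(train, 10, mcmcConfig(profile = "fast"), seed = 5)
summary(fit)[c(5, 6, 8, 9), ]
#>       parameter  mean    sd   q2.5 q97.5
#> 5 mu_v_personal 1.358 0.116  1.137  1.59
#> 6   mu_v_social 0.509 0.194  0.133  0.92
#> 8 mu_z_personal 0.125 0.105 -0.078  0.34
#> 9   mu_z_social 0.063 0.066 -0.066  0.19
posteriorDirectionProb(fit, "v_social")
#> 0.991
```

`mu_v_personal` and `mu_v_social` are the group-level drift sensitivities
to the observer's own signed confidence and to the partner's choice; over
99% of the posterior mass for both lies above zero, i.e. both information
sources bias evidence accumulation toward their favored boundary.
Subject-level perceptual bias estimates track the generating values
(`cor ≈ 0.85` in this cohort):

```r
bi <- biasIndices(fit)
cor(with(attr(trials, "observers"), v_social - v_personal), bi$perceptual_bias)
#> 0.85
```

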