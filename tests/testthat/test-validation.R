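test_that("posterior prediction covers data from the fitted model itself", {
  fit <- small_fit(10)
  tt <- training_trials()
  ppc <- posteriorPredictiveCheck(fit, tt, n_datasets = 80, seed = 2,
                                  allow_unconverged = TRUE)
  s <- ppc$summary
  expect_equal(nrow(s), 4)
  expect_setequal(s$trial_type, c("high_agree", "low_agree",
                                  "high_disagree", "low_disagree"))
  inside_sw <- s$observed_pswitch >= s$pswitch_lo &
    s$observed_pswitch <= s$pswitch_hi
  inside_rt <- s$observed_rt >= s$rt_lo & s$observed_rt <= s$rt_hi
  expect_gte(sum(inside_sw), 3)
  expect_gte(sum(inside_rt), 3)
  # intervals contain their own simulated means
  expect_true(all(s$sim_pswitch >= s$pswitch_lo &
                    s$sim_pswitch <= s$pswitch_hi))
  expect_equal(ppc$n_datasets, 80)
})

test_that("posterior prediction exposes a model without social terms", {
  tt <- training_trials()
  fit1 <- fitHierarchical(tt, 1,
                          mcmcConfig(n_samples = 500, burn_in = 200,
                                     thin = 2, n_chains = 2), seed = 8)
  ppc <- posteriorPredictiveCheck(fit1, tt, n_datasets = 80, seed = 2,
                                  allow_unconverged = TRUE)
  s <- ppc$summary
  # without covariate terms the regenerated choice ignores the initial
  # choice, so the model badly over-predicts switching on agreement trials
  # (where observers almost never switch): observed cells fall outside
  # their predictive intervals
  expect_true(any(s$observed_pswitch < s$pswitch_lo |
                    s$observed_pswitch > s$pswitch_hi))
  agr <- s[s$trial_type %in% c("high_agree", "low_agree"), ]
  expect_true(any(agr$observed_pswitch < agr$pswitch_lo))
})

test_that("unconverged fits are refused unless overridden", {
  fit <- small_fit(10)
  if (fit$converged) skip("short-chain fit unexpectedly converged")
  expect_error(posteriorPredictiveCheck(fit, training_trials(),
                                        n_datasets = 5),
               "allow_unconverged")
})

test_that("generating parameters are recovered from refits", {
  gen <- data.frame(a = c(1.8, 2.0, 2.2, 1.9, 2.1),
                    t0 = c(0.25, 0.3, 0.35, 0.28, 0.32),
                    v0 = 0,
                    v_stim = c(1.8, 2.3, 2.8, 3.3, 3.8),
                    v_personal = c(0.4, 0.9, 1.4, 1.9, 2.4),
                    v_social = c(0.05, 0.3, 0.55, 0.8, 1.05),
                    z0 = 0, z_personal = 0, z_social = 0)
  rec <- parameterRecovery(9, gen, n_datasets = 2,
                           mcmc = mcmcConfig(n_samples = 500,
                                             burn_in = 200, thin = 2,
                                             n_chains = 1),
                           seed = 14)
  expect_equal(rec$n_datasets, 2)
  s <- rec$summary
  expect_true(all(c("v_personal", "v_social") %in% s$parameter))
  expect_gt(s$correlation[s$parameter == "v_personal"], 0.5)
  expect_gt(s$correlation[s$parameter == "v_stim"], 0.5)
})

test_that("simulated boundaries track the partner's boundary", {
  cv <- crossValidateBoundary(n_subjects = 4, seed = 31)
  expect_gt(cv$results$pse60$pse_posttest, cv$results$pse45$pse_posttest + 3)
  expect_gt(cv$results$pse60$pse_revised, cv$results$pse45$pse_revised)
  # fitted psychometric curves are monotone in angle
  for (r in cv$results) {
    expect_true(all(diff(r$curve$p_concentric) > 0))
  }

  null_pop <- observerPopulation(
    mean = list(v_social = 0, z_social = 0),
    sd = list(v_social = 0, z_social = 0),
    assimilation_rate = 0)
  # cohort-mean generating boundaries alone spread the null difference by
  # about 1.2 deg (sd) at 6 subjects; 3.5 deg is ~3 sigma
  cv0 <- crossValidateBoundary(null_pop, n_subjects = 6, seed = 32)
  expect_lt(abs(cv0$results$pse60$pse_posttest -
                  cv0$results$pse45$pse_posttest), 3.5)
})

test_that("delta-PSE grids move with the social and personal weights", {
  g <- gridDeltaPse(v_personal_range = c(0.5, 1.25, 2),
                    v_social_range = c(0, 0.4, 0.8),
                    z_personal_range = c(0.5, 1.25, 2),
                    z_social_range = c(0, 0.4, 0.8),
                    n_trials_per_angle = 1500, seed = 6)
  for (grid in list(g$v_grid$delta_pse, g$z_grid$delta_pse)) {
    expect_true(all(is.finite(grid)))
    # no social dependence, unbiased start: no shift
    expect_true(all(abs(grid[, 1]) < 1.2))
    # increasing in the social weight along every row
    expect_true(all(grid[, 3] > grid[, 1] - 0.6))
    expect_true(all(grid[, 3] > 1))
    # decreasing in the personal weight in the strongest social column
    expect_gt(grid[1, 3], grid[3, 3] - 0.6)
  }
  expect_equal(g$v_grid$n_trials_per_angle, 1500)
})
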