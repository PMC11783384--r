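test_that("partner policy evaluates and samples the printed sigmoid", {
  pol <- partnerPolicy(0.2, 60)
  expect_equal(partnerChoiceProb(60, pol), 0.5)
  expect_equal(partnerChoiceProb(45, pol), 1 / (1 + exp(3)))
  expect_error(partnerPolicy(-0.2, 45), "> 0")
  expect_error(partnerPolicy(0.2, 95), "\\[0, 90\\]")

  pol45 <- partnerPolicy(0.2, 45)
  p <- partnerChoiceProb(70, pol45)
  set.seed(8)
  draws <- partnerChoice(rep(70, 1e5), pol45)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(mean(draws == -1) - p), 3 * se)
})

test_that("stimulus and personal codes use the stated anchors", {
  expect_equal(stimulusCode(0), 1)
  expect_equal(stimulusCode(45), 0)
  expect_equal(stimulusCode(90), -1)
  expect_error(stimulusCode(91), "\\[0, 90\\]")

  expect_equal(personalCode(1, 7), 1)
  expect_equal(personalCode(-1, 7), -1)
  expect_lt(abs(personalCode(1, 1)), abs(personalCode(1, 7)))
  expect_equal(personalCode(1, 4, mapping = "zero_based"), 0.5)
  expect_error(personalCode(1, 8), "1..7")
  expect_error(personalCode(2, 4), "radial")
})

test_that("initial decisions behave like an unbiased diffusion observer", {
  obs_null <- observerParams(v_stim = 0.01, v0 = 0)
  set.seed(5)
  sim <- simulateInitialDecision(obs_null, rep(45, 4000))
  expect_lt(abs(mean(sim$choice == 1) - 0.5), 3 * sqrt(0.25 / 4000))
  expect_true(all(sim$rt > obs_null$t0))

  obs <- observerParams()
  set.seed(6)
  easy <- simulateInitialDecision(obs, rep(0, 400))
  hard <- simulateInitialDecision(obs, rep(45, 400))
  expect_gt(mean(easy$conf), mean(hard$conf))
})

test_that("initial-choice psychometric recovers the internal boundary", {
  obs <- observerParams(boundary_c = 50)
  angles <- stimulusSet()$angles_deg
  set.seed(9)
  k <- vapply(angles, function(ang) {
    sim <- simulateInitialDecision(obs, rep(ang, 2500))
    sum(sim$choice == -1)
  }, numeric(1))
  fit <- fitPsychometric(angles, k, rep(2500, length(angles)))
  expect_lt(abs(fit$c - 50), 1.5)
})

test_that("revised decisions respond to social information as specified", {
  # null social sensitivity: partner presence leaves the choice law alone
  obs0 <- observerParams(v_social = 0, z_social = 0)
  set.seed(11)
  with_partner <- simulateRevisedDecision(obs0, rep(45, 1500), 1, 4,
                                          partner_choice = rep(-1, 1500))
  without <- simulateRevisedDecision(obs0, rep(45, 1500), 1, 4,
                                     partner_choice = rep(NA, 1500))
  p1 <- mean(with_partner$choice == 1)
  p2 <- mean(without$choice == 1)
  se <- sqrt(p1 * (1 - p1) / 1500 + p2 * (1 - p2) / 1500)
  expect_lt(abs(p1 - p2), 3 * max(se, 0.01))

  # dominant social drift forces conformity at the ambiguous angle
  obs_soc <- observerParams(v_social = 5, v_personal = 0, z_personal = 0)
  set.seed(12)
  sim <- simulateRevisedDecision(obs_soc, rep(45, 300), 1, 4,
                                 partner_choice = rep(-1, 300))
  expect_gt(mean(sim$choice == -1), 0.95)

  # higher initial confidence lowers the switch rate under disagreement
  obs <- observerParams()
  set.seed(13)
  low <- simulateRevisedDecision(obs, rep(45, 800), 1, 1,
                                 partner_choice = rep(-1, 800))
  high <- simulateRevisedDecision(obs, rep(45, 800), 1, 7,
                                  partner_choice = rep(-1, 800))
  expect_gt(mean(low$choice == -1), mean(high$choice == -1))
})

test_that("cohort tables have the documented structure", {
  tr <- small_cohort("exp2", n = 3)
  expect_s3_class(tr, "dyad_trials")
  expect_equal(nrow(tr), 3 * (180 + 450 + 180))
  expect_setequal(unique(tr$phase), c("pretest", "training", "posttest"))

  test_rows <- tr[tr$phase != "training", ]
  expect_true(all(is.na(test_rows$partner_choice)))
  expect_true(all(is.na(test_rows$rev_choice)))

  train <- tr[tr$phase == "training", ]
  expect_true(all(!is.na(train$partner_choice)))
  expect_true(all(train$rev_rt > 0))
  expect_true(all(train$init_conf %in% 1:7 & train$rev_conf %in% 1:7))
  expect_identical(train$switch, train$rev_choice != train$init_choice)
  expect_identical(train$agree, train$partner_choice == train$init_choice)
  # revision-phase stimulus is structurally the same spiral angle
  expect_true(all(table(train$angle_deg) == 3 * 450 / 9))

  obs <- attr(tr, "observers")
  expect_equal(nrow(obs), 3)
  expect_true(all(c("aq_social_skill", "extraversion") %in% names(obs)))
})

test_that("cohorts are reproducible and populations can be degenerate", {
  a <- simulateCohort(buildDesign("exp1"), 2, master_seed = 77)
  b <- simulateCohort(buildDesign("exp1"), 2, master_seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))

  zero_sd <- lapply(observerPopulation()$sd, function(x) 0)
  pop0 <- observerPopulation(sd = zero_sd)
  tr <- simulateCohort(buildDesign("exp3"), 3, pop0, master_seed = 5)
  obs <- attr(tr, "observers")
  expect_equal(obs$v_personal, rep(obs$v_personal[1], 3))
  expect_equal(obs$a, rep(obs$a[1], 3))
  # exp3 has no partner anywhere
  expect_true(all(is.na(tr$partner_choice)))
  expect_true(all(!is.na(tr$rev_choice[tr$phase == "training"])))
})

test_that("trial tables round-trip through CSV", {
  tr <- small_cohort("exp2", n = 3)
  path <- tempfile(fileext = ".csv")
  writeTrials(tr, path)
  back <- readTrials(path)
  expect_equal(back$init_rt, tr$init_rt, tolerance = 1e-12)
  expect_identical(back$agree, tr$agree)
  expect_identical(back$phase, tr$phase)
  unlink(path)
})
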