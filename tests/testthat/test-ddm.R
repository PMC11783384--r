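test_that("closed-form choice probability handles limits and symmetry", {
  expect_equal(ddmChoiceProb(2, 0, 0.5), 0.5)
  expect_equal(ddmChoiceProb(1.7, 1e-12, 0.3), 0.3)
  expect_equal(ddmChoiceProb(2, 1, 0.5) + ddmChoiceProb(2, -1, 0.5), 1)
})

test_that("the density obeys the reflection symmetry", {
  t <- seq(0.35, 4, by = 0.25)
  up <- wfptLogpdf(t, "upper", 2, 0.8, 0.4, 0.3)
  lo <- wfptLogpdf(t, "lower", 2, -0.8, 0.6, 0.3)
  expect_equal(up, lo, tolerance = 1e-10)
  expect_identical(wfptLogpdf(0.2, "upper", 2, 1, 0.5, 0.3), -Inf)
  expect_error(wfptLogpdf(1, "top", 2, 1, 0.5, 0.3), "upper")
})

test_that("the density integrates to the closed-form choice probability", {
  for (ps in list(c(2, 1, 0.5, 0.3), c(1.2, -1.5, 0.35, 0.2),
                  c(3, 0, 0.7, 0.4))) {
    f <- function(t) exp(wfptLogpdf(t, "upper", ps[1], ps[2], ps[3], ps[4]))
    I <- integrate(f, ps[4], Inf, rel.tol = 1e-8)$value
    expect_lt(abs(I - ddmChoiceProb(ps[1], ps[2], ps[3])), 1e-6)
  }
})

test_that("the simulator agrees with the density in choice and RT", {
  set.seed(21)
  n <- 2e5
  sim <- simulateTrial(n, 2, 0.8, 0.4, 0.3)
  p <- ddmChoiceProb(2, 0.8, 0.4)
  expect_lt(abs(mean(sim$choice == 1) - p), 3 * sqrt(p * (1 - p) / n))
  expect_true(all(sim$rt > 0.3))

  # upper-boundary RT histogram against the analytic density
  rt_up <- sim$rt[sim$choice == 1]
  breaks <- c(seq(0.3, 3.3, by = 0.25), Inf)
  obs <- table(cut(rt_up, breaks)) / n
  dens <- function(t) exp(wfptLogpdf(t, "upper", 2, 0.8, 0.4, 0.3))
  pred <- vapply(seq_len(length(breaks) - 2), function(i)
    integrate(dens, breaks[i], breaks[i + 1], rel.tol = 1e-7)$value,
    numeric(1))
  pred <- c(pred, p - sum(pred))
  se <- sqrt(pred * (1 - pred) / n)
  # Euler discretization at dt = 1e-3 adds a small systematic bias, so
  # allow a generous multiple of the binomial error plus a bias floor
  expect_true(all(abs(as.numeric(obs) - pred) < 6 * se + 0.004))
})

test_that("the model space matches the ten printed constraint sets", {
  space <- buildModelSpace()
  expect_length(space, 10)
  expect_equal(vapply(space, function(m) m$id, numeric(1)), 1:10)
  expect_true(all(vapply(space, function(m) m$v_has_stimulus, logical(1))))

  m1 <- space[[1]]
  expect_length(m1$z_covariates, 0)
  expect_length(m1$v_covariates, 0)

  m5 <- space[[5]]
  expect_equal(m5$z_covariates, "social")
  expect_length(m5$v_covariates, 0)

  expect_equal(space[[4]]$z_covariates, "personal")
  expect_equal(space[[4]]$v_covariates, "personal")
  expect_equal(space[[8]]$z_covariates, c("personal", "social"))
  expect_length(space[[8]]$v_covariates, 0)
  expect_equal(space[[9]]$v_covariates, c("personal", "social"))

  m10 <- space[[10]]
  expect_setequal(m10$z_covariates, c("personal", "social"))
  expect_setequal(m10$v_covariates, c("personal", "social"))
  expect_error(modelSpec(11), "1..10")
})

test_that("slow revised decisions are excluded with an exact report", {
  tr <- data.frame(rev_rt = c(rep(1, 97), rep(4, 3)))
  out <- filterTrials(tr)
  expect_equal(out$report$n_excluded, 3)
  expect_equal(out$report$fraction, 0.03)
  expect_equal(nrow(out$trials), 97)

  none <- filterTrials(data.frame(rev_rt = rep(1, 10)))
  expect_equal(none$report$n_excluded, 0)
})

test_that("DIC is computed from traces and ignores draw order", {
  dev <- c(100, 104, 96, 102, 98)
  fit <- fake_fit(array(0, c(5, 2, 9)), deviance = dev, d_hat = 95)
  expect_equal(computeDic(fit), 2 * mean(dev) - 95)
  fit2 <- fake_fit(array(0, c(5, 2, 9)), deviance = rev(dev), d_hat = 95)
  expect_equal(computeDic(fit2), computeDic(fit))

  # degenerate posterior: every draw equals the posterior mean
  degen <- fake_fit(array(0, c(5, 2, 9)), deviance = rep(100, 5),
                    d_hat = 100)
  expect_equal(computeDic(degen) - mean(degen$deviance), 0)  # pD = 0
  degen$deviance <- NULL
  expect_error(computeDic(degen), "deviance")
})

test_that("directional posterior probabilities are draw fractions", {
  g <- cbind(mu_v_social = c(-2, -1, 1, 2), mu_v_personal = c(1, 2, 3, 4))
  fit <- fake_fit(array(0, c(4, 2, 9)), group = g)
  expect_equal(posteriorDirectionProb(fit, "v_social"), 0.5)
  expect_equal(posteriorDirectionProb(fit, "mu_v_personal"), 1)
  expect_equal(posteriorDirectionProb(fit, "v_social") +
                 mean(g[, "mu_v_social"] <= 0), 1)
  expect_error(posteriorDirectionProb(fit, "nonesuch"), "unknown parameter")
})
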