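angles9 <- c(0, 20, 30, 40, 45, 50, 60, 70, 90)

# independent oracle: exhaustive grid search of the binomial log-likelihood
grid_mle <- function(x, k, n, a_grid = seq(0.02, 0.6, by = 0.005),
                     c_grid = seq(30, 75, by = 0.05)) {
  best <- c(NA, NA, -Inf)
  for (a in a_grid) {
    p <- outer(c_grid, x, function(cc, xx) 1 / (1 + exp(-a * (xx - cc))))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- as.vector(log(p) %*% k + log(1 - p) %*% (n - k))
    i <- which.max(ll)
    if (ll[i] > best[3]) best <- c(a, c_grid[i], ll[i])
  }
  list(a = best[1], c = best[2])
}

test_that("boltzmann evaluates the sigmoid exactly", {
  expect_equal(boltzmann(45, 0.2, 45), 0.5)
  expect_equal(boltzmann(60, 0.2, 45), 1 / (1 + exp(-3)))
  expect_equal(boltzmann(0, 0.2, 45), 1 / (1 + exp(9)))
  expect_true(all(diff(boltzmann(angles9, 0.3, 45)) > 0))
})

test_that("the MLE recovers the partner policies from analytic counts", {
  for (truth in c(45, 60)) {
    p <- boltzmann(angles9, 0.2, truth)
    k <- round(p * 1e4)
    fit <- fitPsychometric(angles9, k, rep(1e4, 9))
    expect_true(fit$converged)
    expect_lt(abs(fit$c - truth), 0.1)
    expect_lt(abs(fit$a - 0.2), 0.01)
  }
})

test_that("the optimizer agrees with an exhaustive grid-search oracle", {
  set.seed(31)
  for (rep in 1:5) {
    k <- rbinom(9, 20, boltzmann(angles9, 0.2, 45))
    if (sum(k) == 0 || sum(k) == 180) next
    fit <- fitPsychometric(angles9, k, rep(20, 9))
    oracle <- grid_mle(angles9, k, rep(20, 9))
    expect_lt(abs(fit$c - oracle$c), 0.11)
    expect_lt(abs(fit$a - oracle$a), 0.011)
  }
})

test_that("boundary recovery at test-phase trial counts is unbiased", {
  set.seed(7)
  cs <- replicate(200, {
    k <- rbinom(9, 20, boltzmann(angles9, 0.2, 45))
    f <- fitPsychometric(angles9, k, rep(20, 9))
    if (f$converged) f$c else NA
  })
  expect_lt(abs(median(cs, na.rm = TRUE) - 45), 1)
})

test_that("separation yields a flagged, boundary-free fit", {
  fit <- fitPsychometric(angles9, rep(0, 9), rep(20, 9))
  expect_false(fit$converged)
  expect_true(is.na(fit$c))
  expect_error(pseShift(fit, fit), "converged")
})

test_that("fitting radial counts gives the same boundary, negated slope", {
  k <- round(boltzmann(angles9, 0.2, 52) * 1000)
  conc <- fitPsychometric(angles9, k, rep(1000, 9))
  radi <- fitPsychometric(angles9, 1000 - k, rep(1000, 9))
  expect_lt(abs(conc$c - radi$c), 0.2)
  expect_lt(abs(conc$a + radi$a), 0.01)
})

test_that("PSE shift is a signed difference with antisymmetry", {
  f45 <- fitPsychometric(angles9, round(boltzmann(angles9, 0.2, 45) * 1e4),
                         rep(1e4, 9))
  f60 <- fitPsychometric(angles9, round(boltzmann(angles9, 0.2, 60) * 1e4),
                         rep(1e4, 9))
  expect_equal(pseShift(f45, f45), 0)
  expect_lt(abs(pseShift(f45, f60) - 15), 0.2)
  expect_equal(pseShift(f45, f60), -pseShift(f60, f45))
})

test_that("bootstrap confidence intervals cover the estimate", {
  k <- rbinom(9, 50, boltzmann(angles9, 0.2, 45))
  fit <- fitPsychometric(angles9, k, rep(50, 9), ci = "bootstrap",
                         n_boot = 120, seed = 3)
  expect_true(fit$ci_c[1] <= fit$c && fit$c <= fit$ci_c[2])
  fit2 <- fitPsychometric(angles9, k, rep(50, 9), ci = "bootstrap",
                          n_boot = 120, seed = 3)
  expect_identical(fit$ci_c, fit2$ci_c)
})

test_that("least-squares objective is available and close to the MLE", {
  k <- round(boltzmann(angles9, 0.2, 45) * 500)
  mle <- fitPsychometric(angles9, k, rep(500, 9))
  ls <- fitPsychometric(angles9, k, rep(500, 9), objective = "ls")
  expect_lt(abs(mle$c - ls$c), 0.5)
})

test_that("phase and block-wise fits track the boundary trajectory", {
  tr <- small_cohort("exp2", n = 3)
  fits <- blockwisePse(tr, phase = "training", decision = "initial")
  expect_length(fits, 5)
  cs <- vapply(fits, function(f) f$c, numeric(1))
  # assimilation toward the 60 deg partner: last block beyond first block
  expect_gt(cs[5], cs[1])
  expect_error(blockwisePse(tr, phase = "nope"), "no trials")
})
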