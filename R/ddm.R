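#' Closed-form probability of absorption at the upper boundary
#'
#' For a Wiener diffusion with unit noise, threshold `a`, drift `v`, and
#' relative starting point `z`:
#' `P(upper) = (1 - exp(-2 v a z)) / (1 - exp(-2 v a))`, with the
#' drift-free limit handled analytically as `z`. Used throughout as an
#' independent oracle for the simulator and the likelihood.
#'
#' @param a threshold (> 0).
#' @param v drift rate.
#' @param z relative starting point in (0, 1).
#' @return probability of reaching the upper (radial) boundary.
#' @export
ddmChoiceProb <- function(a, v, z) {
  stopifnot(all(a > 0), all(z > 0), all(z < 1))
  n <- max(length(a), length(v), length(z))
  a <- rep(a, length.out = n); v <- rep(v, length.out = n)
  z <- rep(z, length.out = n)
  out <- numeric(n)
  small <- abs(v) < 1e-9
  out[small] <- z[small]
  if (any(!small)) {
    vv <- v[!small]; aa <- a[!small]; zz <- z[!small]
    out[!small] <- expm1(-2 * vv * aa * zz) / expm1(-2 * vv * aa)
  }
  out
}

#' Wiener first-passage-time log-density
#'
#' Log-density of the first passage at the stated boundary at time `t`
#' (including the non-decision time `t0`), computed by the small-time /
#' large-time series with an adaptive switch; `t <= t0` returns `-Inf`
#' (zero density), not an error.
#'
#' @param t response time(s), seconds.
#' @param boundary `"upper"` (radial) or `"lower"` (concentric); may be a
#'   vector.
#' @param a threshold.
#' @param v drift rate.
#' @param z relative starting point in (0, 1), measured from the lower
#'   boundary.
#' @param t0 non-decision time, seconds.
#' @return log-density values.
#' @export
wfptLogpdf <- function(t, boundary, a, v, z, t0) {
  upper <- boundary == "upper"
  if (!all(boundary %in% c("upper", "lower"))) {
    stop_config("boundary must be 'upper' or 'lower'")
  }
  .wfpt_logpdf_cpp(t, upper, a, v, z, t0)
}

#' Simulate diffusion trials (Euler-Maruyama)
#'
#' Unit-noise Wiener paths started at `z * a`, absorbed at 0 (concentric)
#' or `a` (radial); the response time is the absorption time plus `t0`.
#' Paths not absorbed by 10 s are resampled and counted.
#'
#' @param n number of trials.
#' @param a threshold.
#' @param v drift rate (scalar or per-trial).
#' @param z relative starting point (scalar or per-trial).
#' @param t0 non-decision time.
#' @param dt Euler step, seconds.
#' @return data frame with columns `choice` (+1 upper / -1 lower) and `rt`;
#'   attribute `resampled` counts re-drawn paths.
#' @export
simulateTrial <- function(n, a, v, z, t0, dt = 0.001) {
  stopifnot(a > 0, all(z > 0), all(z < 1), t0 >= 0, n >= 1)
  sim <- .ddm_simulate_cpp(as.integer(n), a, as.numeric(v), as.numeric(z),
                           t0, dt, 10)
  out <- data.frame(choice = sim[, 1], rt = sim[, 2])
  attr(out, "resampled") <- attr(sim, "resampled")
  out
}

#' The ten-model specification space
#'
#' The candidate drift-diffusion models differ in which of the starting
#' point (`z`) and drift rate (`v`) depend on personal information (signed
#' initial confidence) and social information (the partner's choice).
#' Drift rate varies with stimulus uncertainty in all models. Model 1 is
#' the baseline (no covariate effects); model 10 is the full model.
#'
#' @return list of 10 objects of class `model_spec`, each with `id`,
#'   `z_covariates`, `v_covariates`, `v_has_stimulus`, `label`.
#' @export
buildModelSpace <- function() {
  combos <- list(
    list(z = character(0), v = character(0),
         label = "baseline: no personal/social effects"),
    list(z = "personal", v = character(0),
         label = "z depends on personal information"),
    list(z = character(0), v = "personal",
         label = "v depends on personal information"),
    list(z = "personal", v = "personal",
         label = "z and v depend on personal information"),
    list(z = "social", v = character(0),
         label = "z depends on social information"),
    list(z = character(0), v = "social",
         label = "v depends on social information"),
    list(z = "social", v = "social",
         label = "z and v depend on social information"),
    list(z = c("personal", "social"), v = character(0),
         label = "z depends on personal and social information"),
    list(z = character(0), v = c("personal", "social"),
         label = "v depends on personal and social information"),
    list(z = c("personal", "social"), v = c("personal", "social"),
         label = "full model"))
  lapply(seq_along(combos), function(i)
    structure(list(id = i, z_covariates = combos[[i]]$z,
                   v_covariates = combos[[i]]$v, v_has_stimulus = TRUE,
                   label = combos[[i]]$label),
              class = "model_spec"))
}

#' Fetch one model specification by id
#'
#' @param id integer 1..10.
#' @return a `model_spec`.
#' @export
modelSpec <- function(id) {
  if (!id %in% 1:10) stop_config("model id must be 1..10")
  buildModelSpace()[[id]]
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("DDM model %d: %s\n", x$id, x$label))
  invisible(x)
}

#' Exclude slow revised decisions
#'
#' Removes revision-phase rows with revised RT greater than `rt_max`
#' (default 3.5 s) before model fitting, and reports the exclusion count
#' and fraction.
#'
#' @param trials trial table with revised RTs.
#' @param rt_max cutoff, seconds.
#' @return list with `trials` (kept rows) and `report` (n_total,
#'   n_excluded, fraction).
#' @export
filterTrials <- function(trials, rt_max = 3.5) {
  if (!"rev_rt" %in% names(trials)) {
    stop_config("trial table lacks revised RTs")
  }
  has_rev <- !is.na(trials$rev_rt)
  drop <- has_rev & trials$rev_rt > rt_max
  list(trials = trials[!drop, , drop = FALSE],
       report = list(n_total = sum(has_rev), n_excluded = sum(drop),
                     fraction = if (sum(has_rev) > 0)
                       sum(drop) / sum(has_rev) else 0))
}

# ---- hierarchical fitting ---------------------------------------------------

# parameter bookkeeping: sampling-scale vector per subject is
# (log a, log t0, v0, v_stim, v_personal, v_social, z0, z_personal, z_social)
.par_names <- c("a", "t0", "v0", "v_stim", "v_personal", "v_social",
                "z0", "z_personal", "z_social")
.samp_names <- c("log_a", "log_t0", "v0", "v_stim", "v_personal",
                 "v_social", "z0", "z_personal", "z_social")

.free_mask <- function(spec) {
  free <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  if ("personal" %in% spec$v_covariates) free[5] <- TRUE
  if ("social" %in% spec$v_covariates) free[6] <- TRUE
  if ("personal" %in% spec$z_covariates) free[8] <- TRUE
  if ("social" %in% spec$z_covariates) free[9] <- TRUE
  free
}

# natural-scale parameter vector for the likelihood from sampling scale
.nat_pars <- function(theta) {
  c(exp(theta[1]), exp(theta[2]), theta[3:9])
}

# weakly-informative group priors (documented constants):
# location: normal(m0, s0); group SD: half-normal(0, hn)
.prior_consts <- function() {
  list(m0 = c(log(2), log(0.3), 0, 0, 0, 0, 0, 0, 0),
       s0 = c(1, 1, 3, 3, 3, 3, 2, 2, 2),
       hn = c(0.5, 0.5, 1, 1, 1, 1, 0.5, 0.5, 0.5))
}

#' Default MCMC settings
#'
#' The default mirrors the reported fitting regime (50,000 samples,
#' burn-in 10,000, thinning 10); `profile = "fast"` is a reduced profile
#' for continuous-integration-scale problems (2,000 samples, burn-in 500,
#' thinning 2). At least two chains are run so split-Rhat can be computed.
#'
#' @param n_samples total MCMC iterations per chain (including burn-in).
#' @param burn_in discarded warm-up iterations (also used for proposal
#'   adaptation).
#' @param thin thinning interval.
#' @param n_chains number of chains (>= 1; 2 recommended).
#' @param profile `"paper"` or `"fast"` preset; explicit arguments
#'   override the preset.
#' @return a list of class `mcmc_config`.
#' @export
mcmcConfig <- function(n_samples = NULL, burn_in = NULL, thin = NULL,
                       n_chains = 2, profile = c("paper", "fast")) {
  profile <- match.arg(profile)
  def <- if (profile == "paper") list(n_samples = 50000, burn_in = 10000,
                                      thin = 10)
         else list(n_samples = 2000, burn_in = 500, thin = 2)
  cfg <- list(n_samples = n_samples %||% def$n_samples,
              burn_in = burn_in %||% def$burn_in,
              thin = thin %||% def$thin,
              n_chains = n_chains)
  if (cfg$burn_in >= cfg$n_samples) {
    stop_config("burn_in must be smaller than n_samples")
  }
  structure(cfg, class = "mcmc_config")
}

# one-subject data bundle for the likelihood
.subject_data <- function(trials, conf_mapping = "proportional") {
  pers <- personalCode(trials$init_choice, trials$init_conf, conf_mapping)
  soc <- ifelse(is.na(trials$partner_choice), 0, trials$partner_choice)
  list(rt = trials$rev_rt, choice = as.integer(trials$rev_choice),
       stim = trials$stim_code, pers = pers, soc = soc)
}

.subject_loglik <- function(dat, theta, p_outlier, cont_dens) {
  .ddm_reg_loglik_cpp(dat$rt, dat$choice, dat$stim, dat$pers, dat$soc,
                      .nat_pars(theta), p_outlier, cont_dens)
}

#' Fit a hierarchical drift-diffusion regression model
#'
#' Hierarchical Bayesian estimation of one of the ten model variants on
#' revised decisions: subject-level parameters (threshold, non-decision
#' time, drift intercept, stimulus/personal/social drift sensitivities,
#' and the logit-scale starting-point regression) are drawn from normal
#' group-level distributions (threshold and non-decision time on the log
#' scale). The likelihood is a mixture of the Wiener first-passage-time
#' density and a 5% uniform outlier component spread over the observed RT
#' range with half mass per boundary. Sampling is adaptive
#' Metropolis-within-Gibbs: component-wise random-walk updates on subject
#' parameters (proposal scales tuned during burn-in), conjugate Gibbs
#' updates for group means, and random-walk updates for group SDs.
#'
#' Only revision-phase trials (rows with a revised RT) enter the fit;
#' initial decisions are never modeled.
#'
#' @param trials trial table (training-phase rows; at least 2 subjects).
#'   Apply [filterTrials()] beforehand to exclude slow outliers.
#' @param spec a [modelSpec()] (or integer id 1..10).
#' @param mcmc an [mcmcConfig()].
#' @param outlier_prob mixture weight of the uniform contaminant.
#' @param seed integer seed.
#' @param conf_mapping confidence scaling for the personal code.
#' @return an object of class `ddm_fit`: posterior draws for group-level
#'   parameters (`group`), subject-level draws (`subject`, a draws x
#'   subject x parameter array), the deviance trace, DIC, split-Rhat
#'   diagnostics, acceptance rates, and the configuration.
#' @export
fitHierarchical <- function(trials, spec, mcmc = mcmcConfig(),
                            outlier_prob = 0.05, seed = 1L,
                            conf_mapping = "proportional") {
  if (is.numeric(spec)) spec <- modelSpec(spec)
  stopifnot(inherits(spec, "model_spec"), inherits(mcmc, "mcmc_config"))
  keep <- !is.na(trials$rev_rt) & !is.na(trials$rev_choice)
  trials <- trials[keep, , drop = FALSE]
  subjects <- sort(unique(trials$subject))
  if (length(subjects) < 2) {
    stop_config("hierarchical fitting needs at least 2 subjects")
  }
  dat <- lapply(subjects, function(s)
    .subject_data(trials[trials$subject == s, , drop = FALSE], conf_mapping))
  ns <- length(subjects)
  cont_dens <- 0.5 / max(trials$rev_rt)
  free <- .free_mask(spec)
  prior <- .prior_consts()
  min_rt <- vapply(dat, function(d) min(d$rt), numeric(1))

  n_keep <- floor((mcmc$n_samples - mcmc$burn_in) / mcmc$thin)
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    chains[[ch]] <- .run_chain(dat, free, prior, mcmc, outlier_prob,
                               cont_dens, min_rt, n_keep,
                               seed = splitSeed(seed, 7L, ch))
  }

  group <- do.call(rbind, lapply(chains, `[[`, "group"))
  subject <- do.call(abind1, lapply(chains, `[[`, "subject"))
  deviance <- unlist(lapply(chains, `[[`, "deviance"))

  # DIC (subject-level focus): Dbar + pD, pD = Dbar - D(posterior mean)
  theta_bar <- apply(subject, c(2, 3), mean)
  d_hat <- -2 * sum(vapply(seq_len(ns), function(s)
    .subject_loglik(dat[[s]], theta_bar[s, ], outlier_prob, cont_dens),
    numeric(1)))
  d_bar <- mean(deviance)
  p_d <- d_bar - d_hat
  dic <- d_bar + p_d
  # d_hat kept so the DIC can be recomputed from stored traces alone

  rhat <- .split_rhat(lapply(chains, `[[`, "group"))
  converged <- all(is.finite(rhat)) && all(rhat < 1.05, na.rm = TRUE)

  structure(list(spec = spec, group = group, subject = subject,
                 deviance = deviance, d_hat = d_hat, dic = dic, p_d = p_d,
                 d_bar = d_bar,
                 rhat = rhat, converged = converged,
                 accept = lapply(chains, `[[`, "accept"),
                 subjects = subjects, mcmc = mcmc,
                 outlier_prob = outlier_prob, cont_dens = cont_dens,
                 conf_mapping = conf_mapping, seed = seed,
                 n_trials = nrow(trials)),
            class = "ddm_fit")
}

# bind 3-d arrays along dim 1
abind1 <- function(...) {
  arrs <- list(...)
  if (length(arrs) == 1) return(arrs[[1]])
  d <- dim(arrs[[1]])
  total <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(NA_real_, c(total, d[2], d[3]),
               dimnames = list(NULL, dimnames(arrs[[1]])[[2]],
                               dimnames(arrs[[1]])[[3]]))
  at <- 1
  for (a in arrs) {
    out[at:(at + dim(a)[1] - 1), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

.run_chain <- function(dat, free, prior, mcmc, p_out, cont_dens, min_rt,
                       n_keep, seed) {
  set.seed(seed)
  ns <- length(dat)
  np <- length(free)
  idx_free <- which(free)

  # initial values: group means at prior centers + jitter; subjects at group
  mu <- prior$m0 + rnorm(np, 0, 0.1)
  sigma <- pmax(prior$hn / 2, 0.05)
  theta <- matrix(rep(mu, each = ns), ns, np)
  theta[, !free] <- 0
  # keep t0 strictly below each subject's fastest RT
  theta[, 2] <- pmin(theta[, 2], log(pmax(min_rt * 0.8, 0.05)))

  ll <- vapply(seq_len(ns), function(s)
    .subject_loglik(dat[[s]], theta[s, ], p_out, cont_dens), numeric(1))
  if (any(!is.finite(ll))) {
    # fall back to conservative starting values
    for (s in which(!is.finite(ll))) {
      theta[s, 1] <- log(2); theta[s, 2] <- log(0.1)
      theta[s, 3:np] <- 0
      ll[s] <- .subject_loglik(dat[[s]], theta[s, ], p_out, cont_dens)
    }
  }

  prop_sd <- matrix(0.15, ns, np)
  acc <- matrix(0, ns, np)
  tries <- matrix(0, ns, np)
  keep_group <- matrix(NA_real_, n_keep,  2 * np)
  keep_subj <- array(NA_real_, c(n_keep, ns, np))
  keep_dev <- numeric(n_keep)
  kept <- 0

  for (it in seq_len(mcmc$n_samples)) {
    # subject-level component-wise random walk
    for (s in seq_len(ns)) {
      for (p in idx_free) {
        prop <- theta[s, ]
        prop[p] <- prop[p] + rnorm(1, 0, prop_sd[s, p])
        ll_new <- .subject_loglik(dat[[s]], prop, p_out, cont_dens)
        lp_old <- dnorm(theta[s, p], mu[p], sigma[p], log = TRUE)
        lp_new <- dnorm(prop[p], mu[p], sigma[p], log = TRUE)
        tries[s, p] <- tries[s, p] + 1
        if (is.finite(ll_new) &&
            log(runif(1)) < (ll_new + lp_new) - (ll[s] + lp_old)) {
          theta[s, ] <- prop
          ll[s] <- ll_new
          acc[s, p] <- acc[s, p] + 1
        }
        # Robbins-Monro adaptation toward 0.44 acceptance during burn-in
        if (it <= mcmc$burn_in && tries[s, p] %% 25 == 0) {
          rate <- acc[s, p] / tries[s, p]
          prop_sd[s, p] <- prop_sd[s, p] * exp(0.5 * (rate - 0.44))
        }
      }
    }
    # group means: conjugate normal update
    for (p in idx_free) {
      prec <- ns / sigma[p]^2 + 1 / prior$s0[p]^2
      m <- (sum(theta[, p]) / sigma[p]^2 + prior$m0[p] / prior$s0[p]^2) / prec
      mu[p] <- rnorm(1, m, sqrt(1 / prec))
    }
    # group SDs: random-walk on log sigma with half-normal prior
    for (p in idx_free) {
      prop_s <- sigma[p] * exp(rnorm(1, 0, 0.2))
      lp_old <- sum(dnorm(theta[, p], mu[p], sigma[p], log = TRUE)) +
        dnorm(sigma[p], 0, prior$hn[p], log = TRUE) + log(sigma[p])
      lp_new <- sum(dnorm(theta[, p], mu[p], prop_s, log = TRUE)) +
        dnorm(prop_s, 0, prior$hn[p], log = TRUE) + log(prop_s)
      if (log(runif(1)) < lp_new - lp_old) sigma[p] <- prop_s
    }
    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0 &&
        kept < n_keep) {
      kept <- kept + 1
      keep_group[kept, ] <- c(mu, sigma)
      keep_subj[kept, , ] <- theta
      keep_dev[kept] <- -2 * sum(ll)
    }
  }
  colnames(keep_group) <- c(paste0("mu_", .samp_names),
                            paste0("sigma_", .samp_names))
  dimnames(keep_subj) <- list(NULL, NULL, .samp_names)
  list(group = keep_group[seq_len(kept), , drop = FALSE],
       subject = keep_subj[seq_len(kept), , , drop = FALSE],
       deviance = keep_dev[seq_len(kept)],
       accept = acc / pmax(tries, 1))
}

# split-Rhat over the group-level draws of each chain
.split_rhat <- function(group_chains) {
  mats <- lapply(group_chains, function(g) {
    n <- nrow(g)
    if (n < 4) return(NULL)
    half <- floor(n / 2)
    list(g[seq_len(half), , drop = FALSE],
         g[(half + 1):(2 * half), , drop = FALSE])
  })
  mats <- unlist(mats, recursive = FALSE)
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (length(mats) < 2) {
    return(setNames(rep(NA_real_, ncol(group_chains[[1]])),
                    colnames(group_chains[[1]])))
  }
  m <- length(mats)
  n <- nrow(mats[[1]])
  vapply(colnames(mats[[1]]), function(cn) {
    means <- vapply(mats, function(x) mean(x[, cn]), numeric(1))
    vars <- vapply(mats, function(x) var(x[, cn]), numeric(1))
    w <- mean(vars)
    b <- n * var(means)
    if (w < 1e-12) return(1)
    sqrt((n - 1) / n + b / (n * w))
  }, numeric(1))
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("Hierarchical DDM fit: model %d (%s)\n", x$spec$id,
              x$spec$label))
  cat(sprintf("  %d subjects, %d trials, %d x %d draws kept\n",
              length(x$subjects), x$n_trials, x$mcmc$n_chains,
              nrow(x$group) / x$mcmc$n_chains))
  cat(sprintf("  DIC = %.1f (pD = %.1f), max split-Rhat = %.3f%s\n", x$dic,
              x$p_d, max(x$rhat, na.rm = TRUE),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(summary(x), digits = 3)
  invisible(x)
}

#' Posterior summary of group-level parameters
#'
#' @param object a `ddm_fit`.
#' @param ... unused.
#' @return data frame with posterior mean, SD, and 95% credible interval
#'   per group-level parameter.
#' @export
summary.ddm_fit <- function(object, ...) {
  g <- object$group
  data.frame(parameter = colnames(g), mean = colMeans(g),
             sd = apply(g, 2, sd),
             q2.5 = apply(g, 2, quantile, 0.025),
             q97.5 = apply(g, 2, quantile, 0.975), row.names = NULL)
}

#' Deviance information criterion of a fit
#'
#' `DIC = mean deviance + pD`, with `pD = mean deviance - deviance at the
#' posterior mean` of the subject-level parameters. Recomputed from the
#' stored deviance trace and the deviance at the posterior mean, so the
#' value is invariant to the order of the posterior draws.
#'
#' @param fit a `ddm_fit`.
#' @return the DIC value.
#' @export
computeDic <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  if (is.null(fit$deviance) || length(fit$deviance) == 0) {
    stop_config("fit lacks a deviance trace")
  }
  d_bar <- mean(fit$deviance)
  2 * d_bar - fit$d_hat
}

#' Posterior probability that a parameter is positive
#'
#' The fraction of posterior draws above zero, for group-level parameters
#' (e.g. `"v_social"` refers to the group mean `mu_v_social`).
#'
#' @param fit a `ddm_fit`.
#' @param parameter parameter name (with or without the `mu_` prefix).
#' @return probability in [0, 1].
#' @export
posteriorDirectionProb <- function(fit, parameter) {
  stopifnot(inherits(fit, "ddm_fit"))
  cn <- colnames(fit$group)
  name <- if (parameter %in% cn) parameter else paste0("mu_", parameter)
  if (!name %in% cn) {
    stop_config("unknown parameter '%s' (available: %s)", parameter,
                paste(cn, collapse = ", "))
  }
  mean(fit$group[, name] > 0)
}

#' Subject-level posterior means
#'
#' @param fit a `ddm_fit`.
#' @param natural return threshold and non-decision time on the natural
#'   scale (exponentiated) instead of the sampling (log) scale.
#' @return data frame, one row per subject, one column per parameter.
#' @export
subjectEstimates <- function(fit, natural = TRUE) {
  stopifnot(inherits(fit, "ddm_fit"))
  m <- apply(fit$subject, c(2, 3), mean)
  colnames(m) <- .samp_names
  out <- as.data.frame(m)
  if (natural) {
    out$log_a <- exp(out$log_a)
    out$log_t0 <- exp(out$log_t0)
    names(out)[1:2] <- c("a", "t0")
  }
  cbind(subject = fit$subjects, out)
}
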