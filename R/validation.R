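# classify training trials into the four printed trial types:
# (high/low initial confidence relative to the subject's own mean,
#  ties assigned to "high") x (agreement/disagreement)
.trial_types <- function(trials, split = c("subject", "grand")) {
  split <- match.arg(split)
  conf_mean <- if (split == "subject") {
    ave(trials$init_conf, trials$subject)
  } else {
    rep(mean(trials$init_conf), nrow(trials))
  }
  conf <- ifelse(trials$init_conf >= conf_mean, "high", "low")
  agree <- ifelse(trials$agree, "agree", "disagree")
  factor(paste(conf, agree, sep = "_"),
         levels = c("high_agree", "low_agree", "high_disagree",
                    "low_disagree"))
}

#' Posterior predictive check of a hierarchical DDM fit
#'
#' Regenerates full datasets from posterior-drawn subject-level parameters
#' (trial covariates held at their observed values) and compares the mean
#' revised RT and switch probability per trial type (high/low initial
#' confidence x agreement/disagreement) with the observed data. Datasets
#' are generated from the Wiener process alone (no outlier component).
#'
#' @param fit a `ddm_fit`.
#' @param trials the observed (filtered) training trials used in the fit.
#' @param n_datasets number of regenerated datasets.
#' @param seed integer seed.
#' @param dt Euler step for the regeneration, seconds.
#' @param conf_split `"subject"` (each subject's own mean confidence,
#'   default) or `"grand"` (grand-mean split).
#' @param allow_unconverged proceed even if the fit is flagged
#'   non-converged.
#' @return an object of class `ppc_summary`: per trial type the observed
#'   mean RT and switch probability, the simulated means, and 95%
#'   predictive intervals; plus `n_datasets` metadata.
#' @export
posteriorPredictiveCheck <- function(fit, trials, n_datasets = 2000,
                                     seed = 1L, dt = 0.001,
                                     conf_split = "subject",
                                     allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "ddm_fit"))
  if (!fit$converged && !allow_unconverged) {
    stop_config(paste("fit is flagged non-converged;",
                      "pass allow_unconverged = TRUE to override"))
  }
  keep <- !is.na(trials$rev_rt) & !is.na(trials$agree)
  trials <- trials[keep, , drop = FALSE]
  type <- .trial_types(trials, conf_split)
  obs_rt <- tapply(trials$rev_rt, type, mean)
  obs_sw <- tapply(trials$switch, type, mean)

  n_draws <- nrow(fit$group)
  with_replacement <- n_draws < n_datasets
  draw_idx <- with_seed(splitSeed(seed, 1L),
                        sample.int(n_draws, n_datasets,
                                   replace = with_replacement))
  pers <- personalCode(trials$init_choice, trials$init_conf,
                       fit$conf_mapping)
  soc <- ifelse(is.na(trials$partner_choice), 0, trials$partner_choice)
  sub_idx <- match(trials$subject, fit$subjects)

  sim_rt <- matrix(NA_real_, n_datasets, nlevels(type))
  sim_sw <- matrix(NA_real_, n_datasets, nlevels(type))
  set.seed(splitSeed(seed, 2L))
  for (d in seq_len(n_datasets)) {
    th <- fit$subject[draw_idx[d], , , drop = TRUE]
    if (is.null(dim(th))) th <- matrix(th, nrow = 1)
    rts <- numeric(nrow(trials))
    chs <- numeric(nrow(trials))
    for (s in seq_along(fit$subjects)) {
      rows <- which(sub_idx == s)
      if (length(rows) == 0) next
      pars <- .nat_pars(th[s, ])
      v <- pars[3] + pars[4] * trials$stim_code[rows] +
        pars[5] * pers[rows] + pars[6] * soc[rows]
      z <- plogis(pars[7] + pars[8] * pers[rows] + pars[9] * soc[rows])
      sim <- .ddm_simulate_cpp(length(rows), pars[1], v, z, pars[2], dt, 10)
      chs[rows] <- sim[, 1]
      rts[rows] <- sim[, 2]
    }
    sw <- chs != trials$init_choice
    sim_rt[d, ] <- tapply(rts, type, mean)
    sim_sw[d, ] <- tapply(sw, type, mean)
  }

  qr <- apply(sim_rt, 2, quantile, c(0.025, 0.975), na.rm = TRUE)
  qs <- apply(sim_sw, 2, quantile, c(0.025, 0.975), na.rm = TRUE)
  out <- data.frame(trial_type = levels(type),
                    observed_rt = as.numeric(obs_rt),
                    sim_rt = colMeans(sim_rt, na.rm = TRUE),
                    rt_lo = qr[1, ], rt_hi = qr[2, ],
                    observed_pswitch = as.numeric(obs_sw),
                    sim_pswitch = colMeans(sim_sw, na.rm = TRUE),
                    pswitch_lo = qs[1, ], pswitch_hi = qs[2, ],
                    row.names = NULL)
  structure(list(summary = out, n_datasets = n_datasets,
                 sampled_with_replacement = with_replacement,
                 conf_split = conf_split, seed = seed),
            class = "ppc_summary")
}

#' @export
print.ppc_summary <- function(x, ...) {
  cat(sprintf("Posterior predictive check (%d datasets)\n", x$n_datasets))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Parameter recovery analysis
#'
#' Generates datasets from known subject-level parameters (either the
#' subject-level posterior means of a fitted model or an explicit
#' parameter table), re-fits each with the generating model, and reports
#' the per-parameter correlation between generating and re-estimated
#' subject-level values plus the mean bias. Parameters recovered with
#' correlation below 0.5 are flagged. Refits are flagged (not silently
#' dropped) when their convergence diagnostics fail; refits that error are
#' dropped and counted.
#'
#' @param spec a [modelSpec()] or id.
#' @param source a `ddm_fit` (subject-level posterior means are used as
#'   generating truth) or a data frame with columns `a`, `t0`, `v0`,
#'   `v_stim`, `v_personal`, `v_social`, `z0`, `z_personal`, `z_social`.
#' @param design experiment design used to regenerate trial structure.
#' @param n_datasets number of simulated datasets.
#' @param mcmc an [mcmcConfig()] for the refits.
#' @param seed integer seed.
#' @return an object of class `recovery_report`: per-parameter correlation
#'   and bias (averaged over datasets), flags, and per-dataset detail.
#' @export
parameterRecovery <- function(spec, source, design = buildDesign("exp2"),
                              n_datasets = 10, mcmc = mcmcConfig(),
                              seed = 1L) {
  if (is.numeric(spec)) spec <- modelSpec(spec)
  params <- if (inherits(source, "ddm_fit")) {
    subjectEstimates(source)[, .par_names]
  } else {
    as.data.frame(source)[, .par_names]
  }
  ns <- nrow(params)
  free <- .free_mask(spec)
  free_names <- .par_names[free]

  per_dataset <- vector("list", n_datasets)
  dropped <- 0
  for (d in seq_len(n_datasets)) {
    pop <- observerPopulation()
    obs_list <- lapply(seq_len(ns), function(s)
      do.call(observerParams, c(as.list(params[s, ]),
                                list(conf_gain = pop$mean$conf_gain,
                                     conf_noise_sd = pop$mean$conf_noise_sd,
                                     boundary_c = 45))))
    trials <- .simulate_training_from(obs_list, design,
                                      splitSeed(seed, 11L, d))
    refit <- tryCatch(
      fitHierarchical(filterTrials(trials)$trials, spec, mcmc,
                      seed = splitSeed(seed, 12L, d)),
      error = function(e) NULL)
    if (is.null(refit)) { dropped <- dropped + 1; next }
    est <- subjectEstimates(refit)
    per_dataset[[d]] <- data.frame(
      dataset = d,
      parameter = free_names,
      correlation = vapply(free_names, function(p)
        suppressWarnings(cor(params[[p]], est[[p]])), numeric(1)),
      bias = vapply(free_names, function(p)
        mean(est[[p]] - params[[p]]), numeric(1)),
      converged = refit$converged, row.names = NULL)
  }
  detail <- do.call(rbind, per_dataset)
  if (is.null(detail)) stop_config("all recovery refits failed")
  agg <- aggregate(detail[, c("correlation", "bias")],
                   by = list(parameter = detail$parameter), FUN = mean,
                   na.rm = TRUE)
  agg$flagged <- !is.na(agg$correlation) & agg$correlation < 0.5
  structure(list(summary = agg, detail = detail, n_datasets = n_datasets,
                 n_dropped = dropped, spec = spec, seed = seed),
            class = "recovery_report")
}

# simulate only the training phase for fixed observers (shared helper for
# recovery and cross-validation)
.simulate_training_from <- function(obs_list, design, seed, dt = 0.001) {
  pop <- observerPopulation()
  policy <- if (!is.na(design$partner_pse_deg)) {
    partnerPolicy(design$partner_slope, design$partner_pse_deg)
  } else NULL
  ph <- design$phases[design$phases$phase == "training", ]
  rows <- vector("list", length(obs_list))
  for (s in seq_along(obs_list)) {
    obs <- obs_list[[s]]
    sched <- enumerateTrials(design, "training",
                             seed = splitSeed(seed, 21L, s))
    set.seed(splitSeed(seed, 22L, s))
    n <- nrow(sched)
    ic <- ir <- icf <- pc <- rc <- rr <- rcf <- numeric(n)
    for (i in seq_len(n)) {
      ang <- sched$angle_deg[i]
      ini <- simulateInitialDecision(obs, ang, dt)
      ic[i] <- ini$choice; ir[i] <- ini$rt; icf[i] <- ini$conf
      pc[i] <- if (ph$dyadic) partnerChoice(ang, policy) else NA_real_
      rev <- simulateRevisedDecision(obs, ang, ini$choice, ini$conf, pc[i],
                                     dt)
      rc[i] <- rev$choice; rr[i] <- rev$rt; rcf[i] <- rev$conf
    }
    rows[[s]] <- data.frame(
      subject = s, experiment = design$id, phase = "training",
      block = sched$block, trial = sched$trial, angle_deg = sched$angle_deg,
      stim_code = stimulusCode(sched$angle_deg), init_choice = ic,
      init_rt = ir, init_conf = icf, partner_choice = pc, agree = pc == ic,
      rev_choice = rc, rev_rt = rr, rev_conf = rcf, switch = rc != ic)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dyad_trials", "data.frame")
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: model %d, %d datasets (%d dropped)\n",
              x$spec$id, x$n_datasets, x$n_dropped))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Cross-validate the fitted model across partner boundaries
#'
#' Simulates full cohorts under a 45 deg (unbiased) and a 60 deg (biased)
#' partner boundary and fits psychometric curves to the simulated revised
#' choices, predicting how the categorization boundary varies with the
#' partner's boundary.
#'
#' @param population an [observerPopulation()] (e.g. matched to fitted
#'   group-level means).
#' @param partner_pse partner boundaries to simulate (subset of 45, 60).
#' @param n_subjects cohort size per boundary.
#' @param seed integer seed.
#' @return an object of class `cross_validation`: per boundary the fitted
#'   revised-choice PSE, the posttest PSE, and the psychometric curve.
#' @export
crossValidateBoundary <- function(population = observerPopulation(),
                                  partner_pse = c(45, 60), n_subjects = 10,
                                  seed = 1L) {
  stopifnot(all(partner_pse %in% c(45, 60)))
  res <- lapply(partner_pse, function(b) {
    design <- buildDesign(if (b == 45) "exp1" else "exp2")
    trials <- simulateCohort(design, n_subjects, population,
                             master_seed = splitSeed(seed, b))
    fit_rev <- fitPhase(trials, "training", decision = "revised")
    fit_post <- fitPhase(trials, "posttest")
    angles <- design$stimulus_set$angles_deg
    curve <- data.frame(angle_deg = angles,
                        p_concentric = boltzmann(angles, fit_rev$a,
                                                 fit_rev$c))
    list(partner_pse = b, pse_revised = fit_rev$c, pse_posttest = fit_post$c,
         curve = curve)
  })
  names(res) <- paste0("pse", partner_pse)
  structure(list(results = res, n_subjects = n_subjects, seed = seed),
            class = "cross_validation")
}

#' @export
print.cross_validation <- function(x, ...) {
  cat("Partner-boundary cross-validation\n")
  for (r in x$results) {
    cat(sprintf("  partner PSE %d: revised-choice PSE %.2f, posttest PSE %.2f\n",
                r$partner_pse, r$pse_revised, r$pse_posttest))
  }
  invisible(x)
}

# exact (choice-marginal) simulation of one grid cell: initial decision and
# revised decision choices are drawn from the closed-form Wiener choice
# probabilities, which is distribution-exact for choices and avoids path
# simulation
.cell_delta_pse <- function(obs, policy, n_per_angle, angles) {
  ang <- rep(angles, each = n_per_angle)
  stim <- stimulusCode(ang, obs$boundary_c)
  p_up0 <- ddmChoiceProb(obs$a, obs$v0 + obs$v_stim * stim, 0.5)
  init <- ifelse(runif(length(ang)) < p_up0, 1, -1)
  conf <- .draw_conf(obs, abs(ang - obs$boundary_c) / 45)
  P <- personalCode(init, conf)
  S <- partnerChoice(ang, policy)
  v <- obs$v0 + obs$v_stim * stim + obs$v_personal * P + obs$v_social * S
  z <- plogis(obs$z0 + obs$z_personal * P + obs$z_social * S)
  p_up <- ddmChoiceProb(obs$a, v, z)
  rev <- ifelse(runif(length(ang)) < p_up, 1, -1)
  k <- tapply(rev == -1, ang, sum)
  fit <- fitPsychometric(angles, as.numeric(k[as.character(angles)]),
                         rep(n_per_angle, length(angles)))
  if (fit$converged) fit$c - 45 else NA_real_
}

#' PSE-shift parameter grids
#'
#' Simulates revised choices under a biased (60 deg) partner across a
#' two-dimensional grid of personal and social dependencies and records
#' the change of PSE (relative to the 45 deg reference) per cell. Two
#' grids are produced: a drift-rate grid varying (v_personal, v_social)
#' with the starting-point dependencies at zero, and a starting-point grid
#' varying (z_personal, z_social) with the drift dependencies at zero.
#' Other parameters are held at the population means (one shared
#' generating observer per grid).
#'
#' @param v_personal_range,v_social_range drift-grid axes; defaults follow
#'   the reported ranges (personal 0.5 to 2 by 0.15; social 0 to 0.8 by
#'   0.08).
#' @param z_personal_range,z_social_range starting-point-grid axes; same
#'   default ranges on the logit scale.
#' @param n_trials_per_angle simulated trials per spiral angle per cell.
#' @param seed integer seed.
#' @param base_observer baseline [observerParams()] providing the fixed
#'   parameters.
#' @param partner_pse partner boundary, degrees (60 = biased training).
#' @return an object of class `grid_result_pair`: two `grid_result`s
#'   (`v_grid`, `z_grid`), each a matrix of delta-PSE values (degrees) with
#'   personal values on rows and social values on columns.
#' @export
gridDeltaPse <- function(v_personal_range = seq(0.5, 2, by = 0.15),
                         v_social_range = seq(0, 0.8, by = 0.08),
                         z_personal_range = seq(0.5, 2, by = 0.15),
                         z_social_range = seq(0, 0.8, by = 0.08),
                         n_trials_per_angle = 10000, seed = 1L,
                         base_observer = observerParams(),
                         partner_pse = 60) {
  angles <- stimulusSet()$angles_deg
  policy <- partnerPolicy(0.2, partner_pse)
  make_grid <- function(p_range, s_range, which) {
    grid <- matrix(NA_real_, length(p_range), length(s_range),
                   dimnames = list(personal = sprintf("%.2f", p_range),
                                   social = sprintf("%.2f", s_range)))
    for (i in seq_along(p_range)) {
      for (j in seq_along(s_range)) {
        obs <- base_observer
        if (which == "v") {
          obs$v_personal <- p_range[i]; obs$v_social <- s_range[j]
          obs$z_personal <- 0; obs$z_social <- 0
        } else {
          obs$z_personal <- p_range[i]; obs$z_social <- s_range[j]
          obs$v_personal <- 0; obs$v_social <- 0
        }
        set.seed(splitSeed(seed, if (which == "v") 31L else 32L, i, j))
        grid[i, j] <- .cell_delta_pse(obs, policy, n_trials_per_angle,
                                      angles)
      }
    }
    structure(list(delta_pse = grid, personal = p_range, social = s_range,
                   parameter = which,
                   n_trials_per_angle = n_trials_per_angle),
              class = "grid_result")
  }
  structure(list(v_grid = make_grid(v_personal_range, v_social_range, "v"),
                 z_grid = make_grid(z_personal_range, z_social_range, "z"),
                 seed = seed, partner_pse = partner_pse),
            class = "grid_result_pair")
}

#' @export
print.grid_result_pair <- function(x, ...) {
  cat(sprintf("Delta-PSE grids (partner boundary %d deg, %d trials/angle)\n",
              x$partner_pse, x$v_grid$n_trials_per_angle))
  cat("v-grid (rows v_personal, cols v_social), degrees:\n")
  print(round(x$v_grid$delta_pse, 1))
  cat("z-grid (rows z_personal, cols z_social), degrees:\n")
  print(round(x$z_grid$delta_pse, 1))
  invisible(x)
}
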