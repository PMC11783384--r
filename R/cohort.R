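#' Partner choice policy (Boltzmann sigmoid)
#'
#' The simulated partner's choices are generated from a psychometric
#' function: P(concentric | angle) = 1 / (1 + exp(-slope * (angle - pse))).
#' Experiment 1 uses slope 0.2 /deg with PSE 45 deg (unbiased); experiment
#' 2 and the control experiment shift the PSE to 60 deg; experiment 4 uses
#' 30 or 60 deg.
#'
#' @param slope_a slope, per degree (> 0).
#' @param pse_c boundary, degrees in [0, 90].
#' @return an object of class `partner_policy`.
#' @export
partnerPolicy <- function(slope_a = 0.2, pse_c = 45) {
  if (!is.finite(slope_a) || slope_a <= 0) stop_config("slope_a must be > 0")
  if (!is.finite(pse_c) || pse_c < 0 || pse_c > 90) {
    stop_config("pse_c must lie in [0, 90] degrees")
  }
  structure(list(slope_a = slope_a, pse_c = pse_c), class = "partner_policy")
}

#' Partner probability of a concentric choice
#'
#' @param angle_deg spiral angle(s), degrees.
#' @param policy a [partnerPolicy()].
#' @return P(concentric) at each angle.
#' @export
partnerChoiceProb <- function(angle_deg, policy) {
  stopifnot(inherits(policy, "partner_policy"))
  boltzmann(angle_deg, policy$slope_a, policy$pse_c)
}

#' Draw partner choices
#'
#' Bernoulli draws from the policy's psychometric function; concentric is
#' coded -1 and radial +1.
#'
#' @param angle_deg spiral angle(s), degrees.
#' @param policy a [partnerPolicy()].
#' @return vector of choices in {+1 (radial), -1 (concentric)}.
#' @export
partnerChoice <- function(angle_deg, policy) {
  p_conc <- partnerChoiceProb(angle_deg, policy)
  ifelse(runif(length(angle_deg)) < p_conc, -1, 1)
}

#' Stimulus uncertainty code
#'
#' Linear map of the spiral angle onto [-1, +1]: 0 deg (radial) -> +1,
#' 45 deg -> 0, 90 deg (concentric) -> -1. With a reference boundary other
#' than 45 deg the map is taken relative to that boundary,
#' `(boundary - angle) / 45`.
#'
#' @param angle_deg spiral angle(s) in [0, 90] degrees.
#' @param boundary_deg reference boundary, default the physical midpoint 45.
#' @return signed stimulus code.
#' @export
stimulusCode <- function(angle_deg, boundary_deg = 45) {
  if (any(!is.finite(angle_deg)) || any(angle_deg < 0) ||
      any(angle_deg > 90)) {
    stop_config("spiral angle must lie in [0, 90] degrees")
  }
  (boundary_deg - angle_deg) / 45
}

#' Personal information code
#'
#' Initial confidence signed with the initial categorization: radial
#' positive, concentric negative, magnitude scaled to (0, 1] so the code
#' ranges parametrically from -1 to +1. The default scaling is conf/7; an
#' alternative affine mapping of 1..7 onto [0, 1] is available.
#'
#' @param init_choice +1 (radial) or -1 (concentric).
#' @param init_conf integer confidence 1..7.
#' @param mapping `"proportional"` (conf/7) or `"zero_based"` ((conf-1)/6).
#' @return signed personal-information code in [-1, 1].
#' @export
personalCode <- function(init_choice, init_conf,
                         mapping = c("proportional", "zero_based")) {
  mapping <- match.arg(mapping)
  if (any(!init_conf %in% 1:7)) stop_config("confidence must be in 1..7")
  if (any(!init_choice %in% c(-1, 1))) {
    stop_config("choice must be +1 (radial) or -1 (concentric)")
  }
  if (mapping == "proportional") init_choice * init_conf / 7
  else init_choice * (init_conf - 1) / 6
}

#' Observer generating parameters
#'
#' The full parameter set of one synthetic observer: drift-diffusion
#' baseline (threshold `a`, non-decision time `t0`, drift intercept `v0`,
#' stimulus drift sensitivity `v_stim`), covariate sensitivities
#' (`v_personal`, `v_social` on the drift; `z0`, `z_personal`, `z_social`
#' on the logit of the starting point), the confidence model (`conf_gain`,
#' `conf_noise_sd`), the internal category boundary `boundary_c` (deg), and
#' trait scores.
#'
#' @param a decision threshold (> 0).
#' @param t0 non-decision time, seconds (>= 0).
#' @param v0 drift intercept.
#' @param v_stim drift per unit stimulus code.
#' @param v_personal,v_social drift sensitivities to the covariates.
#' @param z0,z_personal,z_social starting-point regression (logit scale).
#' @param conf_gain,conf_noise_sd confidence model parameters.
#' @param boundary_c internal category boundary, degrees in [0, 90].
#' @param aq_social_skill,extraversion trait scores (scalars).
#' @return an object of class `observer_params`.
#' @export
observerParams <- function(a = 2, t0 = 0.3, v0 = 0, v_stim = 2.7,
                           v_personal = 1.36, v_social = 0.45, z0 = 0,
                           z_personal = 0.10, z_social = 0.14,
                           conf_gain = 2.5, conf_noise_sd = 1,
                           boundary_c = 45, aq_social_skill = NA_real_,
                           extraversion = NA_real_) {
  if (a <= 0) stop_config("threshold a must be > 0")
  if (t0 < 0) stop_config("non-decision time t0 must be >= 0")
  if (conf_noise_sd < 0) stop_config("conf_noise_sd must be >= 0")
  if (boundary_c < 0 || boundary_c > 90) {
    stop_config("boundary_c must lie in [0, 90] degrees")
  }
  structure(list(a = a, t0 = t0, v0 = v0, v_stim = v_stim,
                 v_personal = v_personal, v_social = v_social, z0 = z0,
                 z_personal = z_personal, z_social = z_social,
                 conf_gain = conf_gain, conf_noise_sd = conf_noise_sd,
                 boundary_c = boundary_c,
                 aq_social_skill = aq_social_skill,
                 extraversion = extraversion),
            class = "observer_params")
}

#' Observer population distributions
#'
#' Independent normal distributions over the observer parameters (with
#' positivity truncation where required). The default location parameters
#' for the covariate sensitivities are the group-level posterior means
#' reported for the biased-feedback condition (v_personal 1.36, v_social
#' 0.45, z_personal 0.10, z_social 0.14); `preset = "unbiased"` switches to
#' the unbiased-feedback means (0.96, 0.33, 0.33, 0.30). Trait scores are
#' generated with a configurable correlation to the perceptual bias
#' (v_social - v_personal) so the mediation structure is present in
#' synthetic cohorts.
#'
#' @param preset `"biased"` (default) or `"unbiased"` covariate means.
#' @param mean named list overriding population means.
#' @param sd named list overriding population standard deviations.
#' @param trait_cor absolute correlation between traits and the generating
#'   perceptual bias (AQ social skill negative, extraversion positive).
#' @param assimilation_rate per-trial exponential assimilation rate of the
#'   internal boundary toward the partner boundary during dyadic training.
#' @param conf_mapping confidence scaling passed to [personalCode()].
#' @return an object of class `observer_population`.
#' @export
observerPopulation <- function(preset = c("biased", "unbiased"),
                               mean = list(), sd = list(), trait_cor = 0.35,
                               assimilation_rate = 0.002,
                               conf_mapping = "proportional") {
  preset <- match.arg(preset)
  mu <- list(a = 2, t0 = 0.3, v0 = 0, v_stim = 2.7,
             v_personal = 1.36, v_social = 0.45,
             z0 = 0, z_personal = 0.10, z_social = 0.14,
             conf_gain = 2.5, conf_noise_sd = 1, boundary_c = 45)
  if (preset == "unbiased") {
    mu$v_personal <- 0.96; mu$v_social <- 0.33
    mu$z_personal <- 0.33; mu$z_social <- 0.30
  }
  sg <- list(a = 0.2, t0 = 0.05, v0 = 0.1, v_stim = 0.3,
             v_personal = 0.35, v_social = 0.20,
             z0 = 0.1, z_personal = 0.15, z_social = 0.15,
             conf_gain = 0.5, conf_noise_sd = 0, boundary_c = 2)
  mu <- modifyList(mu, mean)
  sg <- modifyList(sg, sd)
  if (any(unlist(sg) < 0)) stop_config("population SDs must be >= 0")
  if (trait_cor < 0 || trait_cor > 1) {
    stop_config("trait_cor must lie in [0, 1]")
  }
  structure(list(mean = mu, sd = sg, trait_cor = trait_cor,
                 assimilation_rate = assimilation_rate,
                 conf_mapping = conf_mapping),
            class = "observer_population")
}

#' Draw one observer from a population
#'
#' @param population an [observerPopulation()].
#' @return an `observer_params` (traits are filled in at cohort level).
#' @export
drawObserver <- function(population) {
  stopifnot(inherits(population, "observer_population"))
  mu <- population$mean; sg <- population$sd
  draw <- function(name, lower = -Inf, upper = Inf) {
    x <- rnorm(1, mu[[name]], sg[[name]])
    min(max(x, lower), upper)
  }
  observerParams(a = draw("a", lower = 0.5),
                 t0 = draw("t0", lower = 0.05),
                 v0 = draw("v0"),
                 v_stim = draw("v_stim", lower = 0.2),
                 v_personal = draw("v_personal"),
                 v_social = draw("v_social"),
                 z0 = draw("z0"),
                 z_personal = draw("z_personal"),
                 z_social = draw("z_social"),
                 conf_gain = draw("conf_gain", lower = 0.2),
                 conf_noise_sd = max(mu$conf_noise_sd, 0),
                 boundary_c = draw("boundary_c", lower = 5, upper = 85))
}

# discretized confidence: 1..7 from a logistic transform of evidence
# strength (|angle - boundary| / 45) plus gaussian noise
.draw_conf <- function(obs, proxy, n = length(proxy)) {
  raw <- 1 + 6 * plogis(obs$conf_gain * proxy +
                          rnorm(n, 0, obs$conf_noise_sd))
  pmin(pmax(round(raw), 1), 7)
}

#' Simulate one initial (pre-feedback) decision
#'
#' Drift-diffusion draw with drift `v0 + v_stim * (boundary_c - angle)/45`
#' and an unbiased starting point, followed by a discretized confidence
#' rating driven by evidence strength (distance of the angle from the
#' observer's internal boundary).
#'
#' @param obs an [observerParams()].
#' @param angle_deg spiral angle, degrees.
#' @param dt Euler step, seconds.
#' @return list with `choice` (+1 radial / -1 concentric), `rt` (s),
#'   `conf` (1..7).
#' @export
simulateInitialDecision <- function(obs, angle_deg, dt = 0.001) {
  stopifnot(inherits(obs, "observer_params"))
  v <- obs$v0 + obs$v_stim * stimulusCode(angle_deg, obs$boundary_c)
  sim <- .ddm_simulate_cpp(length(angle_deg), obs$a, v, rep(0.5, 1),
                           obs$t0, dt, 10)
  proxy <- abs(angle_deg - obs$boundary_c) / 45
  list(choice = sim[, 1], rt = sim[, 2],
       conf = .draw_conf(obs, proxy))
}

#' Simulate one revised (post-feedback) decision
#'
#' Drift-diffusion draw in which personal information (signed initial
#' confidence) and social information (the partner's choice, 0 when
#' absent) enter the drift rate additively and the starting point through
#' a logistic link:
#' `v = v0 + v_stim * stim + v_personal * P + v_social * S`,
#' `z = plogis(z0 + z_personal * P + z_social * S)`.
#'
#' @param obs an [observerParams()].
#' @param angle_deg spiral angle(s), degrees.
#' @param init_choice,init_conf the initial decision.
#' @param partner_choice +1 / -1, or `NA` when no partner is present.
#' @param dt Euler step, seconds.
#' @param conf_mapping passed to [personalCode()].
#' @return list with `choice`, `rt`, `conf`.
#' @export
simulateRevisedDecision <- function(obs, angle_deg, init_choice, init_conf,
                                    partner_choice = NA, dt = 0.001,
                                    conf_mapping = "proportional") {
  stopifnot(inherits(obs, "observer_params"))
  n <- length(angle_deg)
  P <- personalCode(init_choice, init_conf, conf_mapping)
  S <- ifelse(is.na(partner_choice), 0, partner_choice)
  stim <- stimulusCode(angle_deg, obs$boundary_c)
  v <- obs$v0 + obs$v_stim * stim + obs$v_personal * P + obs$v_social * S
  z <- plogis(obs$z0 + obs$z_personal * P + obs$z_social * S)
  sim <- .ddm_simulate_cpp(n, obs$a, rep(v, length.out = n),
                           rep(z, length.out = n), obs$t0, dt, 10)
  proxy <- abs(angle_deg - obs$boundary_c) / 45
  list(choice = sim[, 1], rt = sim[, 2], conf = .draw_conf(obs, proxy, n))
}

#' Simulate a full cohort through an experiment design
#'
#' Draws `n_subjects` observers i.i.d. from the population, runs every
#' phase of the design (test phases: initial decisions only; training:
#' two-phase trials with a partner when the design is dyadic), and returns
#' one tidy trial table. During dyadic training the internal category
#' boundary assimilates exponentially toward the partner boundary at the
#' population's `assimilation_rate` per trial (halved under peer-absent
#' feedback), which is what produces the persistent pre/post PSE shift;
#' within-trial behavior is governed by the drift-diffusion model alone.
#' Fully reproducible from `master_seed`.
#'
#' @param design an [buildDesign()] result.
#' @param n_subjects number of observers (>= 1).
#' @param population an [observerPopulation()].
#' @param master_seed integer master seed.
#' @param dt Euler step for the diffusion simulator, seconds.
#' @return a data frame of class `dyad_trials` with one row per initial-
#'   phase decision: `subject`, `experiment`, `phase`, `block`, `trial`,
#'   `angle_deg`, `stim_code`, `init_choice`, `init_rt`, `init_conf`,
#'   `partner_choice`, `agree`, `rev_choice`, `rev_rt`, `rev_conf`,
#'   `switch`. Revision/partner fields are `NA` on test-phase rows.
#'   The generating observers (with traits) are attached as
#'   `attr(x, "observers")`.
#' @export
simulateCohort <- function(design, n_subjects,
                           population = observerPopulation(),
                           master_seed = 1L, dt = 0.001) {
  stopifnot(inherits(design, "experiment_design"), n_subjects >= 1)
  stopifnot(inherits(population, "observer_population"))
  policy <- if (!is.na(design$partner_pse_deg)) {
    partnerPolicy(design$partner_slope, design$partner_pse_deg)
  } else NULL
  kappa <- population$assimilation_rate
  if (design$feedback_mode == "peer_absent") kappa <- kappa / 2

  observers <- lapply(seq_len(n_subjects), function(s)
    with_seed(splitSeed(master_seed, 1L, s), drawObserver(population)))

  rows <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    obs <- observers[[s]]
    boundary <- obs$boundary_c
    phase_rows <- vector("list", nrow(design$phases))
    for (pi in seq_len(nrow(design$phases))) {
      ph <- design$phases[pi, ]
      sched <- enumerateTrials(design, ph$phase,
                               seed = splitSeed(master_seed, 2L, s, pi))
      set.seed(splitSeed(master_seed, 3L, s, pi))
      n <- nrow(sched)
      obs_now <- obs
      if (!ph$two_phase) {
        # test phase: initial decisions only, boundary frozen
        obs_now$boundary_c <- boundary
        ini <- simulateInitialDecision(obs_now, sched$angle_deg, dt)
        phase_rows[[pi]] <- data.frame(
          subject = s, experiment = design$id, phase = ph$phase,
          block = sched$block, trial = sched$trial,
          angle_deg = sched$angle_deg,
          stim_code = stimulusCode(sched$angle_deg),
          init_choice = ini$choice, init_rt = ini$rt, init_conf = ini$conf,
          partner_choice = NA_real_, agree = NA, rev_choice = NA_real_,
          rev_rt = NA_real_, rev_conf = NA_real_, switch = NA)
      } else {
        ic <- ir <- icf <- pc <- rc <- rr <- rcf <- numeric(n)
        for (i in seq_len(n)) {
          obs_now$boundary_c <- boundary
          ang <- sched$angle_deg[i]
          ini <- simulateInitialDecision(obs_now, ang, dt)
          ic[i] <- ini$choice; ir[i] <- ini$rt; icf[i] <- ini$conf
          pc[i] <- if (ph$dyadic) partnerChoice(ang, policy) else NA_real_
          rev <- simulateRevisedDecision(obs_now, ang, ini$choice, ini$conf,
                                         pc[i], dt,
                                         population$conf_mapping)
          rc[i] <- rev$choice; rr[i] <- rev$rt; rcf[i] <- rev$conf
          if (ph$dyadic) {
            boundary <- boundary + kappa * (design$partner_pse_deg - boundary)
          }
        }
        phase_rows[[pi]] <- data.frame(
          subject = s, experiment = design$id, phase = ph$phase,
          block = sched$block, trial = sched$trial,
          angle_deg = sched$angle_deg,
          stim_code = stimulusCode(sched$angle_deg),
          init_choice = ic, init_rt = ir, init_conf = icf,
          partner_choice = pc, agree = pc == ic, rev_choice = rc,
          rev_rt = rr, rev_conf = rcf, switch = rc != ic)
      }
    }
    rows[[s]] <- do.call(rbind, phase_rows)
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL

  # trait scores with the configured correlation to v_social - v_personal
  obs_df <- do.call(rbind, lapply(seq_along(observers), function(s)
    data.frame(subject = s, as.data.frame(unclass(observers[[s]])))))
  d <- obs_df$v_social - obs_df$v_personal
  zd <- if (stats::sd(d) > 0) (d - mean(d)) / stats::sd(d) else d * 0
  rho <- population$trait_cor
  tr <- with_seed(splitSeed(master_seed, 4L), {
    eps1 <- rnorm(n_subjects); eps2 <- rnorm(n_subjects)
    list(aq = 12 + 3 * (-rho * zd + sqrt(1 - rho^2) * eps1),
         ex = 30 + 6 * (rho * zd + sqrt(1 - rho^2) * eps2))
  })
  obs_df$aq_social_skill <- tr$aq
  obs_df$extraversion <- tr$ex

  class(trials) <- c("dyad_trials", "data.frame")
  attr(trials, "observers") <- obs_df
  attr(trials, "design_id") <- design$id
  attr(trials, "master_seed") <- master_seed
  trials
}

.trial_columns <- c("subject", "experiment", "phase", "block", "trial",
                    "angle_deg", "stim_code", "init_choice", "init_rt",
                    "init_conf", "partner_choice", "agree", "rev_choice",
                    "rev_rt", "rev_conf", "switch")

#' Write a trial table as CSV
#'
#' Fixed, documented column order; missing fields are written as empty
#' cells.
#'
#' @param trials a trial table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrials <- function(trials, path) {
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols) > 0) {
    stop_config("trial table lacks columns: %s",
                paste(missing_cols, collapse = ", "))
  }
  write.csv(trials[, .trial_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial table written by [writeTrials()]
#'
#' @param path CSV path.
#' @return a `dyad_trials` data frame.
#' @export
readTrials <- function(path) {
  trials <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols) > 0) {
    stop_config("trial CSV lacks columns: %s",
                paste(missing_cols, collapse = ", "))
  }
  trials$agree <- as.logical(trials$agree)
  trials$switch <- as.logical(trials$switch)
  class(trials) <- c("dyad_trials", "data.frame")
  trials
}
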