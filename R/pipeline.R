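#' Default pipeline configuration
#'
#' @param experiment experiment id(s) to run.
#' @param n_subjects cohort size per experiment.
#' @param seed master seed.
#' @param models DDM model ids to fit and compare.
#' @param mcmc_profile `"fast"` or `"paper"`.
#' @param validate run the (reduced) validation stage.
#' @param out_dir output directory.
#' @param mcmc optional named list of [mcmcConfig()] overrides
#'   (`n_samples`, `burn_in`, `thin`, `n_chains`).
#' @return a named list understood by [runPipeline()].
#' @export
pipelineConfig <- function(experiment = "exp2", n_subjects = 6, seed = 1L,
                           models = 1:10, mcmc_profile = "fast",
                           validate = FALSE,
                           out_dir = tempfile("dyaddm_run_"),
                           mcmc = NULL) {
  list(experiment = experiment, n_subjects = n_subjects, seed = seed,
       models = models, mcmc_profile = mcmc_profile, validate = validate,
       out_dir = out_dir, mcmc = mcmc)
}

.validate_config <- function(config) {
  required <- c("experiment", "n_subjects", "seed", "models",
                "mcmc_profile", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop_config("pipeline config lacks fields: %s",
                paste(missing, collapse = ", "))
  }
  if (!all(config$experiment %in% .design_ids)) {
    stop_config("unknown experiment id in config")
  }
  if (!all(config$models %in% 1:10)) stop_config("model ids must be 1..10")
  config$validate <- config$validate %||% FALSE
  config
}

#' Run the end-to-end analysis pipeline
#'
#' simulate -> filter -> psychometric fits -> hierarchical DDM fits and
#' DIC comparison -> behavioral indices (-> reduced validation), writing
#' every stage product plus a run manifest and a markdown summary into the
#' output directory. Stages are pure file-to-file transformations; inputs
#' are never mutated. Re-running with the same config reproduces the trial
#' tables bit-exactly.
#'
#' @param config a [pipelineConfig()] list or the path of a YAML file with
#'   the same fields.
#' @return the output directory path, invisibly; stage products:
#'   `trials_<exp>.csv`, `psychometrics_<exp>.json`, `dic_<exp>.csv`,
#'   `fit_summary_<exp>.json`, `indices_<exp>.csv`, `manifest.json`,
#'   `report.md`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config,
                   package_version = as.character(
                     utils::packageVersion("dyaddm")),
                   stages = list())
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop_config("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  report <- c("# Dyadic-training pipeline run", "",
              sprintf("- seed: %d", config$seed),
              sprintf("- subjects per experiment: %d", config$n_subjects),
              sprintf("- MCMC profile: %s", config$mcmc_profile), "")

  for (exp_id in config$experiment) {
    design <- buildDesign(exp_id)
    trials <- t_stage(paste0("simulate_", exp_id),
                      simulateCohort(design, config$n_subjects,
                                     master_seed = splitSeed(config$seed,
                                                             101L,
                                                             match(exp_id,
                                                                   .design_ids))))
    trials_path <- file.path(out, sprintf("trials_%s.csv", exp_id))
    writeTrials(trials, trials_path)

    pre <- fitPhase(trials, "pretest")
    post <- fitPhase(trials, "posttest")
    psy <- list(pretest = list(a = pre$a, c = pre$c),
                posttest = list(a = post$a, c = post$c),
                pse_shift = pseShift(pre, post))
    jsonlite::write_json(psy, file.path(out,
                                        sprintf("psychometrics_%s.json",
                                                exp_id)),
                         auto_unbox = TRUE, digits = NA)
    report <- c(report, sprintf("## %s", exp_id), "",
                sprintf("- pretest PSE %.2f deg, posttest PSE %.2f deg, shift %+.2f deg",
                        pre$c, post$c, psy$pse_shift), "")

    train <- trials[trials$phase == "training", ]
    has_partner <- any(!is.na(train$partner_choice))
    if (has_partner && length(config$models) > 0) {
      filt <- filterTrials(train)
      mcmc <- do.call(mcmcConfig,
                      c(list(profile = config$mcmc_profile),
                        config$mcmc))
      fits <- list()
      dic_rows <- vector("list", length(config$models))
      for (k in seq_along(config$models)) {
        mid <- config$models[k]
        fit <- t_stage(sprintf("ddm_fit_%s_m%d", exp_id, mid),
                       fitHierarchical(filt$trials, mid, mcmc,
                                       seed = splitSeed(config$seed, 201L,
                                                        mid)))
        fits[[as.character(mid)]] <- fit
        dic_rows[[k]] <- data.frame(model = mid, dic = fit$dic,
                                    p_d = fit$p_d,
                                    max_rhat = max(fit$rhat, na.rm = TRUE),
                                    converged = fit$converged)
      }
      dic_table <- do.call(rbind, dic_rows)
      write.csv(dic_table, file.path(out, sprintf("dic_%s.csv", exp_id)),
                row.names = FALSE)
      best_id <- dic_table$model[which.min(dic_table$dic)]
      best <- fits[[as.character(best_id)]]
      jsonlite::write_json(
        list(best_model = best_id,
             excluded_trials = filt$report,
             group_summary = summary(best),
             direction_probs = if (best$spec$id == 10) list(
               v_personal = posteriorDirectionProb(best, "v_personal"),
               v_social = posteriorDirectionProb(best, "v_social"),
               z_personal = posteriorDirectionProb(best, "z_personal"),
               z_social = posteriorDirectionProb(best, "z_social"))
             else NULL),
        file.path(out, sprintf("fit_summary_%s.json", exp_id)),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      report <- c(report,
                  sprintf("- best DDM by DIC: model %d (DIC %.1f)", best_id,
                          min(dic_table$dic)), "")

      idx <- t_stage(paste0("indices_", exp_id), {
        st <- summary(switchTable(train))
        meta <- metacognitiveSensitivity(trials)
        ssi <- socialSusceptibility(train)
        merged <- merge(meta, ssi, by = "subject")
        if (10 %in% config$models) {
          merged <- merge(merged, biasIndices(fits[["10"]]), by = "subject")
        }
        obs <- attr(trials, "observers")
        if (!is.null(obs)) {
          merged <- merge(merged,
                          obs[, c("subject", "aq_social_skill",
                                  "extraversion")], by = "subject")
        }
        list(per_subject = merged, switch_group = st)
      })
      write.csv(idx$per_subject,
                file.path(out, sprintf("indices_%s.csv", exp_id)),
                row.names = FALSE)
      if (10 %in% config$models && "perceptual_bias" %in%
          names(idx$per_subject) && nrow(idx$per_subject) >= 10) {
        med <- mediate(idx$per_subject$aq_social_skill,
                       idx$per_subject$perceptual_bias,
                       idx$per_subject$ssi, n_boot = 2000,
                       seed = splitSeed(config$seed, 301L))
        report <- c(report,
                    sprintf("- mediation (AQ -> perceptual bias -> SSI): a x b = %.3f, CI [%.3f, %.3f]",
                            med$indirect, med$ci_indirect[1],
                            med$ci_indirect[2]), "")
      }
    }
    if (isTRUE(config$validate) && has_partner) {
      grids <- t_stage(paste0("grid_", exp_id),
                       gridDeltaPse(v_personal_range = seq(0.5, 2, by = 0.5),
                                    v_social_range = seq(0, 0.8, by = 0.27),
                                    z_personal_range = seq(0.5, 2, by = 0.5),
                                    z_social_range = seq(0, 0.8, by = 0.27),
                                    n_trials_per_angle = 500,
                                    seed = splitSeed(config$seed, 401L)))
      write.csv(as.data.frame(grids$v_grid$delta_pse),
                file.path(out, sprintf("grid_v_%s.csv", exp_id)))
      write.csv(as.data.frame(grids$z_grid$delta_pse),
                file.path(out, sprintf("grid_z_%s.csv", exp_id)))
    }
  }

  writeLines(report, file.path(out, "report.md"))
  files <- setdiff(list.files(out), "manifest.json")
  manifest$file_md5 <- as.list(tools::md5sum(file.path(out, files)))
  names(manifest$file_md5) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Write the deterministic toy fixtures used in unit tests
#'
#' Three small plain-text tables: an 8-trial switch-probability toy (4
#' agreement trials with no switches, 4 disagreement trials with 2
#' switches), a 6-trial confidence-dynamics toy, and a 24-row mediation
#' toy with full mediation structure (m = x + noise, y = m + noise).
#' Byte-identical across runs at a fixed seed.
#'
#' @param seed integer seed (only the mediation toy is stochastic).
#' @param dir output directory.
#' @return the directory path, invisibly.
#' @export
makeFixtures <- function(seed = 1L, dir = tempfile("dyaddm_fixtures_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base_row <- function(trial, angle, ic, icf, pc, rc, rcf) {
    data.frame(subject = 1, experiment = "exp2", phase = "training",
               block = 1, trial = trial, angle_deg = angle,
               stim_code = stimulusCode(angle), init_choice = ic,
               init_rt = 0.8, init_conf = icf, partner_choice = pc,
               agree = pc == ic, rev_choice = rc, rev_rt = 0.9,
               rev_conf = rcf, switch = rc != ic)
  }
  # 4 agreement trials, 0 switches; 4 disagreement trials, 2 switches
  sw <- rbind(base_row(1, 40, 1, 4, 1, 1, 4),
              base_row(2, 40, 1, 4, 1, 1, 4),
              base_row(3, 50, -1, 4, -1, -1, 4),
              base_row(4, 50, -1, 4, -1, -1, 4),
              base_row(5, 45, 1, 4, -1, -1, 4),
              base_row(6, 45, 1, 4, -1, 1, 4),
              base_row(7, 45, -1, 4, 1, 1, 4),
              base_row(8, 45, -1, 4, 1, -1, 4))
  writeTrials(sw, file.path(dir, "switch_toy.csv"))
  # 6 disagreement trials: 3 stay (init 5,6,7; rev 5,6,7),
  # 3 switch (init 2,3,1; rev 4,5,3)
  cd <- rbind(base_row(1, 45, 1, 5, -1, 1, 5),
              base_row(2, 45, 1, 6, -1, 1, 6),
              base_row(3, 45, 1, 7, -1, 1, 7),
              base_row(4, 45, 1, 2, -1, -1, 4),
              base_row(5, 45, 1, 3, -1, -1, 5),
              base_row(6, 45, 1, 1, -1, -1, 3))
  writeTrials(cd, file.path(dir, "confidence_toy.csv"))
  med <- with_seed(splitSeed(seed, 501L), {
    x <- seq(-1.5, 1.5, length.out = 24)
    m <- x + rnorm(24, 0, 0.4)
    y <- m + rnorm(24, 0, 0.4)
    data.frame(x = round(x, 6), m = round(m, 6), y = round(y, 6))
  })
  write.csv(med, file.path(dir, "mediation_toy.csv"), row.names = FALSE)
  invisible(dir)
}
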