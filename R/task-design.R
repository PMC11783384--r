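#' The default Glass-pattern stimulus set
#'
#' Nine spiral angles spanning radial (0 deg) to concentric (90 deg) at 60%
#' signal, with 10 trials per angle in each training block and 20 trials per
#' angle in each test block.
#'
#' @param angles_deg strictly increasing spiral angles in [0, 90] degrees.
#' @param signal_prop fraction of signal dipoles in [0, 1].
#' @param trials_per_angle_train trials per angle in one training block.
#' @param trials_per_angle_test trials per angle in one test block.
#' @return an object of class `stimulus_set`.
#' @export
stimulusSet <- function(angles_deg = c(0, 20, 30, 40, 45, 50, 60, 70, 90),
                        signal_prop = 0.6,
                        trials_per_angle_train = 10,
                        trials_per_angle_test = 20) {
  if (any(!is.finite(angles_deg)) || any(angles_deg < 0) ||
      any(angles_deg > 90) || any(diff(angles_deg) <= 0)) {
    stop_config("angles_deg must be strictly increasing within [0, 90]")
  }
  if (signal_prop < 0 || signal_prop > 1) {
    stop_config("signal_prop must lie in [0, 1]")
  }
  structure(list(angles_deg = angles_deg, signal_prop = signal_prop,
                 trials_per_angle_train = trials_per_angle_train,
                 trials_per_angle_test = trials_per_angle_test),
            class = "stimulus_set")
}

.design_ids <- c("exp1", "exp2", "exp3", "exp4", "control")

#' Build one of the five experiment designs
#'
#' Returns the resolved block/phase structure of the experiment, the partner
#' policy assignment, and the stimulus set. Training blocks contain 90
#' trials (10 per angle); test blocks contain 180 trials (20 per angle).
#' Partner boundaries: `exp1` 45 deg, `exp2` and `control` 60 deg, `exp4`
#' 30 or 60 deg; `exp3` is individual training with no partner.
#'
#' @param id one of `"exp1"`, `"exp2"`, `"exp3"`, `"exp4"`, `"control"`.
#' @param partner_pse_deg partner boundary for `exp4` (30 or 60); ignored
#'   otherwise.
#' @param n_sessions number of individual pre-training sessions for `exp4`,
#'   between 2 and 4 consecutive days.
#' @param include_retest add the six-weeks-later retest phase (`exp2` only;
#'   a label on the phase, no inter-session timing is modeled).
#' @return an object of class `experiment_design` with fields `id`,
#'   `phases` (data frame: phase, n_blocks, trials_per_block,
#'   trials_per_angle, two_phase, dyadic), `partner_pse_deg`,
#'   `partner_slope`, `feedback_mode`, and `stimulus_set`.
#' @examples
#' d <- buildDesign("exp1")
#' sum(d$phases$n_blocks[d$phases$phase == "training"] *
#'     d$phases$trials_per_block[d$phases$phase == "training"])  # 450
#' @export
buildDesign <- function(id, partner_pse_deg = 60, n_sessions = 2,
                        include_retest = FALSE) {
  if (!is.character(id) || length(id) != 1 || !(id %in% .design_ids)) {
    stop_config("unknown experiment id '%s'; valid ids: %s",
                paste(id, collapse = ","), paste(.design_ids, collapse = ", "))
  }
  ss <- stimulusSet()
  n_ang <- length(ss$angles_deg)
  test_block <- n_ang * ss$trials_per_angle_test    # 180
  train_block <- n_ang * ss$trials_per_angle_train  # 90

  phase_row <- function(phase, n_blocks, tpb, tpa, two_phase, dyadic) {
    data.frame(phase = phase, n_blocks = n_blocks, trials_per_block = tpb,
               trials_per_angle = tpa, two_phase = two_phase,
               dyadic = dyadic, stringsAsFactors = FALSE)
  }
  pre <- phase_row("pretest", 1L, test_block, ss$trials_per_angle_test,
                   FALSE, FALSE)
  post <- phase_row("posttest", 1L, test_block, ss$trials_per_angle_test,
                    FALSE, FALSE)
  retest <- phase_row("retest", 1L, test_block, ss$trials_per_angle_test,
                      FALSE, FALSE)

  if (id == "exp1" || id == "exp2" || id == "control") {
    train <- phase_row("training", 5L, train_block, ss$trials_per_angle_train,
                       TRUE, TRUE)
    phases <- rbind(pre, train, post)
    if (include_retest && id == "exp2") phases <- rbind(phases, retest)
    partner_pse <- if (id == "exp1") 45 else 60
    feedback <- if (id == "control") "peer_absent" else "dyadic"
    partner_slope <- 0.2
  } else if (id == "exp3") {
    train <- phase_row("training", 5L, train_block, ss$trials_per_angle_train,
                       TRUE, FALSE)
    phases <- rbind(pre, train, post)
    partner_pse <- NA_real_
    partner_slope <- NA_real_
    feedback <- "none"
  } else { # exp4
    if (!partner_pse_deg %in% c(30, 60)) {
      stop_config("exp4 partner boundary must be 30 or 60 degrees")
    }
    if (n_sessions < 2 || n_sessions > 4) {
      stop_config("exp4 uses between 2 and 4 individual training sessions")
    }
    ind <- phase_row("individual_training", as.integer(n_sessions * 5),
                     test_block, ss$trials_per_angle_test, FALSE, FALSE)
    train <- phase_row("training", 5L, train_block, ss$trials_per_angle_train,
                       TRUE, TRUE)
    phases <- rbind(phase_row("pretraining_test", 1L, test_block,
                              ss$trials_per_angle_test, FALSE, FALSE),
                    ind,
                    phase_row("intermediate_test", 1L, test_block,
                              ss$trials_per_angle_test, FALSE, FALSE),
                    train, post)
    partner_pse <- partner_pse_deg
    partner_slope <- 0.2
    feedback <- "error_feedback_pretraining"
  }

  design <- structure(list(id = id, phases = phases,
                           partner_pse_deg = partner_pse,
                           partner_slope = partner_slope,
                           feedback_mode = feedback,
                           stimulus_set = ss),
                      class = "experiment_design")
  validateDesign(design)
  design
}

#' Validate an experiment design's structural invariants
#'
#' @param design an `experiment_design`.
#' @return the design, invisibly; errors if an invariant is violated.
#' @export
validateDesign <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  ph <- design$phases
  ok <- ph$trials_per_block ==
    length(design$stimulus_set$angles_deg) * ph$trials_per_angle
  if (!all(ok)) stop_config("phase trial counts inconsistent with angles")
  if ("training" %in% ph$phase) {
    tr <- ph[ph$phase == "training", ]
    if (tr$trials_per_block != 90) {
      stop_config("training blocks must have 90 trials")
    }
  }
  if (!is.na(design$partner_pse_deg) &&
      (design$partner_pse_deg < 0 || design$partner_pse_deg > 90)) {
    stop_config("partner boundary out of range")
  }
  invisible(design)
}

#' Enumerate the stimulus schedule of one phase
#'
#' Each angle appears exactly `trials_per_angle` times per block; the order
#' within a block is a uniformly random permutation determined by a
#' per-block seed derived from `seed`, so the same seed always yields the
#' identical schedule.
#'
#' @param design an `experiment_design`.
#' @param phase a phase name present in the design.
#' @param seed integer seed for the within-block shuffles.
#' @return a data frame with columns `block`, `trial` (index within block),
#'   and `angle_deg`.
#' @export
enumerateTrials <- function(design, phase, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  ph <- design$phases
  if (!phase %in% ph$phase) {
    stop_config("phase '%s' not in design '%s' (has: %s)", phase, design$id,
                paste(ph$phase, collapse = ", "))
  }
  row <- ph[ph$phase == phase, ][1, ]
  angles <- design$stimulus_set$angles_deg
  out <- vector("list", row$n_blocks)
  for (b in seq_len(row$n_blocks)) {
    sched <- rep(angles, each = row$trials_per_angle)
    ord <- with_seed(splitSeed(seed, match(phase, ph$phase), b),
                     sample.int(length(sched)))
    out[[b]] <- data.frame(block = b, trial = seq_along(sched),
                           angle_deg = sched[ord])
  }
  do.call(rbind, out)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Experiment design '%s' (feedback: %s)\n", x$id,
              x$feedback_mode))
  if (!is.na(x$partner_pse_deg)) {
    cat(sprintf("  partner policy: slope %.2f /deg, PSE %.0f deg\n",
                x$partner_slope, x$partner_pse_deg))
  } else {
    cat("  no partner\n")
  }
  print(x$phases, row.names = FALSE)
  invisible(x)
}

#' Write an experiment design to a YAML file
#'
#' @param design an `experiment_design`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDesign <- function(design, path) {
  stopifnot(inherits(design, "experiment_design"))
  obj <- unclass(design)
  obj$phases <- lapply(seq_len(nrow(design$phases)), function(i)
    as.list(design$phases[i, ]))
  obj$stimulus_set <- unclass(design$stimulus_set)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read an experiment design written by [writeDesign()]
#'
#' @param path file path.
#' @return an `experiment_design`.
#' @export
readDesign <- function(path) {
  obj <- yaml::read_yaml(path)
  phases <- do.call(rbind, lapply(obj$phases, function(p)
    data.frame(phase = p$phase, n_blocks = as.integer(p$n_blocks),
               trials_per_block = as.integer(p$trials_per_block),
               trials_per_angle = as.integer(p$trials_per_angle),
               two_phase = p$two_phase, dyadic = p$dyadic,
               stringsAsFactors = FALSE)))
  ss <- do.call(stimulusSet, obj$stimulus_set)
  design <- structure(list(id = obj$id, phases = phases,
                           partner_pse_deg = obj$partner_pse_deg %||% NA_real_,
                           partner_slope = obj$partner_slope %||% NA_real_,
                           feedback_mode = obj$feedback_mode,
                           stimulus_set = ss),
                      class = "experiment_design")
  validateDesign(design)
  design
}
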