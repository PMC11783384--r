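#' Switch-probability table
#'
#' Per-subject probability of switching the initial choice in the revised
#' decision, in the 2 x 2 classification of trials by initial confidence
#' (high vs. low relative to the subject's own mean; ties count as high)
#' and social feedback (agreement vs. disagreement with the partner).
#' Cells with no trials are reported as missing, not zero.
#'
#' @param trials training-phase trials with both decisions and a partner
#'   choice.
#' @param conf_split `"subject"` or `"grand"` mean confidence split.
#' @return an object of class `switch_table`: data frame with columns
#'   `subject`, `confidence`, `agreement`, `n_trials`, `p_switch`.
#' @export
switchTable <- function(trials, conf_split = "subject") {
  need <- c("init_conf", "agree", "switch")
  if (any(vapply(need, function(cn) all(is.na(trials[[cn]])), logical(1)))) {
    stop_config("switch table needs revision-phase fields (two-phase trials)")
  }
  keep <- !is.na(trials$agree) & !is.na(trials$switch)
  trials <- trials[keep, , drop = FALSE]
  type <- .trial_types(trials, conf_split)
  cells <- expand.grid(subject = sort(unique(trials$subject)),
                       confidence = c("high", "low"),
                       agreement = c("agree", "disagree"),
                       stringsAsFactors = FALSE)
  key <- paste(cells$confidence, cells$agreement, sep = "_")
  tkey <- paste0(trials$subject, ".", as.character(type))
  n <- table(tkey)
  sw <- tapply(trials$switch, tkey, mean)
  ck <- paste0(cells$subject, ".", key)
  cells$n_trials <- as.integer(ifelse(ck %in% names(n), n[ck], 0))
  cells$p_switch <- ifelse(cells$n_trials > 0, sw[ck], NA_real_)
  cells <- cells[order(cells$subject, cells$confidence, cells$agreement), ]
  rownames(cells) <- NULL
  structure(cells, class = c("switch_table", "data.frame"))
}

#' Group means of a switch table
#'
#' @param x a `switch_table`.
#' @param ... unused.
#' @return data frame of group-mean switch probabilities per cell.
#' @export
summary.switch_table <- function(x, ...) {
  aggregate(p_switch ~ confidence + agreement, data = x, FUN = mean,
            na.rm = TRUE)
}

#' Confidence dynamics under disagreement
#'
#' Per-subject mean initial and revised confidence, separated by whether
#' the revised decision stayed with or switched away from the initial
#' choice, restricted to disagreement trials. Subjects lacking trials in a
#' cell get a missing value.
#'
#' @param trials training-phase trials with both decisions and partner
#'   choice.
#' @return data frame with columns `subject`, `decision` (stay/switch),
#'   `initial_conf`, `revised_conf`.
#' @export
confidenceDynamics <- function(trials) {
  keep <- !is.na(trials$agree) & !trials$agree & !is.na(trials$switch)
  t2 <- trials[keep, , drop = FALSE]
  if (nrow(t2) == 0) stop_config("no disagreement trials")
  subjects <- sort(unique(trials$subject))
  cells <- expand.grid(subject = subjects, decision = c("stay", "switch"),
                       stringsAsFactors = FALSE)
  t2$decision <- ifelse(t2$switch, "switch", "stay")
  key <- paste0(t2$subject, ".", t2$decision)
  mi <- tapply(t2$init_conf, key, mean)
  mr <- tapply(t2$rev_conf, key, mean)
  ck <- paste0(cells$subject, ".", cells$decision)
  cells$initial_conf <- ifelse(ck %in% names(mi), mi[ck], NA_real_)
  cells$revised_conf <- ifelse(ck %in% names(mr), mr[ck], NA_real_)
  cells[order(cells$subject, cells$decision), ]
}

#' Metacognitive sensitivity
#'
#' Per-subject slope of the ordinary least-squares regression of initial
#' confidence on coded accuracy: correct responses 0, incorrect responses
#' 1, responses at the physical boundary (45 deg, where no answer is
#' correct) 0.5. A more negative coefficient indicates confidence that
#' better discriminates correct from incorrect responses under this
#' coding; the sign convention follows the accuracy coding exactly.
#'
#' @param trials initial-decision trials (training phase).
#' @param phase phase to use, default training.
#' @return data frame with columns `subject`, `coefficient`, `n_trials`;
#'   subjects with zero variance in the accuracy regressor get `NA`.
#' @export
metacognitiveSensitivity <- function(trials, phase = "training") {
  t2 <- trials[trials$phase == phase, , drop = FALSE]
  if (nrow(t2) == 0) stop_config("no trials in phase '%s'", phase)
  correct_choice <- ifelse(t2$angle_deg < 45, 1, -1)
  acc <- ifelse(t2$angle_deg == 45, 0.5,
                ifelse(t2$init_choice == correct_choice, 0, 1))
  out <- lapply(sort(unique(t2$subject)), function(s) {
    rows <- t2$subject == s
    x <- acc[rows]; y <- t2$init_conf[rows]
    coefficient <- if (length(unique(x)) < 2) NA_real_ else
      unname(coef(lm(y ~ x))[2])
    data.frame(subject = s, coefficient = coefficient,
               n_trials = sum(rows))
  })
  do.call(rbind, out)
}

#' Social susceptibility index
#'
#' Per-subject multiple regression predicting the z-scored signed revised
#' confidence (confidence signed with the revised categorization:
#' concentric negative, radial positive) from the z-scored signed initial
#' confidence and the partner's choice coded radial 0.5 / concentric
#' -0.5. The social susceptibility index is `beta_social -
#' beta_personal`. Z-scoring is within subject across that subject's
#' training trials.
#'
#' @param trials training-phase trials with both decisions and a partner
#'   choice.
#' @return data frame with columns `subject`, `beta_personal`,
#'   `beta_social`, `ssi`; degenerate design matrices yield `NA` rows.
#' @export
socialSusceptibility <- function(trials) {
  keep <- !is.na(trials$partner_choice) & !is.na(trials$rev_conf)
  t2 <- trials[keep, , drop = FALSE]
  if (nrow(t2) == 0) stop_config("no partner trials with revised confidence")
  zscore <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
    (x - mean(x)) / s
  }
  out <- lapply(sort(unique(t2$subject)), function(s) {
    rows <- t2[t2$subject == s, ]
    y <- zscore(rows$rev_choice * rows$rev_conf)
    x1 <- zscore(rows$init_choice * rows$init_conf)
    x2 <- ifelse(rows$partner_choice > 0, 0.5, -0.5)
    if (anyNA(y) || anyNA(x1) || length(unique(x2)) < 2) {
      return(data.frame(subject = s, beta_personal = NA_real_,
                        beta_social = NA_real_, ssi = NA_real_))
    }
    b <- coef(lm(y ~ x1 + x2))
    data.frame(subject = s, beta_personal = unname(b["x1"]),
               beta_social = unname(b["x2"]),
               ssi = unname(b["x2"] - b["x1"]))
  })
  do.call(rbind, out)
}

#' Perceptual and response bias indices
#'
#' Subject-level posterior-mean differences from a full-model fit:
#' perceptual bias `v_social - v_personal` and response bias `z_social -
#' z_personal`.
#'
#' @param fit a `ddm_fit` of the full model (model 10).
#' @return data frame with columns `subject`, `perceptual_bias`,
#'   `response_bias`.
#' @export
biasIndices <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  if (fit$spec$id != 10) {
    stop_config("bias indices require the full model (model 10)")
  }
  est <- subjectEstimates(fit)
  data.frame(subject = est$subject,
             perceptual_bias = est$v_social - est$v_personal,
             response_bias = est$z_social - est$z_personal)
}

#' Bias-corrected bootstrap mediation analysis
#'
#' Simple mediation: `a` from regressing the mediator on the predictor,
#' `b` and the direct effect `c'` from regressing the outcome on mediator
#' and predictor, total effect `c` from the outcome on the predictor. The
#' indirect effect `a x b` gets a bias-corrected (BC) percentile bootstrap
#' confidence interval; the effect is flagged significant when the 95% CI
#' excludes zero.
#'
#' @param x predictor (e.g. trait score).
#' @param m mediator.
#' @param y outcome.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param conf_level confidence level of the interval.
#' @return an object of class `mediation_result` with path coefficients
#'   `a`, `b`, `c`, `c_prime`, `indirect`, the CI, the stored bootstrap
#'   draws, and the significance flag.
#' @export
mediate <- function(x, m, y, n_boot = 5000, seed = 1L, conf_level = 0.95) {
  stopifnot(length(x) == length(m), length(x) == length(y))
  ok <- complete.cases(x, m, y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  if (length(x) < 10) stop_config("mediation needs n >= 10 complete cases")
  if (sd(x) == 0 || sd(m) == 0 || sd(y) == 0) {
    stop_config("constant input vector")
  }
  paths <- function(xi, mi, yi) {
    X1 <- cbind(1, xi)
    a <- .lm.fit(X1, mi)$coefficients[2]
    cf <- .lm.fit(cbind(1, mi, xi), yi)$coefficients
    c_tot <- .lm.fit(X1, yi)$coefficients[2]
    c(a = a, b = cf[2], c_prime = cf[3], c = c_tot)
  }
  est <- paths(x, m, y)
  indirect <- est["a"] * est["b"]
  n <- length(x)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    p <- paths(x[idx], m[idx], y[idx])
    p["a"] * p["b"]
  }, numeric(1)))
  # bias-corrected percentile interval
  alpha <- (1 - conf_level) / 2
  prop <- mean(boot < indirect)
  prop <- min(max(prop, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
  z0 <- qnorm(prop)
  lo_p <- pnorm(2 * z0 + qnorm(alpha))
  hi_p <- pnorm(2 * z0 + qnorm(1 - alpha))
  ci <- unname(quantile(boot, c(lo_p, hi_p)))
  structure(list(a = unname(est["a"]), b = unname(est["b"]),
                 c = unname(est["c"]), c_prime = unname(est["c_prime"]),
                 indirect = unname(indirect), ci_indirect = ci,
                 significant = ci[1] > 0 || ci[2] < 0,
                 n = n, n_boot = n_boot, seed = seed, boot = boot,
                 conf_level = conf_level),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation (n = %d, %d bootstrap samples)\n", x$n, x$n_boot))
  cat(sprintf("  a = %.3f, b = %.3f, c = %.3f, c' = %.3f\n", x$a, x$b, x$c,
              x$c_prime))
  cat(sprintf("  indirect a x b = %.3f, %d%% BC CI [%.3f, %.3f] %s\n",
              x$indirect, round(100 * x$conf_level), x$ci_indirect[1],
              x$ci_indirect[2],
              if (x$significant) "(excludes 0)" else "(covers 0)"))
  invisible(x)
}
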