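#' Boltzmann sigmoid
#'
#' `f(x) = 1 / (1 + exp(-a * (x - c)))`, the probability of a concentric
#' response at spiral angle `x`. The boundary `c` is the point of
#' subjective equality (PSE); the slope `a` indexes perceptual sensitivity.
#'
#' @param x spiral angle(s), degrees.
#' @param a slope, per degree.
#' @param c boundary (PSE), degrees.
#' @return probability in (0, 1).
#' @examples
#' boltzmann(60, 0.2, 45)  # 1 / (1 + exp(-3))
#' @export
boltzmann <- function(x, a, c) {
  stopifnot(is.finite(a), is.finite(c))
  1 / (1 + exp(-a * (x - c)))
}

#' Fit the Boltzmann sigmoid to categorization counts
#'
#' Maximum-likelihood (binomial) estimation of slope `a` and boundary `c`
#' from per-angle concentric-response counts, using bounded quasi-Newton
#' optimization from a grid of starting values (c in 30/45/60, a in
#' 0.05/0.2/0.5); the best log-likelihood wins and ties go to the smallest
#' `|c - 45|`. A least-squares objective on proportions is available for
#' comparison. Data with all responses in one category (separation) yield a
#' non-converged fit with `c` absent.
#'
#' @param x spiral angles, degrees.
#' @param k number of concentric responses per angle.
#' @param n number of trials per angle.
#' @param objective `"binomial"` (default, MLE) or `"ls"` (least squares on
#'   proportions).
#' @param ci `"none"` or `"bootstrap"` (parametric bootstrap on the fitted
#'   probabilities).
#' @param n_boot bootstrap replicates for the PSE confidence interval.
#' @param seed seed for the bootstrap.
#' @return an object of class `psychometric_fit` with fields `a`, `c`,
#'   `loglik`, `converged`, `ci_c`, `n_per_angle`, `data`.
#' @export
fitPsychometric <- function(x, k, n, objective = c("binomial", "ls"),
                            ci = c("none", "bootstrap"), n_boot = 500,
                            seed = 1L) {
  objective <- match.arg(objective)
  ci <- match.arg(ci)
  stopifnot(length(x) == length(k), length(x) == length(n))
  if (length(unique(x)) < 3) stop_config("need at least 3 distinct angles")
  if (any(n <= 0)) stop_config("every angle needs n > 0 trials")
  if (any(k < 0) || any(k > n)) stop_config("counts must satisfy 0 <= k <= n")

  fit <- .fit_boltzmann_core(x, k, n, objective)
  ci_c <- c(NA_real_, NA_real_)
  if (fit$converged && ci == "bootstrap") {
    p_hat <- boltzmann(x, fit$a, fit$c)
    cs <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      kb <- rbinom(length(x), n, p_hat)
      fb <- .fit_boltzmann_core(x, kb, n, objective)
      if (fb$converged) fb$c else NA_real_
    }, numeric(1)))
    ci_c <- unname(quantile(cs, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(a = fit$a, c = if (fit$converged) fit$c else NA_real_,
                 loglik = fit$loglik, converged = fit$converged,
                 ci_c = ci_c, n_per_angle = n,
                 data = data.frame(x = x, k = k, n = n),
                 objective = objective),
            class = "psychometric_fit")
}

.fit_boltzmann_core <- function(x, k, n, objective) {
  # separation: all responses in one category
  if (sum(k) == 0 || sum(k) == sum(n)) {
    return(list(a = NA_real_, c = NA_real_, loglik = NA_real_,
                converged = FALSE))
  }
  negobj <- if (objective == "binomial") {
    function(par) {
      p <- boltzmann(x, par[1], par[2])
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(k * log(p) + (n - k) * log(1 - p))
    }
  } else {
    function(par) sum((k / n - boltzmann(x, par[1], par[2]))^2)
  }
  # start the slope with the sign of the empirical trend so radial counts
  # fit to the same boundary with the slope negated (orientation-agnostic)
  trend <- sign(cov(x, k / n))
  if (!is.finite(trend) || trend == 0) trend <- 1
  starts <- expand.grid(a = trend * c(0.05, 0.2, 0.5), c = c(30, 45, 60))
  best <- NULL
  better <- function(opt, cur) {
    # prefer cleanly converged starts, then likelihood, then |c - 45|
    if (is.null(cur)) return(TRUE)
    ok_new <- opt$convergence == 0
    ok_cur <- cur$convergence == 0
    if (ok_new != ok_cur) return(ok_new)
    if (opt$value < cur$value - 1e-9) return(TRUE)
    abs(opt$value - cur$value) <= 1e-9 &&
      abs(opt$par[2] - 45) < abs(cur$par[2] - 45)
  }
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(
      optim(c(starts$a[i], starts$c[i]), negobj, method = "L-BFGS-B",
            lower = c(-10, -90), upper = c(10, 180)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (better(opt, best)) best <- opt
  }
  if (is.null(best)) {
    return(list(a = NA_real_, c = NA_real_, loglik = NA_real_,
                converged = FALSE))
  }
  ll <- if (objective == "binomial") -best$value else {
    p <- pmin(pmax(boltzmann(x, best$par[1], best$par[2]), 1e-12), 1 - 1e-12)
    sum(k * log(p) + (n - k) * log(1 - p))
  }
  list(a = best$par[1], c = best$par[2], loglik = ll,
       converged = best$convergence == 0)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Boltzmann fit: slope a = %.4f /deg, PSE c = %.2f deg", x$a,
                x$c))
    if (!any(is.na(x$ci_c))) {
      cat(sprintf(" (95%% CI %.2f-%.2f)", x$ci_c[1], x$ci_c[2]))
    }
    cat(sprintf(", loglik = %.2f\n", x$loglik))
  } else {
    cat("Boltzmann fit: not converged (separation or optimizer failure)\n")
  }
  invisible(x)
}

#' PSE shift between two psychometric fits
#'
#' The change of the categorization boundary, `post$c - pre$c`, in degrees.
#'
#' @param pre,post converged `psychometric_fit` objects.
#' @return shift in degrees.
#' @export
pseShift <- function(pre, post) {
  stopifnot(inherits(pre, "psychometric_fit"),
            inherits(post, "psychometric_fit"))
  if (!pre$converged || !post$converged) {
    stop_config("both fits must have converged to compute a PSE shift")
  }
  post$c - pre$c
}

# aggregate a trial table to per-angle concentric counts for one decision
.angle_counts <- function(trials, decision = c("initial", "revised")) {
  decision <- match.arg(decision)
  col <- if (decision == "initial") "init_choice" else "rev_choice"
  keep <- !is.na(trials[[col]])
  t2 <- trials[keep, ]
  agg <- aggregate(list(k = t2[[col]] == -1), by = list(x = t2$angle_deg),
                   FUN = sum)
  nn <- aggregate(list(n = rep(1, nrow(t2))), by = list(x = t2$angle_deg),
                  FUN = sum)
  merge(agg, nn, by = "x")
}

#' Fit a psychometric function to one phase of a trial table
#'
#' @param trials a trial table (see [simulateCohort()]).
#' @param phase phase name to use.
#' @param decision `"initial"` or `"revised"` choices.
#' @param subject optional subject id; default pools all subjects.
#' @param ... passed to [fitPsychometric()].
#' @return a `psychometric_fit`.
#' @export
fitPhase <- function(trials, phase, decision = "initial", subject = NULL,
                     ...) {
  t2 <- trials[trials$phase == phase, ]
  if (!is.null(subject)) t2 <- t2[t2$subject == subject, ]
  if (nrow(t2) == 0) stop_config("no trials in phase '%s'", phase)
  cnt <- .angle_counts(t2, decision)
  fitPsychometric(cnt$x, cnt$k, cnt$n, ...)
}

#' Block-wise psychometric fits over a phase
#'
#' One fit per block, tracking the gradual boundary shift over training.
#' Blocks with separation are returned flagged (non-converged).
#'
#' @param trials trial table.
#' @param phase phase name (default training).
#' @param decision `"initial"` or `"revised"`.
#' @param subject optional subject id to restrict to.
#' @param ... passed to [fitPsychometric()].
#' @return list of `psychometric_fit`, one per block.
#' @export
blockwisePse <- function(trials, phase = "training", decision = "initial",
                         subject = NULL, ...) {
  t2 <- trials[trials$phase == phase, ]
  if (!is.null(subject)) t2 <- t2[t2$subject == subject, ]
  if (nrow(t2) == 0) stop_config("no trials in phase '%s'", phase)
  blocks <- sort(unique(t2$block))
  lapply(blocks, function(b) {
    tb <- t2[t2$block == b, ]
    if (nrow(tb) == 0) stop_config("empty block %d", b)
    cnt <- .angle_counts(tb, decision)
    fitPsychometric(cnt$x, cnt$k, cnt$n, ...)
  })
}
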