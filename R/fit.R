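# Binomial maximum-likelihood fitting of the Rogers random-predator model.
#
# Each trial contributes Binomial(n_eaten | n_initial, p) with
# p = rogers_expected(n_initial, a, h, t) / n_initial. The predicted
# proportion is always < 1, so trials where every prey was consumed remain
# informative rather than impossible. Optimisation is over (log a, log h) to
# enforce positivity; standard errors come from the inverse observed
# information on the log scale, mapped back by the delta method.

# Negative log-likelihood at natural-scale (a, h). Predictions are computed
# once per unique (n_initial, duration) pair.
rogers_nll <- function(a, h, n0, ne, t) {
  make_nll(n0, ne, t)(a, h)
}

# Build a fast evaluator of the negative log-likelihood for fixed data:
# the unique (n_initial, duration) design points and their row mapping are
# precomputed once, so optimiser iterations only pay for the model curve.
make_nll <- function(n0, ne, t) {
  key <- paste(n0, t)
  uk <- !duplicated(key)
  mi <- match(key, key[uk])
  n0u <- n0[uk]
  tu <- t[uk]
  function(a, h) {
    if (!is.finite(a) || !is.finite(h) || a < 0 || h < 0) {
      return(1e12)
    }
    pred <- tryCatch(
      rogers_expected_by(n0u, a, h, tu),
      error = function(e) NULL
    )
    if (is.null(pred)) {
      return(1e12)
    }
    p <- (pred / n0u)[mi]
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- sum(stats::dbinom(ne, n0, p, log = TRUE))
    if (!is.finite(ll)) {
      return(1e12)
    }
    -ll
  }
}

# rogers_expected over paired (n0, t) vectors (durations may differ).
rogers_expected_by <- function(n0, a, h, t) {
  if (length(unique(t)) == 1L) {
    return(rogers_expected(n0, a, h, t[1]))
  }
  vapply(
    seq_along(n0),
    function(i) rogers_expected(n0[i], a, h, t[i]),
    numeric(1)
  )
}

#' Rogers model log-likelihood at fixed parameters
#'
#' Sum of binomial log-probabilities of the observed prey eaten given the
#' depletion-model predicted proportion eaten. Exposed so the likelihood a
#' fit maximises can be inspected or profiled directly.
#'
#' @inheritParams fit_rogers
#' @inheritParams fr_params
#' @return The log-likelihood (a single number).
#' @examples
#' tr <- tibble::tibble(n_initial = c(8, 16, 32), n_eaten = c(4, 7, 10))
#' rogers_loglik(tr, a = 1, h = 0.1)
#' @export
rogers_loglik <- function(trials, a, h) {
  check_trials(trials)
  check_fr_params(a, h, t = 1)
  -rogers_nll(a, h, trials$n_initial, trials$n_eaten, trial_durations(trials))
}

#' Fit the Rogers random-predator Type-II model by maximum likelihood
#'
#' Step two of the comparative functional-response procedure: estimate the
#' attack rate `a` and handling time `h` from no-replacement feeding trials
#' by maximising the per-trial binomial likelihood of prey eaten, with the
#' expected proportion given by [rogers_expected()]. Optimisation is on
#' `(log a, log h)` from a small deterministic multi-start grid (guarding
#' against the attack-rate/handling-time ridge); standard errors, Z
#' statistics and two-sided normal p-values are derived from the observed
#' information.
#'
#' Trials at densities where prey were completely depleted are retained by
#' default — the depletion model predicts a proportion strictly below 1, so
#' they are informative; set `exclude_depleted = TRUE` for a sensitivity
#' re-fit without them. A fitted handling time at the lower boundary
#' (`h <= 1e-8`) is flagged (`boundary = TRUE`) rather than treated as an
#' error: sparse data can legitimately estimate an effectively unlimited
#' feeding rate.
#'
#' @param trials Data frame of feeding trials for one group: columns
#'   `n_initial`, `n_eaten`, optionally `duration_h` (default 1 hour).
#'   At least 3 distinct densities and some feeding are required.
#' @param init Optional starting values, an [fr_params()] object or a named
#'   list/vector with `a` and `h`; prepended to the multi-start grid.
#' @param exclude_depleted Drop trials with `n_eaten == n_initial` before
#'   fitting (default `FALSE`).
#' @param reltol Relative convergence tolerance on the log-likelihood
#'   passed to [stats::optim()] (default 1e-10).
#' @param multistart Use the deterministic multi-start grid (default
#'   `TRUE`). With `multistart = FALSE` and an `init`, only that start is
#'   used — the fast path for bootstrap refits.
#'
#' @return An object of class `fr_fit` with elements `a`, `h`, `t`, `se_a`,
#'   `se_h`, `z_a`, `z_h`, `p_a`, `p_h`, `log_likelihood`, `converged`,
#'   `boundary`, `n_trials`, `vcov_log` (covariance of `(log a, log h)`),
#'   the `trials` used, and optimisation metadata. Methods: `print()`,
#'   `coef()`, `logLik()`, `predict()`, `confint()`, [generics::tidy()],
#'   [generics::glance()], [ggplot2::autoplot()].
#' @examples
#' set.seed(42)
#' tr <- simulate_trials(a = 1.5, h = 0.08, replicates = 5)
#' fit <- fit_rogers(tr)
#' fit
#' tidy(fit)
#' @export
fit_rogers <- function(trials, init = NULL, exclude_depleted = FALSE,
                       reltol = 1e-10, multistart = TRUE) {
  check_trials(trials)
  if (exclude_depleted) {
    trials <- trials[trials$n_eaten < trials$n_initial, , drop = FALSE]
    if (nrow(trials) == 0L) {
      rlang::abort("No trials left after excluding complete depletion.",
        class = "funcresp_error_data"
      )
    }
  }
  n0 <- trials$n_initial
  ne <- trials$n_eaten
  tt <- trial_durations(trials)
  if (length(unique(n0)) < 3L) {
    rlang::abort(
      sprintf(
        "Fitting needs >= 3 distinct prey densities (got %d); a and h are not jointly identifiable [group %s].",
        length(unique(n0)), group_tag(trials)
      ),
      class = "funcresp_error_data"
    )
  }
  if (all(ne == 0)) {
    rlang::abort(
      sprintf(
        "No prey were eaten in any trial for group %s; the attack rate is not estimable.",
        group_tag(trials)
      ),
      class = "funcresp_error_data"
    )
  }
  if (all(ne == n0)) {
    rlang::abort(
      sprintf(
        "Every trial completely depleted its prey for group %s; the handling time is unidentifiable (h ~ 0).",
        group_tag(trials)
      ),
      class = "funcresp_error_data"
    )
  }

  nll <- make_nll(n0, ne, tt)
  fn <- function(par) nll(exp(par[1]), exp(par[2]))

  starts <- fit_start_grid(n0, ne, tt, init, multistart)
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(log(s), fn,
        method = "Nelder-Mead",
        control = list(reltol = reltol, maxit = 2000)
      ),
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e12) {
    rlang::abort(
      sprintf("Rogers MLE failed to converge for group %s.", group_tag(trials)),
      class = "funcresp_error_convergence"
    )
  }

  par <- best$par
  a <- exp(par[1])
  h <- exp(par[2])
  boundary <- h <= 1e-8
  vcov_log <- fit_vcov_log(fn, par, boundary)
  se_log <- sqrt(pmax(diag(vcov_log), 0))
  se_a <- a * se_log[1]
  se_h <- h * se_log[2]
  z_a <- a / se_a
  z_h <- h / se_h
  structure(
    list(
      a = a, h = h, t = tt[1],
      se_a = se_a, se_h = se_h,
      z_a = z_a, z_h = z_h,
      p_a = 2 * stats::pnorm(-abs(z_a)),
      p_h = 2 * stats::pnorm(-abs(z_h)),
      log_likelihood = -best$value,
      converged = best$convergence == 0,
      boundary = boundary,
      n_trials = nrow(trials),
      vcov_log = vcov_log,
      trials = tibble::as_tibble(trials),
      optim = list(
        counts = best$counts, convergence = best$convergence,
        n_starts = length(starts), start_best = NA
      )
    ),
    class = "fr_fit"
  )
}

# Deterministic multi-start grid: attack rates bracketing typical arena
# efficiencies, handling times anchored at 1/max density, the inverse of the
# largest observed meal (a plateau guess), and 0.1.
fit_start_grid <- function(n0, ne, tt, init = NULL, multistart = TRUE) {
  starts <- list()
  if (!is.null(init)) {
    ia <- init[["a"]]
    ih <- init[["h"]]
    check_fr_params(ia, max(ih, 0), t = 1)
    starts <- list(c(max(ia, 1e-8), max(ih, 1e-8)))
    if (!multistart) {
      return(starts)
    }
  }
  h_guess <- unique(c(
    1 / max(n0),
    stats::median(tt) / max(1, max(ne)),
    0.1
  ))
  grid <- expand.grid(a = c(0.1, 1, 10), h = h_guess)
  c(starts, lapply(seq_len(nrow(grid)), function(i) c(grid$a[i], grid$h[i])))
}

# Observed-information covariance on the log scale; singular or boundary
# Hessians give NA standard errors rather than an error.
fit_vcov_log <- function(fn, par, boundary) {
  hess <- tryCatch(stats::optimHess(par, fn), error = function(e) NULL)
  vc <- matrix(NA_real_, 2, 2, dimnames = list(c("log_a", "log_h"), c("log_a", "log_h")))
  if (!is.null(hess) && !boundary) {
    vci <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vci) && all(is.finite(diag(vci))) && all(diag(vci) > 0)) {
      vc[] <- vci
    }
  }
  vc
}

#' @export
print.fr_fit <- function(x, ...) {
  cat("Rogers random-predator Type-II fit (binomial MLE)\n")
  cat(sprintf(
    "  attack rate   a = %.4g  (SE %.3g, z = %.3g, p = %.3g)\n",
    x$a, x$se_a, x$z_a, x$p_a
  ))
  cat(sprintf(
    "  handling time h = %.4g  (SE %.3g, z = %.3g, p = %.3g)%s\n",
    x$h, x$se_h, x$z_h, x$p_h, if (x$boundary) "  [boundary]" else ""
  ))
  mfr <- if (x$boundary) NA_real_ else 1 / (x$h * x$t)
  cat(sprintf(
    "  max feeding rate 1/(h*t) = %s prey per trial; logLik = %.4f; n = %d trials\n",
    ifelse(is.na(mfr), "undefined", sprintf("%.3g", mfr)),
    x$log_likelihood, x$n_trials
  ))
  if (!x$converged) cat("  WARNING: optimiser did not report convergence\n")
  invisible(x)
}

#' @export
coef.fr_fit <- function(object, ...) c(a = object$a, h = object$h)

#' @export
logLik.fr_fit <- function(object, ...) {
  structure(object$log_likelihood, df = 2, class = "logLik")
}

#' @export
#' @describeIn fit_rogers Wald confidence intervals for `a` and `h`,
#'   computed on the log scale (so they respect positivity) and mapped back.
#' @param object,parm,level Standard [stats::confint()] arguments.
confint.fr_fit <- function(object, parm = c("a", "h"), level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se_log <- sqrt(diag(object$vcov_log))
  est <- c(a = object$a, h = object$h)
  out <- cbind(
    lower = est * exp(-z * se_log),
    upper = est * exp(z * se_log)
  )
  rownames(out) <- c("a", "h")
  out[parm, , drop = FALSE]
}

#' @export
#' @describeIn fit_rogers Predicted prey eaten at new densities (tibble with
#'   `n_initial` and `predicted`).
#' @param newdata Data frame with `n_initial` (and optionally `duration_h`),
#'   or a numeric vector of densities.
predict.fr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$trials
  if (is.numeric(newdata)) newdata <- tibble::tibble(n_initial = newdata)
  t <- if ("duration_h" %in% names(newdata)) newdata$duration_h else rep(object$t, nrow(newdata))
  tibble::tibble(
    n_initial = newdata$n_initial,
    predicted = rogers_expected_by(newdata$n_initial, object$a, object$h, t)
  )
}

#' @describeIn fit_rogers Per-parameter tibble (term, estimate, std.error,
#'   statistic, p.value), broom style.
#' @param x An `fr_fit` object.
#' @param ... Unused.
#' @export
tidy.fr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "h"),
    estimate = c(x$a, x$h),
    std.error = c(x$se_a, x$se_h),
    statistic = c(x$z_a, x$z_h),
    p.value = c(x$p_a, x$p_h)
  )
}

#' @describeIn fit_rogers One-row model summary: log-likelihood,
#'   convergence, boundary flag, number of trials, maximum feeding rate.
#' @export
glance.fr_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_likelihood,
    converged = x$converged,
    boundary = x$boundary,
    n_trials = x$n_trials,
    max_feeding_rate = if (x$boundary) NA_real_ else 1 / (x$h * x$t)
  )
}

#' Tabular summary of a fitted functional response
#'
#' One-row tibble in the shape of a comparative functional-response results
#' table: attack rate and handling time with their p-values and the maximum
#' feeding rate `1/(h*t)` (reported as `NA` for a boundary fit with `h ~ 0`,
#' where the asymptote is undefined).
#'
#' @param fit An `fr_fit` from [fit_rogers()].
#' @return A one-row tibble with columns `a`, `p_a`, `h`, `p_h`,
#'   `max_feeding_rate`.
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "fr_fit"))
  if (!fit$converged) {
    rlang::abort("Cannot summarise a non-converged fit.",
      class = "funcresp_error_convergence"
    )
  }
  tibble::tibble(
    a = fit$a, p_a = fit$p_a,
    h = fit$h, p_h = fit$p_h,
    max_feeding_rate = if (fit$boundary) NA_real_ else 1 / (fit$h * fit$t)
  )
}

#' @describeIn fit_rogers Plot observed prey eaten against density with the
#'   fitted depletion curve.
#' @export
autoplot.fr_fit <- function(object, ...) {
  grid <- tibble::tibble(
    n_initial = seq(0, max(object$trials$n_initial), length.out = 200)
  )
  pred <- predict(object, grid)
  ggplot2::ggplot(object$trials, ggplot2::aes(x = .data$n_initial, y = .data$n_eaten)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(
      data = pred,
      ggplot2::aes(x = .data$n_initial, y = .data$predicted),
      colour = "steelblue", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "Initial prey density", y = "Prey eaten",
      title = sprintf("Rogers Type-II fit: a = %.3g, h = %.3g", object$a, object$h)
    ) +
    ggplot2::theme_minimal()
}
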