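# Juliano's indicator-variable difference test and pairwise group letters.
#
# Two groups are fitted jointly with a = a1 + da * j, h = h1 + dh * j
# (j = 0/1 group indicator) by the same binomial depletion likelihood as
# fit_rogers; Wald Z tests on da and dh test whether attack rate and
# handling time differ between the groups. Fitting is on the natural scale
# (the difference terms are signed); parameter sets leaving either group
# outside the admissible region are rejected with an infinite likelihood.

juliano_nll <- function(par, n0, ne, tt, j) {
  a1 <- par[1]
  h1 <- par[2]
  a2 <- par[1] + par[3]
  h2 <- par[2] + par[4]
  if (a1 <= 0 || h1 < 0 || a2 <= 0 || h2 < 0) {
    return(1e12)
  }
  g0 <- j == 0
  rogers_nll(a1, h1, n0[g0], ne[g0], tt[g0]) +
    rogers_nll(a2, h2, n0[!g0], ne[!g0], tt[!g0])
}

#' Compare attack rate and handling time between two groups (Juliano's method)
#'
#' Step three of the comparative functional-response procedure: the two
#' groups' trials are pooled and fitted with the indicator-variable
#' parameterisation `a = a1 + delta_a * j`, `h = h1 + delta_h * j`
#' (`j = 1` for the second group), so `delta_a` and `delta_h` are the
#' group-2 minus group-1 differences. Wald Z statistics on the difference
#' terms test the null of equal parameters.
#'
#' @param trials_1,trials_2 Trial data frames for the two groups (see
#'   [fit_rogers()] for the required columns). Each group must be fittable
#'   on its own.
#' @param labels Character vector of length 2 naming the groups in the
#'   output (defaults to `"group1"`, `"group2"`).
#' @param reltol Convergence tolerance for the pooled optimisation.
#'
#' @return An object of class `fr_comparison`: difference estimates
#'   `delta_a`, `delta_h`, their standard errors, Z statistics and two-sided
#'   p-values; the per-group fits `fit_1`, `fit_2`; the pooled
#'   log-likelihood; and the group labels. [generics::tidy()] returns a
#'   two-row tibble (one row per difference term).
#' @examples
#' set.seed(7)
#' f <- simulate_trials(a = 1, h = 0.02, replicates = 5, seed = 1)
#' m <- simulate_trials(a = 1, h = 0.20, replicates = 5, seed = 2)
#' juliano_compare(f, m, labels = c("female", "male"))
#' @export
juliano_compare <- function(trials_1, trials_2, labels = c("group1", "group2"),
                            reltol = 1e-12) {
  check_trials(trials_1, "trials_1")
  check_trials(trials_2, "trials_2")
  t1 <- unique(trial_durations(trials_1))
  t2 <- unique(trial_durations(trials_2))
  if (length(unique(c(t1, t2))) > 1L) {
    rlang::abort("Groups must share a single trial duration for comparison.",
      class = "funcresp_error_data"
    )
  }
  if (length(intersect(trials_1$n_initial, trials_2$n_initial)) == 0L) {
    rlang::warn("Density designs of the two groups do not overlap; the comparison extrapolates.")
  }
  fit_1 <- fit_rogers(trials_1)
  fit_2 <- fit_rogers(trials_2)

  n0 <- c(trials_1$n_initial, trials_2$n_initial)
  ne <- c(trials_1$n_eaten, trials_2$n_eaten)
  tt <- c(trial_durations(trials_1), trial_durations(trials_2))
  j <- rep(c(0L, 1L), c(nrow(trials_1), nrow(trials_2)))

  start <- c(fit_1$a, fit_1$h, fit_2$a - fit_1$a, fit_2$h - fit_1$h)
  fn <- function(par) juliano_nll(par, n0, ne, tt, j)
  opt <- stats::optim(start, fn,
    method = "Nelder-Mead",
    control = list(reltol = reltol, maxit = 5000)
  )
  if (!is.finite(opt$value) || opt$value >= 1e12) {
    rlang::abort("Pooled indicator-variable fit failed to converge.",
      class = "funcresp_error_convergence"
    )
  }
  hess <- tryCatch(stats::optimHess(opt$par, fn), error = function(e) NULL)
  se <- rep(NA_real_, 4)
  if (!is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
      se <- sqrt(diag(vc))
    }
  }
  est <- opt$par
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(
      labels = labels,
      delta_a = est[3], delta_h = est[4],
      se_delta_a = se[3], se_delta_h = se[4],
      z_delta_a = z[3], z_delta_h = z[4],
      p_delta_a = p[3], p_delta_h = p[4],
      a_1 = est[1], h_1 = est[2],
      fit_1 = fit_1, fit_2 = fit_2,
      log_likelihood = -opt$value,
      converged = opt$convergence == 0
    ),
    class = "fr_comparison"
  )
}

#' @export
print.fr_comparison <- function(x, ...) {
  cat(sprintf(
    "Juliano difference test: %s vs %s (differences are %s minus %s)\n",
    x$labels[1], x$labels[2], x$labels[2], x$labels[1]
  ))
  cat(sprintf(
    "  delta a = %+.4g  (SE %.3g, z = %.3g, p = %.3g)\n",
    x$delta_a, x$se_delta_a, x$z_delta_a, x$p_delta_a
  ))
  cat(sprintf(
    "  delta h = %+.4g  (SE %.3g, z = %.3g, p = %.3g)\n",
    x$delta_h, x$se_delta_h, x$z_delta_h, x$p_delta_h
  ))
  invisible(x)
}

#' @describeIn juliano_compare Two-row tibble with one row per difference
#'   term (`delta_a`, `delta_h`).
#' @param x An `fr_comparison` object.
#' @param ... Unused.
#' @export
tidy.fr_comparison <- function(x, ...) {
  tibble::tibble(
    term = c("delta_a", "delta_h"),
    estimate = c(x$delta_a, x$delta_h),
    std.error = c(x$se_delta_a, x$se_delta_h),
    statistic = c(x$z_delta_a, x$z_delta_h),
    p.value = c(x$p_delta_a, x$p_delta_h),
    group_1 = x$labels[1],
    group_2 = x$labels[2]
  )
}

#' Pairwise Juliano comparisons across several groups, with letters
#'
#' Applies [juliano_compare()] to every pair of groups in a trial table and
#' summarises which groups differ with a compact letter display (groups
#' sharing no letter differ significantly). Raw and Holm-adjusted p-values
#' are both reported; the letter display uses the adjusted values by
#' default.
#'
#' @param trials Trial data frame containing a grouping column.
#' @param group Name of the grouping column (string).
#' @param alpha Significance level for the letter display (default 0.05).
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"holm"`; use `"none"` for raw letters).
#'
#' @return A list with `pairs` (tibble of pairwise difference tests, raw and
#'   adjusted p-values for both parameters) and `letters` (tibble of per-group
#'   letters for `a` and for `h`).
#' @export
juliano_pairwise <- function(trials, group, alpha = 0.05, adjust = "holm") {
  check_trials(trials)
  if (!group %in% names(trials)) {
    rlang::abort(sprintf("Column `%s` not found in trials.", group),
      class = "funcresp_error_data"
    )
  }
  g <- as.character(trials[[group]])
  lev <- unique(g)
  if (length(lev) < 2L) {
    rlang::abort("Need at least 2 groups for pairwise comparison.",
      class = "funcresp_error_data"
    )
  }
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    cmp <- juliano_compare(
      trials[g == pr[1], , drop = FALSE],
      trials[g == pr[2], , drop = FALSE],
      labels = pr
    )
    tibble::tibble(
      group_1 = pr[1], group_2 = pr[2],
      delta_a = cmp$delta_a, p_a_raw = cmp$p_delta_a,
      delta_h = cmp$delta_h, p_h_raw = cmp$p_delta_h
    )
  })
  res$p_a_adj <- stats::p.adjust(res$p_a_raw, method = adjust)
  res$p_h_adj <- stats::p.adjust(res$p_h_raw, method = adjust)

  pm <- function(p) {
    m <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
    for (i in seq_len(nrow(res))) {
      m[res$group_1[i], res$group_2[i]] <- p[i]
      m[res$group_2[i], res$group_1[i]] <- p[i]
    }
    m
  }
  letters_tbl <- tibble::tibble(
    group = lev,
    letters_a = unname(letters_from_pmatrix(pm(res$p_a_adj), alpha)),
    letters_h = unname(letters_from_pmatrix(pm(res$p_h_adj), alpha))
  )
  list(pairs = res, letters = letters_tbl)
}
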