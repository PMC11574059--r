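#' Determine functional response type by logistic regression
#'
#' Step one of the comparative functional-response procedure: regress the
#' proportion of prey eaten on initial prey density with a binomial GLM and
#' read the sign of the first-order density term. A significantly negative
#' first-order term indicates a Type-II (decelerating, saturating) response;
#' a significantly positive term indicates Type III (sigmoidal); anything
#' else is reported as ambiguous.
#'
#' @param trials Data frame of feeding trials for a single experimental
#'   group, with columns `n_initial` and `n_eaten`; at least two distinct
#'   densities are required.
#' @param degree Degree of the raw polynomial in density (default 1, the
#'   decision rule only uses the first-order sign; degree 2 gives the
#'   quadratic fit sometimes used to confirm sigmoidal shapes).
#' @param alpha Two-sided significance level for the sign rule (default
#'   0.05).
#'
#' @return An object of class `fr_type_test`: a list with
#'   `first_order_coef`, `p_value`, `inferred_type` (one of `"type_II"`,
#'   `"type_III"`, `"ambiguous"`), `degree`, `alpha`, and the fitted `model`.
#'   Use [generics::tidy()] for a one-row tibble.
#' @examples
#' set.seed(1)
#' tr <- simulate_trials(a = 2, h = 0.04, densities = c(2, 4, 8, 16, 32, 64))
#' classify_fr_type(tr)
#' @export
classify_fr_type <- function(trials, degree = 1, alpha = 0.05) {
  check_trials(trials)
  if (length(unique(trials$n_initial)) < 2L) {
    rlang::abort(
      "Type determination needs at least 2 distinct prey densities.",
      class = "funcresp_error_data"
    )
  }
  if (all(trials$n_eaten == trials$n_initial) || all(trials$n_eaten == 0)) {
    rlang::abort(
      sprintf(
        "Degenerate data for group %s: prey were %s in every trial, the logistic regression is separated.",
        group_tag(trials),
        if (all(trials$n_eaten == 0)) "never eaten" else "always fully eaten"
      ),
      class = "funcresp_error_data"
    )
  }
  dat <- data.frame(ne = trials$n_eaten, n0 = trials$n_initial)
  fit <- stats::glm(
    cbind(ne, n0 - ne) ~ poly(n0, degree = degree, raw = TRUE),
    family = stats::binomial(), data = dat
  )
  sm <- summary(fit)$coefficients
  b1 <- sm[2, 1]
  p1 <- sm[2, 4]
  type <- if (is.finite(p1) && p1 < alpha) {
    if (b1 < 0) "type_II" else "type_III"
  } else {
    "ambiguous"
  }
  structure(
    list(
      first_order_coef = b1, p_value = p1, inferred_type = type,
      degree = degree, alpha = alpha, model = fit,
      n_trials = nrow(trials)
    ),
    class = "fr_type_test"
  )
}

#' @export
print.fr_type_test <- function(x, ...) {
  cat("Functional response type test (binomial GLM on density)\n")
  cat(sprintf(
    "  first-order term: %.4g  (p = %.3g, alpha = %g)\n",
    x$first_order_coef, x$p_value, x$alpha
  ))
  cat(sprintf("  inferred type:    %s\n", x$inferred_type))
  invisible(x)
}

#' @describeIn classify_fr_type One-row tibble with the first-order
#'   coefficient, its p-value and the inferred type.
#' @param x An `fr_type_test` object.
#' @param ... Unused.
#' @export
tidy.fr_type_test <- function(x, ...) {
  tibble::tibble(
    first_order_coef = x$first_order_coef,
    p_value = x$p_value,
    inferred_type = x$inferred_type,
    degree = x$degree,
    n_trials = x$n_trials
  )
}
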