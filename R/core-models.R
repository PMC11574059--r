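#' Functional response parameters
#'
#' Bundle and validate the three quantities that define a Type-II functional
#' response: the attack rate `a` (search efficiency per unit time, per
#' arena), the handling time `h` (time spent capturing, consuming and
#' digesting one prey item), and the trial duration `t`. Prey density is
#' treated as a count per experimental arena, so `a` is arena-specific and
#' carries no volume unit.
#'
#' @param a Attack rate, a finite non-negative number.
#' @param h Handling time, a finite non-negative number, in the same time
#'   unit as `t`.
#' @param t Trial duration, a finite positive number (hours in the default
#'   experimental design, where `t = 1`).
#'
#' @return An object of class `fr_params`: a named list with elements `a`,
#'   `h`, `t`.
#' @examples
#' fr_params(a = 1.2, h = 0.05)
#' @export
fr_params <- function(a, h, t = 1) {
  check_fr_params(a, h, t)
  structure(list(a = a, h = h, t = t), class = "fr_params")
}

#' @export
print.fr_params <- function(x, ...) {
  cat(sprintf(
    "<fr_params> attack rate a = %g, handling time h = %g, duration t = %g\n",
    x$a, x$h, x$t
  ))
  invisible(x)
}

check_fr_params <- function(a, h, t) {
  bad <- function(v) !is.numeric(v) || length(v) != 1L || !is.finite(v)
  if (bad(a) || a < 0) {
    rlang::abort("`a` (attack rate) must be a finite number >= 0.",
      class = "funcresp_error_params"
    )
  }
  if (bad(h) || h < 0) {
    rlang::abort("`h` (handling time) must be a finite number >= 0.",
      class = "funcresp_error_params"
    )
  }
  if (bad(t) || t <= 0) {
    rlang::abort("`t` (trial duration) must be a finite number > 0.",
      class = "funcresp_error_params"
    )
  }
  invisible(TRUE)
}

#' Holling disc equation (constant prey density)
#'
#' Expected number of prey eaten under the classical Type-II disc equation
#' `a * N * t / (1 + a * h * N)`, which assumes prey are replaced as they
#' are consumed so density stays constant. It is the baseline that the
#' depletion-corrected [rogers_expected()] relaxes; with no replacement the
#' disc equation can predict more prey eaten than were offered.
#'
#' @param n Prey density (count per arena); non-negative, vectorised.
#' @inheritParams fr_params
#' @return Expected number of prey eaten, same length as `n`.
#' @examples
#' holling_expected(64, a = 2, h = 0.05)
#' @seealso [rogers_expected()] for the no-replacement version.
#' @export
holling_expected <- function(n, a, h, t = 1) {
  check_fr_params(a, h, t)
  check_density(n)
  a * n * t / (1 + a * h * n)
}

#' Rogers' random-predator equation (prey depletion)
#'
#' Expected number of prey eaten in a trial where consumed prey are not
#' replaced. The model is implicit in the number eaten,
#' `Ne = N0 * (1 - exp(a * (Ne * h - t)))`, and is evaluated through its
#' closed form on the principal branch of the Lambert W function:
#' `Ne = N0 - W0(a * h * N0 * exp(-a * (t - h * N0))) / (a * h)`.
#'
#' The W argument grows like `exp(a * h * N0)` and overflows double
#' precision for strong depletion regimes; when its natural logarithm
#' exceeds `exp_cap` the function switches to a bracketing root search of
#' the implicit equation on `[0, N0]`, which is immune to overflow. The two
#' paths agree to well below 1e-8. `n0` may be non-integer so that
#' optimisers can evaluate the curve on a smooth grid. W0 is evaluated by a
#' guarded Halley iteration with a hard iteration cap (falling back to the
#' bracketing root search if the cap is hit), so a single curve evaluation
#' can never fail to terminate inside an optimiser loop.
#'
#' @param n0 Initial prey count(s) offered; non-negative, vectorised.
#' @inheritParams fr_params
#' @param exp_cap Natural-log threshold on the Lambert W argument above
#'   which the bracketing root finder is used instead. Default 700, just
#'   under the double-precision overflow point.
#' @return Expected number eaten, in `[0, n0)`; exactly 0 when `a = 0` or
#'   `n0 = 0`.
#' @examples
#' rogers_expected(c(2, 4, 8, 16, 32, 64), a = 1, h = 0.1)
#' @export
rogers_expected <- function(n0, a, h, t = 1, exp_cap = 700) {
  check_fr_params(a, h, t)
  check_density(n0)
  out <- numeric(length(n0))
  if (a == 0) {
    return(out)
  }
  if (h == 0) {
    return(n0 * (1 - exp(-a * t)))
  }
  pos <- which(n0 > 0)
  if (length(pos) == 0L) {
    return(out)
  }
  np <- n0[pos]
  log_arg <- log(a * h) + log(np) - a * (t - h * np)
  val <- numeric(length(np))
  wp <- log_arg <= exp_cap
  if (any(wp)) {
    w <- lambert_w0(exp(log_arg[wp]))
    val[wp] <- np[wp] - w / (a * h)
    # iteration cap hit (NA): solve those implicitly instead
    miss <- which(wp)[is.na(w)]
    for (i in miss) val[i] <- rogers_root(np[i], a, h, t)
  }
  if (any(!wp)) {
    val[!wp] <- vapply(np[!wp], rogers_root, numeric(1), a = a, h = h, t = t)
  }
  out[pos] <- pmin(pmax(val, 0), np)
  out
}

# Principal branch of the Lambert W function (inverse of w * exp(w)) for
# x >= 0, vectorised. Halley's method from the asymptotic guess
# log(x) - log(log(x)) (or x * (1 - x) near zero), with the step damped to
# keep w > -1 and a hard cap of 80 iterations; elements that fail to reach
# tolerance are returned as NA for the caller to resolve by bracketing.
# Arguments are capped upstream at exp(700), so w * exp(w) never overflows.
lambert_w0 <- function(x) {
  w <- numeric(length(x))
  big <- x > 2.5
  lx <- log(x[big])
  w[big] <- lx - log(lx)
  mid <- !big & x > 0.3
  w[mid] <- 0.5 * log1p(x[mid])
  sml <- x <= 0.3
  w[sml] <- x[sml] * (1 - x[sml])
  done <- x == 0
  for (iter in 1:80) {
    if (all(done)) break
    wa <- w[!done]
    e <- exp(wa)
    f <- wa * e - x[!done]
    # Halley update; denominator is positive for w > -1
    d <- e * (wa + 1) - (wa + 2) * f / (2 * wa + 2)
    step <- f / d
    wn <- wa - step
    w[!done] <- wn
    conv <- abs(step) <= 1e-13 * (1 + abs(wn))
    done[!done] <- conv
  }
  w[!done] <- NA_real_
  w
}

# Bracketing solution of Ne = n0 * (1 - exp(a * (Ne * h - t))) on [0, n0].
# The residual is written as x - n0 + n0 * exp(a * (x * h - t)); the exponent
# is capped so the endpoint evaluations stay finite in extreme regimes.
rogers_root <- function(n0, a, h, t) {
  f <- function(x) {
    # n0 * exp(e) computed in log space and capped so endpoint values stay
    # finite in extreme depletion regimes
    x - n0 + exp(min(a * (x * h - t) + log(n0), 700))
  }
  r <- tryCatch(
    stats::uniroot(f, lower = 0, upper = n0, tol = 1e-12 * max(1, n0)),
    error = function(e) {
      rlang::abort(
        sprintf(
          "Root search for the implicit depletion equation failed (n0=%g, a=%g, h=%g, t=%g): %s",
          n0, a, h, t, conditionMessage(e)
        ),
        class = "funcresp_error_convergence"
      )
    }
  )
  r$root
}

#' Maximum feeding rate
#'
#' Asymptote of the Type-II functional response: `1 / (h * t)` prey per
#' trial duration. Undefined (infinite) when the handling time is zero, in
#' which case an error is signalled rather than `Inf` returned.
#'
#' @inheritParams fr_params
#' @return Prey consumed per trial duration at saturating prey density.
#' @examples
#' max_feeding_rate(h = 0.0113) # about 88 prey per hour
#' @export
max_feeding_rate <- function(h, t = 1) {
  check_fr_params(a = 0, h = h, t = t)
  if (h == 0) {
    rlang::abort(
      "Maximum feeding rate 1/(h*t) is undefined for h = 0 (no asymptote).",
      class = "funcresp_error_params"
    )
  }
  1 / (h * t)
}

check_density <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0)) {
    rlang::abort("Prey density must be finite and >= 0.",
      class = "funcresp_error_params"
    )
  }
  invisible(TRUE)
}
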