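#' Non-parametric bootstrap confidence band around a functional response
#'
#' Resamples whole trials with replacement (trials are the independent
#' experimental units — one predator per arena), refits the Rogers model to
#' each resample, evaluates every refitted curve on a density grid, and
#' returns the pointwise mean and percentile 95% envelope. Replicates whose
#' refit fails are dropped and counted rather than redrawn, so the band is a
#' deterministic function of the seed.
#'
#' @param trials Trial data frame for one group (see [fit_rogers()]).
#' @param n_boot Number of bootstrap replicates (the reference procedure
#'   uses 2000; smaller values are fine for exploration). Must be >= 2.
#' @param grid Densities at which to evaluate the band; defaults to the
#'   sorted unique observed densities.
#' @param seed Integer seed making the resampling reproducible; `NULL`
#'   leaves the RNG state alone.
#' @param level Envelope coverage (default 0.95, i.e. 2.5/97.5 percentiles).
#' @param keep_draws Retain the per-replicate `(a, h)` draws (default
#'   `TRUE`).
#' @param max_fail Error if more than this fraction of replicate refits
#'   fail (default 0.2).
#'
#' @return An object of class `fr_boot`: a list with `band` (tibble with
#'   columns `n_initial`, `mean`, `lower`, `upper`, `point` — `point` is the
#'   curve of the original point-estimate fit), the original `fit`,
#'   `n_boot`, `n_failed`, `seed`, `level`, and `draws` (tibble of
#'   per-replicate estimates, if kept). `lower <= upper` pointwise; the
#'   envelope need not bracket the point-estimate curve.
#' @examples
#' tr <- simulate_trials(a = 1.5, h = 0.05, replicates = 5, seed = 3)
#' bb <- bootstrap_fr(tr, n_boot = 50, seed = 1)
#' bb$band
#' @export
bootstrap_fr <- function(trials, n_boot = 2000, grid = NULL, seed = NULL,
                         level = 0.95, keep_draws = TRUE, max_fail = 0.2) {
  check_trials(trials)
  if (!is.numeric(n_boot) || n_boot < 2) {
    rlang::abort("`n_boot` must be at least 2.", class = "funcresp_error_params")
  }
  n_boot <- as.integer(n_boot)
  fit <- fit_rogers(trials)
  if (is.null(grid)) grid <- sort(unique(trials$n_initial))
  grid <- sort(unique(grid))
  check_density(grid)

  n <- nrow(trials)
  idx <- with_local_seed(seed, {
    matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  })

  start <- list(a = fit$a, h = fit$h)
  curves <- matrix(NA_real_, n_boot, length(grid))
  draws <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    bt <- trials[idx[b, ], , drop = FALSE]
    bf <- tryCatch(
      suppressWarnings(fit_rogers(bt, init = start, reltol = 1e-8, multistart = FALSE)),
      error = function(e) NULL
    )
    if (is.null(bf) || !bf$converged) next
    draws[b, ] <- c(bf$a, bf$h)
    curves[b, ] <- rogers_expected(grid, bf$a, bf$h, fit$t)
  }
  ok <- stats::complete.cases(curves)
  n_failed <- sum(!ok)
  if (n_failed > max_fail * n_boot) {
    rlang::abort(
      sprintf(
        "Bootstrap unstable: %d of %d replicate refits failed (> %.0f%%) for group %s.",
        n_failed, n_boot, 100 * max_fail, group_tag(trials)
      ),
      class = "funcresp_error_bootstrap"
    )
  }
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  band <- tibble::tibble(
    n_initial = grid,
    mean = colMeans(curves[ok, , drop = FALSE]),
    lower = apply(curves[ok, , drop = FALSE], 2, stats::quantile, probs = qs[1]),
    upper = apply(curves[ok, , drop = FALSE], 2, stats::quantile, probs = qs[2]),
    point = rogers_expected(grid, fit$a, fit$h, fit$t)
  )
  structure(
    list(
      band = band, fit = fit, n_boot = n_boot, n_failed = n_failed,
      seed = seed, level = level,
      draws = if (keep_draws) {
        tibble::tibble(replicate = which(ok), a = draws[ok, 1], h = draws[ok, 2])
      } else {
        NULL
      }
    ),
    class = "fr_boot"
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. With seed = NULL the global stream is used.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(eval.parent(substitute(expr)))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' @export
print.fr_boot <- function(x, ...) {
  cat(sprintf(
    "Bootstrap %g%% confidence band (n_boot = %d, %d failed refits dropped%s)\n",
    100 * x$level, x$n_boot, x$n_failed,
    if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)
  ))
  print(x$band, n = 10)
  invisible(x)
}

#' @describeIn bootstrap_fr The band tibble, one row per grid density.
#' @param x An `fr_boot` object.
#' @param ... Unused.
#' @export
tidy.fr_boot <- function(x, ...) x$band

#' @describeIn bootstrap_fr Ribbon plot of the envelope with the bootstrap
#'   mean and point-estimate curves and the observed trials.
#' @param object An `fr_boot` object.
#' @export
autoplot.fr_boot <- function(object, ...) {
  ggplot2::ggplot(object$band, ggplot2::aes(x = .data$n_initial)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue") +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$point),
      colour = "grey30", linetype = "dashed"
    ) +
    ggplot2::geom_point(
      data = object$fit$trials,
      ggplot2::aes(x = .data$n_initial, y = .data$n_eaten), alpha = 0.5
    ) +
    ggplot2::labs(
      x = "Initial prey density", y = "Prey eaten",
      title = sprintf(
        "Functional response with %g%% bootstrap band (n = %d)",
        100 * object$level, object$n_boot
      )
    ) +
    ggplot2::theme_minimal()
}

#' Do two bootstrap confidence bands overlap?
#'
#' Per-density reading of whether the 95% envelopes of two groups
#' intersect — the visual criterion used to judge whether functional
#' responses differ along the density axis.
#'
#' @param band_1,band_2 `fr_boot` objects sharing the same density grid.
#' @return A tibble with one row per grid density: `n_initial`, the two
#'   intervals, and `overlaps` (logical). The attribute
#'   `frac_nonoverlap` gives the fraction of grid points where the
#'   envelopes are disjoint.
#' @export
overlap_verdict <- function(band_1, band_2) {
  b1 <- if (inherits(band_1, "fr_boot")) band_1$band else band_1
  b2 <- if (inherits(band_2, "fr_boot")) band_2$band else band_2
  if (!isTRUE(all.equal(b1$n_initial, b2$n_initial))) {
    rlang::abort("Bands must share the same density grid.",
      class = "funcresp_error_data"
    )
  }
  out <- tibble::tibble(
    n_initial = b1$n_initial,
    lower_1 = b1$lower, upper_1 = b1$upper,
    lower_2 = b2$lower, upper_2 = b2$upper,
    overlaps = b1$lower <= b2$upper & b2$lower <= b1$upper
  )
  attr(out, "frac_nonoverlap") <- mean(!out$overlaps)
  out
}
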