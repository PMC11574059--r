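#' Prey size classes
#'
#' Reference table of the two chironomid size classes offered in the feeding
#' trials: small larvae (4–6 mm, mean mass 0.13 mg, SD 0.03) and large
#' larvae (10–12 mm, mean mass 0.93 mg, SD 0.2). Mean masses are used as
#' constants for count-to-biomass conversion; the SDs are carried for the
#' simulator only.
#'
#' @return A tibble with columns `label`, `length_min_mm`, `length_max_mm`,
#'   `mean_mass_mg`, `sd_mass_mg`.
#' @export
prey_size_classes <- function() {
  tibble::tibble(
    label = c("small", "large"),
    length_min_mm = c(4, 10),
    length_max_mm = c(6, 12),
    mean_mass_mg = c(0.13, 0.93),
    sd_mass_mg = c(0.03, 0.2)
  )
}

#' Convert prey counts to biomass
#'
#' Multiplies counts by the class mean individual mass and returns
#' milligrams. Biomass is linear and additive in the counts.
#'
#' @param counts Non-negative numeric vector of prey consumed (or offered).
#' @param class Character vector of size-class labels, recycled against
#'   `counts`; must match `classes$label`.
#' @param classes Size-class table, by default [prey_size_classes()].
#' @return Biomass in mg, same length as `counts`.
#' @examples
#' biomass(100, "small") # 13 mg
#' biomass(10, "large") # 9.3 mg
#' @export
biomass <- function(counts, class, classes = prey_size_classes()) {
  if (any(!is.finite(counts)) || any(counts < 0)) {
    rlang::abort("`counts` must be finite and >= 0.", class = "funcresp_error_params")
  }
  i <- match(class, classes$label)
  if (anyNA(i)) {
    rlang::abort(
      sprintf(
        "Unknown size class label(s): %s.",
        paste(unique(class[is.na(i)]), collapse = ", ")
      ),
      class = "funcresp_error_params"
    )
  }
  unname(counts * classes$mean_mass_mg[rep_len(i, length(counts))])
}

#' Drop densities where a prey size class was completely depleted
#'
#' Mean small-vs-large consumption can only be compared where neither class
#' hit its ceiling: a fully depleted class censors the count. Within each
#' experimental group, a total density is excluded if *any* replicate fully
#' consumed *either* size class at that density (strict rule, avoiding
#' ceiling-censored comparisons).
#'
#' @param trials Mixed-prey trial data frame with columns
#'   `n_initial_small`, `n_eaten_small`, `n_initial_large`,
#'   `n_eaten_large`, plus any group label columns (`sex`,
#'   `temperature_C`, `pregnancy`). Grouping for the rule is by the label
#'   columns present (excluding replicate) and total density.
#' @return The retained trials (tibble), with a `density` column
#'   (total prey offered) added if absent.
#' @export
nondepleted_filter <- function(trials) {
  miss <- setdiff(fr_class_cols, names(trials))
  if (length(miss) > 0L) {
    rlang::abort(
      sprintf(
        "Mixed-prey trials need per-class columns: missing %s.",
        paste(miss, collapse = ", ")
      ),
      class = "funcresp_error_data"
    )
  }
  trials <- tibble::as_tibble(trials)
  if (!"density" %in% names(trials)) {
    trials$density <- trials$n_initial_small + trials$n_initial_large
  }
  grp <- c(setdiff(present_labels(trials), "prey_size"), "density")
  out <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::filter(
      !any(.data$n_eaten_small >= .data$n_initial_small |
        .data$n_eaten_large >= .data$n_initial_large)
    ) |>
    dplyr::ungroup()
  if (nrow(out) == 0L) {
    rlang::abort(
      sprintf(
        "No densities survive the depletion filter for group %s.",
        group_tag(trials)
      ),
      class = "funcresp_error_data"
    )
  }
  out
}

#' Compare mean consumption of small vs large prey per temperature
#'
#' For each temperature, a t-test compares the numbers of small and large
#' prey eaten in mixed-prey trials (and, on a second set of rows, their
#' biomasses). Welch's unequal-variance test is the default; set
#' `var_equal = TRUE` for the pooled-variance test or `paired = TRUE` if
#' small and large counts from the same arena should be treated as a pair.
#' Significance flags follow the two-star convention `*` p < 0.05, `**`
#' p < 0.001.
#'
#' @param trials Mixed-prey trials, normally the output of
#'   [nondepleted_filter()].
#' @param by Name of the column defining the strata (default
#'   `"temperature_C"`).
#' @param paired,var_equal Passed to [stats::t.test()].
#' @param classes Size-class table for the biomass conversion.
#' @return A tibble with one row per stratum and measure (`count`,
#'   `biomass_mg`): group means with standard errors, `statistic` (t),
#'   `df`, `p.value`, and `signif`.
#' @export
small_vs_large_test <- function(trials, by = "temperature_C", paired = FALSE,
                                var_equal = FALSE,
                                classes = prey_size_classes()) {
  miss <- setdiff(c(fr_class_cols, by), names(trials))
  if (length(miss) > 0L) {
    rlang::abort(sprintf("Missing column(s): %s.", paste(miss, collapse = ", ")),
      class = "funcresp_error_data"
    )
  }
  one_test <- function(s, l, measure, stratum) {
    if (length(s) < 2L) {
      rlang::abort(
        sprintf("Need >= 2 retained trials in stratum %s.", stratum),
        class = "funcresp_error_data"
      )
    }
    if (stats::var(s) == 0 && stats::var(l) == 0 && !paired) {
      if (isTRUE(all.equal(mean(s), mean(l)))) {
        # identical constant samples: no difference, by convention t = 0, p = 1
        return(tibble::tibble(
          measure = measure, n = length(s),
          mean_small = mean(s), se_small = 0,
          mean_large = mean(l), se_large = 0,
          statistic = 0, df = NA_real_, p.value = 1, signif = ""
        ))
      }
      rlang::abort(
        sprintf("Zero variance in both size classes in stratum %s.", stratum),
        class = "funcresp_error_data"
      )
    }
    tt <- stats::t.test(s, l, paired = paired, var.equal = var_equal)
    tibble::tibble(
      measure = measure, n = length(s),
      mean_small = mean(s), se_small = stats::sd(s) / sqrt(length(s)),
      mean_large = mean(l), se_large = stats::sd(l) / sqrt(length(l)),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p.value = tt$p.value,
      signif = if (tt$p.value < 0.001) "**" else if (tt$p.value < 0.05) "*" else ""
    )
  }
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      stratum <- paste(by, "=", paste(unlist(key), collapse = "/"))
      dplyr::bind_rows(
        one_test(d$n_eaten_small, d$n_eaten_large, "count", stratum),
        one_test(
          biomass(d$n_eaten_small, "small", classes),
          biomass(d$n_eaten_large, "large", classes),
          "biomass_mg", stratum
        )
      )
    }) |>
    dplyr::ungroup()
}

#' One-way ANOVA across temperatures with Tukey letters
#'
#' Compares prey consumption between temperature groups with a one-way
#' ANOVA followed by Tukey's HSD pairwise comparisons, summarised as a
#' compact letter display (groups sharing no letter differ at `alpha`). By
#' figure convention, small-prey comparisons use Latin letters and
#' large-prey comparisons Greek letters.
#'
#' @param data Data frame with the response and grouping columns.
#' @param response Name of the numeric response column (string).
#' @param group Name of the grouping column (default `"temperature_C"`);
#'   needs >= 2 groups with >= 2 observations each.
#' @param alpha Significance level for the letters (default 0.05).
#' @param alphabet `"latin"` or `"greek"` letters for the display.
#' @return An object of class `fr_anova`: list with `f_statistic`, `df`,
#'   `p_value`, `pairwise` (tibble of Tukey-adjusted pairwise p-values),
#'   `letters` (tibble group/letters), and the underlying `aov` fit.
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 11, 12, 13, 21, 22, 23), g = rep(1:3, each = 3))
#' temperature_anova(d, "y", "g")
#' @export
temperature_anova <- function(data, response, group = "temperature_C",
                              alpha = 0.05, alphabet = c("latin", "greek")) {
  alphabet <- match.arg(alphabet)
  miss <- setdiff(c(response, group), names(data))
  if (length(miss) > 0L) {
    rlang::abort(sprintf("Missing column(s): %s.", paste(miss, collapse = ", ")),
      class = "funcresp_error_data"
    )
  }
  g <- factor(data[[group]])
  y <- data[[response]]
  if (nlevels(g) < 2L) {
    rlang::abort("ANOVA needs at least 2 groups.", class = "funcresp_error_data")
  }
  if (any(table(g) < 2L)) {
    rlang::abort("Each group needs at least 2 observations.",
      class = "funcresp_error_data"
    )
  }
  d <- data.frame(y = y, g = g)
  fit <- stats::aov(y ~ g, data = d)
  sm <- summary(fit)[[1]]
  f <- sm[["F value"]][1]
  p <- sm[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$g
  lev <- levels(g)
  pmat <- matrix(1, nlevels(g), nlevels(g), dimnames = list(lev, lev))
  pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pair_names)) {
    pr <- pair_names[[i]]
    pmat[pr[1], pr[2]] <- pmat[pr[2], pr[1]] <- tk[i, "p adj"]
  }
  if (!is.finite(f)) pmat[] <- 1 # degenerate: zero within-group variance everywhere
  ab <- if (alphabet == "greek") greek_letters() else letters
  letts <- letters_from_pmatrix(pmat, alpha = alpha, alphabet = ab)
  structure(
    list(
      f_statistic = f,
      df = unname(sm[["Df"]][1:2]),
      p_value = p,
      pairwise = tibble::tibble(
        group_1 = vapply(pair_names, `[`, "", 1),
        group_2 = vapply(pair_names, `[`, "", 2),
        diff = unname(tk[, "diff"]),
        p_adj = unname(tk[, "p adj"])
      ),
      letters = tibble::tibble(group = lev, letters = unname(letts)),
      aov = fit
    ),
    class = "fr_anova"
  )
}

#' @export
print.fr_anova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
    x$df[1], x$df[2], x$f_statistic, x$p_value
  ))
  cat("Tukey letters: ")
  cat(paste0(x$letters$group, ":", x$letters$letters, collapse = "  "), "\n")
  invisible(x)
}

#' @describeIn temperature_anova Pairwise comparison tibble with the group
#'   letters joined on.
#' @param x An `fr_anova` object.
#' @param ... Unused.
#' @export
tidy.fr_anova <- function(x, ...) x$pairwise

#' @describeIn temperature_anova One-row tibble with F, degrees of freedom
#'   and p-value.
#' @export
glance.fr_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$f_statistic, df = x$df[1], df.residual = x$df[2],
    p.value = x$p_value
  )
}

#' Prey-size selection report
#'
#' Full selection analysis for mixed-prey trials: depletion filtering,
#' per-temperature small-vs-large t-tests (counts and biomass), one-way
#' ANOVAs with Tukey letters across temperatures for each size class, and
#' biomass totals.
#'
#' @inheritParams small_vs_large_test
#' @param alpha Significance level for the letters.
#' @return A list of class `fr_selection` with `filtered` (retained
#'   trials), `size_tests` (t-test tibble), `anova_small`, `anova_large`
#'   (`fr_anova` objects, Latin and Greek letters respectively), and
#'   `biomass_totals` (tibble of consumed biomass per stratum and class).
#' @export
selection_report <- function(trials, by = "temperature_C", paired = FALSE,
                             var_equal = FALSE, alpha = 0.05,
                             classes = prey_size_classes()) {
  kept <- nondepleted_filter(trials)
  size_tests <- small_vs_large_test(kept,
    by = by, paired = paired,
    var_equal = var_equal, classes = classes
  )
  anova_small <- temperature_anova(kept, "n_eaten_small", by,
    alpha = alpha, alphabet = "latin"
  )
  anova_large <- temperature_anova(kept, "n_eaten_large", by,
    alpha = alpha, alphabet = "greek"
  )
  totals <- kept |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      count_small = sum(.data$n_eaten_small),
      count_large = sum(.data$n_eaten_large),
      biomass_small_mg = sum(biomass(.data$n_eaten_small, "small", classes)),
      biomass_large_mg = sum(biomass(.data$n_eaten_large, "large", classes)),
      .groups = "drop"
    )
  structure(
    list(
      filtered = kept, size_tests = size_tests,
      anova_small = anova_small, anova_large = anova_large,
      biomass_totals = totals
    ),
    class = "fr_selection"
  )
}

#' @export
print.fr_selection <- function(x, ...) {
  cat(sprintf(
    "Prey-size selection report (%d trials retained after depletion filter)\n",
    nrow(x$filtered)
  ))
  cat("\nSmall vs large consumption (t-tests):\n")
  print(x$size_tests)
  cat("\nAcross temperatures, small prey: ")
  print(x$anova_small)
  cat("Across temperatures, large prey: ")
  print(x$anova_large)
  invisible(x)
}
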