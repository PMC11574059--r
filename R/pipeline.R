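#' Run the full comparative functional-response pipeline
#'
#' Orchestrates the three-step procedure over a factorial trial table:
#' per-group functional-response type determination (logistic regression),
#' Rogers Type-II maximum-likelihood fits with maximum feeding rates,
#' pairwise Juliano comparisons (sex within prey size on pooled
#' temperatures; temperatures within sex and prey size; pregnancy stages),
#' optional bootstrap confidence bands, and — where mixed-prey rows are
#' present — the prey-size-selection report. With `trials = NULL` a
#' synthetic dataset with the study's factorial shape is generated first,
#' so the pipeline runs end to end with no external data.
#'
#' @param trials Trial table as produced by [simulate_study_design()] or
#'   [read_trials()], or `NULL` to simulate one.
#' @param group_map True parameters for the simulation when `trials` is
#'   `NULL` (see [default_group_map()]).
#' @param seed Integer seed controlling simulation and bootstrap
#'   resampling; reruns with the same seed are identical.
#' @param n_boot Bootstrap replicates per group for the confidence bands;
#'   `0` skips the bands.
#' @param alpha Significance level used throughout.
#' @param adjust Multiplicity adjustment for pairwise letter displays
#'   (default `"holm"`).
#'
#' @return An object of class `fr_report`: a list with `trials`, `fits`
#'   (tibble: one row per group with type-test and fit summaries),
#'   `comparisons` (list of `sex`, `temperature`, `pregnancy` pairwise
#'   results), `bands` (named list of [bootstrap_fr()] results, if
#'   requested), `selection` (prey-size [selection_report()] per sex, if
#'   mixed rows exist), and `meta` (seed, alpha, n_boot, package version).
#' @examples
#' \donttest{
#' rep <- run_fr_pipeline(seed = 7, n_boot = 0)
#' rep$fits
#' }
#' @export
run_fr_pipeline <- function(trials = NULL, group_map = default_group_map(),
                            seed = 1, n_boot = 2000, alpha = 0.05,
                            adjust = "holm") {
  if (is.null(trials)) {
    trials <- simulate_study_design(group_map, seed = seed)
  }
  check_trials(trials)
  if (!"prey_size" %in% names(trials)) trials$prey_size <- "small"
  if (!"pregnancy" %in% names(trials)) trials$pregnancy <- "none"
  single <- trials[trials$prey_size != "mixed", , drop = FALSE]
  mixed <- trials[trials$prey_size == "mixed", , drop = FALSE]

  grp_cols <- intersect(
    c("sex", "temperature_C", "prey_size", "pregnancy"),
    names(single)
  )
  groups <- single |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::group_split()

  fits <- purrr::map_dfr(groups, function(g) {
    key <- g[1, grp_cols]
    tt <- classify_fr_type(g, alpha = alpha)
    ft <- fit_rogers(g)
    dplyr::bind_cols(
      tibble::as_tibble(key),
      tibble::tibble(
        first_order_coef = tt$first_order_coef,
        p_type = tt$p_value,
        inferred_type = tt$inferred_type
      ),
      summarize_fit(ft),
      tibble::tibble(n_trials = ft$n_trials)
    )
  })

  comparisons <- list()
  # Sex effect on pooled temperatures, per prey size
  if (all(c("sex", "prey_size") %in% grp_cols) &&
    length(unique(single$sex)) == 2L) {
    base <- single[single$pregnancy == "none", , drop = FALSE]
    comparisons$sex <- purrr::map_dfr(
      unique(base$prey_size),
      function(sz) {
        d <- base[base$prey_size == sz, , drop = FALSE]
        cmp <- juliano_compare(
          d[d$sex == "female", , drop = FALSE],
          d[d$sex == "male", , drop = FALSE],
          labels = c("female", "male")
        )
        dplyr::mutate(tidy(cmp), prey_size = sz, .before = 1)
      }
    )
  }
  # Temperature effect, per sex and prey size
  if (all(c("sex", "temperature_C", "prey_size") %in% grp_cols) &&
    length(unique(single$temperature_C)) >= 2L) {
    base <- single[single$pregnancy == "none", , drop = FALSE]
    cells <- unique(base[, c("sex", "prey_size")])
    comparisons$temperature <- purrr::map(
      seq_len(nrow(cells)),
      function(i) {
        d <- base[
          base$sex == cells$sex[i] & base$prey_size == cells$prey_size[i], ,
          drop = FALSE
        ]
        pw <- juliano_pairwise(d, "temperature_C", alpha = alpha, adjust = adjust)
        pw$sex <- cells$sex[i]
        pw$prey_size <- cells$prey_size[i]
        pw
      }
    )
    names(comparisons$temperature) <-
      paste(cells$sex, cells$prey_size, sep = "_")
  }
  # Pregnancy effect (females, small prey, one temperature)
  if ("pregnancy" %in% grp_cols && length(unique(single$pregnancy)) >= 2L) {
    d <- single[
      single$sex == "female" & single$prey_size == "small" &
        single$temperature_C == 25, ,
      drop = FALSE
    ]
    if (length(unique(d$pregnancy)) >= 2L) {
      comparisons$pregnancy <-
        juliano_pairwise(d, "pregnancy", alpha = alpha, adjust = adjust)
    }
  }

  bands <- NULL
  if (n_boot > 0) {
    bands <- purrr::imap(
      stats::setNames(groups, purrr::map_chr(groups, function(g) {
        paste(unlist(g[1, grp_cols]), collapse = "_")
      })),
      function(g, nm) {
        bootstrap_fr(g,
          n_boot = n_boot,
          seed = seed + utf8ToInt(substr(nm, 1, 1)) + nchar(nm)
        )
      }
    )
  }

  selection <- NULL
  if (nrow(mixed) > 0L && "sex" %in% names(mixed)) {
    selection <- purrr::map(
      stats::setNames(unique(mixed$sex), unique(mixed$sex)),
      function(sx) {
        selection_report(mixed[mixed$sex == sx, , drop = FALSE], alpha = alpha)
      }
    )
  }

  structure(
    list(
      trials = trials, fits = fits, comparisons = comparisons,
      bands = bands, selection = selection,
      meta = list(
        seed = seed, alpha = alpha, n_boot = n_boot, adjust = adjust,
        package_version = as.character(utils::packageVersion("funcresp")),
        r_version = R.version.string,
        timestamp = NA # reruns must be bit-identical, so no clock is read
      )
    ),
    class = "fr_report"
  )
}

#' @export
print.fr_report <- function(x, ...) {
  cat("Comparative functional-response report\n")
  cat(sprintf(
    "  %d trials, %d fitted groups, alpha = %g, n_boot = %d, seed = %s\n\n",
    nrow(x$trials), nrow(x$fits), x$meta$alpha, x$meta$n_boot,
    as.character(x$meta$seed)
  ))
  cat("Per-group type tests and Rogers fits:\n")
  print(x$fits, n = Inf)
  if (!is.null(x$comparisons$sex)) {
    cat("\nFemale vs male (pooled temperatures), difference terms:\n")
    print(x$comparisons$sex)
  }
  if (!is.null(x$comparisons$pregnancy)) {
    cat("\nPregnancy-stage letters (a / h):\n")
    print(x$comparisons$pregnancy$letters)
  }
  if (!is.null(x$selection)) {
    cat(sprintf(
      "\nPrey-size selection reports for: %s (see $selection)\n",
      paste(names(x$selection), collapse = ", ")
    ))
  }
  invisible(x)
}
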