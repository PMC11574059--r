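# Shared helpers for trial tables.
#
# A trial table is a tidy data frame with one row per feeding trial:
#   n_initial (integer > 0), n_eaten (integer, 0..n_initial),
#   duration_h (> 0), plus optional group labels among
#   sex, temperature_C, prey_size, pregnancy, replicate.
# Mixed-prey tables additionally carry n_initial_small / n_eaten_small /
# n_initial_large / n_eaten_large, with n_initial / n_eaten their totals.

fr_label_cols <- c("sex", "temperature_C", "prey_size", "pregnancy")
fr_class_cols <- c(
  "n_initial_small", "n_eaten_small",
  "n_initial_large", "n_eaten_large"
)

# Columns (among the label set) present in `trials`.
present_labels <- function(trials) {
  intersect(fr_label_cols, names(trials))
}

# One-line description of the group a trial subset belongs to, for messages.
group_tag <- function(trials) {
  labs <- present_labels(trials)
  if (length(labs) == 0L) {
    return("(unlabelled group)")
  }
  vals <- vapply(
    labs,
    function(l) paste(unique(as.character(trials[[l]])), collapse = "/"),
    character(1)
  )
  paste(paste0(labs, "=", vals), collapse = ", ")
}

check_trials <- function(trials, arg = "trials") {
  if (!is.data.frame(trials)) {
    rlang::abort(sprintf("`%s` must be a data frame of trials.", arg),
      class = "funcresp_error_data"
    )
  }
  need <- c("n_initial", "n_eaten")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0L) {
    rlang::abort(
      sprintf("`%s` is missing column(s): %s.", arg, paste(miss, collapse = ", ")),
      class = "funcresp_error_data"
    )
  }
  if (nrow(trials) == 0L) {
    rlang::abort(sprintf("`%s` has no rows.", arg), class = "funcresp_error_data")
  }
  bad <- !is.finite(trials$n_initial) | trials$n_initial <= 0 |
    !is.finite(trials$n_eaten) | trials$n_eaten < 0 |
    trials$n_eaten > trials$n_initial
  if (any(bad)) {
    rlang::abort(
      sprintf(
        "`%s` has %d row(s) violating 0 <= n_eaten <= n_initial (rows %s).",
        arg, sum(bad), paste(utils::head(which(bad), 10), collapse = ", ")
      ),
      class = "funcresp_error_data"
    )
  }
  if ("duration_h" %in% names(trials) &&
    any(!is.finite(trials$duration_h) | trials$duration_h <= 0)) {
    rlang::abort(sprintf("`%s` has non-positive duration_h.", arg),
      class = "funcresp_error_data"
    )
  }
  invisible(trials)
}

# Duration column with a default of 1 hour when absent.
trial_durations <- function(trials) {
  if ("duration_h" %in% names(trials)) trials$duration_h else rep(1, nrow(trials))
}
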