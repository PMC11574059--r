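#' Read a trial table from CSV
#'
#' Reads and validates a predation-trial CSV in the package's column
#' dialect: `n_initial`, `n_eaten`, `duration_h` plus any of the label
#' columns `sex`, `temperature_C`, `prey_size`, `pregnancy`, `replicate`,
#' `experiment`, and (for mixed-prey data) `n_initial_small` /
#' `n_eaten_small` / `n_initial_large` / `n_eaten_large`. Rows violating
#' the invariants (integer counts, `0 <= eaten <= offered` per class,
#' positive duration) are rejected with their line numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of trials.
#' @seealso [write_trials()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path), class = "funcresp_error_parse")
  }
  tr <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      rlang::abort(sprintf("Could not parse %s: %s", path, conditionMessage(e)),
        class = "funcresp_error_parse"
      )
    }
  )
  need <- c("n_initial", "n_eaten")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0L) {
    rlang::abort(
      sprintf(
        "Malformed header in %s: missing column(s) %s.",
        path, paste(miss, collapse = ", ")
      ),
      class = "funcresp_error_parse"
    )
  }
  offenses <- character(0)
  note <- function(rows, what) {
    if (length(rows) > 0L) {
      # +1 for the header line, so numbers refer to file lines
      c(offenses, sprintf("line %d: %s", rows + 1L, what))
    } else {
      offenses
    }
  }
  count_cols <- intersect(c("n_initial", "n_eaten", fr_class_cols), names(tr))
  for (cc in count_cols) {
    v <- tr[[cc]]
    bad <- which(!is.na(v) & (!is.numeric(v) | v < 0 | v != round(v)))
    offenses <- note(bad, sprintf("%s is not a non-negative integer", cc))
  }
  offenses <- note(
    which(tr$n_eaten > tr$n_initial),
    "n_eaten exceeds n_initial"
  )
  if (all(c("n_initial_small", "n_eaten_small") %in% names(tr))) {
    offenses <- note(
      which(tr$n_eaten_small > tr$n_initial_small),
      "n_eaten_small exceeds n_initial_small"
    )
  }
  if (all(c("n_initial_large", "n_eaten_large") %in% names(tr))) {
    offenses <- note(
      which(tr$n_eaten_large > tr$n_initial_large),
      "n_eaten_large exceeds n_initial_large"
    )
  }
  if ("duration_h" %in% names(tr)) {
    offenses <- note(
      which(!is.finite(tr$duration_h) | tr$duration_h <= 0),
      "duration_h is not positive"
    )
  }
  if (length(offenses) > 0L) {
    shown <- utils::head(offenses, 10)
    rlang::abort(
      paste(
        c(
          sprintf(
            "%d invalid row(s) in %s (showing up to 10):", length(offenses), path
          ),
          shown
        ),
        collapse = "\n"
      ),
      class = "funcresp_error_parse"
    )
  }
  tr
}

#' Write a trial table to CSV
#'
#' @param trials Trial data frame.
#' @param path Output path.
#' @return `trials`, invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  readr::write_csv(trials, path, progress = FALSE)
  invisible(trials)
}
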