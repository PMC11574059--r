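# Synthetic predation-trial generator.
#
# Emulates a factorial guppy feeding-trial design: doubling prey-density
# ladders, a fixed number of replicate arenas per density, 1-hour trials,
# Type-II consumption with prey depletion. Two noise processes are
# available: "binomial" draws prey eaten as Binomial(N0, Ne_pred/N0) around
# the Rogers expectation — it matches the fitting likelihood exactly, so it
# is the clean generator for recovery tests — while "mechanistic" simulates
# the search-handle renewal sequence itself (exponential waiting time to
# the next capture at rate a * N_remaining, then a deterministic handling
# time h, until the time budget is spent), which is independent of the
# fitted model and so probes robustness.

#' Simulate feeding trials for one experimental group
#'
#' @inheritParams fr_params
#' @param densities Integer prey-density ladder (default the doubling ladder
#'   2–64 used per arena).
#' @param replicates Trials per density (default 3, one predator per arena).
#' @param process `"binomial"` (noise around the depletion expectation,
#'   matching the fitting likelihood) or `"mechanistic"` (explicit
#'   search–handle renewal simulation).
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @return A tibble with columns `replicate`, `n_initial`, `n_eaten`,
#'   `duration_h`; `0 <= n_eaten <= n_initial`, integer.
#' @examples
#' simulate_trials(a = 1.5, h = 0.08, seed = 1)
#' @export
simulate_trials <- function(a, h, t = 1, densities = c(2, 4, 8, 16, 32, 64),
                            replicates = 3,
                            process = c("binomial", "mechanistic"),
                            seed = NULL) {
  process <- match.arg(process)
  check_fr_params(a, h, t)
  if (length(densities) == 0L || any(densities != as.integer(densities)) ||
    any(densities <= 0) || is.unsorted(densities, strictly = TRUE)) {
    rlang::abort("`densities` must be a strictly increasing vector of positive integers.",
      class = "funcresp_error_params"
    )
  }
  if (!is.numeric(replicates) || replicates < 1) {
    rlang::abort("`replicates` must be >= 1.", class = "funcresp_error_params")
  }
  des <- tidyr::expand_grid(
    replicate = seq_len(replicates),
    n_initial = as.integer(densities)
  )
  ne <- with_local_seed(seed, {
    if (process == "binomial") {
      p <- rogers_expected(des$n_initial, a, h, t) / des$n_initial
      stats::rbinom(nrow(des), des$n_initial, p)
    } else {
      vapply(des$n_initial, sim_mechanistic_one, integer(1), a = a, h = h, t = t)
    }
  })
  tibble::tibble(
    replicate = des$replicate,
    n_initial = des$n_initial,
    n_eaten = as.integer(ne),
    duration_h = t
  )
}

# One mechanistic trial: captures occur after Exp(a * N_remaining) search
# waits; each capture is followed by a deterministic handling block h during
# which no search happens. A capture counts if the wait ends within the
# time budget t.
sim_mechanistic_one <- function(n0, a, h, t) {
  if (a <= 0 || n0 <= 0) {
    return(0L)
  }
  time <- 0
  n <- n0
  eaten <- 0L
  repeat {
    if (n <= 0) break
    time <- time + stats::rexp(1, a * n)
    if (time > t) break
    eaten <- eaten + 1L
    n <- n - 1
    time <- time + h
    if (time >= t) break
  }
  eaten
}

# One mechanistic mixed-prey trial: two capture streams (small, large) with
# class-specific (a, h) compete for the same time budget; the earlier
# exponential wait wins each round and its handling time blocks both
# streams.
sim_mixed_one <- function(ns, nl, a_s, h_s, a_l, h_l, t) {
  time <- 0
  es <- 0L
  el <- 0L
  repeat {
    ws <- if (ns > 0 && a_s > 0) stats::rexp(1, a_s * ns) else Inf
    wl <- if (nl > 0 && a_l > 0) stats::rexp(1, a_l * nl) else Inf
    if (!is.finite(min(ws, wl))) break
    time <- time + min(ws, wl)
    if (time > t) break
    if (ws <= wl) {
      es <- es + 1L
      ns <- ns - 1
      time <- time + h_s
    } else {
      el <- el + 1L
      nl <- nl - 1
      time <- time + h_l
    }
    if (time >= t) break
  }
  c(small = es, large = el)
}

#' Default group map of true functional-response parameters
#'
#' The per-condition attack rates and handling times used by
#' [simulate_study_design()]. The values encode the qualitative structure
#' the analysis is meant to detect: females have much lower handling times
#' (about a tenfold higher maximum feeding rate) than males; handling time
#' decreases with temperature on small prey in both sexes (maximum feeding
#' rate rises with warming); large prey take longer to handle than small,
#' with the fastest large-prey handling at the intermediate temperature;
#' and pregnancy lowers handling time further (stage 2 below stage 1 below
#' non-pregnant). Female handling times on small prey at 25 degrees C are
#' anchored so that 1/h reproduces plateau consumptions of roughly 89
#' (non-pregnant), 97 (stage 1) and 119 (stage 2) prey per hour.
#'
#' @return A tibble with columns `sex`, `temperature_C`, `prey_size`,
#'   `pregnancy`, `a`, `h`.
#' @export
default_group_map <- function() {
  single <- tibble::tribble(
    ~sex, ~temperature_C, ~prey_size, ~a, ~h,
    "female", 22, "small", 2.0, 0.0140,
    "female", 25, "small", 1.2, 0.0113,
    "female", 28, "small", 1.3, 0.0090,
    "female", 22, "large", 1.0, 0.0600,
    "female", 25, "large", 1.1, 0.0450,
    "female", 28, "large", 1.2, 0.0550,
    "male", 22, "small", 0.8, 0.1600,
    "male", 25, "small", 0.8, 0.1100,
    "male", 28, "small", 0.9, 0.0800,
    "male", 22, "large", 0.6, 0.5500,
    "male", 25, "large", 0.7, 0.4000,
    "male", 28, "large", 0.7, 0.4800
  )
  single$pregnancy <- "none"
  pregnant <- tibble::tribble(
    ~sex, ~temperature_C, ~prey_size, ~pregnancy, ~a, ~h,
    "female", 25, "small", "stage1", 1.2, 0.0103,
    "female", 25, "small", "stage2", 1.2, 0.0084
  )
  dplyr::bind_rows(single, pregnant)[
    ,
    c("sex", "temperature_C", "prey_size", "pregnancy", "a", "h")
  ]
}

#' Simulate the full factorial feeding-trial design
#'
#' Generates a tidy trial table with the structure of the two-experiment
#' study the analysis pipeline expects. Experiment 1 crosses sex (female,
#' male) with temperature (22, 25, 28 degrees C) and prey treatment (single
#' small, single large, and mixed sizes in a 1:1 ratio) over the doubling
#' density ladder 2–64, with the ladder extended to 128 and 256 for females
#' on small prey (whose response does not plateau by 64). Experiment 2
#' holds temperature at 25 degrees C and crosses female pregnancy stages 1
#' and 2 over the extended ladder on small prey. Single-size cells draw
#' prey eaten through [simulate_trials()]; mixed cells always use the
#' mechanistic competing-streams process (two class-specific capture
#' streams sharing one time budget), since the binomial shortcut has no
#' mixed-prey analogue.
#'
#' @param group_map Tibble of true `(a, h)` per condition, as
#'   [default_group_map()]; every simulated cell must be present.
#' @param replicates Trials per density per cell (default 3).
#' @param densities Base density ladder (default 2–64 doubling).
#' @param extended_densities Ladder for females on small prey and the
#'   pregnancy experiment (default extends to 256).
#' @param process Noise process for single-size cells (see
#'   [simulate_trials()]).
#' @param include_mixed Include the mixed-prey treatment (default `TRUE`).
#' @param t Trial duration in hours.
#' @param seed Optional integer seed; two calls with the same seed give
#'   identical tables.
#' @return A tibble with columns `experiment`, `sex`, `temperature_C`,
#'   `prey_size`, `pregnancy`, `replicate`, `n_initial`, `n_eaten`,
#'   `duration_h`, and (when mixed cells are included) per-class columns
#'   `n_initial_small`, `n_eaten_small`, `n_initial_large`,
#'   `n_eaten_large` (NA on single-size rows).
#' @examples
#' head(simulate_study_design(seed = 1))
#' @export
simulate_study_design <- function(group_map = default_group_map(),
                                  replicates = 3,
                                  densities = c(2, 4, 8, 16, 32, 64),
                                  extended_densities = c(2, 4, 8, 16, 32, 64, 128, 256),
                                  process = c("binomial", "mechanistic"),
                                  include_mixed = TRUE,
                                  t = 1, seed = NULL) {
  process <- match.arg(process)
  lookup <- function(sex, temp, size, pregnancy = "none") {
    row <- group_map[
      group_map$sex == sex & group_map$temperature_C == temp &
        group_map$prey_size == size & group_map$pregnancy == pregnancy,
    ]
    if (nrow(row) != 1L) {
      rlang::abort(
        sprintf(
          "Group map must supply exactly one (a, h) for cell sex=%s, temperature_C=%s, prey_size=%s, pregnancy=%s.",
          sex, temp, size, pregnancy
        ),
        class = "funcresp_error_params"
      )
    }
    row
  }
  sexes <- c("female", "male")
  temps <- c(22, 25, 28)
  with_local_seed(seed, {
    out <- list()
    # Experiment 1, single-size treatments
    for (sex in sexes) {
      for (temp in temps) {
        for (size in c("small", "large")) {
          pars <- lookup(sex, temp, size)
          dl <- if (sex == "female" && size == "small") extended_densities else densities
          tr <- simulate_trials(pars$a, pars$h,
            t = t, densities = dl,
            replicates = replicates, process = process
          )
          tr$experiment <- 1L
          tr$sex <- sex
          tr$temperature_C <- temp
          tr$prey_size <- size
          tr$pregnancy <- "none"
          out[[length(out) + 1L]] <- tr
        }
      }
    }
    # Experiment 1, mixed-prey treatment (1:1 split of the total density)
    if (include_mixed) {
      for (sex in sexes) {
        for (temp in temps) {
          ps <- lookup(sex, temp, "small")
          pl <- lookup(sex, temp, "large")
          des <- tidyr::expand_grid(
            replicate = seq_len(replicates),
            density = as.integer(densities)
          )
          eat <- t(vapply(
            des$density,
            function(d) {
              sim_mixed_one(d %/% 2, d - d %/% 2, ps$a, ps$h, pl$a, pl$h, t)
            },
            integer(2)
          ))
          tr <- tibble::tibble(
            replicate = des$replicate,
            n_initial = des$density,
            n_eaten = as.integer(eat[, 1] + eat[, 2]),
            duration_h = t,
            n_initial_small = des$density %/% 2L,
            n_eaten_small = as.integer(eat[, 1]),
            n_initial_large = des$density - des$density %/% 2L,
            n_eaten_large = as.integer(eat[, 2]),
            experiment = 1L,
            sex = sex, temperature_C = temp,
            prey_size = "mixed", pregnancy = "none"
          )
          out[[length(out) + 1L]] <- tr
        }
      }
    }
    # Experiment 2: pregnancy stages, females on small prey at 25 C
    for (stage in c("stage1", "stage2")) {
      pars <- lookup("female", 25, "small", stage)
      tr <- simulate_trials(pars$a, pars$h,
        t = t,
        densities = extended_densities,
        replicates = replicates, process = process
      )
      tr$experiment <- 2L
      tr$sex <- "female"
      tr$temperature_C <- 25
      tr$prey_size <- "small"
      tr$pregnancy <- stage
      out[[length(out) + 1L]] <- tr
    }
    dplyr::bind_rows(out) |>
      dplyr::select(
        dplyr::all_of(c(
          "experiment", "sex", "temperature_C", "prey_size", "pregnancy",
          "replicate", "n_initial", "n_eaten", "duration_h"
        )),
        dplyr::any_of(fr_class_cols)
      )
  })
}
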