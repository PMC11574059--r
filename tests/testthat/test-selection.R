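# Mixed-prey fixture: counts chosen by hand so depletion status per density
# is unambiguous.
mixed_fixture <- function() {
  tibble::tibble(
    sex = "female",
    temperature_C = rep(rep(c(22, 25, 28), each = 3), times = 3),
    replicate = rep(1:3, times = 9),
    density = rep(c(4, 16, 32), each = 9),
    n_initial_small = density / 2,
    n_initial_large = density / 2,
    # density 4 fully depleted in one replicate; 16 depletes small once at
    # 22 C; 32 never depleted
    n_eaten_small = c(
      rep(2, 9), # density 4: small always gone
      c(8, 5, 4, 6, 5, 4, 6, 5, 4), # density 16: one depletion at 22 C
      c(10, 9, 11, 12, 11, 13, 14, 13, 15) # density 32: never
    ),
    n_eaten_large = c(
      rep(1, 9),
      rep(3, 9),
      c(4, 5, 4, 6, 6, 5, 8, 7, 8)
    )
  )
}

test_that("densities with any depleted class are excluded, others kept", {
  tr <- mixed_fixture()
  kept <- nondepleted_filter(tr)
  expect_false(4 %in% kept$density) # ceiling reached in every replicate
  expect_false(all(c(22, 25, 28) %in% kept$temperature_C[kept$density == 16]))
  # 16 is dropped only where the depletion occurred (22 C group)
  expect_true(all(kept$density[kept$temperature_C == 22] == 32))
  expect_setequal(unique(kept$density[kept$temperature_C == 25]), c(16, 32))
  expect_true(all(kept$n_eaten_small < kept$n_initial_small))
  # a fully depleted table errors
  alldep <- dplyr::mutate(tr, n_eaten_small = n_initial_small)
  expect_error(nondepleted_filter(alldep), class = "funcresp_error_data")
})

test_that("small-vs-large t test matches the frozen hand oracle", {
  tr <- tibble::tibble(
    temperature_C = 25,
    n_initial_small = 40, n_initial_large = 40,
    n_eaten_small = c(30, 32, 31),
    n_eaten_large = c(5, 6, 4)
  )
  res <- small_vs_large_test(tr)
  cnt <- res[res$measure == "count", ]
  # hand value: pooled variance 1, t = 26 / sqrt(2/3), p = 5.797e-6 on 4 df
  expect_equal(cnt$statistic, 26 / sqrt(2 / 3), tolerance = 1e-8)
  expect_lt(cnt$p.value, 0.001)
  expect_identical(cnt$signif, "**")
  # identical samples: t = 0, p = 1
  same <- small_vs_large_test(tibble::tibble(
    temperature_C = 25,
    n_initial_small = 40, n_initial_large = 40,
    n_eaten_small = c(10, 12, 11), n_eaten_large = c(10, 12, 11)
  ))
  expect_equal(same$statistic[same$measure == "count"], 0, tolerance = 1e-12)
  expect_equal(same$p.value[same$measure == "count"], 1, tolerance = 1e-12)
})

test_that("Welch and pooled variants are both available and differ when they should", {
  tr <- tibble::tibble(
    temperature_C = 25,
    n_initial_small = 100, n_initial_large = 100,
    n_eaten_small = c(30, 50, 40, 45, 35),
    n_eaten_large = c(39, 40, 41, 40, 40)
  )
  welch <- small_vs_large_test(tr)
  pooled <- small_vs_large_test(tr, var_equal = TRUE)
  w <- welch[welch$measure == "count", ]
  p <- pooled[pooled$measure == "count", ]
  ref_w <- t.test(tr$n_eaten_small, tr$n_eaten_large)
  ref_p <- t.test(tr$n_eaten_small, tr$n_eaten_large, var.equal = TRUE)
  expect_equal(w$df, unname(ref_w$parameter))
  expect_equal(p$df, unname(ref_p$parameter))
  expect_false(isTRUE(all.equal(w$df, p$df)))
})

test_that("temperature ANOVA reproduces the hand-computed F and letters", {
  d <- tibble::tibble(
    y = c(1, 2, 3, 11, 12, 13, 21, 22, 23),
    temperature_C = rep(c(22, 25, 28), each = 3)
  )
  res <- temperature_anova(d, "y")
  expect_equal(res$f_statistic, 300, tolerance = 1e-8)
  expect_identical(res$letters$letters, c("a", "b", "c"))
  gl <- glance(res)
  expect_identical(gl$df, 2)
  # no between-group variance: everyone shares a letter
  flat <- tibble::tibble(y = rep(5, 9), temperature_C = rep(c(22, 25, 28), each = 3))
  res_flat <- temperature_anova(flat, "y")
  expect_true(all(res_flat$letters$letters == res_flat$letters$letters[1]))
  # greek alphabet option
  res_g <- temperature_anova(d, "y", alphabet = "greek")
  expect_identical(res_g$letters$letters, c("α", "β", "γ"))
  expect_error(
    temperature_anova(d[1:3, ], "y"),
    class = "funcresp_error_data"
  )
})

test_that("ANOVA letters are consistent with Tukey-adjusted p-values", {
  set.seed(99)
  d <- tibble::tibble(
    y = c(rnorm(8, 10), rnorm(8, 11), rnorm(8, 16)),
    temperature_C = rep(c(22, 25, 28), each = 8)
  )
  res <- temperature_anova(d, "y")
  lt <- setNames(res$letters$letters, res$letters$group)
  share <- function(x, y) length(intersect(strsplit(x, "")[[1]], strsplit(y, "")[[1]])) > 0
  for (i in seq_len(nrow(res$pairwise))) {
    expect_identical(
      share(lt[[res$pairwise$group_1[i]]], lt[[res$pairwise$group_2[i]]]),
      res$pairwise$p_adj[i] >= 0.05
    )
  }
})

test_that("biomass conversion is exact, linear and strict about labels", {
  expect_equal(biomass(100, "small"), 13)
  expect_equal(biomass(10, "large"), 9.3)
  expect_equal(biomass(0, "small"), 0)
  x <- c(3, 7)
  expect_equal(
    biomass(sum(x), "large"),
    sum(biomass(x, c("large", "large")))
  )
  expect_error(biomass(5, "medium"), class = "funcresp_error_params")
  expect_error(biomass(-1, "small"), class = "funcresp_error_params")
})

test_that("the full selection report assembles all stages", {
  tr <- mixed_fixture()
  rep <- selection_report(tr)
  expect_s3_class(rep$size_tests, "tbl_df")
  expect_s3_class(rep$anova_small, "fr_anova")
  expect_identical(
    sum(rep$biomass_totals$count_small),
    sum(rep$filtered$n_eaten_small)
  )
  expect_equal(
    rep$biomass_totals$biomass_large_mg,
    rep$biomass_totals$count_large * 0.93
  )
})
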