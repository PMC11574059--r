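make_two_groups <- function(h2 = 0.2, seed = 101, reps = 6) {
  list(
    g1 = simulate_trials(a = 1, h = 0.1, replicates = reps, seed = seed),
    g2 = simulate_trials(a = 1, h = h2, replicates = reps, seed = seed + 1)
  )
}

test_that("self-comparison gives null differences", {
  tr <- simulate_trials(a = 1.2, h = 0.08, replicates = 6, seed = 55)
  cmp <- juliano_compare(tr, tr)
  expect_lt(abs(cmp$delta_a), 1e-3)
  expect_lt(abs(cmp$delta_h), 1e-4)
})

test_that("swapping group order negates deltas and keeps p-values", {
  gg <- make_two_groups()
  c12 <- juliano_compare(gg$g1, gg$g2)
  c21 <- juliano_compare(gg$g2, gg$g1)
  expect_equal(c12$delta_a, -c21$delta_a, tolerance = 1e-4)
  expect_equal(c12$delta_h, -c21$delta_h, tolerance = 1e-4)
  expect_equal(c12$p_delta_a, c21$p_delta_a, tolerance = 1e-4)
  expect_equal(c12$p_delta_h, c21$p_delta_h, tolerance = 1e-4)
})

test_that("a genuine handling-time difference is detected with the right sign", {
  gg <- make_two_groups(h2 = 0.2, reps = 10)
  cmp <- juliano_compare(gg$g1, gg$g2)
  expect_gt(cmp$delta_h, 0) # group 2 handles slower
  expect_lt(cmp$p_delta_h, 0.05)
  td <- tidy(cmp)
  expect_identical(td$term, c("delta_a", "delta_h"))
})

test_that("the pooled fit with zero differences matches the concatenated fit", {
  gg <- make_two_groups(h2 = 0.1) # identical truth
  both <- dplyr::bind_rows(gg$g1, gg$g2)
  fit <- fit_rogers(both)
  n0 <- both$n_initial
  ne <- both$n_eaten
  tt <- both$duration_h
  j <- rep(c(0L, 1L), c(nrow(gg$g1), nrow(gg$g2)))
  nll0 <- funcresp:::juliano_nll(c(fit$a, fit$h, 0, 0), n0, ne, tt, j)
  expect_equal(-nll0, fit$log_likelihood, tolerance = 1e-8)
})

test_that("mismatched durations are rejected, disjoint designs warned about", {
  g1 <- simulate_trials(a = 1, h = 0.1, replicates = 3, seed = 1)
  g2 <- dplyr::mutate(simulate_trials(a = 1, h = 0.1, replicates = 3, seed = 2),
    duration_h = 2
  )
  expect_error(juliano_compare(g1, g2), class = "funcresp_error_data")
  g3 <- simulate_trials(
    a = 1, h = 0.1, densities = c(3, 6, 12, 24, 48),
    replicates = 4, seed = 3
  )
  expect_warning(juliano_compare(g1, g3), regexp = "overlap")
})

test_that("pairwise letters agree with the adjusted p-values", {
  tr <- dplyr::bind_rows(
    dplyr::mutate(simulate_trials(a = 1, h = 0.25, replicates = 8, seed = 71), grp = "g1"),
    dplyr::mutate(simulate_trials(a = 1, h = 0.25, replicates = 8, seed = 72), grp = "g2"),
    dplyr::mutate(simulate_trials(a = 1, h = 0.02, replicates = 8, seed = 73), grp = "g3")
  )
  pw <- juliano_pairwise(tr, "grp")
  expect_identical(nrow(pw$pairs), 3L)
  lt <- setNames(pw$letters$letters_h, pw$letters$group)
  share <- function(x, y) length(intersect(strsplit(x, "")[[1]], strsplit(y, "")[[1]])) > 0
  for (i in seq_len(nrow(pw$pairs))) {
    shared <- share(lt[pw$pairs$group_1[i]], lt[pw$pairs$group_2[i]])
    expect_identical(shared, pw$pairs$p_h_adj[i] >= 0.05,
      label = sprintf("pair %s-%s", pw$pairs$group_1[i], pw$pairs$group_2[i])
    )
  }
  # the fast handler is unambiguously separated from the slow groups
  expect_false(share(lt[["g1"]], lt[["g3"]]))
  expect_false(share(lt[["g2"]], lt[["g3"]]))
})

test_that("compact letter display follows the significance matrix", {
  pm <- matrix(1, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_identical(
    unname(funcresp:::letters_from_pmatrix(pm)),
    c("a", "a", "a")
  )
  pm[] <- 0.001
  diag(pm) <- 1
  expect_identical(
    unname(funcresp:::letters_from_pmatrix(pm)),
    c("a", "b", "c")
  )
  # chain: x != z but y indistinguishable from both
  pm[] <- 1
  pm["x", "z"] <- pm["z", "x"] <- 0.01
  lt <- funcresp:::letters_from_pmatrix(pm)
  expect_false(grepl("a", lt[["z"]]) && grepl("a", lt[["x"]]))
  expect_true(any(strsplit(lt[["y"]], "")[[1]] %in% strsplit(lt[["x"]], "")[[1]]))
  expect_true(any(strsplit(lt[["y"]], "")[[1]] %in% strsplit(lt[["z"]], "")[[1]]))
})
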