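test_that("simulated trials respect counts, bounds and determinism", {
  tr <- simulate_trials(a = 1.5, h = 0.08, seed = 1)
  expect_identical(nrow(tr), 18L) # 6 densities x 3 replicates
  expect_true(all(tr$n_eaten >= 0 & tr$n_eaten <= tr$n_initial))
  expect_true(all(tr$n_eaten == round(tr$n_eaten)))
  expect_identical(tr, simulate_trials(a = 1.5, h = 0.08, seed = 1))
  expect_false(identical(tr, simulate_trials(a = 1.5, h = 0.08, seed = 2)))
})

test_that("zero attack rate means nothing is ever eaten", {
  for (proc in c("binomial", "mechanistic")) {
    tr <- simulate_trials(a = 0, h = 0.1, process = proc, seed = 4)
    expect_true(all(tr$n_eaten == 0), label = proc)
  }
})

test_that("the mechanistic process obeys the handling-time budget", {
  # with handling h, at most floor(t/h) + 1 captures fit in the trial
  tr <- simulate_trials(
    a = 50, h = 0.3, t = 1, densities = c(64L),
    replicates = 200, process = "mechanistic", seed = 9
  )
  expect_true(all(tr$n_eaten <= floor(1 / 0.3) + 1))
  trh <- simulate_trials(
    a = 100, h = 1.5, t = 1, densities = c(64L),
    replicates = 100, process = "mechanistic", seed = 10
  )
  expect_true(all(trh$n_eaten <= 1))
})

test_that("binomial-process mean converges to the depletion expectation", {
  a <- 1
  h <- 0.1
  n0 <- 10
  reps <- 5000
  tr <- simulate_trials(
    a = a, h = h, densities = c(n0), replicates = reps,
    process = "binomial", seed = 12
  )
  mu <- rogers_expected(n0, a, h)
  p <- mu / n0
  mc_se <- sqrt(n0 * p * (1 - p) / reps)
  expect_lt(abs(mean(tr$n_eaten) - mu), 3 * mc_se)
})

test_that("mechanistic means sit close to (but not exactly at) the Rogers root", {
  # the renewal process is not the deterministic implicit-equation root;
  # the gap at this setting is small relative to the mean
  a <- 1
  h <- 0.1
  n0 <- 10
  tr <- simulate_trials(
    a = a, h = h, densities = c(n0), replicates = 5000,
    process = "mechanistic", seed = 13
  )
  mu <- rogers_expected(n0, a, h)
  expect_lt(abs(mean(tr$n_eaten) - mu) / mu, 0.10)
})

test_that("the factorial design has the documented shape", {
  dat <- simulate_study_design(seed = 1)
  # single-size male cells: 2 sizes x 3 temperatures x 6 densities x 3 reps
  males <- dat[dat$sex == "male" & dat$prey_size != "mixed", ]
  expect_identical(nrow(males), 108L)
  # extended ladders: females on small prey reach 256 in both experiments
  fs <- dat[dat$sex == "female" & dat$prey_size == "small", ]
  expect_setequal(unique(fs$n_initial), c(2, 4, 8, 16, 32, 64, 128, 256))
  # pregnancy arms exist only at 25 C on small prey
  preg <- dat[dat$pregnancy != "none", ]
  expect_setequal(unique(preg$pregnancy), c("stage1", "stage2"))
  expect_identical(unique(preg$temperature_C), 25)
  expect_identical(nrow(preg), 2L * 8L * 3L)
  # mixed treatment splits densities 1:1
  mx <- dat[dat$prey_size == "mixed", ]
  expect_true(all(mx$n_initial_small + mx$n_initial_large == mx$n_initial))
  expect_true(all(abs(mx$n_initial_small - mx$n_initial_large) <= 1))
  expect_true(all(mx$n_initial_small[mx$n_initial == 2] == 1))
  # per-class consumption is consistent with the totals
  expect_true(all(mx$n_eaten_small + mx$n_eaten_large == mx$n_eaten))
  expect_true(all(mx$n_eaten_small <= mx$n_initial_small))
  # determinism of the whole table
  expect_identical(dat, simulate_study_design(seed = 1))
})

test_that("an incomplete group map names the missing cell", {
  gm <- default_group_map()
  gm <- gm[!(gm$sex == "male" & gm$temperature_C == 28 & gm$prey_size == "large"), ]
  expect_error(
    simulate_study_design(gm, seed = 1),
    regexp = "male.*28.*large",
    class = "funcresp_error_params"
  )
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulate_trials(a = 1, h = 0.1, densities = c(4, 2)),
    class = "funcresp_error_params"
  )
  expect_error(simulate_trials(a = 1, h = 0.1, densities = c(2.5, 5)),
    class = "funcresp_error_params"
  )
  expect_error(simulate_trials(a = 1, h = 0.1, replicates = 0),
    class = "funcresp_error_params"
  )
})
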