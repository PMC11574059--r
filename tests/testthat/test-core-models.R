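test_that("holling disc equation matches its closed form", {
  expect_equal(holling_expected(50, a = 0, h = 0.1), 0)
  expect_equal(holling_expected(10, a = 1, h = 0), 10)
  expect_equal(holling_expected(64, a = 2, h = 0.05), 128 / (1 + 6.4))
  # replacement model may exceed the offered count
  expect_gt(holling_expected(10, a = 5, h = 0), 10 - 1e-9)
})

test_that("rogers_expected solves the implicit depletion equation", {
  # frozen bisection oracle value, computed independently
  expect_equal(rogers_expected(10, a = 1, h = 0.1), 4.328567095902, tolerance = 1e-9)
  expect_equal(rogers_expected(100, a = 0, h = 0.1), 0)
  expect_equal(rogers_expected(10, a = 1, h = 0), 10 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(rogers_expected(0, a = 2, h = 0.1), 0)
})

test_that("Lambert-W path agrees with bisection across the parameter grid", {
  for (a in c(0.1, 1, 10)) {
    for (h in c(0.001, 0.05, 0.5)) {
      for (n0 in 2^(1:8)) {
        expect_equal(
          rogers_expected(n0, a, h, t = 1),
          bisect_rogers(a, h, 1, n0),
          tolerance = 1e-8,
          label = sprintf("a=%g h=%g n0=%d", a, h, n0)
        )
      }
    }
  }
})

test_that("internal Lambert W inverts w*exp(w), including pracma's failure point", {
  x <- c(0, 1e-12, 0.1, 1, 11234637.631985765, 1e13, exp(500), exp(699))
  w <- funcresp:::lambert_w0(x)
  expect_false(anyNA(w))
  expect_lt(max(abs(w * exp(pmin(w, 700)) - x) / (1 + x)), 1e-12)
  skip_if_not_installed("pracma")
  safe <- c(0.5, 3, 100, 1e6, 1e100)
  expect_equal(
    funcresp:::lambert_w0(safe),
    vapply(safe, pracma::lambertWp, numeric(1)),
    tolerance = 1e-10
  )
})

test_that("depletion predictions stay within bounds and the h->0 limit holds", {
  # 0 < Ne < N0 for positive parameters
  set.seed(3)
  for (i in 1:50) {
    a <- runif(1, 0.01, 20)
    h <- runif(1, 1e-4, 1)
    n0 <- sample(1:256, 1)
    ne <- rogers_expected(n0, a, h)
    expect_gt(ne, 0)
    expect_lt(ne, n0)
  }
  expect_equal(
    rogers_expected(10, a = 1, h = 1e-10),
    10 * (1 - exp(-1)),
    tolerance = 1e-6
  )
})

test_that("rogers_expected is monotone in n0, a (up) and h (down)", {
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 0.1, 5)
    h <- runif(1, 0.005, 0.5)
    n0 <- sort(sample(1:300, 10))
    ne <- rogers_expected(n0, a, h)
    expect_true(all(diff(ne) >= -1e-9))
    na <- vapply(a * c(1, 2, 4), function(aa) rogers_expected(64, aa, h), numeric(1))
    expect_true(all(diff(na) >= -1e-9))
    hs <- h * c(1, 2, 4)
    nh <- vapply(hs, function(hh) rogers_expected(64, a, hh), numeric(1))
    expect_true(all(diff(nh) <= 1e-9))
  }
})

test_that("consumption saturates at the maximum feeding rate as density grows", {
  a <- 1.3
  h <- 0.02
  expect_equal(
    rogers_expected(1e6, a, h, t = 1),
    max_feeding_rate(h, t = 1),
    tolerance = 0.01
  )
})

test_that("max_feeding_rate is 1/(h*t) and rejects h = 0", {
  expect_equal(max_feeding_rate(0.5, 1), 2)
  expect_equal(max_feeding_rate(0.01, 1), 100)
  expect_equal(max_feeding_rate(0.02, 2), 25)
  expect_error(max_feeding_rate(0, 1), class = "funcresp_error_params")
})

test_that("invalid parameters are rejected with a parameter-domain error", {
  expect_error(rogers_expected(10, a = -1, h = 0.1), class = "funcresp_error_params")
  expect_error(rogers_expected(10, a = 1, h = -0.1), class = "funcresp_error_params")
  expect_error(rogers_expected(10, a = 1, h = 0.1, t = 0), class = "funcresp_error_params")
  expect_error(holling_expected(-5, a = 1, h = 0.1), class = "funcresp_error_params")
  expect_error(fr_params(NA, 0.1), class = "funcresp_error_params")
})

test_that("overflow regimes route through the bracketing solver and stay finite", {
  # a*h*n0 ~ 2e4: the W argument would overflow without the guard
  ne <- rogers_expected(2000, a = 10, h = 1, t = 1)
  expect_true(is.finite(ne))
  expect_equal(ne, bisect_rogers(10, 1, 1, 2000), tolerance = 1e-6)
})
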