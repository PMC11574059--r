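# Independent oracles used across test files.

# Bisection root of the implicit depletion equation
# Ne = n0 * (1 - exp(a * (Ne * h - t))) on [0, n0]; pure arithmetic,
# shares no code with the package's Lambert-W path.
bisect_rogers <- function(a, h, t, n0, tol = 1e-12) {
  f <- function(x) {
    e <- a * (x * h - t)
    x - n0 * (1 - exp(min(e, 700)))
  }
  lo <- 0
  hi <- n0
  while (hi - lo > tol * max(1, n0)) {
    m <- (lo + hi) / 2
    if (f(m) > 0) hi <- m else lo <- m
  }
  (lo + hi) / 2
}

# Hand-rolled binomial log-likelihood: lchoose + logs, no dbinom.
hand_binom_loglik <- function(ne, n0, p) {
  sum(lchoose(n0, ne) + ne * log(p) + (n0 - ne) * log1p(-p))
}

# Small standard dataset for fitting tests.
toy_trials <- function(a = 1.5, h = 0.08, reps = 5, seed = 11,
                       densities = c(2, 4, 8, 16, 32, 64, 128, 256)) {
  simulate_trials(a = a, h = h, densities = densities, replicates = reps, seed = seed)
}
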