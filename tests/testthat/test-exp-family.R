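test_that("every family member returns the background a at dose zero and is
           monotone nondecreasing under the increasing-orientation bounds", {
  set.seed(11)
  # grid and rate bounded so b * x^d stays below overflow for the unbounded
  # members (monotonicity is what is under test, not range)
  grid <- seq(0, 5, length.out = 200)
  for (i in 1:25) {
    a <- exp(runif(1, -1, 3))
    b <- exp(runif(1, log(0.01), log(0.5)))
    cc <- 2 + exp(runif(1, -2, 5))
    d <- runif(1, 1, 4)
    pars <- list(m1 = list(a = a), m2 = list(a = a, b = b),
                 m3 = list(a = a, b = b, d = d),
                 m4 = list(a = a, b = b, c = cc),
                 m5 = list(a = a, b = b, c = cc, d = d))
    for (m in names(pars)) {
      y <- exp_mean(m, pars[[m]], grid)
      expect_equal(y[1], a, tolerance = 1e-12)
      expect_true(all(diff(y) >= -1e-12 * max(y)))
    }
    # m4/m5 saturate at a * c
    expect_equal(exp_mean("m4", pars$m4, 1e8), a * cc, tolerance = 1e-9)
    expect_equal(exp_mean("m5", pars$m5, 1e4), a * cc, tolerance = 1e-6)
  }
})

test_that("invalid model/parameter pairings are contract errors", {
  expect_error(exp_mean("m2", list(a = 1), 0), "requires parameter")
  expect_error(exp_mean("m4", list(a = 1, b = 1, c = 0.5), 0), "must be >= 1")
  expect_error(exp_mean("m3", list(a = 1, b = 1, d = 9), 0), "must lie in")
  expect_error(exp_mean("m2", list(a = -1, b = 1), 0), "must be > 0")
  expect_error(exp_mean("m9", list(a = 1), 0), "must be one of")
})

test_that("closed-form BMD inverts the mean curve exactly", {
  # b = log(2), ces = 1 places the doubling dose at exactly 1
  expect_equal(bmd_exp("m2", list(a = 3, b = log(2)), ces = 1), 1)
  # worked m4 case: a=1, b=1, c=5, ces=1 -> log(4/3), checked against the
  # independent bisection oracle
  p4 <- list(a = 1, b = 1, c = 5)
  expect_equal(bmd_exp("m4", p4, ces = 1), log(4 / 3), tolerance = 1e-12)
  expect_equal(bmd_exp("m4", p4, ces = 1), bmd_by_bisection("m4", p4, 1),
               tolerance = 1e-10)
  # the inverted dose reproduces the benchmark response
  set.seed(7)
  for (i in 1:20) {
    ces <- runif(1, 0.2, 2)
    p <- list(a = exp(runif(1, -1, 2)), b = exp(runif(1, -3, 1)),
              c = 1 + ces + exp(runif(1, -2, 4)), d = runif(1, 1, 4))
    for (m in c("m2", "m3", "m4", "m5")) {
      bmd <- bmd_exp(m, p, ces = ces)
      expect_equal(exp_mean(m, p, bmd), p$a * (1 + ces),
                   tolerance = 1e-10)
    }
  }
})

test_that("BMD errors: no dose dependence, unreachable BMR, decreasing trend", {
  expect_error(bmd_exp("m1", list(a = 2), 1), "no dose dependence")
  expect_error(bmd_exp("m4", list(a = 1, b = 1, c = 2), ces = 1),
               "unreachable.*asymptote")
  expect_error(bmd_exp("m2", list(a = 1, b = -0.2), 1),
               "no increasing dose-response")
})

test_that("log-normal log-likelihood is the exact log density including the
           Jacobian, is additive, and is maximized at the RMS log residual", {
  # single observation with zero residual and sigma 1
  y <- exp_mean("m2", list(a = 2, b = 0.3), 1.5)
  ll <- loglik_lognormal("m2", list(a = 2, b = 0.3, sigma = 1), 1.5, y)
  expect_equal(ll, -0.5 * log(2 * pi) - log(y), tolerance = 1e-12)

  set.seed(5)
  dose <- rep(c(0, 1, 5, 25), each = 3)
  resp <- exp_mean("m4", list(a = 1, b = 0.4, c = 8), dose) *
    exp(rnorm(length(dose), 0, 0.3))
  p <- list(a = 1.1, b = 0.35, c = 7, sigma = 0.28)
  ll1 <- loglik_lognormal("m4", p, dose, resp)
  ll2 <- loglik_lognormal("m4", p, rep(dose, 2), rep(resp, 2))
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)

  # grid oracle over sigma: the analytic profile (RMS log residual) wins
  r <- log(resp) - log(exp_mean("m4", p[1:3], dose))
  s_hat <- sqrt(mean(r^2))
  ll_hat <- loglik_lognormal("m4", c(p[1:3], sigma = s_hat), dose, resp)
  for (s in seq(0.05, 1.5, by = 0.01)) {
    expect_lte(loglik_lognormal("m4", c(p[1:3], sigma = s), dose, resp),
               ll_hat + 1e-10)
  }
  expect_error(loglik_lognormal("m2", list(a = 1, b = 1, sigma = 1), 1, -2),
               "strictly positive")
})
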