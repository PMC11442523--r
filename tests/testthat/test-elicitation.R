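test_that("normal elicitation solves the two-sided quantile equation", {
  pr <- elicit_normal(10, 25, 0.99)
  expect_equal(pr$mu0, 17.5)
  expect_within(pr$tau0, 2.912, 5e-4)

  pr2 <- elicit_normal(-1, 1, 0.95)
  expect_equal(pr2$mu0, 0)
  expect_equal(pr2$tau0, 1 / qnorm(0.975), tolerance = 1e-10)

  # dispersion shrinks monotonely as certainty grows
  taus <- vapply(c(0.5, 0.8, 0.9, 0.99, 0.999, 0.999999),
                 function(g) elicit_normal(0, 1, g)$tau0, numeric(1))
  expect_true(all(diff(taus) < 0))
  expect_lt(taus[length(taus)], 0.11)
})

test_that("denominator-mean elicitation matches its defining equation", {
  mu_pr <- elicit_normal(10, 25, 0.99)
  nu_pr <- elicit_fieller_nu(mu_pr, 10, 25, r1 = 1, r2 = 3, psi0 = 2)
  expect_equal(nu_pr$mu0, 8.75)
  # back-substitution reproduces gamma
  expect_equal(
    pnorm((25 / 1 - 8.75) / nu_pr$tau0) - pnorm((10 / 3 - 8.75) / nu_pr$tau0),
    0.99, tolerance = 1e-8
  )
  # when the implied interval (m1/r2, m2/r1) = (1, 6) is symmetric about
  # nu0 = mu0/psi0 = 3.5, the solution is the closed symmetric form
  sym <- elicit_fieller_nu(elicit_normal(2, 6, 0.95), 2, 6,
                           r1 = 1, r2 = 2, psi0 = 8 / 7, gamma = 0.95)
  expect_equal(sym$mu0, 3.5)
  expect_equal(sym$tau0, 2.5 / qnorm(0.975), tolerance = 1e-8)

  expect_error(elicit_fieller_nu(mu_pr, 10, 25, r1 = -1, r2 = 3, psi0 = 2),
               "exclude 0")
  expect_error(elicit_fieller_nu(mu_pr, 10, 25, r1 = 1, r2 = 3, psi0 = 5),
               "inside")
})

test_that("beta elicitation reproduces the bounded-mean prior", {
  pr <- elicit_beta(0, 10, 0.5, 9.5, m0 = 5, gamma = 0.99)
  expect_within(pr$alpha0, 2.20, 5e-3)
  expect_within(pr$beta0, 2.20, 5e-3)
  # defining equation and mode identity hold at the returned values
  expect_equal(prior_cdf(pr, 9.5) - prior_cdf(pr, 0.5), 0.99, tolerance = 1e-8)
  expect_equal((pr$alpha0 - 1) / (pr$alpha0 + pr$beta0 - 2), 0.5,
               tolerance = 1e-10)

  asym <- elicit_beta(0, 10, 1, 6, m0 = 3, gamma = 0.95)
  expect_equal(prior_cdf(asym, 6) - prior_cdf(asym, 1), 0.95, tolerance = 1e-8)
  expect_equal((asym$alpha0 - 1) / (asym$alpha0 + asym$beta0 - 2), 0.3,
               tolerance = 1e-8)

  unif <- elicit_beta(0, 10, 0, 10)
  expect_equal(c(unif$alpha0, unif$beta0), c(1, 1))
  expect_error(elicit_beta(0, 10, 0.5, 9.9, m0 = 5, gamma = 0.5),
               "unattainable")
})

test_that("truncated normal elicitation respects its solvability condition", {
  pr <- elicit_truncnorm(0, 10, 0.5, 9.5, mu0 = 5, gamma = 0.99)
  expect_within(pr$tau0, 1.92, 5e-3)
  cover <- function(tau) {
    (pnorm((9.5 - 5) / tau) - pnorm((0.5 - 5) / tau)) /
      (pnorm((10 - 5) / tau) - pnorm((0 - 5) / tau))
  }
  expect_equal(cover(pr$tau0), 0.99, tolerance = 1e-8)
  # the large-dispersion limit of the conditional coverage is the length ratio
  expect_equal(cover(1e6), 9 / 10, tolerance = 1e-4)
  expect_error(elicit_truncnorm(0, 10, 0.5, 9.5, mu0 = 5, gamma = 0.85),
               "no solution")
})

test_that("gamma-rate elicitation fixes the mode and the interval content", {
  pr <- elicit_gamma_rate(3.5, 9.5, m0 = 6.5, gamma = 0.99)
  expect_within(pr$alpha0, 37.20, 0.01)
  expect_within(pr$beta0, 5.57, 0.01)
  expect_equal((pr$alpha0 - 1) / pr$beta0, 6.5, tolerance = 1e-10)
  expect_equal(prior_cdf(pr, 9.5) - prior_cdf(pr, 3.5), 0.99, tolerance = 1e-8)
})

test_that("every elicited prior records a tiny residual", {
  priors <- list(
    elicit_normal(10, 25),
    elicit_fieller_nu(elicit_normal(10, 25), 10, 25, 1, 3, 2),
    elicit_beta(0, 10, 0.5, 9.5),
    elicit_truncnorm(0, 10, 0.5, 9.5, mu0 = 5),
    elicit_gamma_rate(3.5, 9.5)
  )
  for (pr in priors) expect_lt(attr(pr, "elicitation")$residual, 1e-8)
})

test_that("prior-data conflict tail probability behaves as a calibration", {
  pr <- elicit_normal(10, 25)
  expect_equal(prior_data_conflict(17.5, 10, 1, pr), 1)
  sd_pred <- sqrt(pr$tau0^2 + 1 / 10)
  expect_equal(prior_data_conflict(17.5 + sd_pred, 10, 1, pr),
               2 * (1 - pnorm(1)), tolerance = 1e-12)
  # large-sample limit compares the true mean against the prior alone
  expect_equal(prior_data_conflict(20, 1e8, 1, pr),
               2 * (1 - pnorm(abs(20 - 17.5) / pr$tau0)), tolerance = 1e-4)
  # decreasing in the standardized distance, and always a probability
  xs <- seq(17.5, 30, by = 0.5)
  p <- vapply(xs, prior_data_conflict, numeric(1), n = 10, sigma0 = 1, prior = pr)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("prior densities, cdfs and samplers are mutually consistent", {
  set.seed(31)
  priors <- list(
    normal_prior(2, 1.5),
    scaled_beta_prior(0, 10, 2.2, 2.2),
    truncnorm_prior(5, 1.92, 0, 10),
    gamma_rate_prior(37.2, 5.57)
  )
  for (pr in priors) {
    x <- prior_sample(pr, 2e4)
    # empirical cdf of draws matches prior_cdf at a few probes
    for (q in quantile(x, c(0.25, 0.5, 0.75))) {
      expect_equal(mean(x <= q), prior_cdf(pr, q), tolerance = 0.02)
    }
    # density integrates to the cdf increment
    mid <- unname(quantile(x, 0.5))
    num <- integrate(function(t) prior_density(pr, t), mid - 0.5, mid + 0.5)$value
    expect_equal(num, prior_cdf(pr, mid + 0.5) - prior_cdf(pr, mid - 0.5),
                 tolerance = 1e-6)
  }
})
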