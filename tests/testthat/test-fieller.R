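test_that("fiber parameters reproduce the worked-example anchors", {
  pr <- ex1_priors()
  cp <- psi_cond_params(2, pr)
  expect_within(cp$tau2_psi, 1.5239, 5e-4)
  expect_within(cp$nu0_psi, 8.7502, 5e-4)
  expect_within(cp$z0, -7.0883, 5e-4)
  # the elicited dispersion satisfies exactly the invariant tying the three
  expect_equal(cp$tau2_psi, 1 / (4 / pr$mu$tau0^2 + 1 / pr$nu$tau0^2))

  # algebraic reductions
  cp0 <- psi_cond_params(0, pr)
  expect_equal(cp0$tau2_psi, pr$nu$tau0^2)
  expect_equal(cp0$nu0_psi, pr$nu$mu0)
  pr_eq <- fieller_priors(normal_prior(1, 2), normal_prior(3, 2))
  expect_equal(psi_cond_params(1.5, pr_eq)$tau2_psi, 4 / (1 + 1.5^2))
})

test_that("the closed-form ratio density reduces to Cauchy and normalizes", {
  pr0 <- fieller_priors(normal_prior(0, 1), normal_prior(0, 1))
  psi <- c(0, 1, 2)
  expect_equal(fieller_psi_density(psi, pr0), 1 / (pi * (1 + psi^2)),
               tolerance = 1e-8)
  pr <- ex1_priors()
  expect_equal(
    integrate(fieller_psi_density, -100, 100, priors = pr,
              subdivisions = 2000)$value,
    1, tolerance = 1e-3
  )
})

test_that("the ratio density matches a histogram of prior draws", {
  pr <- ex1_priors()
  set.seed(41)
  n <- 1e5
  psi <- prior_sample(pr$mu, n) / prior_sample(pr$nu, n)
  g <- rb_grid(0.5, 3.5, 0.1, align = FALSE)
  emp <- discretize(psi, psi, g)
  exact <- vapply(seq_len(g$n_bins), function(i) {
    integrate(fieller_psi_density, g$breaks[i], g$breaks[i + 1],
              priors = pr)$value
  }, numeric(1))
  se <- sqrt(exact * (1 - exact) / n)
  expect_true(all(abs(emp$prior_mass - exact) < 4 * se + 1e-4))
})

test_that("posterior density is the prior form at updated hyperparameters", {
  pr <- ex1_priors()
  dat <- ex1_data()
  post <- fieller_posterior(pr, dat)
  expect_equal(post$mu$mu0,
               (10 * 20.188 + 17.5 / pr$mu$tau0^2) / (10 + 1 / pr$mu$tau0^2))
  # with essentially no data weight the posterior collapses to the prior
  flat <- fieller_posterior(pr, fieller_data(20.188, 10.699, 10, 10, 1e8))
  expect_equal(flat$mu$mu0, pr$mu$mu0, tolerance = 1e-6)
  expect_equal(flat$nu$tau0, pr$nu$tau0, tolerance = 1e-6)
  psi <- seq(1, 3, by = 0.25)
  expect_equal(fieller_psi_density(psi, flat),
               fieller_psi_density(psi, pr), tolerance = 1e-6)

  # consistency: with much data the posterior mass piles onto xbar/ybar
  big <- fieller_data(20.188, 10.699, 1e6, 1e6, 1)
  ratio <- 20.188 / 10.699
  inner <- integrate(fieller_psi_posterior_density, ratio - 0.01, ratio + 0.01,
                     priors = pr, data = big)$value
  expect_gt(inner, 0.999)
})

test_that("discretized relative belief agrees with the exact Savage-Dickey form", {
  pr <- ex1_priors()
  dat <- ex1_data()
  fit <- fieller_infer(dat, pr, delta = 0.1, reps = 1e5, seed = 7)
  prof <- fit$profile
  n <- fit$reps
  well <- which(prof$prior_mass >= 0.005 & prof$posterior_mass >= 0.005)
  expect_gt(length(well), 3)
  exact <- fieller_rb_binned(well, prof, pr, dat)
  est <- prof$rb[well]
  se <- est * sqrt(1 / (n * prof$prior_mass[well]) +
                     1 / (n * prof$posterior_mass[well]))
  expect_true(all(abs(est - exact) < 5 * se + 0.01))
})

test_that("pivotal inversion matches the quadratic roots and printed regions", {
  dat <- ex1_data()
  piv <- pivotal_region(dat, 0.95)
  # independent oracle: solve the quadratic directly
  z <- qnorm(0.975)
  A <- 10.699^2 - z^2 / 10
  B <- -2 * 20.188 * 10.699
  C <- 20.188^2 - z^2 / 10
  roots <- sort((-B + c(-1, 1) * sqrt(B^2 - 4 * A * C)) / (2 * A))
  expect_equal(piv$kind, "interval")
  expect_equal(piv$endpoints, roots, tolerance = 1e-12)
  expect_within(piv$endpoints[1], 1.770, 2e-3)
  expect_within(piv$endpoints[2], 2.016, 2e-3)

  cox_a <- pivotal_region(fieller_data(10, 0.5, 1, 1, 1), 0.95)
  expect_equal(cox_a$kind, "exclusive")
  expect_within(cox_a$endpoints[1], -6.752, 3e-3)
  expect_within(cox_a$endpoints[2], 3.968, 3e-3)

  cox_b <- pivotal_region(fieller_data(0.5, 0.5, 1, 1, 1), 0.95)
  expect_equal(cox_b$kind, "whole_line")
  expect_true(glance(cox_b)$improper)
  # the whole-line condition matches the printed characterization
  expect_true(abs(0.5) < qnorm(0.975) && 0.5^2 + 0.5^2 < qnorm(0.975)^2)
})

test_that("a mean interval containing zero maps to an exclusive region for 1/mu", {
  set.seed(42)
  z <- qnorm(0.975)
  for (i in 1:20) {
    ny <- sample(1:50, 1)
    s0 <- runif(1, 0.5, 3)
    ybar <- runif(1, -0.9, 0.9) * z * s0 / sqrt(ny) # interval for mu covers 0
    piv <- pivotal_region(fieller_data(1, ybar, 1e9, ny, s0), 0.95)
    expect_equal(piv$kind, "exclusive")
    expected <- sort(1 / (ybar + c(-1, 1) * z * s0 / sqrt(ny)))
    expect_equal(piv$endpoints, expected, tolerance = 1e-5)
  }
})

test_that("the pivotal 0.95 region has exact frequentist coverage", {
  set.seed(43)
  mu <- 20; nu <- 10; n <- 10
  hits <- vapply(1:2000, function(i) {
    d <- fieller_data(rnorm(1, mu, 1 / sqrt(n)), rnorm(1, nu, 1 / sqrt(n)),
                      n, n, 1)
    piv <- pivotal_region(d, 0.95)
    psi <- mu / nu
    switch(piv$kind,
      interval = psi >= piv$endpoints[1] && psi <= piv$endpoints[2],
      exclusive = psi <= piv$endpoints[1] || psi >= piv$endpoints[2],
      half_line = psi >= piv$endpoints[1] && psi <= piv$endpoints[2],
      whole_line = TRUE,
      empty = FALSE
    )
  }, logical(1))
  expect_within(mean(hits), 0.95, 0.02)
})

test_that("the conditional prior sampler matches its closed-form density", {
  pr <- ex1_priors()
  set.seed(44)
  n <- 1e5
  nu <- sample_nu_given_psi(2, pr, n)
  g <- rb_grid(4, 14, 0.25, align = FALSE)
  emp <- discretize(nu, nu, g)$prior_mass
  exact <- vapply(seq_len(g$n_bins), function(i) {
    integrate(dnu_given_psi, g$breaks[i], g$breaks[i + 1], psi = 2,
              priors = pr)$value
  }, numeric(1))
  se <- sqrt(exact * (1 - exact) / n)
  expect_true(all(abs(emp - exact) < 4 * se + 2e-4))
  # density integrates to 1
  expect_equal(integrate(dnu_given_psi, -30, 40, psi = 2, priors = pr)$value,
               1, tolerance = 1e-6)

  # symmetric case: zero fiber location gives a sign-symmetric density
  pr0 <- fieller_priors(normal_prior(0, 2), normal_prior(0, 2))
  nu0 <- sample_nu_given_psi(1, pr0, n, seed = 9)
  expect_equal(mean(nu0), 0, tolerance = 4 * sd(nu0) / sqrt(n))
  expect_equal(psi_cond_params(1, pr0)$nu0_psi, 0)
})

test_that("predictive sampling composes the sequential scheme", {
  pr <- ex1_priors()
  set.seed(45)
  d <- sample_fieller_predictive(2, pr, 10, 10, 1, 5e4)
  expect_equal(mean(d$ybar), mean(d$nu), tolerance = 4 / sqrt(10 * 5e4))
  expect_equal(mean(d$xbar), 2 * mean(d$nu), tolerance = 4 / sqrt(10 * 5e4))
  # with vanishing noise the draws collapse onto the ray mu = psi * nu
  d0 <- sample_fieller_predictive(2, pr, 10, 10, 1e-8, 1000, seed = 3)
  expect_equal(d0$xbar, 2 * d0$nu, tolerance = 1e-6)
  expect_equal(d0$ybar, d0$nu, tolerance = 1e-6)
})

test_that("full inference reproduces the simulated-study summary", {
  fit <- fieller_infer(ex1_data(), ex1_priors(), delta = 0.1, reps = 1e5,
                       gamma = 0.95, seed = 46)
  g <- glance(fit)
  expect_within(g$estimate, 1.90, 1e-9)
  expect_within(g$pl_lower, 1.75, 1e-9)
  expect_within(g$pl_upper, 2.05, 1e-9)
  expect_within(g$posterior_content, 0.982, 0.01)
  expect_within(g$prior_content, 0.200, 0.01)
  # credible region at 0.95 sits inside the plausible region
  expect_true(all(fit$credible$bins %in% fit$plausible$bins))
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("the monotone-transform hook leaves the inferences invariant", {
  tr <- list(fun = function(x) atan(x / 5), inv = function(w) 5 * tan(w))
  fit <- fieller_infer(ex1_data(), ex1_priors(), delta = 0.01, reps = 1e5,
                       transform = tr, seed = 47)
  g <- glance(fit)
  # delta = 0.01 on the transformed scale is ~0.13 near psi = 2
  expect_within(g$estimate, 1.9, 0.1)
  expect_within(g$posterior_content, 0.982, 0.02)
  expect_true(g$pl_lower > 1.5 && g$pl_upper < 2.4)
})
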