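# shared fixtures: the simulated ratio-of-means study and small generators

# absolute-tolerance comparison (expect_equal's `tolerance` is relative,
# which is far too strict for published values near zero)
expect_within <- function(object, expected, tol) {
  act <- testthat::quasi_label(rlang::enquo(object))
  testthat::expect(
    abs(act$val - expected) <= tol,
    sprintf("%s (%.6g) is not within %g of %g", act$lab, act$val, tol, expected)
  )
  invisible(act$val)
}

# exact relative belief ratio integrated over a grid bin: the oracle the
# discretized ratio estimates
fieller_rb_binned <- function(bins, profile, priors, data) {
  g <- attr(profile, "grid")
  post <- fieller_posterior(priors, data)
  vapply(bins, function(i) {
    num <- integrate(fieller_psi_density, g$breaks[i], g$breaks[i + 1],
                     priors = post)$value
    den <- integrate(fieller_psi_density, g$breaks[i], g$breaks[i + 1],
                     priors = priors)$value
    num / den
  }, numeric(1))
}

ex1_priors <- function() {
  mu_pr <- elicit_normal(10, 25, 0.99)
  fieller_priors(
    mu_pr,
    elicit_fieller_nu(mu_pr, 10, 25, r1 = 1, r2 = 3, psi0 = 2, gamma = 0.99)
  )
}

ex1_data <- function() fieller_data(20.188, 10.699, 10, 10, 1)

# random mass profiles: Dirichlet-ish prior/posterior over k bins, with
# optional zero-prior bins
random_profile <- function(k, zero_prior = 0L) {
  w1 <- rgamma(k, 1)
  w2 <- rgamma(k, 1)
  if (zero_prior > 0) w1[sample(k, zero_prior)] <- 0
  mass_profile(seq_len(k) - 0.5, w1 / sum(w1), w2 / sum(w2), delta = 1)
}

cox_priors <- function(problem) {
  tau <- sqrt(3)
  if (problem == "A") {
    fieller_priors(normal_prior(12, tau), normal_prior(0, tau))
  } else {
    fieller_priors(normal_prior(0, tau), normal_prior(0, tau))
  }
}

beta_model <- function(n, ...) {
  constrained_normal_model(elicit_beta(0, 10, 0.5, 9.5, m0 = 5), n = n, ...)
}

pois_model <- function(n, delta = 0.5) {
  constrained_poisson_model(elicit_gamma_rate(3.5, 9.5, m0 = 6.5), 3, 10,
                            n = n, delta = delta)
}
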