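#' Prior distributions and elicitation
#'
#' Priors are elicited from *virtual certainty* statements: an interval that
#' is believed to contain the true parameter value with high prior
#' probability `gamma` (0.99 by default). The dispersion parameter of each
#' family is found by quantile-matching bisection so that the elicited prior
#' assigns exactly `gamma` to the stated interval; the returned objects
#' record the inputs and the achieved residual.
#'
#' @name elicitation
#' @aliases rb_prior
NULL

new_prior <- function(class, params, elicitation = NULL) {
  structure(
    params,
    elicitation = elicitation,
    class = c(class, "rb_prior")
  )
}

#' @export
print.rb_prior <- function(x, ...) {
  cat(sprintf("<%s> ", class(x)[1]))
  p <- unlist(x[vapply(x, is.numeric, logical(1))])
  cat(paste(sprintf("%s = %.6g", names(p), p), collapse = ", "), "\n")
  el <- attr(x, "elicitation")
  if (!is.null(el)) {
    cat(sprintf("  elicited: gamma = %g, residual = %.2e\n",
                el$gamma, el$residual))
  }
  invisible(x)
}

#' @export
tidy.rb_prior <- function(x, ...) {
  p <- unlist(x[vapply(x, is.numeric, logical(1))])
  tibble(term = names(p), value = unname(p))
}

#' @export
glance.rb_prior <- function(x, ...) {
  el <- attr(x, "elicitation")
  out <- tibble(family = class(x)[1])
  p <- unlist(x[vapply(x, is.numeric, logical(1))])
  out <- dplyr::bind_cols(out, as_tibble(as.list(p)))
  out$gamma <- if (is.null(el)) NA_real_ else el$gamma
  out$residual <- if (is.null(el)) NA_real_ else el$residual
  out
}

#' Construct prior objects directly
#'
#' @param mu0 Location.
#' @param tau0 Standard deviation (dispersion), positive.
#' @return An object inheriting from `rb_prior`.
#' @export
normal_prior <- function(mu0, tau0) {
  assert_scalar(mu0)
  assert_scalar(tau0, positive = TRUE)
  new_prior("normal_prior", list(mu0 = mu0, tau0 = tau0))
}

#' @rdname normal_prior
#' @param l0,u0 Support bounds.
#' @param alpha0,beta0 Shape parameters (both at least 1 for the scaled beta;
#'   shape and rate for the gamma).
#' @export
scaled_beta_prior <- function(l0, u0, alpha0, beta0) {
  assert_scalar(l0); assert_scalar(u0)
  if (u0 <= l0) abort("`u0` must exceed `l0`")
  if (alpha0 < 1 || beta0 < 1) abort("`alpha0` and `beta0` must be >= 1")
  new_prior("scaled_beta_prior",
            list(l0 = l0, u0 = u0, alpha0 = alpha0, beta0 = beta0))
}

#' @rdname normal_prior
#' @export
truncnorm_prior <- function(mu0, tau0, l0, u0) {
  assert_scalar(mu0); assert_scalar(tau0, positive = TRUE)
  assert_scalar(l0); assert_scalar(u0)
  if (u0 <= l0) abort("`u0` must exceed `l0`")
  new_prior("truncnorm_prior",
            list(mu0 = mu0, tau0 = tau0, l0 = l0, u0 = u0))
}

#' @rdname normal_prior
#' @export
gamma_rate_prior <- function(alpha0, beta0) {
  assert_scalar(alpha0, positive = TRUE)
  assert_scalar(beta0, positive = TRUE)
  new_prior("gamma_rate_prior", list(alpha0 = alpha0, beta0 = beta0))
}

# ---- density / cdf / sampling generics ------------------------------------

#' Evaluate or sample an elicited prior
#'
#' @param prior An `rb_prior` object.
#' @param x Numeric vector of evaluation points.
#' @param n Number of draws.
#' @param seed Optional integer seed for reproducible draws.
#' @return `prior_density()` and `prior_cdf()` return numeric vectors;
#'   `prior_sample()` returns `n` draws.
#' @export
prior_density <- function(prior, x) UseMethod("prior_density")
#' @rdname prior_density
#' @export
prior_cdf <- function(prior, x) UseMethod("prior_cdf")
#' @rdname prior_density
#' @export
prior_sample <- function(prior, n, seed = NULL) UseMethod("prior_sample")

#' @export
prior_density.normal_prior <- function(prior, x) dnorm(x, prior$mu0, prior$tau0)
#' @export
prior_cdf.normal_prior <- function(prior, x) pnorm(x, prior$mu0, prior$tau0)
#' @export
prior_sample.normal_prior <- function(prior, n, seed = NULL) {
  with_seed_if(seed, rnorm(n, prior$mu0, prior$tau0))
}

#' @export
prior_density.scaled_beta_prior <- function(prior, x) {
  w <- prior$u0 - prior$l0
  dbeta((x - prior$l0) / w, prior$alpha0, prior$beta0) / w
}
#' @export
prior_cdf.scaled_beta_prior <- function(prior, x) {
  pbeta((x - prior$l0) / (prior$u0 - prior$l0), prior$alpha0, prior$beta0)
}
#' @export
prior_sample.scaled_beta_prior <- function(prior, n, seed = NULL) {
  with_seed_if(seed,
               prior$l0 + (prior$u0 - prior$l0) * rbeta(n, prior$alpha0, prior$beta0))
}

#' @export
prior_density.truncnorm_prior <- function(prior, x) {
  z <- pnorm((prior$u0 - prior$mu0) / prior$tau0) -
    pnorm((prior$l0 - prior$mu0) / prior$tau0)
  ifelse(x >= prior$l0 & x <= prior$u0,
         dnorm(x, prior$mu0, prior$tau0) / z, 0)
}
#' @export
prior_cdf.truncnorm_prior <- function(prior, x) {
  plo <- pnorm((prior$l0 - prior$mu0) / prior$tau0)
  phi <- pnorm((prior$u0 - prior$mu0) / prior$tau0)
  p <- (pnorm((x - prior$mu0) / prior$tau0) - plo) / (phi - plo)
  pmin(pmax(p, 0), 1)
}
#' @export
prior_sample.truncnorm_prior <- function(prior, n, seed = NULL) {
  plo <- pnorm((prior$l0 - prior$mu0) / prior$tau0)
  phi <- pnorm((prior$u0 - prior$mu0) / prior$tau0)
  with_seed_if(seed, prior$mu0 + prior$tau0 * qnorm(runif(n, plo, phi)))
}

#' @export
prior_density.gamma_rate_prior <- function(prior, x) {
  dgamma(x, prior$alpha0, rate = prior$beta0)
}
#' @export
prior_cdf.gamma_rate_prior <- function(prior, x) {
  pgamma(x, prior$alpha0, rate = prior$beta0)
}
#' @export
prior_sample.gamma_rate_prior <- function(prior, n, seed = NULL) {
  with_seed_if(seed, rgamma(n, prior$alpha0, rate = prior$beta0))
}

# ---- elicitation -----------------------------------------------------------

#' Elicit a normal prior from a virtual-certainty interval
#'
#' The prior mean is the midpoint of `(m1, m2)` and the standard deviation
#' solves `P(m1 < mu < m2) = gamma`; by symmetry the solution is
#' `tau0 = (m2 - mu0) / qnorm((1 + gamma) / 2)`.
#'
#' @param m1,m2 Interval believed to contain the true mean with prior
#'   probability `gamma`.
#' @param gamma Virtual-certainty probability, default 0.99.
#' @return A `normal_prior`.
#' @examples
#' elicit_normal(10, 25)  # mu0 = 17.5, tau0 = 2.912
#' @export
elicit_normal <- function(m1, m2, gamma = 0.99) {
  assert_scalar(m1); assert_scalar(m2); assert_prob(gamma)
  if (m2 <= m1) abort("`m2` must exceed `m1`")
  mu0 <- (m1 + m2) / 2
  tau0 <- (m2 - mu0) / qnorm((1 + gamma) / 2)
  residual <- abs(pnorm((m2 - mu0) / tau0) - pnorm((m1 - mu0) / tau0) - gamma)
  new_prior("normal_prior", list(mu0 = mu0, tau0 = tau0),
            list(gamma = gamma, m1 = m1, m2 = m2, residual = residual))
}

#' Elicit the denominator-mean prior in Fieller's ratio problem
#'
#' Given an elicited normal prior for the numerator mean `mu`, beliefs about
#' the ratio `psi = mu / nu` expressed as `psi` in `(r1, r2)` with virtual
#' certainty, and a central value `psi0`, the denominator prior has location
#' `nu0 = mu0 / psi0` and dispersion solving the (generally asymmetric)
#' two-sided equation
#' `pnorm((m2/r1 - nu0)/tau) - pnorm((m1/r2 - nu0)/tau) = gamma`
#' by bisection, so that `nu` lies in `(m1/r2, m2/r1)` with virtual
#' certainty.
#'
#' @param mu_prior The elicited `normal_prior` for the numerator mean.
#' @param m1,m2 The virtual-certainty interval used for `mu`.
#' @param r1,r2 Virtual-certainty interval for the ratio; must exclude 0.
#' @param psi0 Central (or hypothesized) ratio value in `(r1, r2)`.
#' @param gamma Virtual-certainty probability.
#' @return A `normal_prior` for the denominator mean.
#' @examples
#' mu_prior <- elicit_normal(10, 25)
#' elicit_fieller_nu(mu_prior, 10, 25, r1 = 1, r2 = 3, psi0 = 2)
#' @export
elicit_fieller_nu <- function(mu_prior, m1, m2, r1, r2, psi0, gamma = 0.99) {
  if (!inherits(mu_prior, "normal_prior")) {
    abort("`mu_prior` must be a `normal_prior`")
  }
  assert_scalar(r1); assert_scalar(r2); assert_scalar(psi0); assert_prob(gamma)
  if (r2 <= r1) abort("`r2` must exceed `r1`")
  if (r1 <= 0 && r2 >= 0) abort("the ratio interval `(r1, r2)` must exclude 0")
  if (psi0 <= r1 || psi0 >= r2) abort("`psi0` must lie inside `(r1, r2)`")
  nu0 <- mu_prior$mu0 / psi0
  bounds <- sort(c(m1 / r2, m2 / r1))
  if (nu0 <= bounds[1] || nu0 >= bounds[2]) {
    abort("the elicitation equation has no root: `nu0 = mu0/psi0` falls outside the implied interval for `nu`")
  }
  f <- function(tau) {
    pnorm((bounds[2] - nu0) / tau) - pnorm((bounds[1] - nu0) / tau) - gamma
  }
  hi <- expand_upper(f, 1e-8, (bounds[2] - bounds[1]))
  tau0 <- bisect_root(f, 1e-8, hi)
  new_prior("normal_prior", list(mu0 = nu0, tau0 = tau0),
            list(gamma = gamma, bounds = bounds, psi0 = psi0,
                 residual = abs(f(tau0))))
}

#' Elicit a scaled beta prior on a bounded parameter
#'
#' The prior is `l0 + (u0 - l0) * beta(alpha0, beta0)` with both shapes at
#' least 1 (unimodal, no singularities). The mode is fixed at `m0` through
#' `alpha0 = tau0 (m0 - l0)/(u0 - l0) + 1`,
#' `beta0 = tau0 (u0 - m0)/(u0 - l0) + 1`, and the concentration `tau0 >= 0`
#' is found by bisection so the prior assigns probability `gamma` to
#' `(l1, u1)`. When `(l1, u1)` equals the full domain the uniform prior
#' (`alpha0 = beta0 = 1`) is returned.
#'
#' @param l0,u0 Domain bounds (finite).
#' @param l1,u1 Virtual-certainty subinterval.
#' @param m0 Prior mode, inside `(l1, u1)`; defaults to the midpoint.
#' @param gamma Virtual-certainty probability.
#' @return A `scaled_beta_prior`.
#' @examples
#' elicit_beta(0, 10, 0.5, 9.5)  # alpha0 = beta0 = 2.20
#' @export
elicit_beta <- function(l0, u0, l1, u1, m0 = (l1 + u1) / 2, gamma = 0.99) {
  assert_scalar(l0); assert_scalar(u0); assert_scalar(l1); assert_scalar(u1)
  assert_prob(gamma)
  if (!(l0 <= l1 && l1 < u1 && u1 <= u0)) {
    abort("need l0 <= l1 < u1 <= u0")
  }
  el <- list(gamma = gamma, l1 = l1, u1 = u1, m0 = m0, residual = 0)
  if (l1 == l0 && u1 == u0) {
    return(new_prior("scaled_beta_prior",
                     list(l0 = l0, u0 = u0, alpha0 = 1, beta0 = 1), el))
  }
  if (m0 <= l1 || m0 >= u1) abort("`m0` must lie inside `(l1, u1)`")
  w <- u0 - l0
  coverage <- function(tau0) {
    a <- tau0 * (m0 - l0) / w + 1
    b <- tau0 * (u0 - m0) / w + 1
    pbeta((u1 - l0) / w, a, b) - pbeta((l1 - l0) / w, a, b)
  }
  if (coverage(0) >= gamma) {
    abort("`gamma` is unattainable: even the uniform prior (tau0 = 0) assigns more than `gamma` to `(l1, u1)`")
  }
  hi <- expand_upper(function(t) coverage(t) - gamma, 0, 8)
  tau0 <- bisect_root(function(t) coverage(t) - gamma, 0, hi)
  el$residual <- abs(coverage(tau0) - gamma)
  new_prior("scaled_beta_prior",
            list(l0 = l0, u0 = u0,
                 alpha0 = tau0 * (m0 - l0) / w + 1,
                 beta0 = tau0 * (u0 - m0) / w + 1),
            el)
}

#' Elicit a truncated normal prior on a bounded parameter
#'
#' The prior is `N(mu0, tau0^2)` restricted to `(l0, u0)`; `tau0` solves
#' `P(l1 < mu < u1 | l0 < mu < u0) = gamma` by bisection. As
#' `tau0 -> infinity` the conditional coverage tends to
#' `(u1 - l1)/(u0 - l0)` (the uniform limit), so a solution exists exactly
#' when that ratio does not exceed `gamma`.
#'
#' @inheritParams elicit_beta
#' @param mu0 Prior location, inside `(l1, u1)`.
#' @return A `truncnorm_prior`.
#' @examples
#' elicit_truncnorm(0, 10, 0.5, 9.5, mu0 = 5)  # tau0 = 1.92
#' @export
elicit_truncnorm <- function(l0, u0, l1, u1, mu0, gamma = 0.99) {
  assert_scalar(l0); assert_scalar(u0); assert_scalar(mu0); assert_prob(gamma)
  if (!(l0 <= l1 && l1 < u1 && u1 <= u0)) abort("need l0 <= l1 < u1 <= u0")
  if (mu0 <= l1 || mu0 >= u1) abort("`mu0` must lie inside `(l1, u1)`")
  if ((u1 - l1) / (u0 - l0) > gamma) {
    abort(sprintf(
      "no solution: (u1 - l1)/(u0 - l0) = %.4f exceeds gamma = %g, the large-dispersion limit of the conditional coverage",
      (u1 - l1) / (u0 - l0), gamma
    ))
  }
  coverage <- function(tau) {
    (pnorm((u1 - mu0) / tau) - pnorm((l1 - mu0) / tau)) /
      (pnorm((u0 - mu0) / tau) - pnorm((l0 - mu0) / tau))
  }
  f <- function(tau) coverage(tau) - gamma
  hi <- expand_upper(f, 1e-8, u0 - l0)
  tau0 <- bisect_root(f, 1e-8, hi)
  new_prior("truncnorm_prior",
            list(mu0 = mu0, tau0 = tau0, l0 = l0, u0 = u0),
            list(gamma = gamma, l1 = l1, u1 = u1, residual = abs(f(tau0))))
}

#' Elicit a gamma prior (rate parameterization) for a positive rate
#'
#' The mode is fixed at `m0` through `alpha0 = 1 + m0 * beta0`, and the rate
#' `beta0` is found by bisection so the prior assigns probability `gamma` to
#' `(l1, u1)`.
#'
#' @inheritParams elicit_beta
#' @return A `gamma_rate_prior`.
#' @examples
#' elicit_gamma_rate(3.5, 9.5)  # gamma_rate(37.20, 5.57)
#' @export
elicit_gamma_rate <- function(l1, u1, m0 = (l1 + u1) / 2, gamma = 0.99) {
  assert_scalar(l1); assert_scalar(u1); assert_prob(gamma)
  if (l1 <= 0) abort("`l1` must be positive for a rate parameter")
  if (u1 <= l1) abort("`u1` must exceed `l1`")
  if (m0 <= l1 || m0 >= u1) abort("`m0` must lie inside `(l1, u1)`")
  f <- function(b) {
    pgamma(u1, 1 + m0 * b, rate = b) - pgamma(l1, 1 + m0 * b, rate = b) - gamma
  }
  hi <- expand_upper(f, 1e-6, 1)
  beta0 <- bisect_root(f, 1e-6, hi)
  new_prior("gamma_rate_prior",
            list(alpha0 = 1 + m0 * beta0, beta0 = beta0),
            list(gamma = gamma, l1 = l1, u1 = u1, m0 = m0,
                 residual = abs(f(beta0))))
}

#' Prior-data conflict check for a normal mean
#'
#' Compares the observed sample mean with its prior predictive distribution
#' `N(mu0, tau0^2 + sigma0^2/n)`: the two-sided tail probability
#' `2 (1 - pnorm(|xbar - mu0| / sqrt(tau0^2 + sigma0^2/n)))`
#' is small when the observed minimal sufficient statistic lies in the tails
#' of its prior predictive, indicating that the prior and the data are in
#' conflict and the elicitation should be revisited.
#'
#' @param xbar Observed sample mean.
#' @param n Sample size.
#' @param sigma0 Known sampling standard deviation.
#' @param prior A `normal_prior` for the mean.
#' @return The tail probability, a number in `[0, 1]`.
#' @examples
#' prior_data_conflict(20.188, 10, 1, elicit_normal(10, 25))
#' @export
prior_data_conflict <- function(xbar, n, sigma0, prior) {
  assert_scalar(xbar)
  n <- assert_count(n)
  assert_scalar(sigma0, positive = TRUE)
  if (!inherits(prior, "normal_prior")) abort("`prior` must be a `normal_prior`")
  sd_pred <- sqrt(prior$tau0^2 + sigma0^2 / n)
  2 * (1 - pnorm(abs(xbar - prior$mu0) / sd_pred))
}
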