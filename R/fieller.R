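#' Fieller's ratio-of-means problem
#'
#' Two independent normal samples with known common variance `sigma0^2` have
#' means `mu` and `nu`; interest is in the ratio `psi = mu / nu`. The minimal
#' sufficient statistic is the pair of sample means. With independent
#' conjugate priors `mu ~ N(mu0, tau10^2)` and `nu ~ N(nu0, tau20^2)` the
#' marginal prior (and posterior) density of `psi` is available in closed
#' form, so the relative belief ratio is exact, while the reported inferences
#' use the `delta`-discretized form to respect the meaningful difference.
#'
#' @param xbar,ybar Observed sample means of the numerator and denominator
#'   samples.
#' @param nx,ny Sample sizes.
#' @param sigma0 Known common sampling standard deviation.
#' @return `fieller_data()` returns a `fieller_data` list.
#' @examples
#' fieller_data(20.188, 10.699, 10, 10, 1)
#' @export
fieller_data <- function(xbar, ybar, nx, ny, sigma0) {
  assert_scalar(xbar); assert_scalar(ybar)
  nx <- assert_count(nx); ny <- assert_count(ny)
  assert_scalar(sigma0, positive = TRUE)
  structure(list(xbar = xbar, ybar = ybar, nx = nx, ny = ny, sigma0 = sigma0),
            class = "fieller_data")
}

#' @rdname fieller_data
#' @param mu_prior,nu_prior Independent `normal_prior` objects for the
#'   numerator and denominator means.
#' @export
fieller_priors <- function(mu_prior, nu_prior) {
  if (!inherits(mu_prior, "normal_prior") || !inherits(nu_prior, "normal_prior")) {
    abort("both priors must be `normal_prior` objects")
  }
  structure(list(mu = mu_prior, nu = nu_prior), class = "fieller_priors")
}

#' @export
print.fieller_priors <- function(x, ...) {
  cat(sprintf("<fieller_priors> mu ~ N(%.6g, %.6g^2), nu ~ N(%.6g, %.6g^2)\n",
              x$mu$mu0, x$mu$tau0, x$nu$mu0, x$nu$tau0))
  invisible(x)
}

#' Conjugate posterior hyperparameters
#'
#' The posterior under independent normal priors is again a pair of
#' independent normals, with precision-weighted locations
#' `mu(xbar) = (nx/sigma0^2 + 1/tau10^2)^{-1} (nx xbar/sigma0^2 + mu0/tau10^2)`
#' and similarly for `nu(ybar)`. Because posterior and prior share the family,
#' every prior-level computation (the closed-form `psi` density in
#' particular) applies verbatim to the posterior.
#'
#' @param priors A [fieller_priors()] object.
#' @param data A [fieller_data()] object.
#' @return A `fieller_priors` object holding the posterior hyperparameters.
#' @export
fieller_posterior <- function(priors, data) {
  check_fieller(priors, data)
  upd <- function(pr, xbar, n) {
    v <- 1 / (n / data$sigma0^2 + 1 / pr$tau0^2)
    normal_prior(v * (n * xbar / data$sigma0^2 + pr$mu0 / pr$tau0^2), sqrt(v))
  }
  fieller_priors(upd(priors$mu, data$xbar, data$nx),
                 upd(priors$nu, data$ybar, data$ny))
}

check_fieller <- function(priors = NULL, data = NULL) {
  if (!is.null(priors) && !inherits(priors, "fieller_priors")) {
    abort("`priors` must be a `fieller_priors` object")
  }
  if (!is.null(data) && !inherits(data, "fieller_data")) {
    abort("`data` must be a `fieller_data` object")
  }
  invisible(NULL)
}

#' Conditional-density parameters of the ratio fiber
#'
#' On the fiber `mu = psi * nu` the two normal priors combine into a single
#' normal in `nu` with variance
#' `tau2_psi = (psi^2/tau10^2 + 1/tau20^2)^{-1}` and location
#' `nu0_psi = tau2_psi (psi mu0/tau10^2 + nu0/tau20^2)`. These parameters
#' drive both the closed-form marginal density of `psi` and the conditional
#' prior of `nu` given `psi`; `z0 = -nu0_psi / sqrt(tau2_psi)` is the
#' standardized point where the weight `|nu|` changes sign.
#'
#' @param psi Numeric vector of ratio values.
#' @inheritParams fieller_posterior
#' @return A tibble with columns `psi`, `tau2_psi`, `nu0_psi`, `z0`.
#' @examples
#' pr <- fieller_priors(elicit_normal(10, 25),
#'                      elicit_fieller_nu(elicit_normal(10, 25), 10, 25, 1, 3, 2))
#' psi_cond_params(2, pr)  # tau2_psi = 1.5239, nu0_psi = 8.7502, z0 = -7.0883
#' @export
psi_cond_params <- function(psi, priors) {
  check_fieller(priors)
  t1 <- priors$mu$tau0
  t2 <- priors$nu$tau0
  tau2_psi <- 1 / (psi^2 / t1^2 + 1 / t2^2)
  nu0_psi <- tau2_psi * (psi * priors$mu$mu0 / t1^2 + priors$nu$mu0 / t2^2)
  tibble(psi = psi, tau2_psi = tau2_psi, nu0_psi = nu0_psi,
         z0 = -nu0_psi / sqrt(tau2_psi))
}

#' Exact marginal density of the ratio of means
#'
#' Closed form for the density of `psi = mu / nu` when
#' `mu ~ N(mu0, tau10^2)` independent of `nu ~ N(nu0, tau20^2)`:
#' integrating `|nu|` times the joint normal along the fiber `mu = psi nu`
#' gives, with `c = nu0_psi / sqrt(tau2_psi)` from [psi_cond_params()],
#' \deqn{\pi_\Psi(\psi) = \frac{2\,\tau^2(\psi)}{\sqrt{2\pi}\,\tau_{10}\tau_{20}}
#'   \exp\left\{-\frac{(\mu_0 - \nu_0\psi)^2}{2(\psi^2\tau_{20}^2 + \tau_{10}^2)}\right\}
#'   \left\{\varphi(c) + c\,(\Phi(c) - 1/2)\right\}.}
#' When `mu0 = nu0 = 0` this reduces to a rescaled Cauchy density, which is
#' why ratio parameters have such long tails. The same formula evaluated at
#' the posterior hyperparameters ([fieller_posterior()]) is the posterior
#' density, so the exact relative belief ratio [fieller_rb()] is a ratio of
#' two evaluations.
#'
#' @inheritParams psi_cond_params
#' @return Numeric vector of density values.
#' @export
fieller_psi_density <- function(psi, priors) {
  check_fieller(priors)
  mu0 <- priors$mu$mu0
  nu0 <- priors$nu$mu0
  t1 <- priors$mu$tau0
  t2 <- priors$nu$tau0
  cp <- psi_cond_params(psi, priors)
  cc <- cp$nu0_psi / sqrt(cp$tau2_psi)
  2 * cp$tau2_psi / (sqrt(2 * pi) * t1 * t2) *
    exp(-0.5 * (mu0 - nu0 * psi)^2 / (psi^2 * t2^2 + t1^2)) *
    (dnorm(cc) + cc * (pnorm(cc) - 0.5))
}

#' @rdname fieller_psi_density
#' @param data A [fieller_data()]; the posterior density is the prior-form
#'   density at the updated hyperparameters.
#' @export
fieller_psi_posterior_density <- function(psi, priors, data) {
  fieller_psi_density(psi, fieller_posterior(priors, data))
}

#' Exact relative belief ratio for the ratio of means
#'
#' Ratio of the closed-form posterior to prior density of `psi`; by the
#' Savage-Dickey identity this equals the ratio of the conditional to the
#' marginal prior predictive of the data, and it is the efficient route for
#' the bias computations, which require one evaluation per simulated dataset.
#'
#' @inheritParams fieller_psi_posterior_density
#' @export
fieller_rb <- function(psi, priors, data) {
  fieller_psi_posterior_density(psi, priors, data) /
    fieller_psi_density(psi, priors)
}

# ---- pivotal confidence regions --------------------------------------------

#' Invert the normal pivotal for the ratio of means
#'
#' The pivotal `(xbar - psi ybar) / (sigma0 sqrt(1/nx + psi^2/ny)) ~ N(0,1)`
#' yields a gamma-confidence region by solving the quadratic
#' `(xbar - psi ybar)^2 <= z^2 sigma0^2 (1/nx + psi^2/ny)` in `psi`. The
#' solution set is classified by the leading coefficient
#' `A = ybar^2 - z^2 sigma0^2/ny` and the discriminant: an interval when
#' `A > 0`; an *exclusive* region `(-Inf, a) U (b, Inf)` when `A < 0` with
#' real roots; and the whole line -- an improper region -- exactly when
#' `|ybar| < z sigma0/sqrt(ny)` and `nx xbar^2 + ny ybar^2 < z^2 sigma0^2`.
#'
#' @param data A [fieller_data()].
#' @param gamma Confidence level, default 0.95.
#' @return A `pivotal_region`: list with `kind` (one of `"interval"`,
#'   `"exclusive"`, `"half_line"`, `"whole_line"`), `endpoints` (up to 2
#'   values) and `gamma`.
#' @examples
#' pivotal_region(fieller_data(20.188, 10.699, 10, 10, 1))  # (1.769, 2.017)
#' pivotal_region(fieller_data(0.5, 0.5, 1, 1, 1))          # improper
#' @export
pivotal_region <- function(data, gamma = 0.95) {
  check_fieller(data = data)
  assert_prob(gamma)
  z <- qnorm((1 + gamma) / 2)
  s0 <- data$sigma0
  A <- data$ybar^2 - z^2 * s0^2 / data$ny
  B <- -2 * data$xbar * data$ybar
  C <- data$xbar^2 - z^2 * s0^2 / data$nx
  out <- function(kind, endpoints = numeric()) {
    structure(list(kind = kind, endpoints = endpoints, gamma = gamma),
              class = "pivotal_region")
  }
  if (A == 0) {
    # linear boundary: one finite endpoint
    if (B == 0) return(out(if (C <= 0) "whole_line" else "empty"))
    root <- -C / B
    return(out("half_line", if (B > 0) c(-Inf, root) else c(root, Inf)))
  }
  D <- B^2 - 4 * A * C
  if (A > 0) {
    if (D < 0) return(out("empty"))
    r <- sort(c((-B - sqrt(D)) / (2 * A), (-B + sqrt(D)) / (2 * A)))
    return(out("interval", r))
  }
  if (D <= 0) return(out("whole_line"))
  r <- sort(c((-B - sqrt(D)) / (2 * A), (-B + sqrt(D)) / (2 * A)))
  out("exclusive", r)
}

#' @export
print.pivotal_region <- function(x, ...) {
  desc <- switch(x$kind,
    interval = sprintf("(%.4g, %.4g)", x$endpoints[1], x$endpoints[2]),
    exclusive = sprintf("(-Inf, %.4g) U (%.4g, Inf)",
                        x$endpoints[1], x$endpoints[2]),
    half_line = sprintf("(%.4g, %.4g)", x$endpoints[1], x$endpoints[2]),
    whole_line = "the whole real line (improper)",
    empty = "empty (improper)"
  )
  cat(sprintf("<pivotal_region> %g-confidence region for psi: %s\n",
              x$gamma, desc))
  invisible(x)
}

#' @export
glance.pivotal_region <- function(x, ...) {
  tibble(
    kind = x$kind,
    lower = if (length(x$endpoints)) x$endpoints[1] else NA_real_,
    upper = if (length(x$endpoints)) x$endpoints[2] else NA_real_,
    gamma = x$gamma,
    improper = x$kind %in% c("whole_line", "empty")
  )
}

# ---- conditional prior of nu given psi -------------------------------------

# Draws from the density proportional to |z + c| * dnorm(z): the standardized
# conditional prior on the ratio fiber. The closed-form cdf has total mass
# K = 2 dnorm(c) + c (2 pnorm(c) - 1) (= E|Z + c|) and is inverted by
# vectorized bisection; c may vary per draw.
r_weighted_z <- function(n, c) {
  c <- rep_len(c, n)
  K <- 2 * dnorm(c) + c * (2 * pnorm(c) - 1)
  G <- function(z) {
    low <- dnorm(z) - c * pnorm(z)
    at <- dnorm(c) - c * pnorm(-c)
    high <- at + dnorm(c) - dnorm(z) + c * (pnorm(z) - pnorm(-c))
    ifelse(z <= -c, low, high)
  }
  target <- runif(n) * K
  lo <- rep(-13, n) + pmin(-c, 0)
  hi <- rep(13, n) + pmax(-c, 0)
  for (i in 1:64) {
    mid <- (lo + hi) / 2
    below <- G(mid) < target
    lo <- ifelse(below, mid, lo)
    hi <- ifelse(below, hi, mid)
  }
  (lo + hi) / 2
}

#' Conditional prior of the denominator mean given the ratio
#'
#' Conditioning the joint prior of `(mu, nu)` on `psi = mu / nu` introduces
#' the Jacobian factor `|nu|` along the fiber, so
#' `pi(nu | psi) \propto |nu| N(nu0_psi, tau2_psi)` with the fiber parameters
#' of [psi_cond_params()]. `dnu_given_psi()` evaluates the normalized
#' density; `sample_nu_given_psi()` draws from it by closed-form cdf
#' inversion of the `|z + c|`-weighted standard normal.
#'
#' @param nu Numeric vector of evaluation points.
#' @param psi Ratio value; for sampling, a scalar or a vector of length
#'   `n_draws` (one conditioning value per draw).
#' @inheritParams fieller_posterior
#' @param n_draws Number of draws.
#' @param seed Optional integer seed.
#' @return Density values, or a numeric vector of draws.
#' @export
dnu_given_psi <- function(nu, psi, priors) {
  cp <- psi_cond_params(psi, priors)
  s <- sqrt(cp$tau2_psi)
  cc <- cp$nu0_psi / s
  K <- 2 * dnorm(cc) + cc * (2 * pnorm(cc) - 1)
  abs(nu) * dnorm(nu, cp$nu0_psi, s) / (s * K)
}

#' @rdname dnu_given_psi
#' @export
sample_nu_given_psi <- function(psi, priors, n_draws, seed = NULL) {
  check_fieller(priors)
  n_draws <- assert_count(n_draws)
  if (!length(psi) %in% c(1L, n_draws)) {
    abort("`psi` must have length 1 or `n_draws`")
  }
  cp <- psi_cond_params(psi, priors)
  s <- sqrt(cp$tau2_psi)
  cc <- cp$nu0_psi / s
  with_seed_if(seed, cp$nu0_psi + s * r_weighted_z(n_draws, cc))
}

#' Sample the conditional prior predictive given the ratio
#'
#' Composes the sequential scheme for drawing the minimal sufficient
#' statistic from `M(. | psi)`: draw `nu` from the conditional prior given
#' `psi`, then `ybar ~ N(nu, sigma0^2/ny)` and
#' `xbar ~ N(psi nu, sigma0^2/nx)`.
#'
#' @inheritParams sample_nu_given_psi
#' @param nx,ny,sigma0 Shape of the data to be generated.
#' @return A tibble with columns `nu`, `ybar`, `xbar` and `n_draws` rows.
#' @export
sample_fieller_predictive <- function(psi, priors, nx, ny, sigma0, n_draws,
                                      seed = NULL) {
  nx <- assert_count(nx); ny <- assert_count(ny)
  assert_scalar(sigma0, positive = TRUE)
  n_draws <- assert_count(n_draws)
  with_seed_if(seed, {
    nu <- sample_nu_given_psi(psi, priors, n_draws)
    ybar <- rnorm(n_draws, nu, sigma0 / sqrt(ny))
    xbar <- rnorm(n_draws, psi * nu, sigma0 / sqrt(nx))
    tibble(nu = nu, ybar = ybar, xbar = xbar)
  })
}

# ---- discretized inference --------------------------------------------------

#' Relative belief inference for the ratio of means
#'
#' Full discretized pipeline: draw `(mu, nu)` from the prior and the
#' conjugate posterior, map to `psi = mu / nu`, trim the long-tailed prior
#' range ([effective_range()]), bin both samples on a `delta`-grid, and read
#' off the plausible region, the relative belief estimate and the contents.
#'
#' An optional strictly monotone transform can be supplied for very
#' long-tailed problems; the draws and the grid then live on the transformed
#' scale and all region endpoints are mapped back, which is legitimate
#' because relative belief inferences are invariant under reparameterization.
#'
#' @inheritParams fieller_posterior
#' @param delta Meaningful difference for `psi` (bin width).
#' @param reps Monte Carlo sample size for each of prior and posterior.
#' @param tail_mass Prior mass trimmed from the tails, split equally.
#' @param gamma Optional credible-region level to compute alongside.
#' @param transform Optional list with elements `fun` and `inv`, a strictly
#'   increasing map and its inverse (e.g. a long-tailed cdf); `delta` is then
#'   interpreted on the transformed scale.
#' @param seed Optional integer seed.
#' @return A `fieller_fit` list: `profile` (the [relative_belief()] tibble),
#'   `plausible`, optionally `credible`, `pivotal` (at 0.95), `posterior`
#'   hyperparameters, and the call settings.
#' @examples
#' \donttest{
#' mu_pr <- elicit_normal(10, 25)
#' pr <- fieller_priors(mu_pr, elicit_fieller_nu(mu_pr, 10, 25, 1, 3, 2))
#' fit <- fieller_infer(fieller_data(20.188, 10.699, 10, 10, 1), pr,
#'                      delta = 0.1, reps = 1e4, seed = 1)
#' glance(fit)
#' }
#' @export
fieller_infer <- function(data, priors, delta = 0.1, reps = 1e5,
                          tail_mass = 0.001, gamma = NULL, transform = NULL,
                          seed = NULL) {
  check_fieller(priors, data)
  assert_scalar(delta, positive = TRUE)
  reps <- assert_count(reps)
  with_seed_if(seed, {
    post <- fieller_posterior(priors, data)
    draw_psi <- function(pr) {
      prior_sample(pr$mu, reps) / prior_sample(pr$nu, reps)
    }
    psi_prior <- draw_psi(priors)
    psi_post <- draw_psi(post)
    if (!is.null(transform)) {
      psi_prior <- transform$fun(psi_prior)
      psi_post <- transform$fun(psi_post)
    }
    rng <- effective_range(psi_prior, tail_mass)
    grid <- rb_grid(rng[1], rng[2], delta, tail_mass = tail_mass)
    profile <- relative_belief(discretize(psi_prior, psi_post, grid))
    pl <- plausible_region(profile)
    if (!is.null(transform)) {
      pl$intervals$lower <- transform$inv(pl$intervals$lower)
      pl$intervals$upper <- transform$inv(pl$intervals$upper)
      if (!is.na(pl$estimate)) pl$estimate <- transform$inv(pl$estimate)
    }
    cred <- if (!is.null(gamma)) credible_region(profile, gamma)
    structure(
      list(
        profile = profile,
        plausible = pl,
        credible = cred,
        pivotal = pivotal_region(data, 0.95),
        posterior = post,
        data = data, priors = priors,
        delta = delta, reps = reps, tail_mass = tail_mass, seed = seed
      ),
      class = "fieller_fit"
    )
  })
}

#' @export
print.fieller_fit <- function(x, ...) {
  cat("Relative belief inference for psi = mu / nu\n")
  cat(sprintf("  delta = %g, reps = %g, trimmed tail mass = %g\n",
              x$delta, x$reps, x$tail_mass))
  print(x$plausible)
  print(x$pivotal)
  invisible(x)
}

#' @export
tidy.fieller_fit <- function(x, ...) as_tibble(x$profile)

#' @export
glance.fieller_fit <- function(x, ...) {
  pl <- x$plausible
  tibble(
    estimate = pl$estimate,
    pl_lower = if (nrow(pl$intervals)) min(pl$intervals$lower) else NA_real_,
    pl_upper = if (nrow(pl$intervals)) max(pl$intervals$upper) else NA_real_,
    pl_intervals = nrow(pl$intervals),
    posterior_content = pl$posterior_content,
    prior_content = pl$prior_content,
    no_evidence = pl$no_evidence,
    delta = x$delta,
    reps = x$reps
  )
}

#' Evidence model adapter for the bias engine
#'
#' Wraps the Fieller configuration into the generic [evidence_model()]
#' contract: prior draws of `psi`, predictive sampling through the
#' fiber-conditional prior of `nu`, and the exact closed-form relative
#' belief ratio.
#'
#' @inheritParams sample_fieller_predictive
#' @export
fieller_evidence_model <- function(priors, nx, ny, sigma0) {
  check_fieller(priors)
  nx <- assert_count(nx); ny <- assert_count(ny)
  assert_scalar(sigma0, positive = TRUE)
  evidence_model(
    sample_psi = function(n) {
      prior_sample(priors$mu, n) / prior_sample(priors$nu, n)
    },
    sample_data = function(psi) {
      n <- length(psi)
      nu <- sample_nu_given_psi(psi, priors, n)
      tibble(
        xbar = rnorm(n, psi * nu, sigma0 / sqrt(nx)),
        ybar = rnorm(n, nu, sigma0 / sqrt(ny))
      )
    },
    rb = function(psi0, data) {
      post_mu_var <- 1 / (nx / sigma0^2 + 1 / priors$mu$tau0^2)
      post_nu_var <- 1 / (ny / sigma0^2 + 1 / priors$nu$tau0^2)
      m1 <- post_mu_var * (nx * data$xbar / sigma0^2 +
                             priors$mu$mu0 / priors$mu$tau0^2)
      m2 <- post_nu_var * (ny * data$ybar / sigma0^2 +
                             priors$nu$mu0 / priors$nu$tau0^2)
      num <- fieller_density_vec(psi0, m1, sqrt(post_mu_var), m2,
                                 sqrt(post_nu_var))
      den <- fieller_psi_density(psi0, priors)
      num / den
    },
    name = sprintf("Fieller ratio of means (nx = %d, ny = %d)", nx, ny)
  )
}

# density of psi when mu ~ N(m1, s1^2), nu ~ N(m2, s2^2); all arguments may
# be vectors (recycled), unlike fieller_psi_density() which takes a priors
# object
fieller_density_vec <- function(psi, m1, s1, m2, s2) {
  t2p <- 1 / (psi^2 / s1^2 + 1 / s2^2)
  n0p <- t2p * (psi * m1 / s1^2 + m2 / s2^2)
  cc <- n0p / sqrt(t2p)
  2 * t2p / (sqrt(2 * pi) * s1 * s2) *
    exp(-0.5 * (m1 - m2 * psi)^2 / (psi^2 * s2^2 + s1^2)) *
    (dnorm(cc) + cc * (pnorm(cc) - 0.5))
}
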