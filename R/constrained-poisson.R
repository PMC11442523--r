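#' Poisson model with a constrained rate
#'
#' Count data `x_1, ..., x_n` i.i.d. Poisson with rate `lambda` known to lie
#' in `(l0, u0)` (e.g. a physical event rate with a guaranteed floor and
#' ceiling). The sufficient statistic is the total count
#' `s ~ Poisson(n lambda)`. The prior is a gamma (rate parameterization)
#' restricted to the constraint interval; gamma-Poisson conjugacy makes every
#' predictive quantity available in closed form (negative binomial masses
#' times truncation-probability ratios), so the bias quantities are computed
#' by exact enumeration over the total count rather than simulation.
#'
#' @param prior A `gamma_rate_prior`, e.g. from [elicit_gamma_rate()].
#' @param l0,u0 Constraint interval for the rate, `0 < l0 < u0`.
#' @param n Number of count observations.
#' @param delta Meaningful difference for the rate; the relative belief
#'   ratio of a hypothesized rate is that of the interval
#'   `lambda +/- delta/2`.
#' @return A `constrained_poisson_model` list.
#' @examples
#' constrained_poisson_model(elicit_gamma_rate(3.5, 9.5), 3, 10, n = 20)
#' @export
constrained_poisson_model <- function(prior, l0, u0, n, delta = 0.5) {
  if (!inherits(prior, "gamma_rate_prior")) {
    abort("`prior` must be a `gamma_rate_prior`")
  }
  assert_scalar(l0, positive = TRUE)
  assert_scalar(u0, positive = TRUE)
  if (u0 <= l0) abort("`u0` must exceed `l0`")
  n <- assert_count(n)
  assert_scalar(delta, positive = TRUE)
  structure(
    list(prior = prior, l0 = l0, u0 = u0, n = n, delta = delta,
         prior_trunc_mass = prior_cdf(prior, u0) - prior_cdf(prior, l0)),
    class = "constrained_poisson_model"
  )
}

#' @export
print.constrained_poisson_model <- function(x, ...) {
  cat(sprintf(
    "<constrained_poisson_model> Poisson(lambda), lambda in (%g, %g), n = %d, delta = %g\n",
    x$l0, x$u0, x$n, x$delta
  ))
  cat(sprintf("  prior: gamma_rate(%.4g, %.4g) truncated to the constraint\n",
              x$prior$alpha0, x$prior$beta0))
  invisible(x)
}

check_cpois <- function(model) {
  if (!inherits(model, "constrained_poisson_model")) {
    abort("`model` must be a `constrained_poisson_model`")
  }
  invisible(model)
}

# posterior over lambda given total count s is gamma(alpha0 + s, beta0 + n),
# truncated to (l0, u0); interval probabilities under prior/posterior
interval_prob <- function(model, a, b, s = NULL) {
  alpha <- model$prior$alpha0 + (s %||% 0)
  beta <- model$prior$beta0 + if (is.null(s)) 0 else model$n
  pgamma(b, alpha, rate = beta) - pgamma(a, alpha, rate = beta)
}

#' Prior predictive mass of the total count
#'
#' For the truncated gamma prior the predictive of `s = sum(x_i)` is the
#' negative binomial predictive of the untruncated prior times the ratio of
#' posterior to prior truncation masses.
#'
#' @param model A [constrained_poisson_model()].
#' @param s Vector of total counts.
#' @return Predictive probabilities `m(s)`.
#' @export
poisson_predictive <- function(model, s) {
  check_cpois(model)
  pr <- model$prior
  base <- dnbinom(s, size = pr$alpha0,
                  prob = pr$beta0 / (pr$beta0 + model$n))
  base * interval_prob(model, model$l0, model$u0, s) / model$prior_trunc_mass
}

#' Relative belief ratios for a constrained Poisson rate
#'
#' `rb_lambda()` is the pointwise Savage-Dickey ratio
#' `dpois(s, n lambda_star) / m(s)`. `rb_lambda_interval()` is the relative
#' belief ratio of the interval `lambda_star +/- width/2` (intersected with
#' the constraint): the ratio of its posterior to its prior probability.
#' The interval form is the one the meaningful difference calls for and is
#' used by all the bias computations.
#'
#' @inheritParams poisson_predictive
#' @param lambda_star Hypothesized rate inside the constraint interval.
#' @param width Interval width; defaults to the model's `delta`.
#' @return Numeric vector of relative belief ratios, one per element of `s`.
#' @export
rb_lambda <- function(model, lambda_star, s) {
  check_cpois(model)
  check_lambda(model, lambda_star)
  # log scale: both numerator and predictive underflow far in the tails
  pr <- model$prior
  log_m <- dnbinom(s, size = pr$alpha0, prob = pr$beta0 / (pr$beta0 + model$n),
                   log = TRUE) +
    log(interval_prob(model, model$l0, model$u0, s)) -
    log(model$prior_trunc_mass)
  log_num <- dpois(s, model$n * lambda_star, log = TRUE)
  bad <- !is.finite(log_m) & log_num > -600
  if (any(bad)) abort("prior predictive underflow at the supplied counts")
  out <- exp(log_num - log_m)
  out[!is.finite(log_m)] <- 0
  out
}

#' @rdname rb_lambda
#' @export
rb_lambda_interval <- function(model, lambda_star, s, width = model$delta) {
  check_cpois(model)
  check_lambda(model, lambda_star)
  a <- max(model$l0, lambda_star - width / 2)
  b <- min(model$u0, lambda_star + width / 2)
  prior_B <- interval_prob(model, a, b) / model$prior_trunc_mass
  post_B <- interval_prob(model, a, b, s) /
    interval_prob(model, model$l0, model$u0, s)
  post_B / prior_B
}

check_lambda <- function(model, lambda_star) {
  assert_scalar(lambda_star, positive = TRUE)
  if (lambda_star <= model$l0 || lambda_star >= model$u0) {
    abort("`lambda_star` must lie inside the constraint interval")
  }
  invisible(lambda_star)
}

# total-count range covering all but ~1e-12 of Poisson(n * lambda) mass
count_range <- function(n, lambda) {
  qpois(1e-13, n * lambda):qpois(1 - 1e-13, n * lambda)
}

#' Bias quantities for the constrained Poisson rate
#'
#' All bias quantities are exact sums over the total count (no Monte Carlo):
#' `poisson_bias_against()` is `P(RB(lambda_star | s) <= 1)` with
#' `s ~ Poisson(n lambda_star)`; `poisson_bias_in_favor()` generates the
#' count at the displaced rates `lambda_star +/- displacement` (full-`delta`
#' displacement by default, the convention of the constrained-rate analyses)
#' and takes the larger probability of `RB >= 1`; the relative belief ratio
#' is the interval form [rb_lambda_interval()].
#'
#' @inheritParams rb_lambda
#' @param displacement Displacement of the generating rate.
#' @return One-row tibbles.
#' @export
poisson_bias_against <- function(model, lambda_star) {
  check_cpois(model)
  check_lambda(model, lambda_star)
  s <- count_range(model$n, lambda_star)
  rb <- rb_lambda_interval(model, lambda_star, s)
  tibble(
    lambda_star = lambda_star,
    bias_against = sum(dpois(s, model$n * lambda_star)[rb <= 1]),
    n = model$n, delta = model$delta
  )
}

#' @rdname poisson_bias_against
#' @export
poisson_bias_in_favor <- function(model, lambda_star,
                                  displacement = model$delta) {
  check_cpois(model)
  check_lambda(model, lambda_star)
  vals <- rep(NA_real_, 2)
  sides <- lambda_star + c(-1, 1) * displacement
  for (i in 1:2) {
    if (sides[i] <= model$l0 || sides[i] >= model$u0) {
      inform(sprintf("alternative %g outside the constraint interval; skipped",
                     sides[i]))
      next
    }
    s <- count_range(model$n, sides[i])
    rb <- rb_lambda_interval(model, lambda_star, s)
    vals[i] <- sum(dpois(s, model$n * sides[i])[rb >= 1])
  }
  if (all(is.na(vals))) abort("both alternatives fall outside the constraint interval")
  tibble(
    lambda_star = lambda_star, displacement = displacement,
    favor_lower = vals[1], favor_upper = vals[2],
    bias_in_favor = max(vals, na.rm = TRUE),
    n = model$n, delta = model$delta
  )
}

#' Confidence bounds for the constrained-Poisson plausible region
#'
#' Traces the bias against over the delta-grid of representable rates
#' `l0 + (i - 1/2) delta`, and reports the frequentist lower bound
#' `1 - max(curve)` together with the Bayesian confidence
#' `1 - E_prior(curve)` (grid values weighted by the truncated-prior mass of
#' their bins).
#'
#' @inheritParams poisson_bias_against
#' @return One-row tibble with `freq_confidence`, `bayes_confidence`, `n`,
#'   `delta`; the per-rate curve is attached as attribute `"curve"`.
#' @export
poisson_confidence <- function(model) {
  check_cpois(model)
  grid <- model$l0 +
    (seq_len(floor((model$u0 - model$l0) / model$delta + 1e-9)) - 0.5) *
    model$delta
  ba <- vapply(grid, function(l) poisson_bias_against(model, l)$bias_against,
               numeric(1))
  w <- interval_prob(model, pmax(grid - model$delta / 2, model$l0),
                     pmin(grid + model$delta / 2, model$u0))
  w <- w / sum(w)
  out <- tibble(
    freq_confidence = 1 - max(ba),
    bayes_confidence = 1 - sum(w * ba),
    n = model$n, delta = model$delta
  )
  attr(out, "curve") <- tibble(lambda = grid, bias_against = ba)
  out
}

#' @rdname poisson_bias_against
#' @return `poisson_bias_suite()` combines the four quantities in one row.
#' @export
poisson_bias_suite <- function(model, lambda_star,
                               displacement = model$delta) {
  ba <- poisson_bias_against(model, lambda_star)
  bf <- poisson_bias_in_favor(model, lambda_star, displacement)
  conf <- poisson_confidence(model)
  out <- tibble(
    lambda_star = lambda_star,
    bias_against = ba$bias_against,
    bias_in_favor = bf$bias_in_favor,
    freq_confidence = conf$freq_confidence,
    bayes_confidence = conf$bayes_confidence,
    n = model$n, delta = model$delta, displacement = displacement
  )
  attr(out, "curve") <- attr(conf, "curve")
  out
}
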