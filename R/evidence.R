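#' Discretize prior and posterior draws onto a grid
#'
#' Estimates the per-bin prior and posterior probability contents of the
#' parameter of interest by binning Monte Carlo draws, the density-histogram
#' approximation underlying all discretized relative belief inferences.
#' Draws falling outside the grid are tallied separately (they belong to the
#' trimmed tails), so the per-bin masses sum to at most 1.
#'
#' @param prior_draws,posterior_draws Numeric vectors of draws from the prior
#'   and posterior distribution of the parameter of interest.
#' @param grid An [rb_grid()].
#'
#' @return A tibble of class `rb_profile` with one row per bin and columns
#'   `bin`, `midpoint`, `prior_mass`, `posterior_mass`. Attributes record the
#'   grid, the numbers of draws and the out-of-grid (tail) proportions.
#' @seealso [relative_belief()], [plausible_region()]
#' @export
discretize <- function(prior_draws, posterior_draws, grid) {
  if (!inherits(grid, "rb_grid")) abort("`grid` must be an `rb_grid`")
  if (length(prior_draws) == 0 || length(posterior_draws) == 0) {
    abort("draw vectors must be non-empty")
  }
  if (!all(is.finite(prior_draws)) || !all(is.finite(posterior_draws))) {
    abort("draws must be finite")
  }
  bin_mass <- function(x) {
    idx <- findInterval(x, grid$breaks)
    inside <- idx >= 1L & idx <= grid$n_bins & x < grid$hi
    list(
      mass = tabulate(idx[inside], grid$n_bins) / length(x),
      tail = 1 - mean(inside)
    )
  }
  pr <- bin_mass(prior_draws)
  po <- bin_mass(posterior_draws)
  out <- tibble(
    bin = seq_len(grid$n_bins),
    midpoint = grid$midpoints,
    prior_mass = pr$mass,
    posterior_mass = po$mass
  )
  new_rb_profile(out, grid,
                 n_prior = length(prior_draws),
                 n_posterior = length(posterior_draws),
                 prior_tail = pr$tail, posterior_tail = po$tail)
}

#' Construct a mass profile directly from per-bin masses
#'
#' Useful when per-bin prior and posterior contents are available exactly
#' (closed form or quadrature) rather than through simulation.
#'
#' @param midpoint Strictly increasing, equally spaced bin midpoints.
#' @param prior_mass,posterior_mass Nonnegative per-bin masses, each summing
#'   to at most 1 (up to any trimmed tail mass).
#' @param delta Bin width; inferred from `midpoint` spacing when `NULL`.
#' @return A tibble of class `rb_profile`; see [discretize()].
#' @export
mass_profile <- function(midpoint, prior_mass, posterior_mass, delta = NULL) {
  n <- length(midpoint)
  if (n < 1 || length(prior_mass) != n || length(posterior_mass) != n) {
    abort("`midpoint`, `prior_mass` and `posterior_mass` must share a length >= 1")
  }
  if (any(prior_mass < 0) || any(posterior_mass < 0)) {
    abort("masses must be nonnegative")
  }
  if (sum(prior_mass) > 1 + 1e-8 || sum(posterior_mass) > 1 + 1e-8) {
    abort("masses must sum to at most 1")
  }
  if (is.null(delta)) {
    delta <- if (n > 1) diff(midpoint)[1] else 1
  }
  if (n > 1 && max(abs(diff(midpoint) - delta)) > 1e-8 * delta) {
    abort("`midpoint` must be equally spaced with spacing `delta`")
  }
  grid <- rb_grid(midpoint[1] - delta / 2, midpoint[n] + delta / 2, delta,
                  align = FALSE)
  out <- tibble(
    bin = seq_len(n), midpoint = grid$midpoints,
    prior_mass = prior_mass, posterior_mass = posterior_mass
  )
  new_rb_profile(out, grid,
                 n_prior = NA_integer_, n_posterior = NA_integer_,
                 prior_tail = 1 - sum(prior_mass),
                 posterior_tail = 1 - sum(posterior_mass))
}

new_rb_profile <- function(data, grid, n_prior, n_posterior,
                           prior_tail, posterior_tail) {
  structure(
    data,
    grid = grid,
    n_prior = n_prior, n_posterior = n_posterior,
    prior_tail = prior_tail, posterior_tail = posterior_tail,
    class = c("rb_profile", class(tibble()))
  )
}

#' Relative belief ratios over a mass profile
#'
#' The relative belief ratio of a value of the parameter of interest is the
#' ratio of its posterior to its prior density; on a grid it is the ratio of
#' the posterior to the prior content of the bin. Values with `rb > 1` have
#' evidence in their favor, `rb < 1` evidence against, and `rb = 1` no
#' evidence either way. Bins with zero estimated prior mass carry no evidence
#' information (the ratio is 0/0) and are excluded from all regions.
#'
#' The profile satisfies the normalization identity
#' `sum(rb * prior_mass) = sum(posterior_mass)`, the discrete form of
#' the identity that the relative belief ratio integrates to 1 against the
#' prior; it underlies the impossibility of evidence in favor of (or against)
#' every value at once.
#'
#' @param profile An `rb_profile` from [discretize()] or [mass_profile()].
#' @return The profile with columns `rb` (NA for excluded bins) and
#'   `included`, and attribute `no_evidence` set when every included bin has
#'   `rb` exactly 1 (the data carry no evidence about the parameter).
#' @export
relative_belief <- function(profile) {
  check_profile(profile)
  prior <- profile$prior_mass
  post <- profile$posterior_mass
  if (all(prior == 0)) abort("all bins have zero prior mass")
  included <- prior > 0
  rb <- ifelse(included, post / prior, NA_real_)
  profile$rb <- rb
  profile$included <- included
  attr(profile, "no_evidence") <- all(rb[included] == 1)
  profile
}

check_profile <- function(profile, need_rb = FALSE) {
  if (!inherits(profile, "rb_profile")) {
    abort("`profile` must be an `rb_profile` (see `discretize()`)")
  }
  if (need_rb && is.null(profile$rb)) {
    abort("`profile` has no `rb` column; call `relative_belief()` first")
  }
  invisible(profile)
}

# collapse a set of bin indices into maximal runs of adjacent bins,
# reported as half-open intervals on the grid
bins_to_intervals <- function(bins, grid) {
  if (length(bins) == 0) {
    return(tibble(lower = double(), upper = double()))
  }
  bins <- sort(bins)
  run_start <- bins[c(TRUE, diff(bins) != 1)]
  run_end <- bins[c(diff(bins) != 1, TRUE)]
  tibble(
    lower = grid$breaks[run_start],
    upper = grid$breaks[run_end + 1L]
  )
}

new_rb_region <- function(type, bins, profile, extra = list()) {
  grid <- attr(profile, "grid")
  post <- sum(profile$posterior_mass[bins])
  prior <- sum(profile$prior_mass[bins])
  structure(
    c(
      list(
        type = type,
        bins = as.integer(bins),
        intervals = bins_to_intervals(bins, grid),
        posterior_content = post,
        prior_content = prior,
        delta = grid$delta
      ),
      extra
    ),
    class = "rb_region"
  )
}

#' Plausible region and relative belief estimate
#'
#' The plausible region collects the values of the parameter with evidence in
#' their favor (`rb > 1`); the relative belief estimate is the value
#' maximizing the relative belief ratio. The plausible region can never be
#' the whole parameter space, and is empty only in the probability-zero event
#' that the data carry no evidence at all, so it is never improper. Its
#' posterior content measures how strongly it is believed to contain the true
#' value; its prior content is a measure of its size (how much was learned).
#'
#' @param profile An `rb_profile` with relative belief ratios (from
#'   [relative_belief()]).
#' @return An object of class `rb_region` with elements `bins`, `intervals`
#'   (maximal runs of adjacent bins as half-open intervals; non-adjacent runs
#'   are reported separately, never merged), `estimate`, `posterior_content`,
#'   `prior_content` and `no_evidence`. Ties in the maximizing bin are broken
#'   towards the lowest bin and reported via a message.
#' @seealso [credible_region()], [implausible_region()]
#' @export
plausible_region <- function(profile) {
  check_profile(profile, need_rb = TRUE)
  no_ev <- isTRUE(attr(profile, "no_evidence"))
  bins <- which(profile$included & profile$rb > 1)
  if (no_ev) {
    inform("no evidence: the posterior equals the prior on every bin; the plausible region is empty")
    region <- new_rb_region("plausible", integer(), profile,
                            list(estimate = NA_real_, no_evidence = TRUE))
    return(region)
  }
  rb_inc <- ifelse(profile$included, profile$rb, -Inf)
  top <- which(rb_inc == max(rb_inc))
  if (length(top) > 1) {
    inform(sprintf(
      "tie among %d bins for the relative belief maximum; reporting the lowest (midpoint %g)",
      length(top), profile$midpoint[top[1]]
    ))
  }
  new_rb_region("plausible", bins, profile,
                list(estimate = profile$midpoint[top[1]], no_evidence = FALSE))
}

#' Implausible region
#'
#' The values of the parameter with evidence against them (`rb < 1`). Bins
#' with `rb` exactly 1 (no evidence) belong to neither the plausible nor the
#' implausible region.
#'
#' @inheritParams plausible_region
#' @return An `rb_region`; see [plausible_region()].
#' @export
implausible_region <- function(profile) {
  check_profile(profile, need_rb = TRUE)
  bins <- which(profile$included & profile$rb < 1)
  new_rb_region("implausible", bins, profile,
                list(no_evidence = isTRUE(attr(profile, "no_evidence"))))
}

#' Relative belief credible region
#'
#' The gamma-credible region retains the values with the largest relative
#' belief ratios until posterior probability at least `gamma` is captured:
#' `C_gamma = {psi : rb(psi) >= r_gamma}` where `r_gamma` is the largest
#' threshold whose rejected mass does not exceed `1 - gamma`. Whenever
#' `gamma` does not exceed the posterior content of the plausible region,
#' `C_gamma` is contained in the plausible region, so every reported value
#' has evidence in its favor.
#'
#' @inheritParams plausible_region
#' @param gamma Requested posterior content, in (0, 1).
#' @return An `rb_region` with additional element `r_gamma` and `gamma`.
#' @export
credible_region <- function(profile, gamma) {
  check_profile(profile, need_rb = TRUE)
  assert_prob(gamma)
  inc <- which(profile$included)
  rb <- profile$rb[inc]
  post <- profile$posterior_mass[inc]
  # P(RB < r | x) as a step function over candidate thresholds
  r_vals <- sort(unique(rb))
  mass_below <- vapply(r_vals, function(r) sum(post[rb < r]), numeric(1))
  ok <- r_vals[mass_below <= 1 - gamma]
  r_gamma <- if (length(ok)) max(ok) else 0
  bins <- inc[rb >= r_gamma]
  new_rb_region("credible", bins, profile,
                list(gamma = gamma, r_gamma = r_gamma))
}

#' @export
print.rb_region <- function(x, ...) {
  cat(sprintf("<rb_region: %s>\n", x$type))
  if (nrow(x$intervals) == 0) {
    cat("  empty region",
        if (isTRUE(x$no_evidence)) "(no evidence)" else "", "\n")
  } else {
    iv <- sprintf("[%g, %g)", x$intervals$lower, x$intervals$upper)
    cat("  ", paste(iv, collapse = " U "), "\n", sep = "")
  }
  if (!is.null(x$estimate)) cat(sprintf("  estimate: %g\n", x$estimate))
  if (!is.null(x$gamma)) {
    cat(sprintf("  gamma: %g  r_gamma: %g\n", x$gamma, x$r_gamma))
  }
  cat(sprintf("  posterior content: %.4f   prior content: %.4f\n",
              x$posterior_content, x$prior_content))
  invisible(x)
}

#' @export
tidy.rb_region <- function(x, ...) {
  out <- x$intervals
  out$type <- x$type
  out[c("type", "lower", "upper")]
}

#' @export
glance.rb_region <- function(x, ...) {
  tibble(
    type = x$type,
    n_bins = length(x$bins),
    n_intervals = nrow(x$intervals),
    estimate = x$estimate %||% NA_real_,
    posterior_content = x$posterior_content,
    prior_content = x$prior_content,
    gamma = x$gamma %||% NA_real_,
    r_gamma = x$r_gamma %||% NA_real_,
    no_evidence = x$no_evidence %||% NA
  )
}

#' @export
glance.rb_profile <- function(x, ...) {
  grid <- attr(x, "grid")
  inc <- x$included %||% (x$prior_mass > 0)
  tibble(
    n_bins = grid$n_bins,
    delta = grid$delta,
    lo = grid$lo,
    hi = grid$hi,
    prior_tail = attr(x, "prior_tail"),
    posterior_tail = attr(x, "posterior_tail"),
    max_rb = if (!is.null(x$rb)) max(x$rb[inc]) else NA_real_,
    no_evidence = attr(x, "no_evidence") %||% NA
  )
}

#' Plot a relative belief profile
#'
#' Draws the prior and posterior density histograms (masses scaled by the bin
#' width) and the relative belief ratio with the evidence cut-off at 1.
#'
#' @param object An `rb_profile` with relative belief ratios.
#' @param trim Quantile-based trimming of the plotted range: bins outside the
#'   central posterior-or-prior mass are dropped for readability (the long
#'   tails of ratio parameters make untrimmed plots unreadable). Set to 0 to
#'   plot everything.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rb_profile <- function(object, trim = 0.0025, ...) {
  check_profile(object, need_rb = TRUE)
  delta <- attr(object, "grid")$delta
  keep <- rep(TRUE, nrow(object))
  if (trim > 0) {
    keep_mass <- function(m) {
      cm <- cumsum(m) / max(sum(m), 1e-12)
      cm > trim & (cm - m / max(sum(m), 1e-12)) < 1 - trim
    }
    keep <- keep_mass(object$prior_mass) | keep_mass(object$posterior_mass)
  }
  d <- object[keep, ]
  dens <- dplyr::bind_rows(
    tibble(midpoint = d$midpoint, value = d$prior_mass / delta,
           panel = "density", curve = "prior"),
    tibble(midpoint = d$midpoint, value = d$posterior_mass / delta,
           panel = "density", curve = "posterior"),
    tibble(midpoint = d$midpoint, value = d$rb,
           panel = "relative belief ratio", curve = "RB")
  )
  ggplot2::ggplot(dens, ggplot2::aes(.data$midpoint, .data$value,
                                     colour = .data$curve)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::geom_hline(
      data = tibble(panel = "relative belief ratio", y = 1),
      ggplot2::aes(yintercept = .data$y), linetype = 2, colour = "grey40"
    ) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "parameter of interest", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
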