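#' Discretization grid for a scalar parameter of interest
#'
#' Inference for a parameter of interest `psi` proceeds on a grid of bins of
#' width `delta`, the *meaningful difference*: two values of `psi` closer than
#' `delta` are regarded as practically equivalent, so the midpoint of each bin
#' represents all values in it. Bins are half-open intervals
#' `[mid - delta/2, mid + delta/2)`.
#'
#' With `align = TRUE` (the default) the grid is shifted so that bin midpoints
#' fall on integer multiples of `delta`. This reflects the reading of `delta`
#' as a measurement accuracy -- the representable values of `psi` are then the
#' `delta`-rounded values -- and makes the grid, and hence every reported
#' region endpoint, independent of Monte Carlo noise in the estimated range.
#'
#' @param lo,hi Range to cover. The snapped grid always covers `[lo, hi)`.
#' @param delta Bin width (meaningful difference), in the units of `psi`.
#' @param tail_mass Prior probability deliberately left outside the grid when
#'   the range was obtained by trimming (see [effective_range()]). Recorded so
#'   that mass-normalization checks can account for it.
#' @param align Snap bin midpoints to multiples of `delta`?
#'
#' @return An object of class `rb_grid`: a list with elements `lo`, `hi`,
#'   `delta`, `n_bins`, `midpoints`, `breaks` and `tail_mass`.
#' @seealso [effective_range()], [discretize()]
#' @examples
#' rb_grid(0, 1, 0.25)
#' @export
rb_grid <- function(lo, hi, delta, tail_mass = 0, align = TRUE) {
  assert_scalar(lo)
  assert_scalar(hi)
  assert_scalar(delta, positive = TRUE)
  assert_prob(tail_mass, open = FALSE)
  if (hi <= lo) abort("`hi` must exceed `lo`")
  if (align) lo <- round(lo / delta) * delta - delta / 2
  n_bins <- max(1L, as.integer(ceiling((hi - lo) / delta - 1e-9)))
  hi <- lo + n_bins * delta
  structure(
    list(
      lo = lo, hi = hi, delta = delta, n_bins = n_bins,
      midpoints = lo + (seq_len(n_bins) - 0.5) * delta,
      breaks = lo + (0:n_bins) * delta,
      tail_mass = tail_mass
    ),
    class = "rb_grid"
  )
}

#' @export
print.rb_grid <- function(x, ...) {
  cat(sprintf(
    "<rb_grid> %d bins of width %g on [%g, %g) (tail mass %g)\n",
    x$n_bins, x$delta, x$lo, x$hi, x$tail_mass
  ))
  invisible(x)
}

#' Effective prior range of a parameter from Monte Carlo draws
#'
#' Marginal priors of derived parameters (such as a ratio of means) often
#' have very long tails, so discretizing their full support is impossible.
#' The effective range trims a small amount `tail_mass` of prior probability,
#' split equally between the two tails, using empirical quantiles of a prior
#' sample.
#'
#' @param draws Numeric vector of draws from the prior of the parameter of
#'   interest; at least 1000 draws are required for the extreme quantiles to
#'   mean anything.
#' @param tail_mass Total prior probability to ignore; the default 0.001
#'   trims 0.0005 from each tail.
#'
#' @return Named numeric vector `c(lo, hi)`.
#' @examples
#' effective_range(rnorm(10000), tail_mass = 0.01)
#' @export
effective_range <- function(draws, tail_mass = 0.001) {
  if (!is.numeric(draws) || length(draws) < 1000) {
    abort("`draws` must be a numeric vector with at least 1000 elements")
  }
  if (!all(is.finite(draws))) abort("`draws` must be finite")
  assert_prob(tail_mass)
  if (tail_mass >= 0.5) abort("`tail_mass` must be below 0.5")
  q <- unname(quantile(draws, c(tail_mass / 2, 1 - tail_mass / 2),
                       names = FALSE, type = 7))
  if (q[2] <= q[1]) {
    abort("degenerate sample: the trimmed range of `draws` has zero width")
  }
  c(lo = q[1], hi = q[2])
}
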