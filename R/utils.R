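# internal numerical and validation helpers

# Bisection root finder on a bracketing interval. Tolerance is on the
# parameter, not the function value; f must have opposite signs at the ends.
bisect_root <- function(f, lower, upper, tol = 1e-10, max_iter = 200L) {
  flo <- f(lower)
  fhi <- f(upper)
  if (is.na(flo) || is.na(fhi)) abort("bisection endpoints evaluate to NA")
  if (flo == 0) return(lower)
  if (fhi == 0) return(upper)
  if (sign(flo) == sign(fhi)) {
    abort(sprintf(
      "no sign change on [%g, %g]: the defining equation has no bracketed root",
      lower, upper
    ))
  }
  for (i in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (fm == 0 || (upper - lower) / 2 < tol) return(mid)
    if (sign(fm) == sign(flo)) {
      lower <- mid
      flo <- fm
    } else {
      upper <- mid
    }
  }
  (lower + upper) / 2
}

# Geometric expansion of an upper bracket endpoint: grows `upper` until
# f changes sign relative to f(lower), or errors out.
expand_upper <- function(f, lower, upper = max(1, 2 * lower), grow = 4,
                         max_expand = 60L) {
  flo <- f(lower)
  for (i in seq_len(max_expand)) {
    if (sign(f(upper)) != sign(flo)) return(upper)
    upper <- upper * grow
  }
  abort("could not bracket a root by geometric expansion")
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

assert_prob <- function(x, name = deparse(substitute(x)), open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) abort(sprintf("`%s` must be a probability in %s",
                         name, if (open) "(0, 1)" else "[0, 1]"))
  invisible(x)
}

assert_scalar <- function(x, name = deparse(substitute(x)), positive = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && (!positive || x > 0)
  if (!ok) abort(sprintf("`%s` must be a finite %sscalar",
                         name, if (positive) "positive " else ""))
  invisible(x)
}

assert_count <- function(x, name = deparse(substitute(x))) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 &&
    abs(x - round(x)) < 1e-8
  if (!ok) abort(sprintf("`%s` must be a positive integer", name))
  invisible(as.integer(round(x)))
}

signif_rec <- function(x, digits = 6) {
  rapply(x, function(v) if (is.double(v)) signif(v, digits) else v,
         how = "replace")
}
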