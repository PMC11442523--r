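#' Write an analysis report to JSON or CSV
#'
#' JSON reports serialize the full object (regions, contents, settings,
#' seed) with numbers fixed to six significant digits so identical inputs
#' produce byte-identical files. CSV reports are the per-bin (or per-grid
#' point) tabular dump.
#'
#' @param x An `rb_profile`, `rb_region`, `fieller_fit`, `bias_report`,
#'   prior object or plain data frame.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    d <- report_table(x)
    d[] <- lapply(d, function(v) if (is.double(v)) signif(v, 6) else v)
    write.csv(d, path, row.names = FALSE)
  } else {
    jsonlite::write_json(signif_rec(report_list(x), 6), path,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

report_table <- function(x) {
  if (inherits(x, "rb_profile")) return(as.data.frame(x))
  if (inherits(x, "fieller_fit")) return(as.data.frame(x$profile))
  if (inherits(x, "bias_report")) return(as.data.frame(x$by_psi))
  if (is.data.frame(x)) return(as.data.frame(x))
  abort("no tabular representation for this object; use format = \"json\"")
}

report_list <- function(x) {
  if (inherits(x, "rb_region")) {
    return(list(
      type = x$type,
      intervals = as.data.frame(x$intervals),
      bins = x$bins,
      estimate = x$estimate,
      gamma = x$gamma,
      r_gamma = x$r_gamma,
      posterior_content = x$posterior_content,
      prior_content = x$prior_content,
      no_evidence = x$no_evidence
    ))
  }
  if (inherits(x, "rb_profile")) {
    return(list(
      grid = attr(x, "grid")[c("lo", "hi", "delta", "n_bins", "tail_mass")],
      n_prior = attr(x, "n_prior"),
      n_posterior = attr(x, "n_posterior"),
      prior_tail = attr(x, "prior_tail"),
      posterior_tail = attr(x, "posterior_tail"),
      no_evidence = attr(x, "no_evidence"),
      bins = as.data.frame(x)
    ))
  }
  if (inherits(x, "fieller_fit")) {
    return(list(
      settings = list(delta = x$delta, reps = x$reps,
                      tail_mass = x$tail_mass, seed = x$seed),
      data = unclass(x$data),
      priors = list(mu = unclass(x$priors$mu), nu = unclass(x$priors$nu)),
      estimate = x$plausible$estimate,
      plausible = report_list(x$plausible),
      credible = if (!is.null(x$credible)) report_list(x$credible),
      pivotal = unclass(glance(x$pivotal))
    ))
  }
  if (inherits(x, "bias_report")) {
    return(list(model = x$model, seed = x$seed,
                summary = as.list(x$summary)))
  }
  if (inherits(x, "pivotal_region")) return(as.list(glance(x)))
  if (inherits(x, "rb_prior")) {
    return(c(list(family = class(x)[1]), unclass(x),
             list(elicitation = attr(x, "elicitation"))))
  }
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(x)
  abort("unsupported report object")
}

#' Re-run a packaged worked example
#'
#' The package ships configurations for five classic worked examples:
#' `"fieller-example1"` (the simulated ratio-of-means study),
#' `"cox-a"` and `"cox-b"` (Cox's two weighing problems, where pivotal
#' inversion yields an exclusive region and an improper region respectively),
#' `"mandelkern-normal"` and `"mandelkern-poisson"` (bounded-mean and
#' bounded-rate physics problems). Each run recomputes the headline
#' quantities and compares them against the reference values these examples
#' are known to produce, at tolerances reflecting each quantity's Monte
#' Carlo error.
#'
#' @param name Fixture name; see Details.
#' @param seed Integer seed.
#' @param reps Monte Carlo size for the discretized inferences and biases.
#' @param n_mc Predictive simulation size for the histogram algorithm.
#' @return A tibble with columns `quantity`, `computed`, `reference`,
#'   `tolerance`, `within`.
#' @export
reproduce <- function(name, seed = 1, reps = 1e5, n_mc = 1e6) {
  fixtures <- c("fieller-example1", "cox-a", "cox-b",
                "mandelkern-normal", "mandelkern-poisson")
  if (!name %in% fixtures) {
    abort(sprintf("unknown fixture `%s`; available: %s",
                  name, paste(fixtures, collapse = ", ")))
  }
  rows <- switch(name,
    "fieller-example1" = fixture_fieller_example1(seed, reps),
    "cox-a" = fixture_cox(seed, reps, problem = "A"),
    "cox-b" = fixture_cox(seed, reps, problem = "B"),
    "mandelkern-normal" = fixture_mandelkern_normal(seed, n_mc, reps),
    "mandelkern-poisson" = fixture_mandelkern_poisson()
  )
  rows$within <- abs(rows$computed - rows$reference) <= rows$tolerance
  rows
}

fix_row <- function(quantity, computed, reference, tolerance) {
  tibble(quantity = quantity, computed = computed, reference = reference,
         tolerance = tolerance)
}

example1_priors <- function() {
  mu_pr <- elicit_normal(10, 25, 0.99)
  nu_pr <- elicit_fieller_nu(mu_pr, 10, 25, r1 = 1, r2 = 3, psi0 = 2,
                             gamma = 0.99)
  fieller_priors(mu_pr, nu_pr)
}

fixture_fieller_example1 <- function(seed, reps) {
  pr <- example1_priors()
  dat <- fieller_data(20.188, 10.699, 10, 10, 1)
  piv <- pivotal_region(dat, 0.95)
  cp <- psi_cond_params(2, pr)
  fit <- fieller_infer(dat, pr, delta = 0.1, reps = reps, seed = seed)
  g <- glance(fit)
  ba <- bias_against(fieller_evidence_model(pr, 10, 10, 1), 2,
                     reps = reps, seed = seed + 1)
  dplyr::bind_rows(
    fix_row("mu prior sd (tau10)", pr$mu$tau0, 2.912, 5e-4),
    fix_row("nu prior mean (nu0)", pr$nu$mu0, 8.75, 1e-6),
    fix_row("tau2(psi = 2)", cp$tau2_psi, 1.5239, 1e-3),
    fix_row("nu0(psi = 2)", cp$nu0_psi, 8.7502, 1e-3),
    fix_row("z0(psi = 2)", cp$z0, -7.0883, 2e-3),
    fix_row("pivotal 0.95 lower", piv$endpoints[1], 1.770, 2e-3),
    fix_row("pivotal 0.95 upper", piv$endpoints[2], 2.016, 2e-3),
    fix_row("estimate", g$estimate, 1.90, 0.1),
    fix_row("plausible lower", g$pl_lower, 1.75, 0.05),
    fix_row("plausible upper", g$pl_upper, 2.05, 0.05),
    fix_row("plausible posterior content", g$posterior_content, 0.982, 0.01),
    fix_row("plausible prior content", g$prior_content, 0.200, 0.01),
    fix_row("bias against psi0 = 2", ba$bias_against, 0.04, 0.01)
  )
}

cox_priors <- function(problem) {
  tau <- sqrt(3)
  if (problem == "A") {
    fieller_priors(normal_prior(12, tau), normal_prior(0, tau))
  } else {
    fieller_priors(normal_prior(0, tau), normal_prior(0, tau))
  }
}

fixture_cox <- function(seed, reps, problem) {
  pr <- cox_priors(problem)
  if (problem == "A") {
    dat <- fieller_data(10, 0.5, 1, 1, 1)
    piv <- pivotal_region(dat, 0.95)
    fit <- fieller_infer(dat, pr, delta = 0.8, reps = reps, seed = seed)
    g <- glance(fit)
    dplyr::bind_rows(
      fix_row("pivotal exclusive lower", piv$endpoints[1], -6.752, 3e-3),
      fix_row("pivotal exclusive upper", piv$endpoints[2], 3.968, 3e-3),
      fix_row("plausible posterior content", g$posterior_content, 0.791, 0.04),
      fix_row("plausible prior content", g$prior_content, 0.515, 0.04)
    )
  } else {
    dat <- fieller_data(0.5, 0.5, 1, 1, 1)
    piv <- pivotal_region(dat, 0.95)
    fit <- fieller_infer(dat, pr, delta = 0.1, reps = reps, seed = seed)
    g <- glance(fit)
    dplyr::bind_rows(
      fix_row("pivotal region improper (1 = yes)",
              as.numeric(piv$kind == "whole_line"), 1, 0),
      fix_row("plausible posterior content", g$posterior_content, 0.534, 0.05),
      fix_row("plausible prior content", g$prior_content, 0.498, 0.05)
    )
  }
}

fixture_mandelkern_normal <- function(seed, n_mc, reps) {
  beta_pr <- elicit_beta(0, 10, 0.5, 9.5, m0 = 5, gamma = 0.99)
  tn_pr <- elicit_truncnorm(0, 10, 0.5, 9.5, mu0 = 5, gamma = 0.99)
  m10 <- constrained_normal_model(beta_pr, n = 10)
  m100 <- constrained_normal_model(beta_pr, n = 100)
  ba <- bias_against_mu(m10, 4, n_mc = n_mc, seed = seed)
  conf <- normal_confidence(m10, delta = 0.5, n_mc = n_mc, seed = seed + 1)
  bf <- bias_in_favor_mu(m100, 4, delta = 0.5, reps = reps, seed = seed + 2)
  dplyr::bind_rows(
    fix_row("beta prior alpha0", beta_pr$alpha0, 2.20, 5e-3),
    fix_row("truncated normal tau0", tn_pr$tau0, 1.92, 5e-3),
    fix_row("bias against mu* = 4 (n = 10)", ba$bias_against, 0.039, 0.01),
    fix_row("frequentist confidence (n = 10)", conf$freq_confidence, 0.958, 0.01),
    fix_row("Bayesian confidence (n = 10)", conf$bayes_confidence, 0.969, 0.01),
    fix_row("bias in favor mu* = 4 (n = 100, delta = 0.5)",
            bf$bias_in_favor, 0.008, 0.01)
  )
}

fixture_mandelkern_poisson <- function() {
  pr <- elicit_gamma_rate(3.5, 9.5, m0 = 6.5, gamma = 0.99)
  m10 <- constrained_poisson_model(pr, 3, 10, n = 10, delta = 0.5)
  m50 <- constrained_poisson_model(pr, 3, 10, n = 50, delta = 0.5)
  m100 <- constrained_poisson_model(pr, 3, 10, n = 100, delta = 0.5)
  conf <- poisson_confidence(m100)
  dplyr::bind_rows(
    fix_row("gamma prior shape", pr$alpha0, 37.20, 0.01),
    fix_row("gamma prior rate", pr$beta0, 5.57, 0.01),
    fix_row("bias against lambda = 6.2 (n = 10)",
            poisson_bias_against(m10, 6.2)$bias_against, 0.193, 0.01),
    fix_row("bias against lambda = 6.2 (n = 50)",
            poisson_bias_against(m50, 6.2)$bias_against, 0.085, 0.01),
    fix_row("bias in favor lambda = 6.2 (n = 10)",
            poisson_bias_in_favor(m10, 6.2)$bias_in_favor, 0.800, 0.01),
    fix_row("frequentist confidence (n = 100)", conf$freq_confidence, 0.950, 0.005),
    fix_row("Bayesian confidence (n = 100)", conf$bayes_confidence, 0.966, 0.005)
  )
}
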