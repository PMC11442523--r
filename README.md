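# relbel

Relative belief inference with guaranteed a priori coverage.

`relbel` is for analysts who must report an interval for a parameter of
interest together with an honest statement of how reliable that interval is —
and who work in problems where classical confidence regions misbehave:
ratios of means (Fieller's problem), where pivotal inversion can return the
whole real line, and physically constrained parameters (Mandelkern's bounded
normal mean and bounded Poisson rate), where a confidence interval
intersected with the constraint can be empty.

The package builds regions from the **principle of evidence**. With prior
density π(ψ) and posterior density π(ψ | x) for the parameter of interest,
the *relative belief ratio* is

    RB(ψ | x) = π(ψ | x) / π(ψ).

There is evidence in favor of ψ when RB(ψ | x) > 1 and evidence against when
RB(ψ | x) < 1. The reported inference is the *plausible region*

    Pl(x) = { ψ : RB(ψ | x) > 1 },

its posterior content (how strongly the true value is believed to be in it),
its prior content (a measure of size), and the maximizing value ψ(x) as the
estimate. The plausible region is never the whole space and is empty only on
a prior-probability-zero event, so it is never improper — unlike the
pivotal-based confidence regions it replaces.

Reliability is measured a priori, before data are collected, by two biases
computed under the conditional prior predictive M(· | ψ):

* **bias against** ψ₀: M(RB(ψ₀ | x) ≤ 1 | ψ₀), the prior probability of
  failing to find evidence for a true value. One minus its prior average is
  the **Bayesian confidence** of the plausible region; one minus its maximum
  is a frequentist lower bound on the coverage.
* **bias in favor** of ψ₀: the prior probability of failing to find evidence
  against a *meaningfully false* value, one displaced from ψ₀ by the
  meaningful difference δ. One minus its prior average is the **accuracy**.

Both biases go to zero as the data grow, so reliability is set at the design
stage through the sample size (`sample_size_search()`).

Inference is carried out on a δ-grid: δ is the accuracy to which ψ is worth
knowing, the grid bins are δ wide, and per-bin prior and posterior contents
come from Monte Carlo simulation (`discretize()`, `relative_belief()`,
`plausible_region()`, `credible_region()`). For the Fieller model the
marginal density of ψ = μ/ν is also available in closed form, which the bias
engine exploits.

## Worked example: a ratio of normal means

Two samples of size 10 with known unit variance have sample means
(x̄, ȳ) = (20.188, 10.699); interest is in ψ = μ/ν. Elicitation: μ ∈ (10, 25)
and ψ ∈ (1, 3), each with prior probability 0.99, with central ratio ψ₀ = 2.

```r
library(relbel)

mu_prior <- elicit_normal(10, 25)
mu_prior
#> <normal_prior> mu0 = 17.5, tau0 = 2.91168
#>   elicited: gamma = 0.99, residual = 0.00e+00

nu_prior <- elicit_fieller_nu(mu_prior, m1 = 10, m2 = 25, r1 = 1, r2 = 3, psi0 = 2)
priors   <- fieller_priors(mu_prior, nu_prior)
data     <- fieller_data(xbar = 20.188, ybar = 10.699, nx = 10, ny = 10, sigma0 = 1)

# no prior-data conflict: the observed mean is not in the prior predictive tails
prior_data_conflict(20.188, n = 10, sigma0 = 1, mu_prior)
#> [1] 0.3587339

fit <- fieller_infer(data, priors, delta = 0.1, reps = 1e5, seed = 1)
fit
#> Relative belief inference for psi = mu / nu
#>   delta = 0.1, reps = 100000, trimmed tail mass = 0.001
#> <rb_region: plausible>
#>   [1.75, 2.05)
#>   estimate: 1.9
#>   posterior content: 0.9825   prior content: 0.2001
#> <pivotal_region> 0.95-confidence region for psi: (1.769, 2.017)
```

The estimate is 1.90 with plausible region (1.75, 2.05): the true value is
believed to be in that interval with posterior probability 0.982, and the
region occupies only 0.20 of the prior — a lot was learned from 20
observations. How reliable is this design a priori?

```r
model <- fieller_evidence_model(priors, nx = 10, ny = 10, sigma0 = 1)
bias_against(model, 2, reps = 1e5, seed = 2)
#>    psi0 bias_against    mc_se   reps
#> 1     2       0.0409 0.000626 100000

bias_in_favor(model, 2, delta = 0.1, reps = 1e5, seed = 3)
#>    psi0 delta displacement favor_lower favor_upper bias_in_favor    mc_se   reps
#> 1     2   0.1         0.05       0.917       0.916         0.917 0.000872 100000
```

Bias against ψ₀ = 2 is only 0.04 — the plausible region is at least a
0.96-confidence region — but the bias in favor at δ = 0.1 is 0.92: with
n = 10 there is a large prior probability of failing to find evidence
against a value that is off by a meaningful amount. Pushing it down to ~0.09
requires n ≈ 500, which is how the sample size would be set.

`glance()` and `tidy()` return these summaries as tibbles,
`autoplot(fit$profile)` draws the prior/posterior histograms and the
relative belief ratio, and the constrained-mean and constrained-rate models
have the analogous surface (`constrained_normal_model()`,
`constrained_poisson_model()`, `bias_against_mu()`, `poisson_bias_suite()`,
...). A thin command-line wrapper is installed at `inst/cli/relbel` with
YAML configurations (examples under `inst/extdata/`).

## References

* Fieller, E. C. (1954). Some problems in interval estimation. *JRSS B* 16, 175–185.
* Mandelkern, M. (2002). Setting confidence intervals for bounded parameters. *Statistical Science* 17, 149–172.
* Evans, M. (2015). *Measuring Statistical Evidence Using Relative Belief.* CRC Press.
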