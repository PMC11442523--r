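---
title: "Evidence-based regions and a priori bias control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based regions and a priori bias control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relbel)
```

## The inferential model

A statistical model $\{f_\theta\}$, a proper prior $\pi$, and a marginal
parameter of interest $\psi = \Psi(\theta)$ induce prior and posterior
densities $\pi_\Psi$ and $\pi_\Psi(\cdot \mid x)$. The relative belief ratio

$$RB(\psi \mid x) = \frac{\pi_\Psi(\psi \mid x)}{\pi_\Psi(\psi)}$$

orders values by how much the data moved belief toward them. The principle of
evidence reads $RB > 1$ as evidence in favor, $RB < 1$ as evidence against,
and $RB = 1$ as no evidence. The reported inference is the plausible region
$Pl(x) = \{\psi : RB(\psi \mid x) > 1\}$ with its posterior and prior
contents, plus the maximizing value as the estimate. Because
$\int RB \, d\Pi_\Psi = 1$, evidence in favor of every value at once is
impossible, and outside the prior-null event that the posterior equals the
prior everywhere, some value always has evidence in favor: the plausible
region is never improper. Both facts are asserted as property tests on
randomly generated mass profiles.

Relative belief credible regions $C_\gamma$ collect the largest-$RB$ values
until posterior content $\gamma$ is reached; whenever $\gamma$ does not
exceed the posterior content of $Pl(x)$, $C_\gamma \subseteq Pl(x)$, so every
reported value still has evidence in its favor.

Reliability is a design-stage, frequentist-style calculation under the
conditional prior predictive $M(\cdot \mid \psi)$ (nuisance parameters
integrated out by the conditional prior): the *bias against*
$M(RB(\psi_0 \mid x) \le 1 \mid \psi_0)$ and the *bias in favor*, the
probability of $RB(\psi_0 \mid x) \ge 1$ when the generating value is
displaced from $\psi_0$ by the meaningful difference. One minus the
prior-averaged bias against is the Bayesian confidence of $Pl$; one minus
its maximum over $\psi$ is a frequentist lower bound on coverage. Both
inequalities are weak: $RB = 1$ (no evidence) counts toward both biases.

## Discretization and the meaningful difference

All generic inference happens on a grid of bins of width $\delta$, the
accuracy to which $\psi$ is worth knowing; values inside a bin are treated
as equivalent and the bin midpoint represents them. Choices made here:

* **Bin midpoints sit on integer multiples of $\delta$** (the grid's lower
  edge is snapped). Reading $\delta$ as a measurement accuracy, the
  representable values of $\psi$ are its $\delta$-rounded values; snapping
  also makes reported region endpoints deterministic rather than functions
  of the Monte Carlo draws that estimated the range. `rb_grid(align = FALSE)`
  disables this.
* **Bins are half-open** $[m - \delta/2, m + \delta/2)$, so the bins
  partition the range and region endpoints are bin edges.
* **Tail trimming.** Ratio-type parameters have Cauchy-like tails, so the
  grid covers the *effective* prior range: the empirical
  $(\alpha/2, 1 - \alpha/2)$ quantiles of a prior sample with
  $\alpha = 0.001$ by default. Draws outside the grid are tallied as tail
  mass, never silently dropped. As an alternative to truncation,
  `fieller_infer(transform = )` accepts a strictly monotone map (e.g. a
  long-tailed cdf) and carries out the inference on the transformed scale,
  which is legitimate because relative belief inferences are invariant under
  reparameterization; truncation is the default because it is what the
  worked analyses use.
* **Bins with zero estimated prior mass** have an undefined ratio (0/0) and
  are excluded from every region and flagged, rather than being assigned a
  value. With heavy-tailed priors this produces a small downward bias in
  estimated region contents at moderate Monte Carlo sizes (quantified below).
* **Ties.** The estimate is the midpoint of the maximizing bin, with ties
  broken to the lowest bin and reported via a message. Bins with $RB$
  exactly 1 belong to neither the plausible nor the implausible region.

Monte Carlo sizes default to $10^5$ draws for each of prior and posterior in
the discretized inferences and $10^5$ predictive replicates per bias value,
the scales at which the packaged examples were originally analyzed; the test
suite runs the constrained-normal histogram algorithm at $10^5$ predictive
draws and $k = 10^3$ intervals, and the acceptance script at $10^6$ draws.

## Elicitation

Every prior family is elicited from a virtual-certainty statement: an
interval believed to contain the parameter with prior probability $\gamma$
(default 0.99 — certainty is never categorical, and the prior-data conflict
check guards the choice). The dispersion parameter solves the corresponding
quantile equation by bisection with geometrically expanded brackets,
tolerance $10^{-10}$ on the parameter and at most 200 iterations; every
returned object records its achieved residual, and the tests require
residuals below $10^{-8}$. Degenerate and unsolvable cases error with the
violated condition: the truncated normal requires
$(u_1 - l_1)/(u_0 - l_0) \le \gamma$ (the large-dispersion limit of the
conditional coverage), and the scaled beta cannot hit a $\gamma$ below the
uniform content. For the Fieller denominator mean, the implied interval
$(m_1/r_2,\, m_2/r_1)$ presumes a ratio interval excluding zero, and the
location $\nu_0 = \mu_0/\psi_0$ must fall inside it; both are validated.

The prior-data conflict check compares the observed sufficient statistic
with its prior predictive distribution through a two-sided tail probability;
small values say the elicitation should be revisited *before* inference, and
the bias computations then need redoing with the new prior.

## The ratio-of-means model

With $\mu \sim N(\mu_0, \tau_{10}^2)$ independent of
$\nu \sim N(\nu_0, \tau_{20}^2)$, conditioning on $\psi = \mu/\nu$
concentrates the prior on the fiber $\mu = \psi\nu$, where it becomes
$|\nu| \cdot N(\nu_0(\psi), \tau^2(\psi))$ with
$\tau^2(\psi) = (\psi^2/\tau_{10}^2 + 1/\tau_{20}^2)^{-1}$ — the $|\nu|$ is
the Jacobian of the ratio map. Integrating the fiber gives the closed-form
marginal density of $\psi$ (a rescaled Cauchy when $\mu_0 = \nu_0 = 0$,
which is the Cauchy-reduction test), and conjugacy makes the posterior the
same expression at updated hyperparameters, so the exact relative belief
ratio is a ratio of two closed-form evaluations. The discretized and exact
ratios are cross-checked bin-by-bin in the tests (the Savage–Dickey
equivalence).

Sampling $\nu \mid \psi$ standardizes to the density
$\propto |z + c|\,\varphi(z)$ with $c = \nu_0(\psi)/\tau(\psi)$; its cdf is
available in closed form with total mass $2\varphi(c) + c(2\Phi(c) - 1)$ and
is inverted by vectorized bisection (64 halvings on a bracket of half-width
$13 + |c|$, resolution far below Monte Carlo noise; $c$ may vary per draw,
which the nested bias simulations rely on). The sampler is validated against
the quadrature-normalized density histogram-by-histogram. The sign-change
point $-c$ of the weight is exposed as `z0` in `psi_cond_params()`.

The pivotal $(\bar{x} - \psi\bar{y})/(\sigma_0\sqrt{1/n_x + \psi^2/n_y})$
is inverted exactly by the quadratic formula and classified by leading
coefficient and discriminant into interval, exclusive, half-line or
whole-line regions. The published endpoints for the two classic data sets
carry roughly $0.002$ of numerical error (they are mutually inconsistent in
the implied normal quantile), so the tests anchor the exact roots against an
independent in-test quadratic solution and compare with the published values
at a $0.002$–$0.003$ tolerance.

## Constrained-mean and constrained-rate models

For the bounded normal mean, the relative belief ratio of $\mu_*$ given
$\bar{x}$ is the conditional-over-marginal predictive ratio
$\varphi_{\sigma_0/\sqrt{n}}(\bar x - \mu_*)/m(\bar x)$; $m$ is evaluated by
adaptive quadrature windowed to $\pm 12$ standard errors (vital when
$\sigma_0/\sqrt n$ is tiny) for single points, and by fixed 801-node
Gauss–Legendre quadrature plus chunked matrix products for the $10^5$-draw
bias simulations. The bias against is computed by the histogram algorithm:
bin $\bar x$ over $(l_0 - 3\sigma_0/\sqrt n,\, u_0 + 3\sigma_0/\sqrt n)$
into $k$ intervals, estimate each interval's ratio as its exact
$N(\mu_*, \sigma_0^2/n)$ probability over its simulated predictive
proportion, and sum the exact probabilities where the ratio is at most 1.
$k$ defaults to $\max(10^3, 20\sqrt n)$, finer as the predictive
concentrates. Intervals with positive hypothesis probability but no
predictive draws are given half a draw, making their ratio very large; they
count as evidence in favor and leave the bias-against sum — the conservative
direction, and the only place the algorithm needs a convention the
derivation does not supply.

For the bounded Poisson rate, gamma–Poisson conjugacy gives every predictive
quantity in closed form (negative-binomial masses times ratios of gamma
truncation probabilities), so all bias quantities are exact sums over the
total count — no Monte Carlo at all. The ratio used by the bias machinery is
the *interval* relative belief ratio of $\lambda_* \pm \delta/2$, the
discrete analogue of knowing the rate to accuracy $\delta$; the pointwise
Savage–Dickey ratio is also exposed.

**Displacement convention.** The bias in favor evaluates the two displaced
alternatives rather than a supremum, since the probability of failing to
find evidence against decays with distance. The worked analyses are not
unanimous about the displacement: the ratio-of-means study displaces by
$\delta/2$, while the constrained-mean and constrained-rate tables displace
by the full $\delta$ (we verified numerically that only those conventions
reproduce the respective published values). The generic engine therefore
defaults to $\delta/2$ and the constrained-model wrappers to $\delta$, each
overridable through `displacement=`, and every report records which was
used.

## What the fixtures emulate, and known limitations

The packaged fixtures (`reproduce()`) regenerate the published analyses:
simulated two-sample ratio data summarized by $(\bar x, \bar y)$, the two
exclusive/improper-region data sets, and the bounded-mean and bounded-rate
designs. They exercise known-variance normal and Poisson sampling models
with honestly elicited proper priors — they do not emulate model
misspecification, unknown variances, outliers, or dependence, so passing
tests speak to the correctness of the evidence computations, not to
robustness of the models themselves. Unknown or unequal variances in the
ratio problem, one-sided constraints with an infinite bound (approximate
with a large finite bound), multivariate parameters of interest, and kernel
density estimation (histograms only) are out of scope.

Two numerical limitations are worth knowing. First, region *contents* for
extremely heavy-tailed ratio posteriors carry a downward bias of order
$0.01$–$0.02$ at $10^5$ draws, because deep-tail bins with no prior draws
are excluded; the bias shrinks as draws grow (for the exclusive-region
fixture the contents move from about $0.777/0.497$ at $10^5$ draws to about
$0.803/0.520$ at $10^6$, against exact closed-form values $0.808/0.525$),
and the grid resolution for those fixtures ($\delta = 0.8$ and $0.1$) was
fixed from the lattice of the originally reported region endpoints. Second,
the bias-in-favor of a value next to a constraint boundary can only be
evaluated on its feasible side; reports flag the skipped side.
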