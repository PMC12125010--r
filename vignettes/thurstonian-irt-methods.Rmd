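---
title: "Thurstonian IRT for forced-choice rankings: models, samplers, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thurstonian IRT for forced-choice rankings: models, samplers, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Multidimensional forced-choice (MFC) questionnaires present statements in
blocks of $n_b$ and ask respondents to rank them. Because every statement in
a block measures a different trait and every rank is awarded exactly once,
classical scoring yields ipsative scores that cannot be compared between
persons. Thurstonian item response theory treats the ranking as the order
statistics of latent utilities
$$t_{ij} = \mu_i + \lambda_i \theta_{j} + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, \psi_i),\qquad
\theta_j \sim N(0, \Sigma),$$
with $\mu_i$ the utility mean of statement $i$, $\lambda_i$ its signed
loading on the single trait it measures (simple structure), $\psi_i$ its
error variance, and $\Sigma$ a trait correlation matrix. Statement $i$ is
ranked above statement $l$ exactly when $t_{ij} > t_{lj}$; rankings are
therefore transitive by construction.

A ranking is recoded into binary pairwise outcomes through a contrast matrix
$A$ with one row per statement pair. All $n_b(n_b-1)/2$ pairwise differences
$y^*_j = A t_j$ are multivariate normal with covariance $A \Psi A^\top$.
Because $A$ has per-block rank $n_b - 1$, that covariance is singular: the
law of the full difference vector is a *degenerate* normal whose density
involves only the non-zero eigenvalues and the pseudo-inverse
(`singular_normal_logpdf()`).

## Three implementations

The package fits the same measurement model under three likelihoods:

* **original** — every pairwise comparison is an independent probit
  (Bernoulli) outcome with its own free intercept $\gamma_{il}$. Nothing
  forces $\gamma_{AB} + \gamma_{BC} = \gamma_{AC}$, so intransitive binary
  patterns such as $(1, 0, 1)$ have positive probability: the model is not
  fully faithful to the ranking process (*stochastic dependencies* are
  ignored).
* **stochastic** — the intercepts are constrained to $\gamma = -A\mu$, and
  the likelihood is the degenerate multivariate normal of the full pairwise
  difference vector. Intransitive patterns now have probability zero.
* **stochastic_logical** — additionally, only the $n_b - 1$ comparisons
  between *neighbouring* ranks enter, through a person-specific design matrix
  $A_j$ (+1 on the better-ranked statement of each adjacent pair). These
  comparisons determine the full pattern, so nothing is lost (*logical
  dependencies* are respected), and the covariance $A_j \Psi A_j^\top$ is
  positive definite.

The last two likelihoods are equivalent: the full difference vector is the
image of the neighbouring differences under a fixed linear embedding $M$
(`expand_latent_diffs()`), so their log-densities differ by the
parameter-free constant $-\tfrac12 \log\det(M^\top M)$ per block
($-\tfrac12\log 3$ for $n_b = 3$, $-\tfrac12\log 16$ for $n_b = 4$).
`test-acceptance.R` verifies this constant numerically across random
parameter draws and shows that grid-search MAP estimation of $\theta$ is
unaffected by it. A related bookkeeping constant appears in model comparison:
a three-dimensional normal normalizer $(2\pi)^{-3/2}$ differs from the
correct two-dimensional $(2\pi)^{-1}$ by $-\tfrac12\log 2\pi \approx -0.92$
per observation, which shifts WAIC's elpd by exactly $n_{\mathrm{obs}}$ times
the offset without affecting any comparison of substance. We implement the
degenerate-normal normalizer as $(2\pi)^{-r/2}\,(\prod_i v_i)^{-1/2}$ with
$v_1,\dots,v_r$ the non-zero eigenvalues; the $-\tfrac12$ power on the
eigenvalue product is required for the full-rank limit to agree with the
ordinary multivariate normal density, which the test suite checks.

## Priors

All prior scale parameters are **variances**: loadings
$\lambda_i \sim N(\pm 1, 0.5)$ truncated to the keyed side of zero, utility
means $\mu_i \sim N(0, 2)$, error variances $\psi_i \sim N(1, 0.3)$ truncated
to $(0, \infty)$, the trait correlation matrix LKJ with shape $\eta = 1$
(uniform over correlation matrices), and free intercepts
$\gamma \sim N(0, 4)$ in the original implementation. The variance reading is
the only one under which the free-intercept prior is the distribution implied
by differences of two independent $N(0, 2)$ utility means ($2 + 2 = 4$);
`log_prior()` exposes an `"sd"` switch for the other convention.

## What is and is not identified

The ranking likelihood of a block is invariant to (a) adding a constant to
all utility means of the block and (b) rescaling the block's
$(\mu, \lambda, \sqrt\psi)$ by a common positive factor. Both directions are
identified only through the priors. Two practical consequences:

* Posterior error variances sit near the prior centre ($\psi \approx 1$)
  whatever the generating values; raw loadings inherit the corresponding
  scale. Parameter recovery is therefore scored on **standardized loadings**
  $\lambda/\sqrt{\lambda^2 + \psi}$ (`standardized_loadings()`), the
  scale-invariant quantity. The simulator draws $\psi_i = 1 - \lambda_i^2$,
  giving unit-variance utilities, so the generating $\lambda$ is already
  standardized.
* A Gibbs sampler that only alternates full conditionals random-walks along
  these prior-identified directions. The constrained-model kernel therefore
  includes two dedicated moves: an exact conditional draw of the per-block
  location shift, and a Metropolis move along the per-block scale orbit
  (multiplicative proposal with Jacobian $c^{4 n_b}$). An ancillary
  interweaving step for $\mu$ (holding $t - \mu$ fixed) removes the remaining
  slow coupling between utility means and the augmented utilities.

## Samplers

The posterior is explored by Markov chain Monte Carlo with data
augmentation; all moves are exact conditional draws or Metropolis steps, so
no asymptotic gradient approximations are involved.

* **Constrained implementations**: the latent utilities $t_{ij}$ are
  augmented and sampled as truncated normals between the utilities of the
  adjacently ranked statements (two sweeps per scan). Trait scores, utility
  means and loadings then have conjugate (truncated) normal conditionals;
  error variances use adaptive random-walk Metropolis on $\log\psi$; the
  correlation matrix uses element-wise random-walk Metropolis under the
  LKJ(1) prior with positive-definiteness checks. Both constrained
  implementations share this kernel — their likelihoods are provably
  proportional — but run on independent seed streams and record different
  pointwise log-likelihoods (degenerate full-$A$ density versus reduced
  $A_j$ density).
* **Original implementation**: one latent normal variable per pairwise
  comparison, truncated by the observed binary outcome; free intercepts,
  loadings and trait scores are conjugate; $\psi$ and $\Sigma$ as above.

Each stored iteration comprises several full Gibbs scans (three for the
constrained kernel, two for the original) because the augmentation dominates
the autocorrelation and extra scans are cheap relative to bookkeeping.
Warm-up is half of `iter` by default; adaptation of Metropolis step sizes
(Robbins–Monro toward 0.44 acceptance) runs only during warm-up, so the
post-warm-up kernel is a fixed, valid MCMC kernel. Chains are deterministic
functions of `seed`; the three implementations use distinct sub-streams so
that cross-implementation comparisons are between genuinely independent
runs.

The augmented latent quantities are discarded; reported draws cover
$\mu, \lambda, \psi, \Sigma, \theta$, and $\gamma$ (free in the original
implementation; the deterministic transform $-A\mu$, recomputed per draw, in
the constrained ones — the two definitions differ, which must be kept in
mind when comparing $\gamma$ across implementations).

## Diagnostics and model comparison

`convergence_diagnostics()` reports rank-normalized split-chain
$\widehat R$ and bulk effective sample size (Geyer's initial positive and
monotone sequence estimator on rank-normalized split chains), with
MCSE $= \mathrm{sd}/\sqrt{\mathrm{ESS}}$. The rank-normalized bulk variant is
pinned because diagnostics differ across the literature; the test suite
cross-checks the estimator against the closed-form AR(1) effective sample
size and against `coda` on i.i.d. chains. Antithetic chains may report ESS
above the raw draw count; this is expected and not truncated.

`waic()` uses the variance-based penalty with one respondent-block as the
observation unit in *all three* implementations, so elpd differences are
aligned. The pointwise log-likelihoods are densities of the augmented latent
quantities at their sampled values in all three implementations, so they
share a scale: the diagonal $n_b(n_b-1)/2$-dimensional normal of the latent
comparison variables (original), the degenerate full-$A$ density of the
latent difference vector (stochastic), and the reduced $(n_b-1)$-dimensional
$A_j$ density (stochastic_logical). The two constrained implementations
consequently differ by exactly the embedding constant per block, which shows
up in `compare_waic()` as an elpd difference of $n_{\mathrm{obs}}$ times the
constant with near-zero paired SE — a normalizer bookkeeping offset (of the
same nature as the $-0.92$ dimension-count offset above), not a fit
difference. The reduced implementation therefore reports the highest elpd,
followed by the full constrained and then the original implementation.
`loglik_original()` itself remains the observed-data Bernoulli probit
product.

## The simulator and the study harness

`simulate_mfc()` generates questionnaires and responses with the statistical
structure of a typical implementation-comparison study: $\mu \sim U[-1, 1]$,
$|\lambda| \sim U[0.65, 0.95]$ with sign from keying,
$\psi = 1 - \lambda^2$, five correlated traits, and two thirds of blocks
mixed-keyed. Choices the study description leaves open were fixed once:

* the exact Big-5-like correlation values are not published with the study
  design, so a documented default with moderate correlations (magnitude
  $\le 0.45$, positive-definiteness checked at construction) ships as
  `big5_trait_corr()`, overridable per study;
* "two thirds unequally keyed" is read as the fraction of *blocks* containing
  both keying directions (`mixed_keying_fraction = 2/3`), since mixed-keyed
  blocks are the construct of interest in MFC designs; which statements flip
  is a seeded draw, and unmixed blocks are all positively keyed;
* trait-to-statement assignment cycles through the traits across blocks, so
  statements within a block measure distinct traits (requires
  $n_b \le d$) — standard MFC construction practice.

The simulator emulates clean, complete ranking data from a correctly
specified utility model. It does not emulate faking, response styles,
missing data, heterogeneous block lengths, or violations of simple
structure, so passing tests speak to the estimators under the model, not to
robustness against such features of real data.

`run_simulation_study()` crosses block length, test length and sample size,
fits the three implementations per replication on common data, and scores
pairwise mean absolute differences of posterior means against combined Monte
Carlo standard errors, streaming per-cell CSVs so partial runs resume. The
default replication count (3) is desk scale; larger studies raise it
explicitly.

## Numerical choices

* Degenerate-density support: the numerical rank uses the eigenvalue
  threshold $p \cdot \max v \cdot 10^{-12}$; points are accepted on the
  support when the projected off-support residual is below a relative
  $10^{-8}$. Off-support evaluation raises a distinct error (it signals a
  coding error, never an unlikely observation). Both tolerances are
  arguments.
* Orthant (ranking) probabilities for $n_b \le 4$ use a deterministic
  low-dimensional algorithm, so the oracle is reproducible without seeds.
* Ties: rankings with tied ranks are rejected during validation, and exactly
  tied simulated utilities (a probability-zero event) raise rather than
  being silently reordered — the model has no tie process.
* Problem sizes in tests: the implementation-agreement check runs one
  synthetic dataset at $n_b = 3$, $K = 10$, $J = 50$ with 4 chains of 1000
  iterations, and the recovery check one dataset at $J = 200$; these sizes
  give Monte Carlo error small enough for the properties being asserted
  while keeping the default suite fast. The full factorial study with many
  replications remains available through `run_simulation_study()`.

## Known limitations

* Only complete rankings of equal-length blocks are supported (no
  "most/least" partial formats).
* The original implementation's composite (independent-Bernoulli) likelihood
  is kept deliberately faithful, including its overstated precision; it is
  the comparison baseline, not a recommended estimator.
* Posterior agreement between the original and constrained implementations
  is a finite-sample property: at small $J$ their loading posteriors can
  differ by a few hundredths on the standardized scale, which a
  well-mixing sampler resolves as larger than its own Monte Carlo error.
* The absolute $\lambda/\psi$ scale is reported as sampled; users comparing
  against external analyses should compare standardized loadings.
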