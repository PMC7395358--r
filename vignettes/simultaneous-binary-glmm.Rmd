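---
title: "Simultaneous hierarchical models for correlated binary survey outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous hierarchical models for correlated binary survey outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

National health surveys collect several binary responses from the same
respondents — here an HIV blood-test result, awareness of HIV/AIDS, and
awareness of an HIV/AIDS campaign — under a hierarchical sampling design:
adults nested in households nested in enumeration clusters.  Modeling each
response with its own three-level logistic model accounts for the design
but ignores that the three responses share unexplained heterogeneity at
the cluster and household level.  `triglmm` implements both strategies and
the test that decides between them.

## The separate model

For one outcome, individual $i$ in household $h$ in cluster $c$:

$$
\operatorname{logit}\, p_{ihc} = \mathbf{x}_{ihc}'\boldsymbol\beta
  + u_{c} + u_{hc}, \qquad
u_{c} \sim N(0, \sigma^2_{c}),\quad u_{hc} \sim N(0, \sigma^2_{h}),
$$

with $u_c$ and $u_{hc}$ independent of each other and across units.
`fit_separate()` maximizes the marginal likelihood in which both random
intercepts are integrated out.

### Latent-scale intraclass correlation

For a logistic model the individual-level residual is taken as a latent
logistic variable with variance $\pi^2/3 \approx 3.29$; `compute_icc()`
uses the rounded constant 3.29 by default (pass `level1 = pi^2/3` for the
unrounded value; the difference is about 0.003, well below the precision
at which ICCs are reported).  The cluster-level ICC is
$\sigma^2_c / (\sigma^2_c + \sigma^2_h + 3.29)$ and the household-level
ICC is cumulative, $(\sigma^2_c + \sigma^2_h)/(\sigma^2_c + \sigma^2_h +
3.29)$, the share of latent variance attributable to living in the same
household *including* its cluster.

## The simultaneous model

The three outcomes $q = 1, 2, 3$ get outcome-specific coefficients
$\boldsymbol\beta^{(q)}$ and a *trivariate* random intercept at each
level:

$$
\mathbf{u}_c \sim N_3(\mathbf 0, \Sigma_C), \qquad
\mathbf{u}_{hc} \sim N_3(\mathbf 0, \Sigma_H),
$$

independent across levels (the implied $6\times6$ covariance of
$(\mathbf u_c, \mathbf u_{hc})$ is block-diagonal).  The off-diagonal
entries of $\Sigma_C$ and $\Sigma_H$ are the cross-outcome covariances:
how much the unexplained cluster (household) propensity for one response
moves with the unexplained propensity for another.  If all six are zero
the likelihood factorises into the three separate models — exactly, not
approximately, and the package's quadrature is constructed so that this
identity holds to machine precision (a regression test asserts it at
`1e-8`).

`lrt_cross_covariances()` compares the full fit with the
`restrict_cross = TRUE` fit by a likelihood-ratio test on 6 degrees of
freedom.  No boundary correction is applied: the tested parameters are
covariances, interior points of the parameter space whenever the
variances are positive.  The restricted fit is computed as the three
separate fits (the factorisation identity makes this the exact restricted
optimum) and its log-likelihood is re-evaluated with the joint machinery,
so the two model fits being compared are guaranteed to use the same
quadrature construction; comparability is additionally enforced by
hashing the complete-case records and the node count.

## Likelihood evaluation: nested adaptive Gauss–Hermite quadrature

The marginal likelihood of cluster $c$ is

$$
L_c = \int \phi(\mathbf u; \Sigma_C) \prod_h
  \int \phi(\mathbf v; \Sigma_H) \prod_i \prod_q
  p_{qihc}^{y} (1-p_{qihc})^{1-y} \, d\mathbf v \, d\mathbf u .
$$

Both integrals are evaluated by adaptive Gauss–Hermite quadrature on
Cholesky-whitened coordinates: each integrand is centred at its
conditional mode (found by damped Newton iterations with analytic
gradient and Hessian) and scaled by the conditional curvature, then a
tensor-product Gauss–Hermite grid with `quad_nodes` points per dimension
is applied.  `quad_nodes = 1` is the adaptive-Laplace point of this
ladder; 3 nodes per dimension means $27$-point grids for each
3-dimensional integral of the joint model.

Numerical details that matter:

* **Mode searches.** The inner (household) Newton iteration uses the exact
  gradient and Hessian of the integrand and is damped by step-halving; it
  converges to `1e-10`.  The outer (cluster) iteration uses the envelope
  gradient — the posterior-expected Bernoulli residual, accumulated during
  the inner quadrature — which drops the derivative of the inner
  log-determinant.  Because that makes the merit function and the gradient
  slightly inconsistent, damping is applied only to macroscopic steps;
  tiny steps are accepted unconditionally so the iteration converges to
  the unique root of the gradient regardless of its starting point.
* **Curvature at one node.** A single quadrature node cannot estimate the
  posterior-variance term of the outer Hessian, so at `quad_nodes = 1` the
  implicit-function formula $-D + D(\Sigma_H^{-1}+D)^{-1}D$ is used
  instead, with $D$ the Bernoulli information at the conditional mode.
* **Degenerate variances.** A level whose covariance block is entirely
  zero is dropped from the integration (the likelihood is then exactly
  the plain logistic one); a semidefinite but nonzero block is jittered by
  at most `1e-8` on the diagonal before factorisation.
* **Verification.** `mc_loglik_oracle()` is an independent plain
  Monte-Carlo estimate of the same integral (with a delta-method standard
  error), implemented in R with no code shared with the quadrature path.
  The test suite requires agreement within 3 Monte-Carlo standard errors
  on fixed small instances, and that the node ladder (3, 5, 7/9) forms a
  shrinking-increment sequence.

## Fitting

Variance parameters are optimized on the log-standard-deviation
(separate) or log-Cholesky (joint) scale, which enforces positive
semidefiniteness without constraints.  Optimization is L-BFGS-B with
central-difference gradients; the finite-difference evaluations restart
the Newton mode searches from the base point's modes, which makes a
gradient only a little more expensive than a handful of function
evaluations.  The joint fit runs in two stages: first the 12 covariance
parameters with the coefficients frozen at the separate-fit estimates,
then all parameters together.  The cross-covariance start is taken from
the correlation of the per-unit posterior modes of the three separate
fits — nearly free to compute and close enough that the second stage is a
short polish.

Standard errors come from the inverse observed information (numerical
central-difference Hessian, relative step `1e-4`), with the delta method
mapping the Cholesky parameters to covariance entries.  When a variance
sits at its boundary ($\hat\sigma^2 \to 0$) the information matrix is
singular in that direction; the fit is returned with the variance
reported as 0, a boundary flag, and standard errors marked unavailable
rather than fabricated.  This is not rare: with three binary observations
per household, a small household-level variance (the survey's own
household estimates for the awareness outcomes are 0.039 and 0.067) is
only weakly identified at desk-scale sizes, and its maximum-likelihood
estimate frequently collapses to zero.

Wald tables report two-sided normal p-values for coefficients and
one-sided (upper-tail) p-values for variance components — a reporting
convention for heterogeneity parameters, not a boundary-corrected test;
no multiplicity adjustment is applied.

The package fits by direct maximization of the quadrature-approximated
marginal likelihood.  An EM-type algorithm treating the random effects as
missing data would reach the same optimum at greater cost per iteration;
direct ML keeps a single, testable likelihood path shared by the fits,
the factorisation identity and the LRT.

## The synthetic-data generator

No individual-level survey data ship with the package, so every analysis
and test runs on data from `simulate_survey()`, which draws from exactly
the generative model the joint fit assumes: trivariate normal cluster and
household intercepts, independent across levels, Bernoulli outcomes
through the logistic link, covariates generated at their declared level
(individual, household or cluster), and missingness that blanks a
record's whole outcome triple at random (analysis is complete-case, with
exclusions counted).

The default emulation (`default_emulation_config()`) fixes the
conditions: diagonal variance components at the published survey
magnitudes (cluster 0.394/0.696/0.851, household 0.385/0.039/0.067),
cross-outcome correlations 0.5 at cluster level and 0.3 at household
level (the survey report gives no cross-covariance estimates; these are
one-time choices of plausible same-level association for HIV outcomes),
marginal prevalences near 0.134/0.772/0.549 via a latent-normal intercept
calibration (marginal prevalence $\approx \operatorname{expit}(\beta_0 /
\sqrt{1 + v/3.29})$ with $v$ the extra latent variance), generic covariate
effects, and a 2% missing-outcome rate.  The draw order is fixed and
documented (clusters → households → individuals → outcomes → missingness)
so a seed pins down the dataset byte-for-byte across versions.

Problem sizes are the package's desk-scale choices: the bundled demo uses
40–50 clusters of 6 households with 3 adults; parameter-recovery runs use
200 clusters × 6 × 3 with 50 replicates; LRT size runs use 200 replicates
of 40 × 5 × 3 surveys and power runs 100 replicates of 300 × 2 × 2 at
cross-correlation 0.8.  Simulation-study fits run at `quad_nodes = 1`;
the quadrature ladder is validated separately against the Monte-Carlo
oracle, so what the simulations certify is the estimation pipeline at the
Laplace point, with the small additional integration error that implies.

The size calibration deliberately uses household variances away from zero
(0.3–0.4) with three adults per household.  The $\chi^2_6$ reference for
the cross-covariance LRT presumes all six cross-covariances are free
parameters; when a household variance sits at (or its estimate collapses
to) the boundary — which happens routinely under the survey's own tiny
household components of 0.039 and 0.067, and for any component at designs
with only two adults per household — the corresponding household
cross-covariances freeze at zero in both models and the statistic behaves
like a $\chi^2$ with fewer degrees of freedom.  Measured at such designs
the test is markedly conservative (empirical size near
$P(\chi^2_3 > 12.59) \approx 0.006$ rather than 0.05), never inflated:
a rejection remains trustworthy, but the test loses power in that regime.

What passing tests do *not* show about real surveys: the generator has no
informative sampling, no survey weights or stratification, no
missingness mechanism beyond missing-completely-at-random, no covariate
dependence between levels, and no misspecification — a real survey
departs from the assumed model in all of these ways.

## Separate versus simultaneous estimates

When data truly come from the joint model, both strategies estimate the
same regression coefficients consistently; the comparison table produced
by `compare_fits()` therefore tends to show closely agreeing estimates,
and significance-class flips concentrate on terms whose p-values sit near
the chosen $\alpha$.  Large systematic coefficient differences between
the two columns of a comparison table are a sign of something beyond
shared random effects — misspecification, estimation at different scales,
or a different estimator — not an automatic consequence of correlation.
The package's own demonstration flags borderline terms only.

## Limitations

* Three outcomes are assumed throughout the user interface (the
  quadrature core is generic in dimension, but only $Q \in \{1, 3\}$ is
  exercised).
* `quad_nodes = 1` fits inherit Laplace bias — variance components are
  attenuated by a few percent at desk-scale cluster sizes.
* Boundary variance estimates get no standard errors and the LRT's
  $\chi^2_6$ reference is asymptotic; at very small surveys its size can
  drift within the tolerance the tests document.
* No survey weights, no stratification, no random slopes, no
  crossed random effects.
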