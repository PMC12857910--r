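---
title: "Variational trajectory analysis: model, priors, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational trajectory analysis: model, priors, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The generative model

`trajvi` models heterogeneous longitudinal data as a truncated
Dirichlet-process (DP) mixture of regression models.  Subject $i$ carries a
latent group indicator $z_i$ drawn from stick-breaking weights

$$\pi_k(v) = v_k \prod_{j<k}(1-v_j), \qquad v_k \sim \mathrm{Beta}(1,\alpha),
\qquad k = 1,\dots,K,$$

with the final stick implicit ($\pi_K$ is the remaining mass, so the weights
sum to one exactly).  Given $z_i = k$ and a design row $x_{it}$ (typically an
intercept plus transformations of age or time):

* each **continuous target** $d$ follows
  $y_{itd} = x_{it}^\top w_{kd} + z_{it}^\top u_{id} + \varepsilon_{itd}$ with
  $\varepsilon_{itd} \sim N(0, \lambda_{kd}^{-1})$.  Coefficients have
  independent Gaussian priors $w_{kd} \sim N(w_{0d}, \mathrm{diag}(p_{0d})^{-1})$
  and the residual precision has a conjugate Gamma prior
  $\lambda_{kd} \sim \mathrm{Gamma}(a_{0d}, b_{0d})$ — one posterior per
  component and per target, so trajectories may differ in noise level as well
  as in shape;
* each **binary target** follows a logistic model
  $b_{itd} \sim \mathrm{Bernoulli}(\sigma(x_{it}^\top w_{kd}))$ with the same
  Gaussian coefficient prior;
* optionally, continuous targets carry **subject-level random effects**
  $u_{id} \sim N(0, \Sigma_{kd})$ on a user-chosen predictor subset $z_{it}$
  (e.g. a random intercept), with an unstructured covariance shared within a
  component and regularized by an inverse-Wishart-style prior
  $(S_{0d}, \nu_{0d})$.  With random effects the model is a Bayesian
  nonparametric analogue of the latent-class mixed model; without them it is
  a group-based trajectory model.

Targets are conditionally independent given $z_i$, so the subject-level
log-likelihood is a sum over targets and visits; this is what lets the model
scale to several markers at once.  Errors are uncorrelated across visits
and targets; count targets are not supported.

Missing target cells are allowed (missing completely at random is assumed):
a missing cell simply contributes nothing to its target's likelihood terms.
Rows with missing *predictors* are rejected at load time, because the model
conditions on the design.

## The variational approximation

The posterior is approximated by the mean-field family

$$q(v)\,q(z)\,\prod_{k,d} q(w_{kd})\,q(\lambda_{kd})\,\prod_{i,d} q(u_{id}),$$

with Beta sticks, Gaussian coefficients, Gamma precisions, categorical
responsibilities $R_{ik}$, and Gaussian random-effect factors.  All updates
are closed-form; one CAVI sweep updates, in order: sticks, per-component
coefficient Gaussians, precision Gammas, random-effect posteriors and their
covariances, logistic bound parameters, and finally the responsibilities.
Responsibilities are updated *last* in the sweep: the fit starts from a
seeded random responsibility draw while all components still sit at their
identical priors, and updating responsibilities first would collapse that
initial symmetry breaking back to the uniform saddle point.  Since CAVI's
ascent property holds for any fixed update order, this choice costs nothing.

Binary targets use the Jaakkola–Jordan quadratic lower bound on the logistic
log-likelihood, with one local parameter $\xi$ per observation and component,
updated to $\xi^2 = E[(x^\top w)^2]$.  The bound never exceeds the exact
Bernoulli log-likelihood and touches it at $\xi = |x^\top w|$; because the
bound replaces the exact term, the traced objective is the *bounded* ELBO.

The random-effect covariance $\Sigma_{kd}$ is treated as a penalized point
estimate rather than a full variational factor: after each sweep it is set to
the responsibility-weighted second moment of the $u_{id}$ posteriors,
shrunk toward the prior scale,

$$\Sigma_{kd} \leftarrow \frac{S_{0d} + \sum_i R_{ik}\,E[u_{id}u_{id}^\top]}
{\nu_{0d} + q + 1 + \sum_i R_{ik}}.$$

This is the maximizer of the ELBO augmented with the log inverse-Wishart
prior density of $\Sigma_{kd}$, so the traced objective (ELBO plus that
penalty) remains monotone; the regularization also guarantees positive
definiteness.  Keeping $\Sigma$ as a point estimate keeps every other update
closed-form; the cost is that uncertainty in $\Sigma$ itself is not
propagated.

Monotonicity of the (penalized, bounded) ELBO across sweeps — to slack
1e−8 — is the package's primary correctness oracle and is asserted on every
test cohort.  In the fully conjugate single-component limit (one Gaussian
target, fixed precision, no random effects) the converged ELBO equals the
exact log marginal likelihood and the coefficient posterior equals the
textbook conjugate posterior; the test suite checks both against
independently coded closed forms.

## Prior specification workflow

`generate_prior()` turns a dataset and an a-priori trajectory-count estimate
into a complete prior:

* **Coefficient means** $w_{0d}$ come from a pooled (population-level)
  least-squares fit of each continuous target on the predictors, or a pooled
  logistic fit for binary targets (falling back to a zero-mean prior with
  standard deviation equal to the inflation factor if that fit fails, e.g.
  under complete separation).  Pooled fits are well-defined even with a
  single observation per subject.
* **Coefficient precisions** are set so the prior standard deviation is
  `inflation` (default 10) times the pooled-fit standard error — wide enough
  that distinct trajectories can move far from the pooled curve, anchored
  enough to keep the scale sensible.
* **Residual precision**: a Gamma with shape $a_0 = 2$ (weakly informative:
  finite mean and variance) and rate $b_0 = a_0 \hat\sigma^2$, so the prior
  mean precision is $1/\hat\sigma^2$.  For $\hat\sigma^2$ the package prefers
  the *within-subject* residual variance — pooled residuals of per-subject
  least-squares fits — because the pooled-fit residual variance confounds
  measurement noise with between-trajectory spread and would centre the
  precision prior far too low.  When no subject has enough observations for
  a per-subject fit, the pooled residual variance is used.
* **Random-effect scale**: $S_0$ is chosen so the prior mode of
  $\Sigma$ matches the empirical covariance of per-subject coefficient
  estimates on the random-effect predictors (the natural data-informed scale
  for between-subject variation), with $\nu_0 = q + 2$; the same value seeds
  the initial $\Sigma_{kd}$.  This matters: initializing the random-effect
  covariance far too small forces subject-level offsets to be explained by
  spurious extra mixture components.
* **Concentration**: $\alpha$ solves
  $E[\#\text{clusters}] = \sum_{i=0}^{n-1} \alpha/(\alpha+i) = k_{\text{est}}$
  by bracketed bisection to 1e−10 on the cluster-count scale.  $\alpha$ is
  fixed during inference (no hyperprior).

`sample_prior_draws()`, `plot_prior_draws()` and `plot_gamma_dists()` close
the loop: draw mean curves and precision densities from a candidate prior
and inspect them against the data before fitting.

## Fitting options and numerical choices

* **Truncation** defaults to $K = 30$ and is user-settable; analyses in this
  package's tests use $K = 5$–$10$, comfortably above the simulated group
  counts.  Occupied components (those holding more than 1% of responsibility
  mass, a user-settable threshold) are what the summaries report.
* **Initialization**: responsibilities are drawn from a symmetric
  Dirichlet(1) per subject with a user seed; all component posteriors start
  at their priors.  Fits are bit-for-bit reproducible given the seed.
* **Restarts**: CAVI finds local optima; `traj_control(restarts = r)` runs
  `r` seeded initializations and keeps the best final ELBO.  The recovery
  analyses in the tests use 1–3 restarts.
* **Convergence**: relative ELBO change below 1e−6 over one sweep, with a
  cap of 500 sweeps.
* **Degenerate components**: a component whose responsibility mass falls
  below 1e−10 is reset to its prior (which is also the exact no-data CAVI
  update), preserving the truncation-level bookkeeping rather than deleting
  components.
* **Ties** in MAP assignment break toward the lowest component index.
* A continuous target's residual precision may be *fixed* at a known value
  (`lambda_fixed` in `traj_prior()`), which removes its Gamma factor; this
  is also what makes the fully conjugate oracle comparisons exact.

## Post-fit tools

`assign_trajectory()` computes each subject's posterior over components from
the expected log mixture weights plus the log-likelihood of the subject's
observations at each component's **posterior-mean parameters** (plug-in
rule).  For random-effect targets the subject effect is integrated out
against the component's estimated covariance, giving the marginal Gaussian
likelihood.  A full posterior-predictive assignment would integrate over the
coefficient and precision posteriors as well; for the concentrated
posteriors typical after fitting, the difference is small, and the plug-in
rule keeps out-of-sample assignment cheap.  Subjects with no usable target
observation receive the prior expected weights and a warning flag.
Assignment of the training data agrees with the fitted responsibilities'
MAP labels (at least 99% in the test suite).

`summarize_traj_model()` reports, per occupied component, subject counts by
MAP assignment, coefficient posterior means with Gaussian 95% credible
intervals ($\mu \pm 1.959964\,\mathrm{sd}$), and the posterior-mean residual
standard deviation $\sqrt{b/(a-1)}$.  `tidy()`, `glance()` and `augment()`
provide the same information as tibbles.

## The synthetic-cohort generator

`simulate_cohort()` draws directly from the generative model: group
memberships from the specified proportions, sorted uniform visit times,
group-specific polynomial mean curves, optional Gaussian random effects, and
Gaussian or Bernoulli observations, with optional missing-completely-at-random
target cells.  Four pinned-seed presets are used across the test suite:

* `separated3` — 3 groups (proportions 0.35/0.40/0.25), three continuous
  targets with quadratic curves whose between-group separation exceeds five
  residual standard deviations everywhere on the time range, 300 subjects,
  5 visits each.  Used for cluster, coefficient, and residual-scale
  recovery.
* `overlap2` — 2 deliberately overlapping linear groups, 200 subjects; used
  for ELBO-ascent and determinism checks where ambiguity is wanted.
* `binary2` — 2 separable groups observed only through one binary target
  (logits of roughly ±2.5), 400 subjects, 6 visits; exercises the logistic
  bound end to end.
* `randint1` — one group with random intercepts (sd 2) around a linear
  curve with residual sd 0.5, 500 subjects; exercises the random-effect
  machinery, cross-checked in the tests against a REML mixed model fitted
  to the same data.

What the generator deliberately does **not** emulate: informative dropout or
missingness, correlated residuals, non-Gaussian noise, covariate
measurement error, unequal follow-up designs driven by outcome history, or
count outcomes.  Passing recovery tests on these cohorts therefore shows the
inference machinery is correct under the model's own assumptions — not that
the model is adequate for any particular real cohort.

## Model files

Fitted models are saved as versioned plain-text JSON with doubles encoded at
17 significant digits, so save/load round-trips reproduce every numeric
field bit-for-bit; prior files are human-readable YAML with provenance
comments.

## Limitations

Beyond the generator's idealizations listed above: mean-field variational
posteriors tend to underestimate posterior correlations (and hence some
variances); the random-effect covariance is a penalized point estimate, so
its own uncertainty is not reported; the DP concentration is fixed rather
than given a hyperprior; and CAVI converges to local optima, so restarts are
recommended for ambiguous data.
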