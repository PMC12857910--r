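# trajvi

Bayesian trajectory analysis for longitudinal data: a truncated
Dirichlet-process (DP) mixture of multi-target regression models fitted with
coordinate-ascent variational inference (CAVI).

## The problem

Longitudinal cohorts — repeated measurements of health markers, behavioural
scores, or any outcome observed over time — are often heterogeneous: distinct
subgroups of subjects follow distinct patterns of change ("trajectories").
Trajectory analysis asks three questions at once: how many subgroups are
there, what does each subgroup's mean curve look like, and which subgroup
does each subject most likely belong to?  `trajvi` answers them with a
Bayesian nonparametric model that

* simultaneously models **multiple continuous and binary targets**, assumed
  conditionally independent given trajectory membership;
* uses a **Dirichlet-process mixture** so the number of occupied groups is
  inferred from the data, guided by a prior estimate of the trajectory count;
* estimates a **separate residual-variance posterior per trajectory and per
  target**;
* optionally adds **subject-level random effects** with unstructured
  covariance to continuous targets (the latent-class mixed-model setting);
* fits by **CAVI**, which is fast, deterministic given a seed, and far less
  affected by label switching than MCMC.

## The model

For subject *i* with design rows `x_it` (e.g. `1, t, t²`) and latent group
`z_i = k` drawn from stick-breaking weights `π(v)`, `v_k ~ Beta(1, α)`
truncated at level `K`:

* continuous target *d*:
  `y_itd = x_itᵀ w_kd + z_itᵀ u_id + ε_itd`, with `ε_itd ~ N(0, 1/λ_kd)`,
  coefficient prior `w_kd ~ N(w₀d, diag(1/p₀d))`, residual precision
  `λ_kd ~ Gamma(a₀d, b₀d)`, and optional random effects
  `u_id ~ N(0, Σ_kd)` on a chosen predictor subset;
* binary target *d*: `b_itd ~ Bernoulli(σ(x_itᵀ w_kd))`, handled inside
  CAVI with the Jaakkola–Jordan quadratic bound (one local parameter `ξ` per
  observation and component), which restores Gaussian conjugacy.

The variational posterior factorizes over sticks, per-component coefficient
Gaussians, precision Gammas, subject responsibilities, and per-subject
random-effect Gaussians; every sweep has closed-form updates and the
evidence lower bound (ELBO) is non-decreasing — the package's primary
internal correctness check.

The DP concentration `α` is calibrated from the analyst's estimate of the
number of trajectories: `alpha_for_expected_clusters(k_est, n)` inverts
`E[#clusters] = Σ_{i=0}^{n−1} α/(α+i)`.

## Worked example

Three well-separated quadratic trajectory groups, three continuous targets,
300 subjects with 5 visits each:

```r
library(trajvi)

sim <- simulate_cohort(traj_sim_preset("separated3"))
td  <- traj_data(sim$data, subject = "id",
                 predictors = c("intercept", "t", "t2"),
                 targets = c("y1", "y2", "y3"))

prior <- generate_prior(td, k_est = 3, K = 10)   # alpha = 0.3434
fit   <- fit_traj(td, prior, traj_control(seed = 1, restarts = 3))
fit
#> <traj_model> K = 10 (3 occupied), 300 subjects
#>   ELBO -3122.462231 after 6 sweeps (converged)

glance(fit)
#>   n_subjects n_obs     K n_components   elbo iterations converged  seed
#> 1        300  1500    10            3 -3122.          6 TRUE          1
```

Although truncated at `K = 10`, the DP mixture leaves exactly three
components occupied — the simulated group count.  `tidy()` exposes the
coefficient posteriors (the first group was simulated with
`y1 = 5 − 0.8 t − 0.2 t²`):

```r
head(tidy(fit), 3)
#>   component target type       term      estimate std.error conf.low conf.high
#> 1         5 y1     continuous intercept   5.03      0.0234   4.99       5.08
#> 2         5 y1     continuous t          -0.789     0.0137  -0.816     -0.762
#> 3         5 y1     continuous t2         -0.241     0.0137  -0.268     -0.214

summarize_traj_model(fit)$components
#>   component n_subjects percent mass_percent
#> 1         5        103    34.3         34.3
#> 2         6        116    38.7         38.7
#> 3         7         81    27           27
```

Each subject's posterior group membership (here essentially certain):

```r
head(assign_trajectory(fit, td), 3)
#>   subject_id prob_5 prob_6 prob_7 map_label warning
#> 1 1               0      1      0         6 FALSE
#> 2 2               1      0      0         5 FALSE
#> 3 3               0      0      1         7 FALSE
```

`autoplot(fit, td)` (or `plot_model_trajs()`) overlays the observed series,
coloured by assignment, with each component's posterior-mean curve and a
±2-residual-sd band; `plot_prior_draws()` and `plot_gamma_dists()` give
visual feedback on a prior before fitting.

## Command-line workflow

The same pipeline is available as Rscript tools (installed under
`inst/cli/`, located with `traj_cli_path()`): `make_cohort`,
`generate_prior`, `viz_data_prior_draws`, `viz_gamma_dists`,
`bayes_traj_main` (fitting), `viz_model_trajs`, `summarize_traj_model` and
`assign_trajectory`.  Every tool supports `-h` and exits 0 on success, 1 on
a runtime error and 2 on a usage error:

```sh
Rscript inst/cli/make_cohort.R --preset separated3 --out data.csv --truth-out truth.csv
Rscript inst/cli/generate_prior.R --data data.csv --groupby id \
    --predictors intercept,t,t2 --targets y1,y2,y3 --k-est 3 --k 10 --out prior.yaml
Rscript inst/cli/bayes_traj_main.R --data data.csv --prior prior.yaml \
    --out model.json --seed 11 --num-restarts 2
Rscript inst/cli/summarize_traj_model.R --model model.json
Rscript inst/cli/assign_trajectory.R --model model.json --data data.csv --out assign.csv
```

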