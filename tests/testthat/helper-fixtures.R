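# Shared fixtures: cohorts are generated in code from the named presets and
# fitted once per test run (cached across test files).

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_sim <- function(name) {
  .cached(paste0("sim_", name), simulate_cohort(traj_sim_preset(name)))
}

fixture_data <- function(name) {
  sim <- fixture_sim(name)
  switch(name,
    separated3 = traj_data(sim$data, "id", c("intercept", "t", "t2"),
                           targets = c("y1", "y2", "y3")),
    overlap2 = traj_data(sim$data, "id", c("intercept", "t", "t2"),
                         targets = "y"),
    binary2 = traj_data(sim$data, "id", c("intercept", "t"),
                        targets_binary = "s"),
    randint1 = traj_data(sim$data, "id", c("intercept", "t"), targets = "y")
  )
}

fixture_fit <- function(name) {
  .cached(paste0("fit_", name), {
    td <- fixture_data(name)
    switch(name,
      separated3 = fit_traj(td, generate_prior(td, k_est = 3, K = 10),
                            traj_control(seed = 1, restarts = 3)),
      overlap2 = fit_traj(td, generate_prior(td, k_est = 2, K = 5),
                          traj_control(seed = 1, max_iter = 200)),
      binary2 = fit_traj(td, generate_prior(td, k_est = 2, K = 10),
                         traj_control(seed = 3, restarts = 3)),
      randint1 = fit_traj(td, generate_prior(td, k_est = 2, K = 5,
                                             re_predictors = "intercept"),
                          traj_control(seed = 2))
    )
  })
}

map_labels <- function(fit) apply(fit$posterior$R, 1, which.max)

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# full command-line workflow on the separated3 preset, run once per session
fixture_cli_chain <- function() {
  .cached("cli_chain", {
    dir <- file.path(tempdir(), "trajvi-cli-chain")
    dir.create(dir, showWarnings = FALSE)
    paths <- list(
      dir = dir,
      data = file.path(dir, "data.csv"),
      truth = file.path(dir, "truth.csv"),
      prior = file.path(dir, "prior.yaml"),
      model = file.path(dir, "model.json"),
      summary = file.path(dir, "summary.txt"),
      assign = file.path(dir, "assign.csv"),
      trajs = file.path(dir, "trajs.png"),
      draws = file.path(dir, "draws.png"),
      gamma = file.path(dir, "gamma.png")
    )
    status <- c(
      make_cohort = traj_cli_run("make_cohort",
        c("--preset", "separated3", "--out", paths$data,
          "--truth-out", paths$truth))$status,
      generate_prior = traj_cli_run("generate_prior",
        c("--data", paths$data, "--groupby", "id",
          "--predictors", "intercept,t,t2", "--targets", "y1,y2,y3",
          "--k-est", "3", "--k", "10", "--out", paths$prior))$status,
      viz_data_prior_draws = traj_cli_run("viz_data_prior_draws",
        c("--data", paths$data, "--prior", paths$prior, "--target", "y1",
          "--out", paths$draws))$status,
      viz_gamma_dists = traj_cli_run("viz_gamma_dists",
        c("--prior", paths$prior, "--out", paths$gamma))$status,
      bayes_traj_main = traj_cli_run("bayes_traj_main",
        c("--data", paths$data, "--prior", paths$prior, "--out", paths$model,
          "--seed", "11", "--num-restarts", "2"))$status,
      viz_model_trajs = traj_cli_run("viz_model_trajs",
        c("--model", paths$model, "--data", paths$data, "--target", "y1",
          "--out", paths$trajs))$status,
      summarize_traj_model = traj_cli_run("summarize_traj_model",
        c("--model", paths$model, "--out", paths$summary))$status,
      assign_trajectory = traj_cli_run("assign_trajectory",
        c("--model", paths$model, "--data", paths$data,
          "--out", paths$assign))$status
    )
    list(paths = paths, status = status)
  })
}

# small deterministic toy CSV: 2 subjects x 3 visits
write_toy_csv <- function(path, y = c(1, 2, 3, 4, 5, 6)) {
  df <- data.frame(id = rep(c("a", "b"), each = 3),
                   age = rep(0:2, 2), y = y)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
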