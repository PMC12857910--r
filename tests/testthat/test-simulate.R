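test_that("identical seeds reproduce identical cohorts", {
  spec <- traj_sim_preset("separated3")
  s1 <- simulate_cohort(spec)
  s2 <- simulate_cohort(spec)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(spec, seed = 999)
  expect_false(identical(s1$data, s3$data))
})

test_that("noise-free single-group cohorts lie exactly on the mean curve", {
  spec <- traj_sim_spec(n_subjects = 20, obs_per_subject = 4,
                        group_prob = 1,
                        targets = list(y = list(w = rbind(c(2, -1, 0.5)),
                                                sigma = 0)),
                        seed = 7)
  sim <- simulate_cohort(spec)
  X <- as.matrix(sim$data[c("intercept", "t", "t2")])
  expect_equal(sim$data$y, drop(X %*% c(2, -1, 0.5)), tolerance = 1e-12)
})

test_that("sampled group fractions match the specified proportions", {
  spec <- traj_sim_spec(n_subjects = 2000, obs_per_subject = 2,
                        group_prob = c(0.3, 0.7),
                        targets = list(y = list(w = rbind(c(0, 0, 0),
                                                          c(5, 0, 0)),
                                                sigma = 1)),
                        seed = 11)
  sim <- simulate_cohort(spec)
  frac <- mean(sim$truth$group == 1)
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("make_cohort writes loadable CSVs with conserved row counts", {
  dir <- withr::local_tempdir()
  data_f <- file.path(dir, "cohort.csv")
  truth_f <- file.path(dir, "truth.csv")
  sim <- make_cohort("separated3", data_f, truth_f)
  expect_equal(nrow(sim$data), 300 * 5)
  td <- read_traj_csv(data_f, "id", c("intercept", "t", "t2"),
                      targets = c("y1", "y2", "y3"))
  expect_equal(n_subjects(td), 300)
  expect_equal(nrow(td$X), 1500)
  expect_true(all(is.finite(td$X)))
  expect_true(all(rowSums(!is.na(td$Y)) == 3))
  truth <- readr::read_csv(truth_f, show_col_types = FALSE)
  expect_equal(sort(unique(truth$group)), 1:3)
  # determinism on disk
  data_f2 <- file.path(dir, "cohort2.csv")
  make_cohort("separated3", data_f2)
  expect_identical(readLines(data_f), readLines(data_f2))
})

test_that("zero-noise cohorts give exactly zero within-group residuals", {
  spec <- traj_sim_spec(n_subjects = 30, obs_per_subject = 5,
                        group_prob = c(0.5, 0.5),
                        targets = list(y = list(w = rbind(c(0, 1, 0),
                                                          c(4, -1, 0)),
                                                sigma = 0)),
                        seed = 5)
  sim <- simulate_cohort(spec)
  grp <- sim$truth$group[sim$data$id]
  X <- as.matrix(sim$data[c("intercept", "t", "t2")])
  for (g in 1:2) {
    rows <- grp == g
    fit <- lm.fit(X[rows, ], sim$data$y[rows])
    expect_lt(max(abs(fit$residuals)), 1e-10)
  }
})

test_that("missing-at-random cells are generated and masked on load", {
  spec <- traj_sim_spec(n_subjects = 100, obs_per_subject = 4,
                        group_prob = 1,
                        targets = list(y = list(w = rbind(c(1, 0, 0)),
                                                sigma = 0.5)),
                        missing_rate = 0.2, seed = 3)
  sim <- simulate_cohort(spec)
  n_miss <- sum(is.na(sim$data$y))
  expect_gt(n_miss, 0)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(sim$data, f, na = "")
  td <- read_traj_csv(f, "id", c("intercept", "t", "t2"), targets = "y")
  expect_equal(sum(is.na(td$Y)), n_miss)
})

test_that("cohort specifications round-trip through YAML configs", {
  spec <- traj_sim_spec(n_subjects = 40, obs_per_subject = c(3, 6),
                        predictors = c(intercept = "1", t = "t"),
                        group_prob = c(0.4, 0.6),
                        targets = list(y = list(
                          w = rbind(c(0, 1), c(3, -1)), sigma = c(0.5, 1),
                          re = list(predictors = "intercept",
                                    Sigma = matrix(2, 1, 1)))),
                        targets_binary = list(s = list(
                          w = rbind(c(1, 0), c(-1, 0)))),
                        seed = 77)
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    n_subjects = 40, obs_per_subject = c(3, 6),
    predictors = list(intercept = "1", t = "t"),
    group_prob = c(0.4, 0.6),
    targets = list(y = list(w = list(c(0, 1), c(3, -1)), sigma = c(0.5, 1),
                            re = list(predictors = "intercept",
                                      Sigma = list(c(2))))),
    targets_binary = list(s = list(w = list(c(1, 0), c(-1, 0)))),
    seed = 77
  ), f)
  spec2 <- read_traj_sim_spec(f)
  expect_identical(simulate_cohort(spec)$data, simulate_cohort(spec2)$data)
})
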