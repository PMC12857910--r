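# helpers building small variational states by hand ------------------------

make_simple_setup <- function(y_by_subject, lambda_fixed = 4, K = 2,
                              p0 = 1e-4) {
  n <- length(y_by_subject)
  df <- tibble::tibble(
    id = rep(seq_len(n), times = lengths(y_by_subject)),
    one = 1,
    y = unlist(y_by_subject)
  )
  td <- traj_data(df, "id", "one", targets = "y")
  pr <- traj_prior("one", targets = "y", w0 = matrix(0, 1),
                   p0 = matrix(p0, 1), a0 = 2, b0 = 2, alpha = 1, K = K,
                   lambda_fixed = c(y = lambda_fixed))
  ctx <- trajvi:::.build_ctx(td, pr)
  state <- trajvi:::.cavi_init(ctx, pr, seed = 1)
  list(td = td, pr = pr, ctx = ctx, state = state)
}

test_that("stick updates match direct substitution and a loop oracle", {
  R <- cbind(rep(1, 10), 0, 0)
  st <- trajvi:::.update_sticks(R, alpha = 1)
  expect_equal(st$g1[1], 11)
  expect_equal(st$g2[1], 1)

  R2 <- matrix(0.5, 4, 2)
  st2 <- trajvi:::.update_sticks(R2, alpha = 2)
  expect_equal(st2$g1[1], 3)
  expect_equal(st2$g2[1], 4)

  set.seed(3)
  R3 <- matrix(rgamma(7 * 5, 1), 7, 5)
  R3 <- R3 / rowSums(R3)
  st3 <- trajvi:::.update_sticks(R3, alpha = 0.7)
  for (k in 1:4) {
    g2_loop <- 0.7
    for (i in 1:7) for (j in (k + 1):5) g2_loop <- g2_loop + R3[i, j]
    expect_equal(st3$g1[k], 1 + sum(R3[, k]), tolerance = 1e-12)
    expect_equal(st3$g2[k], g2_loop, tolerance = 1e-12)
  }
})

test_that("responsibilities normalize, respect symmetry, and match arithmetic", {
  # K = 1: trivially one
  s1 <- make_simple_setup(list(c(1, 2), c(0, 1)), K = 1)
  R <- trajvi:::.update_responsibilities(s1$state, s1$ctx, s1$pr)
  expect_equal(drop(R), c(1, 1))

  # identical components and equal E[log pi] give a 50/50 split
  s2 <- make_simple_setup(list(c(1, 2), c(0, 1)), K = 2)
  s2$state$Elogpi <- c(log(0.5), log(0.5))
  R2 <- trajvi:::.update_responsibilities(s2$state, s2$ctx, s2$pr)
  expect_equal(unname(R2), matrix(0.5, 2, 2))

  # 1 subject, 2 components with point-mass coefficients: direct arithmetic
  s3 <- make_simple_setup(list(c(1.2, 0.8)), K = 2, lambda_fixed = 4)
  s3$state$Elogpi <- log(c(0.6, 0.4))
  s3$state$cont$y$mu_w <- matrix(c(1, 0), 2, 1)
  s3$state$cont$y$Sigma_w <- array(0, c(1, 1, 2))
  R3 <- trajvi:::.update_responsibilities(s3$state, s3$ctx, s3$pr)
  lik1 <- 0.6 * prod(dnorm(c(1.2, 0.8), 1, 0.5))
  lik2 <- 0.4 * prod(dnorm(c(1.2, 0.8), 0, 0.5))
  expect_equal(drop(R3), c(lik1, lik2) / (lik1 + lik2), tolerance = 1e-12)
})

test_that("coefficient updates interpolate between prior and conjugate fit", {
  set.seed(8)
  n <- 15
  df <- tibble::tibble(id = rep(1:n, each = 2), one = 1,
                       t = rnorm(2 * n), y = rnorm(2 * n, 1 + 0.5 * rnorm(1)))
  td <- traj_data(df, "id", c("one", "t"), targets = "y")
  lam <- 2.5
  w0 <- c(0.3, -0.2)
  p0 <- c(2, 5)
  pr <- traj_prior(c("one", "t"), targets = "y", w0 = matrix(w0, 1),
                   p0 = matrix(p0, 1), a0 = 2, b0 = 2, alpha = 1, K = 2,
                   lambda_fixed = c(y = lam))
  ctx <- trajvi:::.build_ctx(td, pr)
  state <- trajvi:::.cavi_init(ctx, pr, seed = 1)

  # zero responsibility: posterior equals the prior
  state$R <- cbind(rep(0, n), 1)
  state <- trajvi:::.update_coefficients_cont(state, ctx, pr, 1)
  expect_equal(state$cont$y$mu_w[1, ], w0)
  expect_equal(state$cont$y$Sigma_w[, , 1], diag(1 / p0))

  # full responsibility: textbook conjugate Bayesian linear regression,
  # computed here from the closed form as an independent oracle
  X <- ctx$cont$y$X
  y <- ctx$cont$y$y
  V <- solve(diag(p0) + lam * t(X) %*% X)
  m <- V %*% (diag(p0) %*% w0 + lam * t(X) %*% y)
  expect_equal(state$cont$y$mu_w[2, ], drop(m), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(state$cont$y$Sigma_w[, , 2], V, tolerance = 1e-10,
               ignore_attr = TRUE)

  # an extremely precise prior pins its coefficient at the prior mean
  pr2 <- pr
  pr2$p0[1, "t"] <- 1e12
  state2 <- trajvi:::.update_coefficients_cont(state, ctx, pr2, 1)
  state2$R <- cbind(rep(1, n), 0)
  state2 <- trajvi:::.update_coefficients_cont(state2, ctx, pr2, 1)
  expect_equal(state2$cont$y$mu_w[1, 2], -0.2, tolerance = 1e-5)
})

test_that("precision updates match the no-data limit and direct substitution", {
  s <- make_simple_setup(list(c(1, 1)), K = 2, lambda_fixed = NA)
  s$pr$lambda_fixed[] <- NA
  s$pr$a0[] <- 1
  s$pr$b0[] <- 1
  # component 2 has no mass: posterior equals the prior
  s$state$R <- matrix(c(1, 0), 1, 2)
  # point-mass coefficients at 0 so the residuals are exactly (1, 1)
  s$state$cont$y$mu_w <- matrix(0, 2, 1)
  s$state$cont$y$Sigma_w <- array(0, c(1, 1, 2))
  st <- trajvi:::.update_precisions(s$state, s$ctx, s$pr, 1)
  expect_equal(st$cont$y$a, c(1 + 1, 1))
  expect_equal(st$cont$y$b, c(1 + 1, 1))
})

test_that("expected squared residuals match an explicit scalar expansion", {
  set.seed(9)
  n <- 6
  df <- tibble::tibble(id = rep(1:n, each = 3), one = 1,
                       t = rnorm(3 * n), y = rnorm(3 * n))
  td <- traj_data(df, "id", c("one", "t"), targets = "y")
  pr <- generate_prior(td, k_est = 2, K = 3, re_predictors = "one")
  ctx <- trajvi:::.build_ctx(td, pr)
  state <- trajvi:::.cavi_init(ctx, pr, seed = 4)
  state <- trajvi:::.cavi_sweep(state, ctx, pr)
  er2 <- trajvi:::.exp_sq_resid(state, ctx, 1, 2)
  cd <- ctx$cont$y
  for (r in seq_along(cd$y)) {
    x <- cd$X[r, ]
    z <- cd$Z[r, , drop = FALSE]
    i <- cd$subj[r]
    mu <- sum(x * state$cont$y$mu_w[2, ]) +
      sum(z * state$re$y$mu_u[i, ])
    quad <- drop(x %*% state$cont$y$Sigma_w[, , 2] %*% x) +
      drop(z %*% state$re$y$Sigma_u[, , i] %*% t(z))
    expect_equal(er2[r], (cd$y[r] - mu)^2 + quad, tolerance = 1e-10)
  }
})

test_that("random-effect posteriors match the ridge closed form", {
  set.seed(12)
  df <- tibble::tibble(id = rep(1, 5), one = 1, t = rnorm(5),
                       y = rnorm(5, 2))
  td <- traj_data(df, "id", c("one", "t"), targets = "y")
  lam <- 3
  pr <- traj_prior(c("one", "t"), targets = "y", w0 = matrix(0, 1, 2),
                   p0 = matrix(1, 1, 2), a0 = 2, b0 = 2, alpha = 1, K = 1,
                   re = list(predictors = c("one", "t"),
                             S0 = list(y = diag(2)), nu0 = c(y = 4)),
                   lambda_fixed = c(y = lam))
  ctx <- trajvi:::.build_ctx(td, pr)
  state <- trajvi:::.cavi_init(ctx, pr, seed = 2)
  Sre <- diag(c(0.5, 2))
  state$re$y$Sigma_re[, , 1] <- Sre
  mw <- c(0.4, -0.1)
  state$cont$y$mu_w <- matrix(mw, 1, 2)
  state <- trajvi:::.update_random_effects(state, ctx, pr, "y")
  Z <- ctx$cont$y$Z
  r <- ctx$cont$y$y - drop(ctx$cont$y$X %*% mw)
  Prec <- solve(Sre) + lam * t(Z) %*% Z
  expect_equal(state$re$y$Sigma_u[, , 1], solve(Prec), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(state$re$y$mu_u[1, ], drop(solve(Prec, lam * t(Z) %*% r)),
               tolerance = 1e-10, ignore_attr = TRUE)

  # vanishing random-effect covariance shrinks the posterior mean to zero
  state$re$y$Sigma_re[, , 1] <- diag(1e-10, 2)
  state <- trajvi:::.update_random_effects(state, ctx, pr, "y")
  expect_lt(max(abs(state$re$y$mu_u)), 1e-8)
})

test_that("the Jaakkola-Jordan bound lies below the exact log-likelihood", {
  jj_bound <- function(h, xi, b) {
    lam <- trajvi:::.jj_lambda(xi)
    plogis(xi, log.p = TRUE) + ((2 * b - 1) * h - xi) / 2 -
      lam * (h^2 - xi^2)
  }
  exact <- function(h, b) plogis((2 * b - 1) * h, log.p = TRUE)
  expect_equal(jj_bound(0, 0, 1), log(0.5), tolerance = 1e-12)
  expect_equal(jj_bound(0, 0, 0), log(0.5), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:200) {
    h <- rnorm(1, 0, 3)
    xi <- abs(rnorm(1, 0, 3))
    b <- rbinom(1, 1, 0.5)
    expect_lte(jj_bound(h, xi, b), exact(h, b) + 1e-12)
    expect_lt(abs(jj_bound(h, abs(h), b) - exact(h, b)), 1e-10)
  }
})

test_that("a point-mass posterior at zero gives xi = 0 and bound log(1/2)", {
  df <- tibble::tibble(id = rep(1:4, each = 3), one = 1,
                       s = rep(c(0, 1), 6))
  td <- traj_data(df, "id", "one", targets_binary = "s")
  pr <- traj_prior("one", targets_binary = "s", w0_bin = matrix(0, 1),
                   p0_bin = matrix(1e16, 1), alpha = 1, K = 2)
  ctx <- trajvi:::.build_ctx(td, pr)
  state <- trajvi:::.cavi_init(ctx, pr, seed = 1)
  state <- trajvi:::.update_logistic(state, ctx, pr, 1)
  expect_lt(max(state$bin$s$xi), 1e-6)
  L <- trajvi:::.subject_loglik(state, ctx, pr)
  expect_equal(unname(L), matrix(3 * log(0.5), 4, 2), tolerance = 1e-6)
})

test_that("initialization is seeded, normalized, and seed-sensitive", {
  td <- fixture_data("overlap2")
  pr <- generate_prior(td, k_est = 2, K = 5)
  ctx <- trajvi:::.build_ctx(td, pr)
  s1 <- trajvi:::.cavi_init(ctx, pr, seed = 33)
  s2 <- trajvi:::.cavi_init(ctx, pr, seed = 33)
  s3 <- trajvi:::.cavi_init(ctx, pr, seed = 34)
  expect_identical(s1, s2)
  expect_false(identical(s1$R, s3$R))
  expect_equal(rowSums(s1$R), rep(1, n_subjects(td)))
  expect_true(all(s1$R >= 0))
})

test_that("the ELBO ascends on a hard mixed-target fit with missing cells", {
  spec <- traj_sim_spec(
    n_subjects = 80, obs_per_subject = c(3, 6),
    predictors = c(intercept = "1", t = "t"),
    group_prob = c(0.5, 0.5),
    targets = list(y = list(w = rbind(c(0, 1), c(2, -1)), sigma = 0.7,
                            re = list(predictors = "intercept",
                                      Sigma = matrix(1, 1, 1)))),
    targets_binary = list(s = list(w = rbind(c(1, 0.5), c(-1, 0)))),
    missing_rate = 0.15, seed = 31
  )
  sim <- simulate_cohort(spec)
  td <- traj_data(sim$data, "id", c("intercept", "t"), targets = "y",
                  targets_binary = "s")
  pr <- generate_prior(td, k_est = 2, K = 4, re_predictors = "intercept")
  fit <- fit_traj(td, pr, traj_control(seed = 6, max_iter = 60))
  expect_gte(min(diff(elbo_trace(fit))), -1e-8)
})

test_that("single-component fits reproduce the conjugate evidence exactly", {
  set.seed(14)
  n <- 8
  df <- tibble::tibble(id = rep(1:n, each = 2), one = 1, t = rnorm(2 * n),
                       y = rnorm(2 * n, 1))
  td <- traj_data(df, "id", c("one", "t"), targets = "y")
  lam <- 1.7
  w0 <- c(0.5, 0)
  p0 <- c(1.2, 3)
  pr <- traj_prior(c("one", "t"), targets = "y", w0 = matrix(w0, 1),
                   p0 = matrix(p0, 1), a0 = 2, b0 = 2, alpha = 1, K = 1,
                   lambda_fixed = c(y = lam))
  fit <- fit_traj(td, pr, traj_control(seed = 1, max_iter = 50))

  X <- td$X
  y <- td$Y[, 1]
  V <- solve(diag(p0) + lam * crossprod(X))
  m <- drop(V %*% (diag(p0) %*% w0 + lam * crossprod(X, y)))
  expect_equal(fit$posterior$cont$y$mu_w[1, ], m, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$posterior$cont$y$Sigma_w[, , 1], V, tolerance = 1e-8,
               ignore_attr = TRUE)

  # exact log marginal likelihood of the conjugate model
  Cov <- diag(1 / lam, nrow(X)) + X %*% diag(1 / p0) %*% t(X)
  r <- y - drop(X %*% w0)
  ch <- chol(Cov)
  z <- backsolve(ch, r, transpose = TRUE)
  evidence <- -0.5 * (nrow(X) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(z^2))
  expect_lte(fit$elbo, evidence + 1e-10)
  expect_lt(abs(fit$elbo - evidence), 1e-6)
})

test_that("duplicating every subject doubles the data-dependent ELBO terms", {
  fit <- fixture_fit("overlap2")
  td <- fixture_data("overlap2")
  sim <- fixture_sim("overlap2")
  df2 <- dplyr::bind_rows(sim$data,
                          dplyr::mutate(sim$data, id = id + 10000))
  td2 <- traj_data(df2, "id", c("intercept", "t", "t2"), targets = "y")
  ctx1 <- trajvi:::.build_ctx(td, fit$prior)
  ctx2 <- trajvi:::.build_ctx(td2, fit$prior)
  state2 <- fit$posterior
  state2$R <- rbind(fit$posterior$R, fit$posterior$R)
  e1 <- trajvi:::.elbo(fit$posterior, ctx1, fit$prior)
  e2 <- trajvi:::.elbo(state2, ctx2, fit$prior)
  expect_equal(e2$per_subject, 2 * e1$per_subject, tolerance = 1e-8)
  expect_equal(e2$global, e1$global, tolerance = 1e-10)
})

test_that("identical seeds give identical fits; mismatches are errors", {
  td <- fixture_data("overlap2")
  pr <- generate_prior(td, k_est = 2, K = 4)
  f1 <- fit_traj(td, pr, traj_control(seed = 17, max_iter = 25))
  f2 <- fit_traj(td, pr, traj_control(seed = 17, max_iter = 25))
  expect_identical(elbo_trace(f1), elbo_trace(f2))
  expect_identical(f1$posterior, f2$posterior)

  pr_bad <- generate_prior(fixture_data("randint1"), k_est = 2, K = 4)
  expect_error(fit_traj(td, pr_bad, traj_control(seed = 1)),
               "predictor")
})

test_that("noise-free one-group data collapses onto a single component", {
  spec <- traj_sim_spec(n_subjects = 50, obs_per_subject = 5,
                        group_prob = 1,
                        targets = list(y = list(w = rbind(c(2, 1, -0.5)),
                                                sigma = 0)),
                        seed = 19)
  sim <- simulate_cohort(spec)
  td <- traj_data(sim$data, "id", c("intercept", "t", "t2"), targets = "y")
  pr <- traj_prior(c("intercept", "t", "t2"), targets = "y",
                   w0 = matrix(0, 1, 3), p0 = matrix(1e-4, 1, 3),
                   a0 = 2, b0 = 2, alpha = 0.5, K = 5)
  fit <- fit_traj(td, pr, traj_control(seed = 2, max_iter = 100))
  expect_gte(max(colSums(fit$posterior$R)) / 50, 0.99)
  expect_gte(min(diff(elbo_trace(fit))), -1e-8)
})

test_that("subject order only permutes labels, not the partition", {
  spec <- traj_sim_spec(n_subjects = 120, obs_per_subject = 4,
                        predictors = c(intercept = "1", t = "t"),
                        group_prob = c(0.5, 0.5),
                        targets = list(y = list(w = rbind(c(0, 1),
                                                          c(5, -1)),
                                                sigma = 0.5)),
                        seed = 23)
  sim <- simulate_cohort(spec)
  td <- traj_data(sim$data, "id", c("intercept", "t"), targets = "y")
  pr <- generate_prior(td, k_est = 2, K = 5)
  f1 <- fit_traj(td, pr, traj_control(seed = 4, restarts = 2))
  set.seed(99)
  perm <- sample(120)
  df_perm <- dplyr::arrange(sim$data, match(id, perm))
  td_perm <- traj_data(df_perm, "id", c("intercept", "t"), targets = "y")
  f2 <- fit_traj(td_perm, pr, traj_control(seed = 4, restarts = 2))
  m1 <- map_labels(f1)
  m2 <- map_labels(f2)[match(names(map_labels(f1)), names(map_labels(f2)))]
  expect_equal(ari(m1, m2), 1)
})
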