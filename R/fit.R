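#' Fitting options for the variational trajectory model
#'
#' @param max_iter Maximum number of full coordinate-ascent sweeps
#'   (default 500).
#' @param tol Relative ELBO-change convergence tolerance per sweep
#'   (default 1e-6).
#' @param restarts Number of random restarts; the fit with the best final
#'   ELBO is kept (default 1).
#' @param seed Integer seed controlling the random initialization.  Restart
#'   `r` uses `seed + r - 1`.
#' @param verbose If `TRUE`, print the ELBO trace while fitting.
#' @return A list of class `traj_control`.
#' @export
traj_control <- function(max_iter = 500, tol = 1e-6, restarts = 1,
                         seed = NULL, verbose = FALSE) {
  stopifnot(max_iter >= 1, tol > 0, restarts >= 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 restarts = as.integer(restarts),
                 seed = if (!is.null(seed)) as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "traj_control")
}

# ---- precomputed data context -------------------------------------------

.build_ctx <- function(data, prior) {
  stopifnot(inherits(data, "traj_data"), inherits(prior, "traj_prior"))
  if (!identical(data$predictors, prior$predictors)) {
    stop("predictor columns of data (",
         paste(data$predictors, collapse = ", "),
         ") do not match the prior (",
         paste(prior$predictors, collapse = ", "), ")", call. = FALSE)
  }
  if (!identical(data$targets, prior$targets) ||
      !identical(data$targets_binary, prior$targets_binary)) {
    stop("target columns of data (",
         paste(c(data$targets, data$targets_binary), collapse = ", "),
         ") do not match the prior (",
         paste(c(prior$targets, prior$targets_binary), collapse = ", "),
         ")", call. = FALSE)
  }
  re_targets <- if (!is.null(prior$re)) names(prior$re$S0) else character()
  re_idx <- if (!is.null(prior$re)) {
    match(prior$re$predictors, prior$predictors)
  }
  cont <- lapply(seq_along(data$targets), function(d) {
    rows <- which(!is.na(data$Y[, d]))
    out <- list(rows = rows, y = data$Y[rows, d],
                X = data$X[rows, , drop = FALSE],
                subj = data$subj_index[rows])
    if (data$targets[d] %in% re_targets) {
      out$Z <- out$X[, re_idx, drop = FALSE]
    }
    out
  })
  names(cont) <- data$targets
  bin <- lapply(seq_along(data$targets_binary), function(d) {
    rows <- which(!is.na(data$B[, d]))
    list(rows = rows, b = data$B[rows, d],
         X = data$X[rows, , drop = FALSE],
         subj = data$subj_index[rows])
  })
  names(bin) <- data$targets_binary
  list(n = length(data$subjects), subjects = data$subjects,
       M = length(data$predictors), cont = cont, bin = bin,
       re_targets = re_targets, re_idx = re_idx,
       q = length(re_idx))
}

# ---- initialization ------------------------------------------------------

.cavi_init <- function(ctx, prior, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- prior$K
  M <- ctx$M
  n <- ctx$n
  # responsibilities from a symmetric Dirichlet(1) draw per subject
  R <- matrix(stats::rgamma(n * K, shape = 1, rate = 1), n, K)
  R <- R / rowSums(R)

  state <- list(K = K, alpha = prior$alpha, R = R,
                g1 = if (K > 1) rep(1, K - 1),
                g2 = if (K > 1) rep(prior$alpha, K - 1),
                Elogpi = rep(-log(K), K))
  state$cont <- lapply(seq_along(prior$targets), function(d) {
    Sig0 <- diag(1 / prior$p0[d, ], M)
    list(mu_w = matrix(prior$w0[d, ], K, M, byrow = TRUE),
         Sigma_w = array(unname(Sig0), c(M, M, K)),
         a = rep(unname(prior$a0[d]), K), b = rep(unname(prior$b0[d]), K))
  })
  names(state$cont) <- prior$targets
  state$bin <- lapply(seq_along(prior$targets_binary), function(d) {
    Sig0 <- diag(1 / prior$p0_bin[d, ], M)
    Xd <- ctx$bin[[d]]$X
    xi0 <- sqrt(rowSums((Xd %*% (Sig0 +
             tcrossprod(prior$w0_bin[d, ]))) * Xd))
    list(mu_w = matrix(prior$w0_bin[d, ], K, M, byrow = TRUE),
         Sigma_w = array(Sig0, c(M, M, K)),
         xi = matrix(xi0, K, length(xi0), byrow = TRUE))
  })
  names(state$bin) <- prior$targets_binary
  if (length(ctx$re_targets) > 0) {
    q <- ctx$q
    state$re <- lapply(ctx$re_targets, function(tg) {
      S_init <- prior$re$S0[[tg]] / (prior$re$nu0[tg] + q + 1)
      list(mu_u = matrix(0, n, q),
           Sigma_u = array(S_init, c(q, q, n)),
           Sigma_re = array(S_init, c(q, q, K)))
    })
    names(state$re) <- ctx$re_targets
  }
  state
}

# ---- factor expectations and helpers ------------------------------------

.jj_lambda <- function(xi) {
  out <- rep(0.125, length(xi))
  big <- xi > 1e-8
  out[big] <- tanh(xi[big] / 2) / (4 * xi[big])
  out
}

.elam <- function(state, prior, d) {
  lf <- prior$lambda_fixed[d]
  if (!is.na(lf)) rep(lf, state$K) else state$cont[[d]]$a / state$cont[[d]]$b
}

.eloglam <- function(state, prior, d) {
  lf <- prior$lambda_fixed[d]
  if (!is.na(lf)) {
    rep(log(lf), state$K)
  } else {
    digamma(state$cont[[d]]$a) - log(state$cont[[d]]$b)
  }
}

.elogpi_from_sticks <- function(g1, g2, K) {
  if (K == 1) return(0)
  Elogv <- digamma(g1) - digamma(g1 + g2)
  Elog1mv <- digamma(g2) - digamma(g1 + g2)
  cum <- c(0, cumsum(Elog1mv))
  c(Elogv + cum[seq_len(K - 1)], cum[K])
}

.logdet <- function(S) 2 * sum(log(diag(chol(S))))

# ---- coordinate updates --------------------------------------------------

.update_sticks <- function(R, alpha) {
  K <- ncol(R)
  Nk <- colSums(R)
  tail_mass <- rev(cumsum(rev(Nk)))           # sum_{j >= k} N_j
  list(g1 = 1 + Nk[seq_len(K - 1)],
       g2 = alpha + tail_mass[seq_len(K - 1) + 1])
}

.update_coefficients_cont <- function(state, ctx, prior, d) {
  cd <- ctx$cont[[d]]
  sc <- state$cont[[d]]
  tg <- names(ctx$cont)[d]
  has_re <- !is.null(cd$Z)
  Elam <- .elam(state, prior, d)
  p0 <- prior$p0[d, ]
  w0 <- prior$w0[d, ]
  ystar <- cd$y
  if (has_re) {
    ystar <- ystar - rowSums(cd$Z * state$re[[tg]]$mu_u[cd$subj, ,
                                                        drop = FALSE])
  }
  for (k in seq_len(state$K)) {
    wr <- state$R[cd$subj, k]
    if (sum(wr) < 1e-10) {                     # empty component: prior
      sc$mu_w[k, ] <- w0
      sc$Sigma_w[, , k] <- diag(1 / p0, ctx$M)
      next
    }
    P <- diag(p0, ctx$M) + Elam[k] * crossprod(cd$X * wr, cd$X)
    cP <- tryCatch(chol(P), error = function(e) {
      stop("singular coefficient posterior precision for target '", tg,
           "', component ", k, call. = FALSE)
    })
    Sig <- chol2inv(cP)
    sc$Sigma_w[, , k] <- Sig
    sc$mu_w[k, ] <- Sig %*% (p0 * w0 + Elam[k] * crossprod(cd$X, wr * ystar))
  }
  state$cont[[d]] <- sc
  state
}

# expected squared residual per row of target d for component k
.exp_sq_resid <- function(state, ctx, d, k) {
  cd <- ctx$cont[[d]]
  sc <- state$cont[[d]]
  tg <- names(ctx$cont)[d]
  m <- drop(cd$X %*% sc$mu_w[k, ])
  quad_x <- rowSums((cd$X %*% sc$Sigma_w[, , k]) * cd$X)
  r <- cd$y - m
  quad_z <- 0
  if (!is.null(cd$Z)) {
    st <- state$re[[tg]]
    r <- r - rowSums(cd$Z * st$mu_u[cd$subj, , drop = FALSE])
    q <- ncol(cd$Z)
    for (a_ in seq_len(q)) {
      for (b_ in seq_len(q)) {
        quad_z <- quad_z + cd$Z[, a_] * cd$Z[, b_] *
          st$Sigma_u[a_, b_, cd$subj]
      }
    }
  }
  r^2 + quad_x + quad_z
}

.update_precisions <- function(state, ctx, prior, d) {
  if (!is.na(prior$lambda_fixed[d])) return(state)
  cd <- ctx$cont[[d]]
  for (k in seq_len(state$K)) {
    wr <- state$R[cd$subj, k]
    state$cont[[d]]$a[k] <- prior$a0[d] + 0.5 * sum(wr)
    state$cont[[d]]$b[k] <- prior$b0[d] +
      0.5 * sum(wr * .exp_sq_resid(state, ctx, d, k))
  }
  state
}

.update_random_effects <- function(state, ctx, prior, tg) {
  d <- match(tg, names(ctx$cont))
  cd <- ctx$cont[[d]]
  st <- state$re[[tg]]
  q <- ctx$q
  K <- state$K
  Elam <- .elam(state, prior, d)
  invSre <- array(0, c(q, q, K))
  for (k in seq_len(K)) invSre[, , k] <- chol2inv(chol(st$Sigma_re[, , k]))
  # responsibility-weighted prior precision and noise precision per subject
  invSre_flat <- matrix(invSre, q * q, K)            # (q*q) x K
  A <- state$R %*% t(invSre_flat)                    # n x (q*q)
  cvec <- drop(state$R %*% Elam)                     # n
  # responsibility- and precision-weighted coefficient means per subject
  W <- (state$R * matrix(Elam, ctx$n, K, byrow = TRUE)) %*%
    state$cont[[d]]$mu_w                             # n x M
  rows_by_subj <- split(seq_along(cd$subj), cd$subj)
  for (i in seq_len(ctx$n)) {
    rows <- rows_by_subj[[as.character(i)]]
    if (is.null(rows)) {
      # no usable observations: posterior is the R-weighted prior mixture
      Prec <- matrix(A[i, ], q, q)
      st$Sigma_u[, , i] <- chol2inv(chol(Prec))
      st$mu_u[i, ] <- 0
      next
    }
    Zi <- cd$Z[rows, , drop = FALSE]
    Xi <- cd$X[rows, , drop = FALSE]
    yi <- cd$y[rows]
    Prec <- matrix(A[i, ], q, q) + cvec[i] * crossprod(Zi)
    rhs <- cvec[i] * crossprod(Zi, yi) - crossprod(Zi, Xi %*% W[i, ])
    Sig <- chol2inv(chol(Prec))
    st$Sigma_u[, , i] <- Sig
    st$mu_u[i, ] <- Sig %*% rhs
  }
  state$re[[tg]] <- st
  state
}

.update_re_cov <- function(state, ctx, prior, tg) {
  st <- state$re[[tg]]
  q <- ctx$q
  S0 <- prior$re$S0[[tg]]
  nu0 <- prior$re$nu0[tg]
  Euu <- array(0, c(q, q, ctx$n))
  for (i in seq_len(ctx$n)) {
    Euu[, , i] <- st$Sigma_u[, , i] + tcrossprod(st$mu_u[i, ])
  }
  Euu_flat <- matrix(Euu, q * q, ctx$n)
  Nk <- colSums(state$R)
  Sk <- Euu_flat %*% state$R                        # (q*q) x K
  for (k in seq_len(state$K)) {
    state$re[[tg]]$Sigma_re[, , k] <-
      (S0 + matrix(Sk[, k], q, q)) / (nu0 + q + 1 + Nk[k])
  }
  state
}

.update_logistic <- function(state, ctx, prior, d) {
  bd <- ctx$bin[[d]]
  sb <- state$bin[[d]]
  p0 <- prior$p0_bin[d, ]
  w0 <- prior$w0_bin[d, ]
  for (k in seq_len(state$K)) {
    wr <- state$R[bd$subj, k]
    lam <- .jj_lambda(sb$xi[k, ])
    if (sum(wr) < 1e-10) {
      sb$mu_w[k, ] <- w0
      sb$Sigma_w[, , k] <- diag(1 / p0, ctx$M)
    } else {
      P <- diag(p0, ctx$M) + 2 * crossprod(bd$X * (wr * lam), bd$X)
      Sig <- chol2inv(chol(P))
      sb$Sigma_w[, , k] <- Sig
      sb$mu_w[k, ] <- Sig %*% (p0 * w0 + crossprod(bd$X, wr * (bd$b - 0.5)))
    }
    # local bound parameters: xi^2 = E[(x'w)^2]
    m <- drop(bd$X %*% sb$mu_w[k, ])
    quad <- rowSums((bd$X %*% sb$Sigma_w[, , k]) * bd$X)
    sb$xi[k, ] <- sqrt(pmax(quad + m^2, 0))
  }
  state$bin[[d]] <- sb
  state
}

# ---- subject-level expected log-likelihood matrix ------------------------

# n x K matrix of Sum_d Sum_{t in i} E[log p(y_itd | z_i = k)] plus, for
# random-effect targets, E[log p(u_id | Sigma_re_kd)]
.subject_loglik <- function(state, ctx, prior) {
  n <- ctx$n
  K <- state$K
  L <- matrix(0, n, K)
  for (d in seq_along(ctx$cont)) {
    cd <- ctx$cont[[d]]
    tg <- names(ctx$cont)[d]
    Elam <- .elam(state, prior, d)
    Eloglam <- .eloglam(state, prior, d)
    for (k in seq_len(K)) {
      ll <- 0.5 * (Eloglam[k] - log(2 * pi)) -
        0.5 * Elam[k] * .exp_sq_resid(state, ctx, d, k)
      agg <- rowsum(ll, cd$subj)
      L[as.integer(rownames(agg)), k] <- L[as.integer(rownames(agg)), k] +
        agg[, 1]
    }
    if (!is.null(cd$Z)) {
      st <- state$re[[tg]]
      q <- ctx$q
      Euu_flat <- matrix(0, n, q * q)
      for (i in seq_len(n)) {
        Euu_flat[i, ] <- as.vector(st$Sigma_u[, , i] +
                                     tcrossprod(st$mu_u[i, ]))
      }
      invSre_flat <- matrix(0, q * q, K)
      ldet <- numeric(K)
      for (k in seq_len(K)) {
        Sre <- st$Sigma_re[, , k]
        invSre_flat[, k] <- as.vector(chol2inv(chol(Sre)))
        ldet[k] <- .logdet(Sre)
      }
      L <- L - 0.5 * Euu_flat %*% invSre_flat -
        matrix(0.5 * (q * log(2 * pi) + ldet), n, K, byrow = TRUE)
    }
  }
  for (d in seq_along(ctx$bin)) {
    bd <- ctx$bin[[d]]
    sb <- state$bin[[d]]
    for (k in seq_len(K)) {
      m <- drop(bd$X %*% sb$mu_w[k, ])
      Eh2 <- rowSums((bd$X %*% sb$Sigma_w[, , k]) * bd$X) + m^2
      xi <- sb$xi[k, ]
      lam <- .jj_lambda(xi)
      bound <- stats::plogis(xi, log.p = TRUE) - xi / 2 + lam * xi^2 +
        (bd$b - 0.5) * m - lam * Eh2
      agg <- rowsum(bound, bd$subj)
      L[as.integer(rownames(agg)), k] <- L[as.integer(rownames(agg)), k] +
        agg[, 1]
    }
  }
  L
}

.update_responsibilities <- function(state, ctx, prior) {
  L <- .subject_loglik(state, ctx, prior)
  logR <- sweep(L, 2, state$Elogpi, "+")
  mx <- apply(logR, 1, max)
  bad <- which(!is.finite(mx))
  if (length(bad) > 0) {
    stop("responsibility update degenerate (all components -Inf) for ",
         "subject '", ctx$subjects[bad[1]], "'", call. = FALSE)
  }
  R <- exp(logR - mx)
  R / rowSums(R)
}

# ---- evidence lower bound ------------------------------------------------

.gauss_kl_diagprior <- function(mu1, Sig1, mu0, p0) {
  M <- length(mu1)
  0.5 * (sum(p0 * diag(Sig1)) + sum(p0 * (mu0 - mu1)^2) - M -
           sum(log(p0)) - .logdet(Sig1))
}

.gamma_kl <- function(a, b, a0, b0) {
  (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
}

.beta_kl_stick <- function(g1, g2, alpha) {
  -log(alpha) - lbeta(g1, g2) + (g1 - 1) * digamma(g1) +
    (g2 - alpha) * digamma(g2) + (1 + alpha - g1 - g2) * digamma(g1 + g2)
}

.elbo <- function(state, ctx, prior) {
  K <- state$K
  R <- state$R
  L <- .subject_loglik(state, ctx, prior)
  lr <- ifelse(R > 0, log(R), 0)
  assign_term <- sum(R * (L + matrix(state$Elogpi, ctx$n, K, byrow = TRUE) -
                            lr))
  u_entropy <- 0
  for (tg in ctx$re_targets) {
    st <- state$re[[tg]]
    q <- ctx$q
    for (i in seq_len(ctx$n)) {
      u_entropy <- u_entropy +
        0.5 * (q * (1 + log(2 * pi)) + .logdet(st$Sigma_u[, , i]))
    }
  }
  kl_sticks <- if (K > 1) {
    sum(.beta_kl_stick(state$g1, state$g2, prior$alpha))
  } else 0
  kl_coef <- 0
  kl_prec <- 0
  for (d in seq_along(ctx$cont)) {
    sc <- state$cont[[d]]
    for (k in seq_len(K)) {
      kl_coef <- kl_coef + .gauss_kl_diagprior(sc$mu_w[k, ],
                                               sc$Sigma_w[, , k],
                                               prior$w0[d, ], prior$p0[d, ])
    }
    if (is.na(prior$lambda_fixed[d])) {
      kl_prec <- kl_prec + sum(.gamma_kl(sc$a, sc$b, prior$a0[d],
                                         prior$b0[d]))
    }
  }
  for (d in seq_along(ctx$bin)) {
    sb <- state$bin[[d]]
    for (k in seq_len(K)) {
      kl_coef <- kl_coef + .gauss_kl_diagprior(sb$mu_w[k, ],
                                               sb$Sigma_w[, , k],
                                               prior$w0_bin[d, ],
                                               prior$p0_bin[d, ])
    }
  }
  re_penalty <- 0
  for (tg in ctx$re_targets) {
    st <- state$re[[tg]]
    q <- ctx$q
    S0 <- prior$re$S0[[tg]]
    nu0 <- prior$re$nu0[tg]
    for (k in seq_len(K)) {
      iS <- chol2inv(chol(st$Sigma_re[, , k]))
      re_penalty <- re_penalty -
        0.5 * ((nu0 + q + 1) * .logdet(st$Sigma_re[, , k]) + sum(S0 * iS))
    }
  }
  per_subject <- assign_term + u_entropy
  global <- -kl_sticks - kl_coef - kl_prec + re_penalty
  list(total = per_subject + global,
       per_subject = per_subject, global = global,
       parts = c(assignment = assign_term, u_entropy = u_entropy,
                 kl_sticks = kl_sticks, kl_coefficients = kl_coef,
                 kl_precisions = kl_prec, re_penalty = re_penalty))
}

# ---- one full sweep ------------------------------------------------------

.cavi_sweep <- function(state, ctx, prior) {
  if (state$K > 1) {
    st <- .update_sticks(state$R, prior$alpha)
    state$g1 <- st$g1
    state$g2 <- st$g2
  }
  state$Elogpi <- .elogpi_from_sticks(state$g1, state$g2, state$K)
  for (d in seq_along(ctx$cont)) {
    state <- .update_coefficients_cont(state, ctx, prior, d)
    state <- .update_precisions(state, ctx, prior, d)
  }
  for (tg in ctx$re_targets) {
    state <- .update_random_effects(state, ctx, prior, tg)
    state <- .update_re_cov(state, ctx, prior, tg)
  }
  for (d in seq_along(ctx$bin)) {
    state <- .update_logistic(state, ctx, prior, d)
  }
  state$R <- .update_responsibilities(state, ctx, prior)
  state
}

#' Fit the Dirichlet-process mixture of trajectory regressions
#'
#' Runs coordinate-ascent variational inference on a truncated (level `K`)
#' stick-breaking representation of a Dirichlet-process mixture in which each
#' component is a multi-target regression: Gaussian likelihoods with
#' per-component residual-precision posteriors for continuous targets,
#' logistic likelihoods handled through the Jaakkola–Jordan quadratic bound
#' for binary targets, and optional subject-level random effects with
#' unstructured covariance.  Each sweep updates the stick Beta factors,
#' per-component coefficient Gaussians, residual-precision Gammas,
#' random-effect posteriors, local logistic bound parameters, and subject
#' responsibilities; the (bounded) evidence lower bound is non-decreasing
#' across sweeps and is used as the convergence criterion.
#'
#' @param data A `traj_data` object whose predictor and target columns match
#'   the prior.
#' @param prior A `traj_prior` object (see [generate_prior()]).
#' @param control A [traj_control()] list of fitting options.
#' @return An object of class `traj_model` holding the prior, all variational
#'   posterior factors (including the `n x K` responsibility matrix), the
#'   ELBO trace, and fitting metadata.  Methods: [tidy()][tidy.traj_model],
#'   [glance()][glance.traj_model], [augment()][augment.traj_model],
#'   [autoplot()][autoplot.traj_model], `print()`.
#' @export
#' @examples
#' sim <- simulate_cohort(traj_sim_preset("overlap2"))
#' td <- traj_data(sim$data, "id", c("intercept", "t", "t2"), targets = "y")
#' pr <- generate_prior(td, k_est = 2, K = 5)
#' fit <- fit_traj(td, pr, traj_control(seed = 1, max_iter = 50))
#' glance(fit)
fit_traj <- function(data, prior, control = traj_control()) {
  stopifnot(inherits(control, "traj_control"))
  ctx <- .build_ctx(data, prior)
  seed <- control$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)

  best <- NULL
  for (r in seq_len(control$restarts)) {
    rseed <- seed + r - 1L
    state <- .cavi_init(ctx, prior, seed = rseed)
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(control$max_iter)) {
      state <- .cavi_sweep(state, ctx, prior)
      el <- .elbo(state, ctx, prior)$total
      if (!is.finite(el)) {
        stop("non-finite ELBO at sweep ", it, call. = FALSE)
      }
      trace <- c(trace, el)
      if (control$verbose) {
        message(sprintf("restart %d sweep %d ELBO %.6f", r, it, el))
      }
      if (it > 1 &&
          abs(el - trace[it - 1]) / (abs(trace[it - 1]) + 1e-12) <
            control$tol) {
        converged <- TRUE
        break
      }
    }
    if (is.null(best) || trace[length(trace)] > best$elbo) {
      best <- list(state = state, trace = trace, elbo = trace[length(trace)],
                   converged = converged, seed = rseed, restart = r)
    }
  }

  rownames(best$state$R) <- data$subjects
  structure(list(
    prior = prior,
    posterior = best$state,
    elbo = best$elbo,
    elbo_trace = best$trace,
    iterations = length(best$trace),
    converged = best$converged,
    seed = best$seed,
    restart = best$restart,
    subject_col = data$subject_col,
    predictors = data$predictors,
    targets = data$targets,
    targets_binary = data$targets_binary,
    subjects = data$subjects,
    n_subjects = length(data$subjects),
    n_obs = nrow(data$X),
    version = "1"
  ), class = "traj_model")
}

#' @export
print.traj_model <- function(x, ...) {
  occ <- sum(colSums(x$posterior$R) / x$n_subjects > 0.01)
  cat("<traj_model> K = ", x$prior$K, " (", occ,
      " occupied), ", x$n_subjects, " subjects\n", sep = "")
  cat("  ELBO ", format(x$elbo, digits = 10), " after ", x$iterations,
      " sweeps (", if (x$converged) "converged" else "max iterations",
      ")\n", sep = "")
  invisible(x)
}

#' ELBO trace of a fitted trajectory model
#' @param model A `traj_model`.
#' @return Numeric vector of the evidence lower bound after each sweep.
#' @export
elbo_trace <- function(model) {
  stopifnot(inherits(model, "traj_model"))
  model$elbo_trace
}
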