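#' Construct a prior specification for trajectory model fitting
#'
#' Collects every hyperparameter of the truncated Dirichlet-process mixture of
#' regressions: per-target coefficient prior means and precisions, residual
#' precision Gamma parameters for continuous targets, an optional
#' random-effect block (inverse-Wishart-style scale matrix and degrees of
#' freedom), the DP concentration `alpha`, and the truncation level `K`.
#'
#' Most users will not call this directly: [generate_prior()] builds a
#' data-informed prior and [read_traj_prior()] loads one from file.
#'
#' @param predictors Character vector of predictor names (length `M`).
#' @param targets Character vector of continuous target names.
#' @param targets_binary Character vector of binary target names.
#' @param w0,p0 Coefficient prior means and precisions for continuous
#'   targets: numeric matrices with one row per target and one column per
#'   predictor (`p0` strictly positive).
#' @param a0,b0 Gamma shape and rate for each continuous target's residual
#'   precision prior (named or positional numeric vectors, strictly positive).
#' @param w0_bin,p0_bin Coefficient prior means/precisions for binary targets.
#' @param alpha Positive DP concentration.
#' @param K Truncation level of the stick-breaking representation (default
#'   30).
#' @param re Optional random-effect block: a list with elements `predictors`
#'   (subset of `predictors` carrying random effects), `S0` (named list of
#'   symmetric positive-definite scale matrices, one per continuous target
#'   with random effects) and `nu0` (named numeric degrees of freedom, each
#'   greater than the random-effect dimension minus one).
#' @param lambda_fixed Optional named numeric vector fixing the residual
#'   precision of selected continuous targets at a known value instead of
#'   inferring it (use `NA` to infer; the default infers all).
#'
#' @return An object of class `traj_prior`.
#' @export
traj_prior <- function(predictors, targets = character(),
                       targets_binary = character(),
                       w0 = NULL, p0 = NULL, a0 = NULL, b0 = NULL,
                       w0_bin = NULL, p0_bin = NULL,
                       alpha = 1, K = 30, re = NULL, lambda_fixed = NULL) {
  M <- length(predictors)
  Dc <- length(targets)
  Db <- length(targets_binary)
  if (M == 0) stop("at least one predictor is required", call. = FALSE)
  if (Dc + Db == 0) stop("at least one target is required", call. = FALSE)

  shape <- function(m, default, what) {
    if (is.null(m)) m <- default
    m <- matrix(as.numeric(m), nrow = nrow(default), ncol = M)
    dimnames(m) <- dimnames(default)
    if (anyNA(m)) stop(what, " contains missing values", call. = FALSE)
    m
  }
  blank_c <- matrix(0, Dc, M, dimnames = list(targets, predictors))
  blank_b <- matrix(0, Db, M, dimnames = list(targets_binary, predictors))
  w0 <- shape(w0, blank_c, "w0")
  p0 <- shape(p0, blank_c + 1e-2, "p0")
  w0_bin <- shape(w0_bin, blank_b, "w0_bin")
  p0_bin <- shape(p0_bin, blank_b + 1e-2, "p0_bin")

  vec <- function(v, default, what) {
    if (is.null(v)) v <- default
    v <- as.numeric(v)[seq_len(Dc)]
    names(v) <- targets
    v
  }
  a0 <- vec(a0, rep(2, Dc))
  b0 <- vec(b0, rep(2, Dc))
  lf <- rep(NA_real_, Dc)
  names(lf) <- targets
  if (!is.null(lambda_fixed)) {
    lf[names(lambda_fixed)] <- as.numeric(lambda_fixed)
  }

  if (Dc > 0 && (any(p0 <= 0) || any(a0 <= 0) || any(b0 <= 0))) {
    stop("precisions, Gamma shapes and rates must be strictly positive",
         call. = FALSE)
  }
  if (Db > 0 && any(p0_bin <= 0)) {
    stop("binary-target prior precisions must be strictly positive",
         call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0) {
    stop("alpha must be positive", call. = FALSE)
  }
  K <- as.integer(K)
  if (is.na(K) || K < 1) stop("K must be a positive integer", call. = FALSE)

  if (!is.null(re)) re <- .validate_re_block(re, predictors, targets)

  structure(list(
    predictors = predictors, targets = targets,
    targets_binary = targets_binary,
    w0 = w0, p0 = p0, a0 = a0, b0 = b0,
    w0_bin = w0_bin, p0_bin = p0_bin,
    lambda_fixed = lf, re = re,
    alpha = as.numeric(alpha), K = K
  ), class = "traj_prior")
}

.validate_re_block <- function(re, predictors, targets) {
  if (!is.list(re) || is.null(re$predictors) || is.null(re$S0)) {
    stop("re block must list 'predictors' and 'S0'", call. = FALSE)
  }
  if (!all(re$predictors %in% predictors)) {
    stop("random-effect predictors must be a subset of the predictors",
         call. = FALSE)
  }
  q <- length(re$predictors)
  re$S0 <- lapply(re$S0, function(S) {
    S <- matrix(as.numeric(S), q, q)
    if (any(abs(S - t(S)) > 1e-10) ||
        inherits(try(chol(S), silent = TRUE), "try-error")) {
      stop("random-effect scale matrix S0 must be symmetric positive definite",
           call. = FALSE)
    }
    S
  })
  if (!all(names(re$S0) %in% targets)) {
    stop("random-effect targets must be continuous targets", call. = FALSE)
  }
  if (is.null(re$nu0)) re$nu0 <- stats::setNames(rep(q + 2, length(re$S0)),
                                                 names(re$S0))
  re$nu0 <- stats::setNames(as.numeric(re$nu0)[seq_along(re$S0)],
                            names(re$S0))
  if (any(re$nu0 <= q - 1)) {
    stop("random-effect degrees of freedom nu0 must exceed q - 1",
         call. = FALSE)
  }
  re
}

#' @export
print.traj_prior <- function(x, ...) {
  cat("<traj_prior> K = ", x$K, ", alpha = ", signif(x$alpha, 4), "\n",
      sep = "")
  cat("  predictors: ", paste(x$predictors, collapse = ", "), "\n", sep = "")
  if (length(x$targets) > 0) {
    cat("  continuous targets: ", paste(x$targets, collapse = ", "), "\n",
        sep = "")
  }
  if (length(x$targets_binary) > 0) {
    cat("  binary targets: ", paste(x$targets_binary, collapse = ", "), "\n",
        sep = "")
  }
  if (!is.null(x$re)) {
    cat("  random effects on: ", paste(x$re$predictors, collapse = ", "),
        " (targets: ", paste(names(x$re$S0), collapse = ", "), ")\n",
        sep = "")
  }
  invisible(x)
}

#' Generate a data-informed prior specification
#'
#' Seeds coefficient prior means from pooled (population-level) regressions of
#' each target on the predictors — ordinary least squares for continuous
#' targets, logistic regression for binary targets — and widens them by an
#' inflation factor: each coefficient's prior standard deviation is
#' `inflation` times its pooled-fit standard error.  The residual-precision
#' prior for each continuous target is a Gamma with shape `a0 = 2` whose mean
#' equals the reciprocal of the pooled residual variance.  The DP
#' concentration is calibrated so that the prior expected number of occupied
#' clusters equals `k_est` via [alpha_for_expected_clusters()].
#'
#' @param data A `traj_data` object.
#' @param k_est A-priori estimate of the number of trajectories (must be at
#'   least 1 and less than the number of subjects).
#' @param inflation Positive multiplier widening each coefficient prior
#'   standard deviation relative to the pooled-fit standard error
#'   (default 10).
#' @param K Truncation level for the stick-breaking representation.
#' @param re_predictors Optional character vector of predictors to carry
#'   subject-level random effects (continuous targets only).  The
#'   random-effect scale matrix defaults to the pooled residual variance times
#'   the identity with `q + 2` degrees of freedom.
#' @param a0 Gamma shape for the residual-precision priors (default 2, weakly
#'   informative).
#'
#' @return A `traj_prior` object.
#' @export
generate_prior <- function(data, k_est, inflation = 10, K = 30,
                           re_predictors = NULL, a0 = 2) {
  stopifnot(inherits(data, "traj_data"))
  if (n_subjects(data) < 2) stop("need at least 2 subjects", call. = FALSE)
  if (inflation <= 0) stop("inflation must be positive", call. = FALSE)
  M <- length(data$predictors)
  Dc <- length(data$targets)
  Db <- length(data$targets_binary)

  qrX <- qr(data$X)
  if (qrX$rank < M) {
    dropped <- data$predictors[qrX$pivot[(qrX$rank + 1):M]]
    stop("pooled design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  w0 <- p0 <- matrix(0, Dc, M, dimnames = list(data$targets, data$predictors))
  a0v <- rep(a0, Dc)
  b0v <- rep(1, Dc)
  resvar <- rep(1, Dc)
  for (d in seq_len(Dc)) {
    obs <- which(!is.na(data$Y[, d]))
    y <- data$Y[obs, d]
    Xd <- data$X[obs, , drop = FALSE]
    fit <- stats::lm.fit(Xd, y)
    rss <- sum(fit$residuals^2)
    df <- length(obs) - M
    s2 <- if (df > 0) rss / df else 1
    if (s2 <= 0) s2 <- .Machine$double.eps
    se <- sqrt(pmax(diag(chol2inv(chol(crossprod(Xd)))) * s2, 1e-12))
    w0[d, ] <- fit$coefficients
    p0[d, ] <- 1 / (inflation * se)^2
    s2w <- .within_subject_resvar(data, obs, y)
    resvar[d] <- if (is.na(s2w) || s2w <= 0) s2 else s2w
    resvar[d] <- max(resvar[d], .Machine$double.eps)
    b0v[d] <- a0 * resvar[d]   # prior mean precision a0/b0 = 1/resvar
  }

  w0b <- p0b <- matrix(0, Db, M,
                       dimnames = list(data$targets_binary, data$predictors))
  for (d in seq_len(Db)) {
    obs <- which(!is.na(data$B[, d]))
    bfit <- tryCatch(
      suppressWarnings(stats::glm.fit(data$X[obs, , drop = FALSE],
                                      data$B[obs, d],
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (!is.null(bfit) && bfit$converged) {
      XtWX <- crossprod(data$X[obs, , drop = FALSE] *
                          sqrt(bfit$weights), data$X[obs, , drop = FALSE])
      se <- sqrt(pmax(diag(chol2inv(chol(XtWX))), 1e-12))
      w0b[d, ] <- bfit$coefficients
      p0b[d, ] <- 1 / (inflation * se)^2
    } else {
      # zero-mean default with sd = inflation when the pooled logistic fit
      # fails (e.g. complete separation)
      w0b[d, ] <- 0
      p0b[d, ] <- 1 / inflation^2
    }
  }

  re <- NULL
  if (!is.null(re_predictors) && length(re_predictors) > 0 && Dc > 0) {
    q <- length(re_predictors)
    if (!all(re_predictors %in% data$predictors)) {
      stop("re_predictors must be a subset of the data's predictors",
           call. = FALSE)
    }
    nu0 <- q + 2
    re <- list(
      predictors = re_predictors,
      # scale chosen so the prior mode S0/(nu0+q+1) matches the
      # between-subject spread of per-subject coefficient estimates
      S0 = stats::setNames(lapply(seq_len(Dc), function(d) {
        Sb <- .between_subject_cov(data, d, re_predictors)
        if (is.null(Sb)) Sb <- diag(resvar[d], q)
        (nu0 + q + 1) * Sb
      }), data$targets),
      nu0 = stats::setNames(rep(nu0, Dc), data$targets)
    )
  }

  traj_prior(
    predictors = data$predictors, targets = data$targets,
    targets_binary = data$targets_binary,
    w0 = w0, p0 = p0, a0 = a0v, b0 = b0v,
    w0_bin = w0b, p0_bin = p0b,
    alpha = alpha_for_expected_clusters(k_est, n_subjects(data)),
    K = K, re = re
  )
}

# Residual noise scale for the Gamma prior: the pooled cross-subject
# residual variance confounds measurement noise with between-trajectory
# spread, so prefer the within-subject estimate — residual variance of
# per-subject least-squares fits, pooled over subjects with positive
# degrees of freedom.  Returns NA when no subject has enough observations,
# in which case the caller falls back to the pooled residual variance.
.within_subject_resvar <- function(data, obs, y) {
  M <- ncol(data$X)
  idx <- data$subj_index[obs]
  rss <- 0
  df <- 0
  for (rows in split(seq_along(obs), idx)) {
    if (length(rows) <= 1) next
    Xi <- data$X[obs[rows], , drop = FALSE]
    ki <- qr(Xi)$rank
    if (length(rows) <= ki) next
    fi <- stats::lm.fit(Xi, y[rows])
    rss <- rss + sum(fi$residuals^2)
    df <- df + length(rows) - ki
  }
  if (df > 0) rss / df else NA_real_
}

# Empirical covariance of per-subject OLS coefficients on the random-effect
# predictors: the natural data-informed scale for the random-effect
# covariance prior.  NULL when fewer than 3 subjects admit a full-rank
# per-subject fit.
.between_subject_cov <- function(data, d, re_predictors) {
  obs <- which(!is.na(data$Y[, d]))
  idx <- data$subj_index[obs]
  M <- ncol(data$X)
  coefs <- list()
  for (rows in split(seq_along(obs), idx)) {
    Xi <- data$X[obs[rows], , drop = FALSE]
    if (length(rows) < M || qr(Xi)$rank < M) next
    coefs[[length(coefs) + 1]] <-
      stats::lm.fit(Xi, data$Y[obs[rows], d])$coefficients[re_predictors]
  }
  if (length(coefs) < 3) return(NULL)
  Sb <- stats::cov(do.call(rbind, coefs))
  q <- length(re_predictors)
  Sb <- Sb + diag(1e-8, q)
  if (inherits(try(chol(Sb), silent = TRUE), "try-error")) return(NULL)
  Sb
}

#' Draw trajectory curves from a prior
#'
#' Samples coefficient vectors from a target's prior Gaussian (optionally
#' with residual precision drawn from its Gamma prior) and evaluates the
#' implied mean curve on a design grid — the visual feedback loop for prior
#' specification.
#'
#' @param prior A `traj_prior` object.
#' @param target Name of the target to draw curves for.
#' @param newdata Data frame (or matrix) containing the prior's predictor
#'   columns; one drawn curve value is produced per row.
#' @param num_draws Number of prior draws (default 100).
#' @param seed Integer seed for reproducibility.
#' @param include_noise If `TRUE`, add residual noise with precision drawn
#'   from the Gamma prior (continuous targets only).
#'
#' @return A tibble in long format with columns `draw`, `row`, and `value`,
#'   plus the predictor columns of `newdata`.
#' @export
sample_prior_draws <- function(prior, target, newdata, num_draws = 100,
                               seed = NULL, include_noise = FALSE) {
  stopifnot(inherits(prior, "traj_prior"))
  is_cont <- target %in% prior$targets
  if (!is_cont && !(target %in% prior$targets_binary)) {
    stop("unknown target: ", target, call. = FALSE)
  }
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(prior$predictors, names(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  G <- as.matrix(newdata[prior$predictors])
  if (!is.null(seed)) set.seed(seed)

  if (is_cont) {
    mu <- prior$w0[target, ]
    sdv <- 1 / sqrt(prior$p0[target, ])
  } else {
    mu <- prior$w0_bin[target, ]
    sdv <- 1 / sqrt(prior$p0_bin[target, ])
  }
  M <- length(mu)
  W <- matrix(stats::rnorm(num_draws * M, rep(mu, each = num_draws),
                           rep(sdv, each = num_draws)), num_draws, M)
  curves <- W %*% t(G)                     # num_draws x nrow(G)
  if (!is_cont) curves <- stats::plogis(curves)
  if (include_noise && is_cont) {
    lam <- stats::rgamma(num_draws, shape = prior$a0[target],
                         rate = prior$b0[target])
    curves <- curves + matrix(stats::rnorm(length(curves)), num_draws) /
      sqrt(lam)
  }
  out <- tibble::tibble(
    draw = rep(seq_len(num_draws), times = nrow(G)),
    row = rep(seq_len(nrow(G)), each = num_draws),
    value = as.vector(curves)
  )
  dplyr::bind_cols(out, tibble::as_tibble(newdata)[out$row, , drop = FALSE])
}
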