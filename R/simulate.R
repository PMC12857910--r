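#' Specify a synthetic longitudinal cohort
#'
#' Describes the ground truth of a simulated cohort drawn from the generative
#' model the package fits: each subject belongs to one of `G` latent groups;
#' continuous targets follow group-specific mean curves plus optional
#' subject-level random effects and Gaussian noise; binary targets are
#' Bernoulli draws through a logistic link.
#'
#' @param n_subjects Number of subjects.
#' @param obs_per_subject Observations per subject: a single integer or a
#'   `c(min, max)` range sampled uniformly per subject.
#' @param t_range Range of the time variable `t`; observation times are drawn
#'   uniformly and sorted within subject.
#' @param predictors Named character vector of expressions in `t` defining the
#'   predictor columns, e.g. `c(intercept = "1", t = "t", t2 = "t^2")`.
#' @param group_prob Group proportions (length `G`, summing to 1).
#' @param targets Named list of continuous target descriptions; each element
#'   is a list with `w` (a `G x M` coefficient matrix), `sigma` (residual
#'   standard deviations, length `G` or scalar) and optionally `re`, a list
#'   with `predictors` (names carrying random effects) and `Sigma` (their
#'   `q x q` covariance, shared across groups).
#' @param targets_binary Named list of binary target descriptions; each a
#'   list with a `G x M` coefficient matrix `w` on the logit scale.
#' @param missing_rate Probability that an individual target cell is missing
#'   (missing completely at random; default 0).
#' @param seed Default RNG seed pinned into the specification.
#'
#' @return An object of class `traj_sim_spec`.
#' @seealso [simulate_cohort()], [traj_sim_preset()], [make_cohort()]
#' @export
traj_sim_spec <- function(n_subjects, obs_per_subject = 5,
                          t_range = c(-2, 2),
                          predictors = c(intercept = "1", t = "t",
                                         t2 = "t^2"),
                          group_prob = 1,
                          targets = list(), targets_binary = list(),
                          missing_rate = 0, seed = 1L) {
  G <- length(group_prob)
  if (abs(sum(group_prob) - 1) > 1e-8 || any(group_prob < 0)) {
    stop("group_prob must be nonnegative and sum to 1", call. = FALSE)
  }
  if (length(targets) + length(targets_binary) == 0) {
    stop("at least one target is required", call. = FALSE)
  }
  if (is.null(names(predictors))) {
    stop("predictors must be a named vector of expressions in t",
         call. = FALSE)
  }
  M <- length(predictors)
  chk_w <- function(w, nm) {
    w <- matrix(as.numeric(w), nrow = G, ncol = M)
    if (anyNA(w)) stop("invalid coefficients for target ", nm, call. = FALSE)
    w
  }
  targets <- purrr::imap(targets, function(tg, nm) {
    tg$w <- chk_w(tg$w, nm)
    tg$sigma <- rep(as.numeric(tg$sigma), length.out = G)
    if (any(tg$sigma < 0)) stop("sigma must be nonnegative", call. = FALSE)
    if (!is.null(tg$re)) {
      if (!all(tg$re$predictors %in% names(predictors))) {
        stop("random-effect predictors unknown for target ", nm,
             call. = FALSE)
      }
      q <- length(tg$re$predictors)
      tg$re$Sigma <- matrix(as.numeric(tg$re$Sigma), q, q)
      eg <- eigen(tg$re$Sigma, symmetric = TRUE, only.values = TRUE)$values
      if (any(eg < -1e-10)) {
        stop("random-effect covariance must be positive semidefinite",
             call. = FALSE)
      }
    }
    tg
  })
  targets_binary <- purrr::imap(targets_binary, function(tg, nm) {
    tg$w <- chk_w(tg$w, nm)
    tg
  })
  structure(list(
    n_subjects = as.integer(n_subjects),
    obs_per_subject = as.integer(obs_per_subject),
    t_range = as.numeric(t_range),
    predictors = predictors,
    group_prob = as.numeric(group_prob),
    targets = targets, targets_binary = targets_binary,
    missing_rate = as.numeric(missing_rate),
    seed = as.integer(seed)
  ), class = "traj_sim_spec")
}

#' Named cohort presets used throughout the package's examples and tests
#'
#' * `"separated3"`: 3 well-separated quadratic trajectory groups, three
#'   continuous targets, 300 subjects with 5 visits each — easy recovery.
#' * `"overlap2"`: 2 overlapping linear groups, one continuous target,
#'   200 subjects — deliberately ambiguous.
#' * `"binary2"`: 2 separable groups observed only through one binary
#'   target, 400 subjects with 6 visits each.
#' * `"randint1"`: a single group with subject-level random intercepts
#'   (standard deviation 2) around a linear mean curve with residual
#'   standard deviation 0.5, 500 subjects.
#'
#' @param name One of `"separated3"`, `"overlap2"`, `"binary2"`,
#'   `"randint1"`.
#' @return A `traj_sim_spec` with a pinned seed.
#' @export
traj_sim_preset <- function(name = c("separated3", "overlap2", "binary2",
                                     "randint1")) {
  name <- match.arg(name)
  switch(name,
    separated3 = traj_sim_spec(
      n_subjects = 300, obs_per_subject = 5,
      group_prob = c(0.35, 0.40, 0.25),
      targets = list(
        y1 = list(w = rbind(c(5, -0.8, -0.20),
                            c(10, 0.4, 0.10),
                            c(15, 1.2, -0.15)),
                  sigma = c(0.35, 0.40, 0.45)),
        y2 = list(w = rbind(c(12, 1.0, 0.10),
                            c(6, -0.5, -0.10),
                            c(18, 0.3, 0.20)),
                  sigma = c(0.40, 0.35, 0.45)),
        y3 = list(w = rbind(c(-4, 0.4, 0.00),
                            c(0, -0.6, 0.15),
                            c(6, 0.0, -0.15)),
                  sigma = c(0.5, 0.5, 0.5))
      ),
      seed = 4201L
    ),
    overlap2 = traj_sim_spec(
      n_subjects = 200, obs_per_subject = 4,
      group_prob = c(0.5, 0.5),
      targets = list(
        y = list(w = rbind(c(3.0, 0.3, 0),
                           c(4.2, -0.2, 0)),
                 sigma = c(1.2, 1.2))
      ),
      seed = 4202L
    ),
    binary2 = traj_sim_spec(
      n_subjects = 400, obs_per_subject = 6,
      predictors = c(intercept = "1", t = "t"),
      group_prob = c(0.5, 0.5),
      targets_binary = list(
        s = list(w = rbind(c(2.5, 0.5),
                           c(-2.5, -0.5)))
      ),
      seed = 4203L
    ),
    randint1 = traj_sim_spec(
      n_subjects = 500, obs_per_subject = 5,
      predictors = c(intercept = "1", t = "t"),
      group_prob = 1,
      targets = list(
        y = list(w = rbind(c(10, 0.5)), sigma = 0.5,
                 re = list(predictors = "intercept",
                           Sigma = matrix(4, 1, 1)))
      ),
      seed = 4204L
    )
  )
}

#' Draw a synthetic cohort from its specification
#'
#' Samples group memberships, visit times, random effects, and target values
#' according to a [traj_sim_spec()].  Identical seeds give identical output.
#'
#' @param spec A `traj_sim_spec` object.
#' @param seed Optional seed overriding the one pinned in `spec`.
#' @return A list with elements `data` (observation-level tibble with columns
#'   `id`, the predictors, and the targets), `truth` (subject-level tibble
#'   with the true group and any random-effect values) and `spec`.
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "traj_sim_spec"))
  set.seed(if (is.null(seed)) spec$seed else seed)
  n <- spec$n_subjects
  G <- length(spec$group_prob)

  group <- sample.int(G, n, replace = TRUE, prob = spec$group_prob)
  n_obs <- if (length(spec$obs_per_subject) == 1) {
    rep(spec$obs_per_subject, n)
  } else {
    sample(seq(spec$obs_per_subject[1], spec$obs_per_subject[2]), n,
           replace = TRUE)
  }
  subj <- rep(seq_len(n), times = n_obs)
  tt <- unlist(lapply(n_obs, function(k) {
    sort(stats::runif(k, spec$t_range[1], spec$t_range[2]))
  }))
  X <- vapply(spec$predictors,
              function(e) eval(parse(text = e), list(t = tt)) + 0 * tt,
              numeric(length(tt)))
  colnames(X) <- names(spec$predictors)
  grow <- group[subj]

  data <- tibble::tibble(id = subj)
  data <- dplyr::bind_cols(data, tibble::as_tibble(X))
  truth <- tibble::tibble(subject_id = seq_len(n), group = group)

  for (nm in names(spec$targets)) {
    tg <- spec$targets[[nm]]
    mu <- rowSums(X * tg$w[grow, , drop = FALSE])
    if (!is.null(tg$re)) {
      q <- length(tg$re$predictors)
      L <- chol(tg$re$Sigma + diag(1e-12, q))
      U <- matrix(stats::rnorm(n * q), n, q) %*% L   # n x q subject effects
      Z <- X[, tg$re$predictors, drop = FALSE]
      mu <- mu + rowSums(Z * U[subj, , drop = FALSE])
      colnames(U) <- paste0("u_", nm, "_", tg$re$predictors)
      truth <- dplyr::bind_cols(truth, tibble::as_tibble(U))
    }
    y <- mu + stats::rnorm(length(mu)) * tg$sigma[grow]
    if (spec$missing_rate > 0) {
      y[stats::runif(length(y)) < spec$missing_rate] <- NA_real_
    }
    data[[nm]] <- y
  }
  for (nm in names(spec$targets_binary)) {
    tg <- spec$targets_binary[[nm]]
    p <- stats::plogis(rowSums(X * tg$w[grow, , drop = FALSE]))
    b <- as.numeric(stats::runif(length(p)) < p)
    if (spec$missing_rate > 0) {
      b[stats::runif(length(b)) < spec$missing_rate] <- NA_real_
    }
    data[[nm]] <- b
  }
  list(data = data, truth = truth, spec = spec)
}

#' Write a synthetic cohort to CSV files
#'
#' Generates a cohort with [simulate_cohort()] and writes the observation
#' table plus a subject-level ground-truth table (true group and random
#' effects) as CSV, with missing cells left empty.
#'
#' @param spec A `traj_sim_spec`, or a preset name accepted by
#'   [traj_sim_preset()].
#' @param data_path Output path for the observation-level CSV.
#' @param truth_path Optional output path for the subject-level truth CSV.
#' @param seed Optional seed overriding the specification's pinned seed.
#' @return The simulated cohort list, invisibly.
#' @export
make_cohort <- function(spec, data_path, truth_path = NULL, seed = NULL) {
  if (is.character(spec)) spec <- traj_sim_preset(spec)
  sim <- simulate_cohort(spec, seed = seed)
  readr::write_csv(sim$data, data_path, na = "")
  if (!is.null(truth_path)) readr::write_csv(sim$truth, truth_path, na = "")
  invisible(sim)
}

#' Load a cohort specification from a YAML configuration file
#'
#' The file mirrors the arguments of [traj_sim_spec()]; coefficient matrices
#' are written as lists of per-group rows.
#'
#' @param path Path to the YAML file.
#' @return A `traj_sim_spec` object.
#' @export
read_traj_sim_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  as_w <- function(x) do.call(rbind, lapply(x, as.numeric))
  targets <- lapply(cfg$targets, function(tg) {
    tg$w <- as_w(tg$w)
    if (!is.null(tg$re)) {
      tg$re$predictors <- as.character(unlist(tg$re$predictors))
      q <- length(tg$re$predictors)
      tg$re$Sigma <- matrix(as.numeric(unlist(tg$re$Sigma)), q, q,
                            byrow = TRUE)
    }
    tg
  })
  targets_binary <- lapply(cfg$targets_binary, function(tg) {
    tg$w <- as_w(tg$w)
    tg
  })
  traj_sim_spec(
    n_subjects = cfg$n_subjects,
    obs_per_subject = unlist(cfg$obs_per_subject),
    t_range = if (is.null(cfg$t_range)) c(-2, 2) else unlist(cfg$t_range),
    predictors = if (is.null(cfg$predictors)) {
      c(intercept = "1", t = "t", t2 = "t^2")
    } else {
      unlist(cfg$predictors)
    },
    group_prob = unlist(cfg$group_prob),
    targets = targets, targets_binary = targets_binary,
    missing_rate = if (is.null(cfg$missing_rate)) 0 else cfg$missing_rate,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed
  )
}
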