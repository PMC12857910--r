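#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.posterior_resid_var <- function(model, d) {
  lf <- model$prior$lambda_fixed[d]
  sc <- model$posterior$cont[[d]]
  if (!is.na(lf)) rep(1 / lf, model$prior$K) else {
    ifelse(sc$a > 1, sc$b / (sc$a - 1), NA_real_)
  }
}

.component_mass <- function(model) {
  colSums(model$posterior$R) / model$n_subjects
}

#' Number of occupied mixture components
#'
#' Counts the components holding more than `threshold` of the total
#' responsibility mass (default 1% of subjects).
#'
#' @param model A `traj_model`.
#' @param threshold Mass fraction above which a component counts as occupied.
#' @return Integer count.
#' @export
occupied_components <- function(model, threshold = 0.01) {
  sum(.component_mass(model) > threshold)
}

#' Assign subjects to trajectory groups with a fitted model
#'
#' Computes, for every subject in `data`, the posterior probability of each
#' mixture component under the fitted model, using the expected log mixture
#' weights plus the log-likelihood of the subject's observations evaluated at
#' each component's posterior-mean parameters (a plug-in rule; random effects
#' are integrated out against the component's estimated random-effect
#' covariance).  Works on the training cohort or on new, out-of-sample
#' subjects; target cells may be missing.  A subject with no usable target
#' observation receives the prior expected weights and a warning flag.
#'
#' @param model A `traj_model`.
#' @param data A `traj_data` whose predictor and target columns match the
#'   model.
#' @param all_components If `TRUE`, report a probability column for every
#'   component up to the truncation level; otherwise only components whose
#'   training mass exceeds `threshold` get a column (the MAP label is always
#'   computed over all components).
#' @param threshold Occupancy threshold used when `all_components = FALSE`.
#' @return A tibble with columns `subject_id`, `prob_<k>`, `map_label`
#'   (integer component index; ties broken toward the lowest index) and
#'   `warning` (`TRUE` for subjects assigned from the prior).
#' @export
assign_trajectory <- function(model, data, all_components = FALSE,
                              threshold = 0.01) {
  stopifnot(inherits(model, "traj_model"), inherits(data, "traj_data"))
  prior <- model$prior
  ctx <- .build_ctx(data, prior)
  state <- model$posterior
  K <- prior$K
  n <- ctx$n
  logp <- matrix(rep(state$Elogpi, each = n), n, K)
  usable <- rep(FALSE, n)

  for (d in seq_along(ctx$cont)) {
    cd <- ctx$cont[[d]]
    if (length(cd$rows) == 0) next
    usable[unique(cd$subj)] <- TRUE
    s2 <- .posterior_resid_var(model, d)
    tg <- names(ctx$cont)[d]
    if (is.null(cd$Z)) {
      for (k in seq_len(K)) {
        r <- cd$y - drop(cd$X %*% state$cont[[d]]$mu_w[k, ])
        ll <- stats::dnorm(r, 0, sqrt(s2[k]), log = TRUE)
        agg <- rowsum(ll, cd$subj)
        idx <- as.integer(rownames(agg))
        logp[idx, k] <- logp[idx, k] + agg[, 1]
      }
    } else {
      rows_by_subj <- split(seq_along(cd$subj), cd$subj)
      for (k in seq_len(K)) {
        Sre <- state$re[[tg]]$Sigma_re[, , k]
        mw <- state$cont[[d]]$mu_w[k, ]
        for (nm in names(rows_by_subj)) {
          rows <- rows_by_subj[[nm]]
          i <- as.integer(nm)
          Zi <- cd$Z[rows, , drop = FALSE]
          ri <- cd$y[rows] - drop(cd$X[rows, , drop = FALSE] %*% mw)
          Cov <- diag(s2[k], length(rows)) + Zi %*% Sre %*% t(Zi)
          ch <- chol(Cov)
          z <- backsolve(ch, ri, transpose = TRUE)
          logp[i, k] <- logp[i, k] -
            0.5 * (length(rows) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                     sum(z^2))
        }
      }
    }
  }
  for (d in seq_along(ctx$bin)) {
    bd <- ctx$bin[[d]]
    if (length(bd$rows) == 0) next
    usable[unique(bd$subj)] <- TRUE
    for (k in seq_len(K)) {
      p <- stats::plogis(drop(bd$X %*% state$bin[[d]]$mu_w[k, ]))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll <- bd$b * log(p) + (1 - bd$b) * log(1 - p)
      agg <- rowsum(ll, bd$subj)
      idx <- as.integer(rownames(agg))
      logp[idx, k] <- logp[idx, k] + agg[, 1]
    }
  }

  probs <- exp(logp - apply(logp, 1, max))
  probs <- probs / rowSums(probs)
  if (any(!usable)) {
    # fall back to the prior expected weights E[pi]
    Epi <- if (K > 1) {
      stick_breaking_weights(state$g1 / (state$g1 + state$g2))
    } else 1
    probs[!usable, ] <- matrix(Epi, sum(!usable), K, byrow = TRUE)
  }
  map <- apply(probs, 1, which.max)

  keep <- if (all_components) seq_len(K) else {
    which(.component_mass(model) > threshold)
  }
  if (length(keep) == 0) keep <- seq_len(K)
  out <- tibble::as_tibble(probs[, keep, drop = FALSE],
                           .name_repair = "minimal")
  names(out) <- paste0("prob_", keep)
  dplyr::bind_cols(
    tibble::tibble(subject_id = ctx$subjects),
    out,
    tibble::tibble(map_label = as.integer(map), warning = !usable)
  )
}

#' Tidy the coefficient posteriors of a fitted trajectory model
#'
#' @param x A `traj_model`.
#' @param conf_level Credible-interval level (default 0.95; Gaussian
#'   quantiles of the coefficient posterior).
#' @param all_components Include empty components (default `FALSE`: only
#'   components above 1% responsibility mass).
#' @param ... Unused.
#' @return A tibble with one row per (component, target, term): posterior
#'   `estimate`, `std.error`, and credible bounds `conf.low`/`conf.high`.
#' @method tidy traj_model
#' @export
tidy.traj_model <- function(x, conf_level = 0.95, all_components = FALSE,
                            ...) {
  keep <- if (all_components) seq_len(x$prior$K) else {
    which(.component_mass(x) > 0.01)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- list()
  grab <- function(block, targets, type) {
    for (d in seq_along(targets)) {
      for (k in keep) {
        est <- block[[d]]$mu_w[k, ]
        se <- sqrt(diag(block[[d]]$Sigma_w[, , k]))
        rows[[length(rows) + 1]] <<- tibble::tibble(
          component = k, target = targets[d], type = type,
          term = x$predictors, estimate = est, std.error = se,
          conf.low = est - z * se, conf.high = est + z * se
        )
      }
    }
  }
  grab(x$posterior$cont, x$targets, "continuous")
  grab(x$posterior$bin, x$targets_binary, "binary")
  dplyr::arrange(dplyr::bind_rows(rows), .data$component, .data$target)
}

#' One-row summary of a fitted trajectory model
#'
#' @param x A `traj_model`.
#' @param ... Unused.
#' @return A tibble with the subject/observation counts, truncation level,
#'   occupied-component count, final ELBO, sweep count, convergence flag and
#'   seed.
#' @method glance traj_model
#' @export
glance.traj_model <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_obs = x$n_obs,
    K = x$prior$K,
    n_components = occupied_components(x),
    elbo = x$elbo,
    iterations = x$iterations,
    converged = x$converged,
    seed = x$seed
  )
}

#' Augment observation-level data with trajectory assignments
#'
#' @param x A `traj_model`.
#' @param data A `traj_data` (typically the training data).
#' @param ... Passed to [assign_trajectory()].
#' @return The observation tibble with appended columns `.map_label` and
#'   `.prob_map` (the posterior probability of the assigned component),
#'   repeated across each subject's rows.
#' @method augment traj_model
#' @export
augment.traj_model <- function(x, data, ...) {
  stopifnot(inherits(data, "traj_data"))
  asg <- assign_trajectory(x, data, all_components = TRUE, ...)
  probm <- as.matrix(asg[paste0("prob_", seq_len(x$prior$K))])
  pm <- probm[cbind(seq_len(nrow(asg)), asg$map_label)]
  idx <- match(data$subject_id, asg$subject_id)
  dplyr::bind_cols(data$df,
                   tibble::tibble(.map_label = asg$map_label[idx],
                                  .prob_map = pm[idx]))
}

#' Summarize a fitted trajectory model
#'
#' Produces a quantitative report: per occupied component the subject count
#' and percentage (by MAP assignment of the training responsibilities), the
#' posterior mean and credible interval of every coefficient, and the
#' posterior-mean residual standard deviation of each continuous target;
#' plus overall fit statistics.
#'
#' @param model A `traj_model`.
#' @param threshold Responsibility-mass fraction below which a component is
#'   omitted from the report (default 0.01).
#' @param conf_level Credible-interval level for coefficients.
#' @return An object of class `traj_summary`: a list of tibbles
#'   (`components`, `coefficients`, `residuals`, `overall`) with a print
#'   method.
#' @export
summarize_traj_model <- function(model, threshold = 0.01,
                                 conf_level = 0.95) {
  stopifnot(inherits(model, "traj_model"))
  mass <- .component_mass(model)
  keep <- which(mass > threshold)
  map <- apply(model$posterior$R, 1, which.max)
  counts <- tabulate(map, nbins = model$prior$K)
  components <- tibble::tibble(
    component = keep,
    n_subjects = counts[keep],
    percent = 100 * counts[keep] / model$n_subjects,
    mass_percent = 100 * mass[keep]
  )
  residuals <- dplyr::bind_rows(lapply(seq_along(model$targets), function(d) {
    tibble::tibble(component = keep, target = model$targets[d],
                   resid_sd = sqrt(.posterior_resid_var(model, d))[keep])
  }))
  structure(list(
    components = components,
    coefficients = tidy(model, conf_level = conf_level),
    residuals = residuals,
    overall = glance(model),
    threshold = threshold
  ), class = "traj_summary")
}

#' @export
print.traj_summary <- function(x, ...) {
  ov <- x$overall
  cat("Trajectory model summary\n")
  cat("  subjects: ", ov$n_subjects, "   observations: ", ov$n_obs, "\n",
      sep = "")
  cat("  truncation K = ", ov$K, ", occupied components: ",
      ov$n_components, "\n", sep = "")
  cat("  final ELBO ", format(ov$elbo, digits = 10), " after ",
      ov$iterations, " sweeps\n\n", sep = "")
  cat("Components (MAP assignment):\n")
  print(as.data.frame(x$components), row.names = FALSE, digits = 4)
  if (nrow(x$residuals) > 0) {
    cat("\nResidual standard deviations (posterior mean):\n")
    print(as.data.frame(x$residuals), row.names = FALSE, digits = 4)
  }
  cat("\nCoefficient posteriors:\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a model summary to file
#'
#' @param summary A `traj_summary`.
#' @param path Output path.
#' @param format `"text"` for the printed report, `"yaml"` for a
#'   machine-readable key-value variant.
#' @return `path`, invisibly.
#' @export
write_traj_summary <- function(summary, path, format = c("text", "yaml")) {
  stopifnot(inherits(summary, "traj_summary"))
  format <- match.arg(format)
  if (format == "text") {
    txt <- utils::capture.output(print(summary))
    writeLines(txt, path)
  } else {
    yaml::write_yaml(list(
      overall = as.list(summary$overall),
      components = lapply(seq_len(nrow(summary$components)), function(i) {
        as.list(summary$components[i, ])
      }),
      residuals = lapply(seq_len(nrow(summary$residuals)), function(i) {
        as.list(summary$residuals[i, ])
      }),
      coefficients = lapply(seq_len(nrow(summary$coefficients)), function(i) {
        as.list(summary$coefficients[i, ])
      })
    ), path)
  }
  invisible(path)
}
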