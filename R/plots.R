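#' @importFrom rlang .data
NULL

.save_plot <- function(p, out) {
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    ggplot2::ggsave(out, p, width = 7, height = 5, dpi = 150)
  }
  p
}

#' Plot fitted trajectories over the observed data
#'
#' Overlays each subject's observed series (colored by MAP component) with
#' the posterior-mean curve of every occupied component and a shaded band of
#' plus/minus two posterior-mean residual standard deviations.
#'
#' @param model A `traj_model`.
#' @param data A `traj_data` with matching columns.
#' @param target Name of the continuous or binary target to display
#'   (defaults to the first continuous target).
#' @param x Name of the predictor used for the horizontal axis (defaults to
#'   the first non-constant predictor).
#' @param threshold Mass fraction above which a component's curve is drawn.
#' @param out Optional path; when given, the plot is also written to file.
#' @return A ggplot object, invisibly when `out` is given.
#' @export
plot_model_trajs <- function(model, data, target = NULL, x = NULL,
                             threshold = 0.01, out = NULL) {
  stopifnot(inherits(model, "traj_model"), inherits(data, "traj_data"))
  if (is.null(target)) {
    target <- c(model$targets, model$targets_binary)[1]
  }
  is_cont <- target %in% model$targets
  if (!is_cont && !(target %in% model$targets_binary)) {
    stop("unknown target: ", target, call. = FALSE)
  }
  if (is.null(x)) {
    spread <- apply(data$X, 2, function(v) diff(range(v)))
    x <- colnames(data$X)[which(spread > 0)[1]]
  }
  keep <- which(.component_mass(model) > threshold)
  asg <- assign_trajectory(model, data, all_components = TRUE)
  map <- asg$map_label[match(data$subject_id, asg$subject_id)]

  yv <- if (is_cont) data$Y[, target] else data$B[, target]
  obs <- tibble::tibble(xv = data$X[, x], y = yv,
                        subject = data$subject_id,
                        component = factor(map))
  block <- if (is_cont) model$posterior$cont[[target]] else {
    model$posterior$bin[[target]]
  }
  curves <- dplyr::bind_rows(lapply(keep, function(k) {
    mu <- drop(data$X %*% block$mu_w[k, ])
    if (!is_cont) mu <- stats::plogis(mu)
    band <- if (is_cont) {
      d <- match(target, model$targets)
      2 * sqrt(.posterior_resid_var(model, d)[k])
    } else 0
    ord <- order(data$X[, x])
    tibble::tibble(xv = data$X[ord, x], mu = mu[ord],
                   lo = mu[ord] - band, hi = mu[ord] + band,
                   component = factor(k, levels = levels(obs$component)))
  }))

  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$xv, y = .data$y)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject,
                                    color = .data$component),
                       alpha = 0.25, linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_ribbon(data = curves,
                         ggplot2::aes(x = .data$xv, ymin = .data$lo,
                                      ymax = .data$hi,
                                      fill = .data$component),
                         alpha = 0.2, inherit.aes = FALSE) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$xv, y = .data$mu,
                                    color = .data$component),
                       linewidth = 1, inherit.aes = FALSE) +
    ggplot2::labs(x = x, y = target, color = "component",
                  fill = "component",
                  title = paste0("Posterior mean trajectories: ", target)) +
    ggplot2::theme_minimal()
  .save_plot(p, out)
}

#' Plot draws from a prior over trajectory curves
#'
#' Spaghetti plot of prior predictive mean curves for one target, optionally
#' over the observed data — the visual check that a prior is neither too
#' tight nor absurdly wide.
#'
#' @param prior A `traj_prior`.
#' @param target Target name.
#' @param newdata Data frame with the prior's predictor columns (the
#'   evaluation grid); typically the observed data.
#' @param x Name of the predictor for the horizontal axis.
#' @param num_draws Number of prior draws.
#' @param seed RNG seed.
#' @param data Optional `traj_data` whose observed series are drawn behind
#'   the prior curves.
#' @param out Optional output image path.
#' @return A ggplot object.
#' @export
plot_prior_draws <- function(prior, target, newdata, x, num_draws = 50,
                             seed = 1, data = NULL, out = NULL) {
  draws <- sample_prior_draws(prior, target, newdata, num_draws = num_draws,
                              seed = seed)
  p <- ggplot2::ggplot(draws, ggplot2::aes(x = .data[[x]], y = .data$value,
                                           group = .data$draw)) +
    ggplot2::geom_line(alpha = 0.3, color = "steelblue", linewidth = 0.3) +
    ggplot2::labs(x = x, y = target,
                  title = paste0("Prior draws: ", target)) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    yv <- if (target %in% data$targets) data$Y[, target] else {
      data$B[, target]
    }
    obs <- tibble::tibble(xv = data$X[, x], y = yv,
                          subject = data$subject_id)
    p <- p + ggplot2::geom_line(
      data = obs,
      ggplot2::aes(x = .data$xv, y = .data$y, group = .data$subject),
      inherit.aes = FALSE, alpha = 0.15, linewidth = 0.2, na.rm = TRUE)
  }
  .save_plot(p, out)
}

#' Plot residual-precision Gamma priors and posteriors
#'
#' Density curves of each continuous target's Gamma prior over the residual
#' precision and, when a fitted model is supplied, the posterior Gamma of
#' every occupied component.
#'
#' @param prior A `traj_prior`.
#' @param model Optional `traj_model` adding posterior densities.
#' @param threshold Occupancy threshold for posterior curves.
#' @param out Optional output image path.
#' @return A ggplot object.
#' @export
plot_gamma_dists <- function(prior, model = NULL, threshold = 0.01,
                             out = NULL) {
  stopifnot(inherits(prior, "traj_prior"))
  targets <- prior$targets[is.na(prior$lambda_fixed)]
  if (length(targets) == 0) {
    stop("no continuous target with an inferred residual precision",
         call. = FALSE)
  }
  dens <- dplyr::bind_rows(lapply(targets, function(tg) {
    d <- match(tg, prior$targets)
    a0 <- prior$a0[d]; b0 <- prior$b0[d]
    hi <- stats::qgamma(0.995, a0, rate = b0)
    if (!is.null(model)) {
      keep <- which(.component_mass(model) > threshold)
      sc <- model$posterior$cont[[d]]
      hi <- max(hi, stats::qgamma(0.995, sc$a[keep], rate = sc$b[keep]))
    }
    grid <- seq(1e-9, hi, length.out = 400)
    out0 <- tibble::tibble(target = tg, curve = "prior", precision = grid,
                           density = stats::dgamma(grid, a0, rate = b0))
    if (is.null(model)) return(out0)
    keep <- which(.component_mass(model) > threshold)
    sc <- model$posterior$cont[[d]]
    dplyr::bind_rows(out0, dplyr::bind_rows(lapply(keep, function(k) {
      tibble::tibble(target = tg, curve = paste0("posterior k=", k),
                     precision = grid,
                     density = stats::dgamma(grid, sc$a[k], rate = sc$b[k]))
    })))
  }))
  p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$precision,
                                          y = .data$density,
                                          color = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(~target, scales = "free") +
    ggplot2::labs(title = "Residual-precision Gamma distributions") +
    ggplot2::theme_minimal()
  .save_plot(p, out)
}

#' Autoplot method for fitted trajectory models
#'
#' @param object A `traj_model`.
#' @param data The `traj_data` used for fitting.
#' @param ... Passed to [plot_model_trajs()].
#' @return A ggplot object.
#' @method autoplot traj_model
#' @export
autoplot.traj_model <- function(object, data, ...) {
  plot_model_trajs(object, data, ...)
}
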