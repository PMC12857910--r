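#' Write a prior specification to a human-readable YAML file
#'
#' @param prior A `traj_prior` object.
#' @param path Output file path.
#' @param provenance Optional named list (e.g. source data file, `k_est`)
#'   written as comment lines at the top of the file.
#' @return `path`, invisibly.
#' @export
write_traj_prior <- function(prior, path, provenance = NULL) {
  stopifnot(inherits(prior, "traj_prior"))
  body <- list(
    format = "trajvi-prior",
    version = 1L,
    alpha = prior$alpha,
    K = prior$K,
    predictors = as.list(prior$predictors),
    targets_continuous = as.list(prior$targets),
    targets_binary = as.list(prior$targets_binary),
    continuous = stats::setNames(lapply(seq_along(prior$targets), function(d) {
      out <- list(
        w0 = as.list(unname(prior$w0[d, ])),
        p0 = as.list(unname(prior$p0[d, ])),
        a0 = unname(prior$a0[d]),
        b0 = unname(prior$b0[d])
      )
      if (!is.na(prior$lambda_fixed[d])) {
        out$lambda_fixed <- unname(prior$lambda_fixed[d])
      }
      out
    }), prior$targets),
    binary = stats::setNames(lapply(seq_along(prior$targets_binary),
                                    function(d) {
      list(w0 = as.list(unname(prior$w0_bin[d, ])),
           p0 = as.list(unname(prior$p0_bin[d, ])))
    }), prior$targets_binary)
  )
  if (!is.null(prior$re)) {
    body$random_effects <- list(
      predictors = as.list(prior$re$predictors),
      targets = stats::setNames(lapply(names(prior$re$S0), function(tg) {
        list(S0 = apply(prior$re$S0[[tg]], 1, as.list, simplify = FALSE),
             nu0 = unname(prior$re$nu0[tg]))
      }), names(prior$re$S0))
    )
  }
  header <- c("# trajvi prior specification",
              sprintf("# created: %s", format(Sys.time(), "%Y-%m-%d")))
  if (!is.null(provenance)) {
    header <- c(header, vapply(names(provenance), function(nm) {
      sprintf("# %s: %s", nm, as.character(provenance[[nm]]))
    }, character(1)))
  }
  writeLines(c(header, yaml::as.yaml(body, precision = 17L)), path)
  invisible(path)
}

#' Read a prior specification from a YAML file
#'
#' @param path Path to a file written by [write_traj_prior()].
#' @return A `traj_prior` object.
#' @export
read_traj_prior <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  body <- yaml::read_yaml(path)
  if (is.null(body$format) || body$format != "trajvi-prior") {
    stop("not a trajvi prior file: ", path, call. = FALSE)
  }
  if (is.null(body$version) || body$version != 1L) {
    stop("unsupported prior file version: ", body$version, call. = FALSE)
  }
  predictors <- unlist(body$predictors)
  targets <- as.character(unlist(body$targets_continuous))
  targets_bin <- as.character(unlist(body$targets_binary))
  M <- length(predictors)
  pick <- function(block, field, targets_vec) {
    do.call(rbind, lapply(targets_vec,
                          function(tg) as.numeric(unlist(block[[tg]][[field]]))))
  }
  w0 <- if (length(targets)) pick(body$continuous, "w0", targets) else NULL
  p0 <- if (length(targets)) pick(body$continuous, "p0", targets) else NULL
  a0 <- vapply(targets, function(tg) as.numeric(body$continuous[[tg]]$a0),
               numeric(1))
  b0 <- vapply(targets, function(tg) as.numeric(body$continuous[[tg]]$b0),
               numeric(1))
  lf <- vapply(targets, function(tg) {
    v <- body$continuous[[tg]]$lambda_fixed
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  w0b <- if (length(targets_bin)) pick(body$binary, "w0", targets_bin) else NULL
  p0b <- if (length(targets_bin)) pick(body$binary, "p0", targets_bin) else NULL
  re <- NULL
  if (!is.null(body$random_effects)) {
    rb <- body$random_effects
    q <- length(unlist(rb$predictors))
    re <- list(
      predictors = as.character(unlist(rb$predictors)),
      S0 = lapply(rb$targets, function(tg) {
        matrix(as.numeric(unlist(tg$S0)), q, q, byrow = TRUE)
      }),
      nu0 = vapply(rb$targets, function(tg) as.numeric(tg$nu0), numeric(1))
    )
  }
  traj_prior(predictors = predictors, targets = targets,
             targets_binary = targets_bin,
             w0 = w0, p0 = p0, a0 = a0, b0 = b0,
             w0_bin = w0b, p0_bin = p0b,
             alpha = as.numeric(body$alpha), K = as.integer(body$K),
             re = re, lambda_fixed = if (any(!is.na(lf))) lf[!is.na(lf)])
}
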