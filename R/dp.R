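#' Truncated stick-breaking weights
#'
#' Maps `K - 1` stick-breaking fractions to `K` mixture weights under the
#' truncated Dirichlet-process construction: the k-th weight is
#' `v[k] * prod(1 - v[1:(k-1)])`, and the final component receives the
#' remaining stick `prod(1 - v)`, so the weights always sum to one exactly.
#'
#' @param v Numeric vector of stick fractions, each in `[0, 1]`.
#' @return Numeric vector of `length(v) + 1` nonnegative weights summing to 1.
#' @export
#' @examples
#' stick_breaking_weights(c(0.5, 0.5))  # 0.5, 0.25, 0.25
stick_breaking_weights <- function(v) {
  v <- as.numeric(v)
  if (length(v) > 0 && (anyNA(v) || any(v < 0) || any(v > 1))) {
    stop("stick fractions must lie in [0, 1]", call. = FALSE)
  }
  if (length(v) == 0) return(1)
  remaining <- cumprod(1 - v)
  c(v * c(1, remaining[-length(v)]), remaining[length(v)])
}

#' Expected number of occupied clusters under a Dirichlet process
#'
#' For a Dirichlet process with concentration `alpha`, the expected number of
#' distinct clusters among `n` subjects is `sum(alpha / (alpha + 0:(n-1)))`,
#' increasing in both `alpha` and `n`.
#'
#' @param alpha Positive DP concentration parameter.
#' @param n Number of subjects (integer, at least 1).
#' @return Expected count of occupied clusters (a positive real).
#' @seealso [alpha_for_expected_clusters()] for the inverse map.
#' @export
#' @examples
#' expected_num_clusters(1, 3)  # 1 + 1/2 + 1/3
expected_num_clusters <- function(alpha, n) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha <= 0) {
    stop("alpha must be a positive number", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be a positive integer", call. = FALSE)
  sum(alpha / (alpha + (seq_len(n) - 1)))
}

#' Calibrate the DP concentration from an estimated trajectory count
#'
#' Solves `expected_num_clusters(alpha, n) == k_est` for `alpha` by bracketed
#' root-finding, so that an investigator's a-priori estimate of the number of
#' trajectories in a cohort of `n` subjects determines the concentration of
#' the Dirichlet-process prior.
#'
#' @param k_est Estimated number of trajectories; must satisfy
#'   `1 <= k_est < n`.
#' @param n Number of subjects.
#' @return The unique positive concentration `alpha` whose expected cluster
#'   count equals `k_est` (to within `1e-10` on the cluster-count scale).
#' @export
#' @examples
#' a <- alpha_for_expected_clusters(3, 100)
#' expected_num_clusters(a, 100)  # 3
alpha_for_expected_clusters <- function(k_est, n) {
  n <- as.integer(n)
  if (!is.numeric(k_est) || length(k_est) != 1 || is.na(k_est) ||
      k_est < 1 || k_est >= n) {
    stop("k_est must satisfy 1 <= k_est < n", call. = FALSE)
  }
  if (k_est == 1) return(1e-12)
  f <- function(a) expected_num_clusters(a, n) - k_est
  lo <- 1e-12
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  root <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75,
                         maxiter = 1000L)$root
  # polish by bisection until the cluster-count residual is tiny
  lo <- root / 2; hi <- root * 2
  if (f(lo) > 0) lo <- 1e-12
  while (f(hi) < 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < 1e-12 || (hi - lo) < .Machine$double.eps * mid) break
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  mid
}
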