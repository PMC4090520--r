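#' @name simultaneous_ci
#' @rdname simultaneous_ci
#' @title Simultaneous confidence intervals for all pairwise mean differences
#'
#' @description
#' Two-sided simultaneous \eqn{1-\alpha} intervals for every pairwise
#' difference \eqn{\mu_i - \mu_j}, \eqn{i < j}, calibrated by the studentized
#' maximum modulus
#' \deqn{M = \max_{i<j} \frac{|(\mu_i - \mu_j) - (\hat\mu_i - \hat\mu_j)|}
#'      {\sqrt{v_{ij}}}, \qquad
#'      v_{ij} = \frac{s_i^2}{T n_i (n_i - 3)} + \frac{s_j^2}{T n_j (n_j - 3)}.}
#' Each interval is \eqn{(\hat\mu_i - \hat\mu_j) \pm q \sqrt{v_{ij}}} where
#' \eqn{q} is the conditional upper-\eqn{\alpha} quantile of a Monte Carlo
#' approximation of \eqn{M}:
#' \itemize{
#'   \item \code{gpq_simultaneous_ci} uses the fiducial GPQ deviations
#'     \eqn{R_{\mu_i} - R_{\mu_j} - (\hat\mu_i - \hat\mu_j)} (same pivotal
#'     draws as [sp_test()]);
#'   \item \code{pb_simultaneous_ci} uses the parametric bootstrap: deviations
#'     \eqn{\hat\mu_i^B - \hat\mu_j^B - (\hat\mu_i - \hat\mu_j)} standardized
#'     by \eqn{v_{ij}} recomputed from the bootstrap variances
#'     \eqn{(\hat\phi_i^B)^2} (the interval halfwidths still use the
#'     observed \eqn{v_{ij}}).
#' }
#' The empirical quantile uses the conservative order statistic with index
#' \eqn{\lceil (1-\alpha)\, \mathrm{mc} \rceil}.
#'
#' @param summary a [study_summary]; every group needs \eqn{n_i \ge 4}.
#' @param level confidence level \eqn{1-\alpha}, strictly between 0 and 1.
#' @param mc_samples Monte Carlo draws for the quantile.
#' @param seed optional integer seed (self-contained stream).
#' @return An object of class \code{"pairwise_ci"}: a data frame with one
#'   row per pair (\code{i}, \code{j}, \code{center}, \code{halfwidth},
#'   \code{lower}, \code{upper}) and attributes \code{level}, \code{method},
#'   \code{q}, \code{mc_samples}, \code{seed}.
#' @examples
#' ci <- gpq_simultaneous_ci(example_study_summary(), level = 0.95,
#'                           mc_samples = 20000, seed = 1)
#' ci
NULL

upper_quantile <- function(x, alpha) {
  k <- ceiling((1 - alpha) * length(x))
  k <- min(max(k, 1L), length(x))
  sort(x, partial = k)[k]
}

pair_index <- function(I) {
  utils::combn(I, 2L)
}

new_pairwise_ci <- function(summary, q, method, level, mc_samples, seed) {
  n <- summary$n; ss <- summary$ss; T <- summary$T
  pr <- pair_index(length(n))
  v <- ss / (T * n * (n - 3))
  vij <- v[pr[1L, ]] + v[pr[2L, ]]
  center <- summary$mu_hat[pr[1L, ]] - summary$mu_hat[pr[2L, ]]
  half <- q * sqrt(vij)
  out <- data.frame(i = summary$group_names[pr[1L, ]],
                    j = summary$group_names[pr[2L, ]],
                    center = center, halfwidth = half,
                    lower = center - half, upper = center + half,
                    stringsAsFactors = FALSE)
  structure(out, level = level, method = method, q = q,
            mc_samples = as.integer(mc_samples), seed = seed,
            class = c("pairwise_ci", "data.frame"))
}

#' @export
print.pairwise_ci <- function(x, ...) {
  cat(sprintf("Simultaneous %g%% intervals for pairwise mean differences (%s)\n",
              100 * attr(x, "level"), attr(x, "method")))
  cat(sprintf("  critical quantile q = %.4g from %d draws\n",
              attr(x, "q"), attr(x, "mc_samples")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

check_ci_input <- function(summary, level) {
  check_positive_ss(summary)
  if (any(summary$n <= 3L))
    stop("simultaneous intervals require n_i >= 4 in every group")
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must be in (0, 1)")
}

# GPQ draws of the studentized maximum modulus
.q_gpq <- function(n, mu_hat, ss, T, alpha, mc) {
  I <- length(n)
  pr <- pair_index(I)
  v <- ss / (T * n * (n - 3))
  vij <- v[pr[1L, ]] + v[pr[2L, ]]
  Z <- matrix(stats::rnorm(mc * I), mc, I)
  V <- .chisq_draws(n, mc)
  D <- -Z * sqrt(sweep(1 / V, 2L, ss / (T * n), `*`))   # R_mu - mu_hat
  Dd <- D[, pr[1L, ], drop = FALSE] - D[, pr[2L, ], drop = FALSE]
  Rd <- do.call(pmax, as.data.frame(abs(sweep(Dd, 2L, sqrt(vij), `/`))))
  upper_quantile(Rd, alpha)
}

# bootstrap draws of the studentized maximum modulus
.q_pb <- function(n, mu_hat, ss, T, alpha, mc) {
  I <- length(n)
  pr <- pair_index(I)
  phih <- ss / (n - 1)
  phiB <- .chisq_draws(n, mc) * rep(phih / (n - 1), each = mc)
  muB <- matrix(stats::rnorm(mc * I), mc, I) * rep(sqrt(phih / (T * n)), each = mc)
  # v_ij with (n_i - 1)(phi_i^B)^2 in place of s_i^2
  vB <- sweep(phiB, 2L, (n - 1) / (T * n * (n - 3)), `*`)
  Dd <- muB[, pr[1L, ], drop = FALSE] - muB[, pr[2L, ], drop = FALSE]
  Vd <- vB[, pr[1L, ], drop = FALSE] + vB[, pr[2L, ], drop = FALSE]
  Mb <- do.call(pmax, as.data.frame(abs(Dd) / sqrt(Vd)))
  upper_quantile(Mb, alpha)
}

#' @rdname simultaneous_ci
#' @export
gpq_simultaneous_ci <- function(summary, level = 0.95, mc_samples = 10000,
                                seed = NULL) {
  summary <- as_study_summary(summary)
  check_ci_input(summary, level)
  mc_samples <- check_mc(mc_samples)
  alpha <- 1 - level
  q <- with_seed(seed, .q_gpq(summary$n, summary$mu_hat, summary$ss,
                              summary$T, alpha, mc_samples))
  new_pairwise_ci(summary, q, "GPQ", level, mc_samples, seed)
}

#' @rdname simultaneous_ci
#' @export
pb_simultaneous_ci <- function(summary, level = 0.95, mc_samples = 10000,
                               seed = NULL) {
  summary <- as_study_summary(summary)
  check_ci_input(summary, level)
  mc_samples <- check_mc(mc_samples)
  alpha <- 1 - level
  q <- with_seed(seed, .q_pb(summary$n, summary$mu_hat, summary$ss,
                             summary$T, alpha, mc_samples))
  new_pairwise_ci(summary, q, "PB", level, mc_samples, seed)
}
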