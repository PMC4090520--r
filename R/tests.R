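#' Canonical contrast matrix for equality of I means
#'
#' The \eqn{(I-1) \times I} matrix whose row \eqn{k} has \eqn{+1} in
#' position \eqn{k} and \eqn{-1} in position \eqn{I}: \eqn{H\mu = 0} iff all
#' means are equal.
#'
#' @param I number of groups (>= 2).
#' @return A full-row-rank matrix whose rows each sum to zero.
#' @export
canonical_contrast <- function(I) {
  I <- as.integer(I)
  if (length(I) != 1L || I < 2L) stop("'I' must be an integer >= 2")
  cbind(diag(1, I - 1L), rep(-1, I - 1L))
}

check_contrast <- function(H, I) {
  H <- as.matrix(H)
  if (nrow(H) != I - 1L || ncol(H) != I)
    stop("contrast matrix must be (I-1) x I")
  if (max(abs(rowSums(H))) > 1e-8)
    stop("contrast rows must sum to zero")
  if (qr(H)$rank < I - 1L)
    stop("contrast matrix must have full row rank I-1")
  H
}

new_test_result <- function(method, p, statistic, mc_samples, seed, mc_se) {
  structure(list(method = method, p_value = p, statistic = statistic,
                 mc_samples = as.integer(mc_samples), seed = seed,
                 mc_se = mc_se),
            class = "mean_eq_test")
}

#' @export
print.mean_eq_test <- function(x, ...) {
  label <- c(GF = "Generalized F-test",
             SP = "Standardization-based (GPQ) test",
             PB = "Parametric bootstrap test")[x$method]
  cat(label, "of equal group means\n")
  if (!is.null(x$statistic) && is.finite(x$statistic))
    cat(sprintf("  statistic = %.6g\n", x$statistic))
  cat(sprintf("  p-value   = %.6g  (MC SE %.2g, %d draws%s)\n",
              x$p_value, x$mc_se, x$mc_samples,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

# snapshot the global RNG state; returns a restorer for on.exit()
rng_snapshot <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

check_mc <- function(mc_samples) {
  mc_samples <- as.integer(mc_samples)
  if (length(mc_samples) != 1L || is.na(mc_samples) || mc_samples < 1L)
    stop("'mc_samples' must be a positive integer")
  if (mc_samples < 1000L)
    warning("mc_samples < 1000 gives a noisy p-value estimate")
  mc_samples
}

check_positive_ss <- function(summary) {
  if (any(summary$ss <= 0))
    stop("degenerate input: every group must have a strictly positive ",
         "residual sum of squares")
}

# ---- Monte Carlo kernels --------------------------------------------------
# These operate on plain vectors, consume the current RNG stream, and are
# shared by the user-facing tests and the simulation drivers.

# chi-square draw matrix, mc x I, column i has n_i - 1 df
.chisq_draws <- function(n, mc) {
  matrix(stats::rchisq(mc * length(n), rep(n - 1, each = mc)), mc, length(n))
}

# Generalized F-test: Rao-Blackwellized estimator. Conditional on
# V_i ~ chi2(n_i - 1), the p-value contribution is the chi2(I-1) upper tail
# beyond the between-SS with weights T n_i V_i / s_i^2.
.p_gf <- function(n, mu_hat, ss, T, mc) {
  I <- length(n)
  V <- .chisq_draws(n, mc)
  W <- sweep(V, 2L, T * n / ss, `*`)
  tail_probs <- stats::pchisq(.bss_rows(W, mu_hat), I - 1, lower.tail = FALSE)
  list(p = mean(tail_probs),
       se = stats::sd(tail_probs) / sqrt(mc))
}

# Standardization-based test: GPQ draws R_mu_i = mu_hat_i - Z_i s_i /
# sqrt(V_i T n_i); Mahalanobis norm wrt A = H diag(s_i^2/(T n_i (n_i-3))) H'.
.p_sp <- function(n, mu_hat, ss, T, mc, H) {
  I <- length(n)
  A <- H %*% (ss / (T * n * (n - 3)) * t(H))
  Ainv <- solve(A)
  hm <- drop(H %*% mu_hat)
  obs <- drop(crossprod(hm, Ainv %*% hm))
  Z <- matrix(stats::rnorm(mc * I), mc, I)
  V <- .chisq_draws(n, mc)
  D <- -Z * sqrt(sweep(1 / V, 2L, ss / (T * n), `*`))  # R_mu - mu_hat
  HD <- D %*% t(H)
  norms <- rowSums((HD %*% Ainv) * HD)
  p <- mean(norms >= obs)
  list(p = p, se = sqrt(p * (1 - p) / mc), statistic = obs)
}

# Parametric bootstrap test: TS at phi_hat_i^2 = s_i^2/(n_i - 1); bootstrap
# means mu_i^B ~ N(0, phi_hat_i^2/(T n_i)) and variances
# (phi_i^B)^2 = phi_hat_i^2 chi2(n_i-1)/(n_i-1); p = Pr(TS^B >= TS).
.p_pb <- function(n, mu_hat, ss, T, mc) {
  I <- length(n)
  phih <- ss / (n - 1)
  TS <- .bss(T * n / phih, mu_hat)
  phiB <- .chisq_draws(n, mc) * rep(phih / (n - 1), each = mc)
  muB <- matrix(stats::rnorm(mc * I), mc, I) * rep(sqrt(phih / (T * n)), each = mc)
  Wb <- sweep(1 / phiB, 2L, T * n, `*`)
  TSB <- .bss_rows2(Wb, muB)
  p <- mean(TSB >= TS)
  list(p = p, se = sqrt(p * (1 - p) / mc), statistic = TS)
}

# ---- user-facing tests ----------------------------------------------------

#' Generalized F-test of equal group means
#'
#' Tests \eqn{H_0: \mu_1 = \cdots = \mu_I} in the heteroscedastic
#' equicorrelated one-way layout via the generalized p-value of the
#' standardized between-group sum of squares \eqn{\tilde S_B^2}
#' (see [between_group_ss()]).  The generalized p-value is estimated by the
#' Rao-Blackwellized Monte Carlo form: draw
#' \eqn{V_i \sim \chi^2_{n_i-1}} independently, evaluate
#' \eqn{\tilde S_B^2} at the variance arguments \eqn{s_i^2 / V_i}, and
#' average the \eqn{\chi^2_{I-1}} upper-tail probability beyond it.
#'
#' @param summary a [study_summary] (raw studies are reduced first).
#' @param mc_samples number of Monte Carlo draws; 10,000 is adequate
#'   interactively, 500,000 for reporting.
#' @param seed optional integer seed for a reproducible, self-contained
#'   draw stream (the caller's RNG state is restored).
#' @return A \code{"mean_eq_test"} object: \code{method}, \code{p_value},
#'   \code{statistic} (here \code{NA}: the generalized p-value has no single
#'   observed statistic), \code{mc_samples}, \code{seed}, \code{mc_se}.
#' @references Lin, S. H. and Lee, J. C. (2003) Exact tests in simple growth
#'   curve models and one-way ANOVA with equicorrelation error structure.
#'   Journal of Multivariate Analysis 84, 351-368.
#' @examples
#' gf_test(example_study_summary(), mc_samples = 20000, seed = 1)
#' @export
gf_test <- function(summary, mc_samples = 10000, seed = NULL) {
  summary <- as_study_summary(summary)
  check_positive_ss(summary)
  mc_samples <- check_mc(mc_samples)
  res <- with_seed(seed, .p_gf(summary$n, summary$mu_hat, summary$ss,
                               summary$T, mc_samples))
  new_test_result("GF", res$p, NA_real_, mc_samples, seed, res$se)
}

#' Standardization-based (fiducial GPQ) test of equal group means
#'
#' Tests \eqn{H_0: H\mu = 0} through fiducial generalized pivotal quantities
#' \eqn{R_{\mu_i} = \hat\mu_i - Z_i \sqrt{s_i^2 / (V_i T n_i)}} with
#' \eqn{Z_i \sim N(0,1)}, \eqn{V_i \sim \chi^2_{n_i-1}}.  The p-value is the
#' fiducial probability that \eqn{H R_\mu} deviates from its center
#' \eqn{H\hat\mu} by more, in the Mahalanobis norm with respect to
#' \eqn{\mathrm{Cov}^*(H R_\mu) = H\,\mathrm{diag}\{s_i^2/(T n_i (n_i-3))\} H'},
#' than the center deviates from zero.  The p-value is invariant to
#' replacing \eqn{H} by \eqn{M H} for any invertible \eqn{M}.
#'
#' @inheritParams gf_test
#' @param contrast optional \eqn{(I-1) \times I} full-row-rank contrast
#'   matrix; defaults to [canonical_contrast()].
#' @return A \code{"mean_eq_test"}; \code{statistic} is the observed
#'   Mahalanobis norm of \eqn{H\hat\mu}.
#' @note Requires \eqn{n_i \ge 4} in every group (the fiducial covariance
#'   has denominators \eqn{n_i - 3}).
#' @examples
#' sp_test(example_study_summary(), mc_samples = 20000, seed = 1)
#' @export
sp_test <- function(summary, mc_samples = 10000, seed = NULL, contrast = NULL) {
  summary <- as_study_summary(summary)
  check_positive_ss(summary)
  I <- length(summary$n)
  if (any(summary$n <= 3L))
    stop("sp_test requires n_i >= 4 in every group (fiducial covariance ",
         "uses n_i - 3 denominators)")
  H <- if (is.null(contrast)) canonical_contrast(I) else check_contrast(contrast, I)
  mc_samples <- check_mc(mc_samples)
  res <- with_seed(seed, .p_sp(summary$n, summary$mu_hat, summary$ss,
                               summary$T, mc_samples, H))
  new_test_result("SP", res$p, res$statistic, mc_samples, seed, res$se)
}

#' Parametric bootstrap test of equal group means
#'
#' The test statistic is \eqn{TS = \tilde S_B^2(\hat\phi_1^2, \ldots,
#' \hat\phi_I^2)} with \eqn{\hat\phi_i^2 = S_i^2/(n_i - 1)}.  Its null
#' distribution is approximated by the parametric bootstrap: each draw sets
#' \eqn{\hat\mu_i^B \sim N(0, \hat\phi_i^2/(T n_i))} and
#' \eqn{(\hat\phi_i^B)^2 = \hat\phi_i^2 \chi^2_{n_i-1}/(n_i-1)}, and
#' recomputes the statistic.  The p-value is the proportion of bootstrap
#' statistics at or above \eqn{TS}.
#'
#' @inheritParams gf_test
#' @return A \code{"mean_eq_test"}; \code{statistic} carries \eqn{TS}.
#' @references Krishnamoorthy, K., Lu, F. and Mathew, T. (2007) A parametric
#'   bootstrap approach for ANOVA with unequal variances. Computational
#'   Statistics & Data Analysis 51, 5731-5742.
#' @examples
#' pb_test(example_study_summary(), mc_samples = 20000, seed = 1)
#' @export
pb_test <- function(summary, mc_samples = 10000, seed = NULL) {
  summary <- as_study_summary(summary)
  check_positive_ss(summary)
  mc_samples <- check_mc(mc_samples)
  res <- with_seed(seed, .p_pb(summary$n, summary$mu_hat, summary$ss,
                               summary$T, mc_samples))
  new_test_result("PB", res$p, res$statistic, mc_samples, seed, res$se)
}
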