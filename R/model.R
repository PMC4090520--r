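#' Generative parameters of the equicorrelated one-way layout
#'
#' Bundles the parameters of the one-way ANOVA model with compound-symmetric
#' within-subject errors: each subject \eqn{j} in group \eqn{i} contributes a
#' vector of \eqn{T} repeated measurements
#' \deqn{Y_{ij} = \mu_i 1_T + \alpha_{ij} 1_T + \epsilon_{ij},}
#' with subject random effect \eqn{\alpha_{ij} \sim N(0, \sigma_\alpha^2)} and
#' error \eqn{\epsilon_{ij} \sim N(0, \Sigma_{ei})},
#' \eqn{\Sigma_{ei} = \sigma_i^2[(1-\rho) I_T + \rho 1_T 1_T']}.
#' Group error variances \eqn{\sigma_i^2} may differ; the equicorrelation
#' \eqn{\rho} and the random-effect scale \eqn{\sigma_\alpha} are shared.
#'
#' @param n integer vector of per-group subject counts (each >= 2); its length
#'   defines the number of groups \eqn{I}.
#' @param mu numeric vector of group means \eqn{\mu_i} (length \eqn{I}, or a
#'   scalar recycled to all groups).
#' @param sigma positive numeric vector of within-subject error SDs
#'   \eqn{\sigma_i} (length \eqn{I} or scalar).
#' @param rho equicorrelation, \eqn{-1/(T-1) < \rho < 1} (any \eqn{\rho < 1}
#'   when \code{T == 1}).
#' @param sigma_alpha nonnegative random-effect SD \eqn{\sigma_\alpha}.
#' @param T integer number of repeated measurements per subject (>= 1).
#'
#' @return An object of class \code{"model_params"}: a list with components
#'   \code{I}, \code{T}, \code{n}, \code{mu}, \code{sigma}, \code{rho},
#'   \code{sigma_alpha}.
#' @seealso [generate_dataset()], [phi_squared()]
#' @examples
#' model_params(n = c(5, 5, 10), mu = c(0, 0, 0), sigma = c(1, 1.5, 2),
#'              rho = 0.2, sigma_alpha = 1, T = 4)
#' @export
model_params <- function(n, mu = 0, sigma = 1, rho = 0, sigma_alpha = 0, T = 1) {
  I <- length(n)
  if (I < 2L) stop("at least two groups are required")
  n <- as.integer(n)
  if (any(n < 2L)) stop("every group needs n_i >= 2 subjects")
  T <- as.integer(T)
  if (length(T) != 1L || T < 1L) stop("'T' must be a single integer >= 1")
  mu <- rep_len(as.numeric(mu), I)
  sigma <- rep_len(as.numeric(sigma), I)
  if (any(!is.finite(mu))) stop("'mu' must be finite")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("'sigma' must be positive")
  if (!is.finite(rho) || rho >= 1 || (T > 1L && rho <= -1 / (T - 1)))
    stop("'rho' must satisfy -1/(T-1) < rho < 1")
  if (!is.finite(sigma_alpha) || sigma_alpha < 0)
    stop("'sigma_alpha' must be nonnegative")
  phi2 <- phi_squared(sigma^2, rho, sigma_alpha^2, T)
  if (any(phi2 <= 0)) stop("derived phi^2 must be strictly positive")
  structure(list(I = I, T = T, n = n, mu = mu, sigma = sigma,
                 rho = rho, sigma_alpha = sigma_alpha),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Equicorrelated one-way layout: I = %d groups, T = %d repeats\n",
              x$I, x$T))
  cat("  n          :", paste(x$n, collapse = " "), "\n")
  cat("  mu         :", paste(format(x$mu), collapse = " "), "\n")
  cat("  sigma      :", paste(format(x$sigma), collapse = " "), "\n")
  cat(sprintf("  rho = %s, sigma_alpha = %s, phi^2 = %s\n",
              format(x$rho), format(x$sigma_alpha),
              paste(format(phi_squared(x$sigma^2, x$rho, x$sigma_alpha^2, x$T)),
                    collapse = " ")))
  invisible(x)
}

#' Per-group nuisance scale phi^2
#'
#' The variance of \eqn{\sqrt{T}} times a subject mean,
#' \deqn{\phi_i^2 = \sigma_i^2 (1 - \rho) + T (\rho \sigma_i^2 + \sigma_\alpha^2),}
#' is the single scale parameter each group contributes to every test and
#' interval in the package: the subject means are
#' \eqn{\bar Y_{ij\cdot} \sim N(\mu_i, \phi_i^2 / T)} and the residual sum of
#' squares satisfies \eqn{S_i^2 / \phi_i^2 \sim \chi^2_{n_i-1}}.
#'
#' @param sigma2 within-subject error variance \eqn{\sigma_i^2} (vectorized).
#' @param rho equicorrelation.
#' @param sigma_alpha2 random-effect variance \eqn{\sigma_\alpha^2}.
#' @param T repeats per subject.
#' @return \eqn{\phi^2}, same length as the longest argument.
#' @examples
#' phi_squared(1, 0.2, 1, 4)      # 5.6
#' phi_squared(20.25, 0.2, 1, 4)  # 36.4
#' @export
phi_squared <- function(sigma2, rho, sigma_alpha2, T) {
  out <- sigma2 * (1 - rho) + T * (rho * sigma2 + sigma_alpha2)
  if (any(!is.finite(out)) || any(out <= 0))
    stop("phi^2 must be strictly positive; check sigma2, rho, sigma_alpha2")
  out
}

#' Compound-symmetry error covariance
#'
#' The \eqn{T \times T} within-subject error covariance
#' \eqn{\Sigma_e = \sigma^2[(1-\rho) I_T + \rho 1_T 1_T']}: constant variance
#' \eqn{\sigma^2} on the diagonal and constant covariance \eqn{\rho\sigma^2}
#' off it.  Its eigenvalues are \eqn{\sigma^2(1-\rho)} (multiplicity
#' \eqn{T-1}) and \eqn{\sigma^2(1 + (T-1)\rho)}.
#'
#' @param sigma2 error variance (scalar, positive).
#' @param rho equicorrelation.
#' @param T dimension.
#' @return A \eqn{T \times T} positive-definite matrix.
#' @export
equicorr_cov <- function(sigma2, rho, T) {
  T <- as.integer(T)
  if (sigma2 * (1 - rho) <= 0 || sigma2 * (1 + (T - 1) * rho) <= 0)
    stop("parameters do not give a positive-definite compound-symmetry matrix")
  m <- matrix(rho * sigma2, T, T)
  diag(m) <- sigma2
  m
}

#' Inverse marginal covariance of a subject's observation vector
#'
#' The marginal covariance of one subject's \eqn{T}-vector is
#' \eqn{\Sigma = \Sigma_e + \sigma_\alpha^2 1_T 1_T'}; its inverse has the
#' closed form
#' \deqn{\Sigma^{-1} = [\sigma^2(1-\rho)]^{-1}
#'   \left[I_T - \frac{\phi^2 - \sigma^2(1-\rho)}{T\,\phi^2} 1_T 1_T'\right],}
#' with \eqn{\phi^2} as in [phi_squared()].
#'
#' @inheritParams phi_squared
#' @return A \eqn{T \times T} matrix, the inverse of
#'   \code{equicorr_cov(sigma2, rho, T) + sigma_alpha2}.
#' @export
marginal_cov_inverse <- function(sigma2, rho, sigma_alpha2, T) {
  T <- as.integer(T)
  a <- sigma2 * (1 - rho)
  if (a <= 0) stop("sigma^2 (1 - rho) must be positive")
  phi2 <- phi_squared(sigma2, rho, sigma_alpha2, T)
  m <- matrix(-(phi2 - a) / (T * phi2), T, T)
  diag(m) <- diag(m) + 1
  m / a
}

#' Standardized between-group sum of squares
#'
#' The weighted between-group variability
#' \deqn{\tilde S_B^2(\phi_1^2,\ldots,\phi_I^2) =
#'   \sum_i w_i \hat\mu_i^2 - \left(\sum_i w_i \hat\mu_i\right)^2 \Big/
#'   \sum_i w_i, \qquad w_i = T n_i / \phi_i^2,}
#' which follows \eqn{\chi^2_{I-1}} under the null of equal means when
#' evaluated at the true \eqn{\phi_i^2}.  This is the common kernel of the
#' generalized F-test and the parametric bootstrap test.
#'
#' @param phi2 positive vector of variance arguments, one per group.
#' @param summary a [study_summary] object supplying \code{n}, \code{mu_hat}
#'   and \code{T}.
#' @return A nonnegative scalar.
#' @export
between_group_ss <- function(phi2, summary) {
  summary <- as_study_summary(summary)
  if (length(phi2) != length(summary$n))
    stop("'phi2' must have one entry per group")
  if (any(!is.finite(phi2)) || any(phi2 <= 0))
    stop("all phi^2 arguments must be strictly positive")
  .bss(summary$T * summary$n / phi2, summary$mu_hat)
}

# weighted between-SS kernel; w = T n / phi^2.  Centered form (anchored at
# m[1]) so the result is nonnegative in floating point and exactly zero when
# all means coincide.
.bss <- function(w, m) {
  m0 <- m - m[1L]
  mb <- sum(w * m0) / sum(w)
  sum(w * (m0 - mb)^2)
}

# row-wise kernel for draw matrices: W is mc x I, common mean vector m
.bss_rows <- function(W, m) {
  m0 <- m - m[1L]
  dev <- matrix(m0, nrow(W), length(m0), byrow = TRUE) -
    drop(W %*% m0) / rowSums(W)
  rowSums(W * dev^2)
}

# row-wise kernel when the means vary by row: M and W are both mc x I
.bss_rows2 <- function(W, M) {
  M0 <- M - M[, 1L]
  dev <- M0 - rowSums(W * M0) / rowSums(W)
  rowSums(W * dev^2)
}
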