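#' Generate a study from the equicorrelated one-way model
#'
#' Draws a complete repeated-measures dataset: for each subject \eqn{j} of
#' group \eqn{i}, an independent random effect
#' \eqn{\alpha_{ij} \sim N(0, \sigma_\alpha^2)} and an error vector
#' \eqn{\epsilon_{ij} \sim N(0, \Sigma_{ei})} with compound-symmetric
#' \eqn{\Sigma_{ei}}, giving
#' \eqn{Y_{ij} = \mu_i 1_T + \alpha_{ij} 1_T + \epsilon_{ij}}.  The random
#' effect is drawn per subject, which is what makes the residual sum of
#' squares satisfy \eqn{S_i^2/\phi_i^2 \sim \chi^2_{n_i-1}}.
#'
#' @param params a [model_params] object.
#' @param seed optional integer seed (self-contained stream).
#' @return A [raw_study].
#' @examples
#' p <- model_params(n = c(5, 5), mu = c(0, 1), sigma = c(1, 2),
#'                   rho = 0.2, sigma_alpha = 1, T = 4)
#' summarize_study(generate_dataset(p, seed = 1))
#' @export
generate_dataset <- function(params, seed = NULL) {
  if (!inherits(params, "model_params")) stop("expected a 'model_params' object")
  with_seed(seed, .generate(params))
}

.generate <- function(params) {
  T <- params$T; n <- params$n; I <- params$I
  # correlation factor shared across groups; scale rows by sigma_i
  R <- equicorr_cov(1, params$rho, T)
  U <- chol(R)
  total <- sum(n)
  gi <- rep.int(seq_len(I), n)                     # group of each subject
  eps <- matrix(stats::rnorm(total * T), total, T) %*% U
  eps <- eps * params$sigma[gi]
  shift <- params$mu[gi] +
    if (params$sigma_alpha > 0) stats::rnorm(total, 0, params$sigma_alpha) else 0
  Y <- eps + shift
  raw_study(lapply(split.data.frame(Y, gi), unname))
}

check_reps <- function(reps) {
  reps <- as.integer(reps)
  if (length(reps) != 1L || is.na(reps) || reps < 1L)
    stop("'reps' must be a positive integer")
  reps
}

# master -> per-rep -> per-stage seed table (reps x k)
spawn_seeds <- function(seed, reps, k) {
  with_seed(seed,
            matrix(sample.int(2147483646L, reps * k, replace = TRUE), reps, k))
}

#' Monte Carlo Type I error study
#'
#' Repeatedly generates null data from [generate_dataset()], reduces each
#' dataset with [summarize_study()], applies the selected tests, and reports
#' the proportion of p-values at or below \code{alpha} with its binomial
#' standard error.  The model in \code{params} must satisfy the null (all
#' \eqn{\mu_i} equal); anything else is refused.
#'
#' Seeds are spawned deterministically, master seed to per-replicate to
#' per-test, so results are reproducible bit-exactly for a fixed
#' \code{seed} regardless of which methods are requested.
#'
#' @param params a [model_params] with all means equal.
#' @param reps number of simulated datasets.
#' @param mc_samples inner Monte Carlo size for each p-value.
#' @param alpha nominal level.
#' @param methods subset of \code{c("GF", "SP", "PB")}.
#' @param seed master seed.
#' @return A data frame with columns \code{method}, \code{rate}, \code{se},
#'   plus attributes \code{reps}, \code{mc_samples}, \code{alpha},
#'   \code{params}, \code{seed}.
#' @examples
#' p <- model_params(n = c(5, 5, 5), mu = 0, sigma = 1, rho = 0.2,
#'                   sigma_alpha = 1, T = 4)
#' type_i_error_study(p, reps = 50, mc_samples = 1000, seed = 1)
#' @export
type_i_error_study <- function(params, reps = 2000, mc_samples = 2000,
                               alpha = 0.05, methods = c("GF", "SP", "PB"),
                               seed = NULL) {
  if (!inherits(params, "model_params")) stop("expected a 'model_params' object")
  if (max(params$mu) - min(params$mu) > 0)
    stop("Type I error study requires a true null: all 'mu' equal")
  methods <- match.arg(methods, c("GF", "SP", "PB"), several.ok = TRUE)
  if ("SP" %in% methods && any(params$n <= 3L))
    stop("SP requires n_i >= 4 in every group")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
  reps <- check_reps(reps)
  mc_samples <- check_mc(mc_samples)
  seeds <- spawn_seeds(seed, reps, 4L)
  restore_rng <- rng_snapshot()
  on.exit(restore_rng(), add = TRUE)
  H <- canonical_contrast(params$I)
  rej <- matrix(0, reps, length(methods), dimnames = list(NULL, methods))
  for (r in seq_len(reps)) {
    set.seed(seeds[r, 1L])
    s <- summarize_study(.generate(params))
    for (m in methods) {
      p <- switch(m,
        GF = { set.seed(seeds[r, 2L])
               .p_gf(s$n, s$mu_hat, s$ss, s$T, mc_samples)$p },
        SP = { set.seed(seeds[r, 3L])
               .p_sp(s$n, s$mu_hat, s$ss, s$T, mc_samples, H)$p },
        PB = { set.seed(seeds[r, 4L])
               .p_pb(s$n, s$mu_hat, s$ss, s$T, mc_samples)$p })
      rej[r, m] <- (p <= alpha)
    }
  }
  rate <- colMeans(rej)
  out <- data.frame(method = methods, rate = as.numeric(rate),
                    se = sqrt(rate * (1 - rate) / reps),
                    stringsAsFactors = FALSE)
  structure(out, reps = reps, mc_samples = mc_samples, alpha = alpha,
            params = params, seed = seed)
}

#' Monte Carlo simultaneous coverage study
#'
#' Repeatedly generates data from [generate_dataset()], builds simultaneous
#' confidence intervals for all pairwise mean differences, and reports the
#' proportion of replicates in which every interval covers its true
#' difference \eqn{\mu_i - \mu_j} simultaneously.
#'
#' @param params a [model_params]; every group needs \eqn{n_i \ge 4}.
#' @param level confidence level.
#' @param reps number of simulated datasets.
#' @param mc_samples Monte Carlo draws per critical quantile.
#' @param methods subset of \code{c("GPQ", "PB")}.
#' @param seed master seed.
#' @return A data frame with columns \code{method}, \code{coverage},
#'   \code{se}, with the same attributes as [type_i_error_study()].
#' @examples
#' p <- model_params(n = rep(10, 4), mu = c(1, 1, 2, 2), sigma = 1,
#'                   rho = 0, sigma_alpha = 0, T = 4)
#' coverage_study(p, reps = 50, mc_samples = 1000, seed = 1)
#' @export
coverage_study <- function(params, level = 0.95, reps = 2000,
                           mc_samples = 2000, methods = c("GPQ", "PB"),
                           seed = NULL) {
  if (!inherits(params, "model_params")) stop("expected a 'model_params' object")
  methods <- match.arg(methods, c("GPQ", "PB"), several.ok = TRUE)
  if (any(params$n <= 3L))
    stop("simultaneous intervals require n_i >= 4 in every group")
  if (!is.numeric(level) || level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  reps <- check_reps(reps)
  mc_samples <- check_mc(mc_samples)
  alpha <- 1 - level
  seeds <- spawn_seeds(seed, reps, 3L)
  restore_rng <- rng_snapshot()
  on.exit(restore_rng(), add = TRUE)
  pr <- pair_index(params$I)
  dtrue <- params$mu[pr[1L, ]] - params$mu[pr[2L, ]]
  cov <- matrix(0, reps, length(methods), dimnames = list(NULL, methods))
  for (r in seq_len(reps)) {
    set.seed(seeds[r, 1L])
    s <- summarize_study(.generate(params))
    v <- s$ss / (s$T * s$n * (s$n - 3))
    vij <- v[pr[1L, ]] + v[pr[2L, ]]
    dhat <- s$mu_hat[pr[1L, ]] - s$mu_hat[pr[2L, ]]
    dev <- abs(dhat - dtrue)
    for (m in methods) {
      q <- switch(m,
        GPQ = { set.seed(seeds[r, 2L])
                .q_gpq(s$n, s$mu_hat, s$ss, s$T, alpha, mc_samples) },
        PB  = { set.seed(seeds[r, 3L])
                .q_pb(s$n, s$mu_hat, s$ss, s$T, alpha, mc_samples) })
      cov[r, m] <- all(dev <= q * sqrt(vij))
    }
  }
  rate <- colMeans(cov)
  out <- data.frame(method = methods, coverage = as.numeric(rate),
                    se = sqrt(rate * (1 - rate) / reps),
                    stringsAsFactors = FALSE)
  structure(out, reps = reps, mc_samples = mc_samples, level = level,
            params = params, seed = seed)
}

#' Leave-one-out test battery
#'
#' For each group in turn, drops that group and applies the selected tests
#' to the remaining ones, a convenient screen when one suspects a single
#' treatment drives an overall rejection.
#'
#' @param summary a [study_summary] with at least three groups.
#' @param mc_samples Monte Carlo draws per test.
#' @param methods subset of \code{c("GF", "SP", "PB")}.
#' @param seed optional master seed (one sub-seed per subset and method).
#' @return A data frame with columns \code{dropped}, one p-value column per
#'   method.
#' @examples
#' leave_one_out_tests(example_study_summary(), mc_samples = 5000, seed = 1)
#' @export
leave_one_out_tests <- function(summary, mc_samples = 10000,
                                methods = c("GF", "SP", "PB"), seed = NULL) {
  summary <- as_study_summary(summary)
  methods <- match.arg(methods, c("GF", "SP", "PB"), several.ok = TRUE)
  I <- length(summary$n)
  if (I < 3L) stop("need at least three groups to drop one")
  seeds <- spawn_seeds(seed, I, 3L)
  out <- data.frame(dropped = summary$group_names, stringsAsFactors = FALSE)
  for (m in methods) out[[paste0("p_", tolower(m))]] <- NA_real_
  for (k in seq_len(I)) {
    sk <- subset_groups(summary, setdiff(seq_len(I), k))
    for (m in methods) {
      col <- paste0("p_", tolower(m))
      out[[col]][k] <- switch(m,
        GF = gf_test(sk, mc_samples, seed = seeds[k, 1L])$p_value,
        SP = sp_test(sk, mc_samples, seed = seeds[k, 2L])$p_value,
        PB = pb_test(sk, mc_samples, seed = seeds[k, 3L])$p_value)
    }
  }
  out
}
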