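# Shared fixtures and independent oracles for the test suite.

# The packaged eight-treatment example, loaded once.
example8 <- example_study_summary()

# Weighted between-group SS computed the naive way (independent of the
# package's kernel): explicit weighted mean and loop-free quadratic form.
bss_naive <- function(phi2, n, mu_hat, T) {
  w <- T * n / phi2
  mbar <- sum(w * mu_hat) / sum(w)
  sum(w * (mu_hat - mbar)^2)
}

# Simulate subject means directly from their exact marginal law
# N(mu_i, phi_i^2 / T): reps x n_i matrix for one group.
sim_subject_means <- function(reps, n, mu, phi2, T) {
  matrix(rnorm(reps * n, mu, sqrt(phi2 / T)), reps, n)
}

# Reduce a reps x n matrix of subject means to (mu_hat, ss) per replicate.
reduce_rows <- function(Y, T) {
  m <- rowMeans(Y)
  list(mu_hat = m, ss = T * rowSums((Y - m)^2))
}

# Brute-force nested-simulation estimate of the generalized F-test p-value:
# simulate the model under H0 at a chosen true phi^2 and take the proportion
# of replicates where the standardized between-SS at the true phi^2 exceeds
# the observed statistic evaluated at s_obs^2 * phi^2 / S_sim^2.
gf_oracle <- function(summary, phi2_true, reps) {
  n <- summary$n; T <- summary$T
  I <- length(n)
  sim <- lapply(seq_len(I), function(i)
    reduce_rows(sim_subject_means(reps, n[i], 0, phi2_true[i], T), T))
  mu_sim <- sapply(sim, `[[`, "mu_hat")
  ss_sim <- sapply(sim, `[[`, "ss")
  lhs <- rhs <- numeric(reps)
  for (r in seq_len(reps)) {
    lhs[r] <- bss_naive(phi2_true, n, mu_sim[r, ], T)
    rhs[r] <- bss_naive(summary$ss * phi2_true / ss_sim[r, ], n,
                        summary$mu_hat, T)
  }
  p <- mean(lhs >= rhs)
  list(p = p, se = sqrt(p * (1 - p) / reps))
}

random_invertible <- function(k) {
  repeat {
    M <- matrix(rnorm(k * k), k, k)
    if (abs(det(M)) > 1e-3) return(M)
  }
}
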