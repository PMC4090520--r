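test_that("canonical_contrast has the identity-block structure", {
  expect_equal(canonical_contrast(2), matrix(c(1, -1), 1))
  expect_equal(canonical_contrast(3), rbind(c(1, 0, -1), c(0, 1, -1)))
  for (I in c(5, 12, 20)) {
    H <- canonical_contrast(I)
    expect_equal(qr(H)$rank, I - 1)
    expect_equal(rowSums(H), rep(0, I - 1))
  }
  expect_error(canonical_contrast(1), ">= 2")
})

test_that("all three tests return p = 1 when every group mean is equal", {
  s <- study_summary(n = c(6, 8, 10), mu_hat = rep(1.7, 3),
                     ss = c(5, 9, 14), T = 4)
  expect_identical(gf_test(s, 2000, seed = 1)$p_value, 1)
  expect_identical(sp_test(s, 2000, seed = 1)$p_value, 1)
  expect_identical(pb_test(s, 2000, seed = 1)$p_value, 1)
  expect_equal(pb_test(s, 2000, seed = 1)$statistic, 0)
})

test_that("p-values are location and scale invariant at a fixed seed", {
  s0 <- subset_groups(example8, 1:7)
  # scale by 2 (exact in binary floating point): bit-identical p-values
  s2 <- study_summary(s0$n, 2 * s0$mu_hat, 4 * s0$ss, s0$T)
  expect_identical(gf_test(s0, 5000, seed = 3)$p_value,
                   gf_test(s2, 5000, seed = 3)$p_value)
  expect_identical(sp_test(s0, 5000, seed = 3)$p_value,
                   sp_test(s2, 5000, seed = 3)$p_value)
  expect_identical(pb_test(s0, 5000, seed = 3)$p_value,
                   pb_test(s2, 5000, seed = 3)$p_value)
  # general shift and scale: equality up to floating-point rounding
  for (tr in list(c(0, 2.5), c(-7.25, 1), c(3, 0.6))) {
    st <- study_summary(s0$n, tr[2] * s0$mu_hat + tr[1], tr[2]^2 * s0$ss, s0$T)
    expect_equal(gf_test(st, 5000, seed = 3)$p_value,
                 gf_test(s0, 5000, seed = 3)$p_value, tolerance = 1e-9)
    expect_equal(sp_test(st, 5000, seed = 3)$p_value,
                 sp_test(s0, 5000, seed = 3)$p_value, tolerance = 1e-9)
    expect_equal(pb_test(st, 5000, seed = 3)$p_value,
                 pb_test(s0, 5000, seed = 3)$p_value, tolerance = 1e-9)
  }
})

test_that("sp_test is invariant to the choice of contrast matrix", {
  s <- subset_groups(example8, 1:5)
  I <- 5
  H0 <- canonical_contrast(I)
  p0 <- sp_test(s, 20000, seed = 5)$p_value
  set.seed(99)
  for (k in 1:3) {
    M <- random_invertible(I - 1)
    pk <- sp_test(s, 20000, seed = 5, contrast = M %*% H0)$p_value
    expect_equal(pk, p0, tolerance = 1e-6)
  }
  # a genuinely different contrast basis: successive differences
  Hd <- diff(diag(I))
  expect_equal(sp_test(s, 20000, seed = 5, contrast = Hd)$p_value, p0,
               tolerance = 1e-6)
})

test_that("gf_test agrees with the nested-simulation brute-force oracle", {
  s <- study_summary(n = c(5, 5), mu_hat = c(0, 1.2), ss = c(6, 9), T = 4)
  r <- gf_test(s, 2e5, seed = 11)
  set.seed(12)
  o <- gf_oracle(s, phi2_true = c(1, 1), reps = 3e5)
  expect_lt(abs(r$p_value - o$p), 3 * sqrt(r$mc_se^2 + o$se^2))
  # the oracle itself must not depend on the chosen true phi^2
  set.seed(13)
  o2 <- gf_oracle(s, phi2_true = c(4, 4), reps = 3e5)
  expect_lt(abs(o2$p - o$p), 3 * sqrt(o$se^2 + o2$se^2))
})

test_that("pb_test weakens with inflated residual sums of squares", {
  s0 <- subset_groups(example8, 1:6)
  for (seed in c(2, 7, 19)) {
    p1 <- pb_test(s0, 20000, seed = seed)$p_value
    sbig <- study_summary(s0$n, s0$mu_hat, 2 * s0$ss, s0$T)
    p2 <- pb_test(sbig, 20000, seed = seed)$p_value
    expect_gt(p2, p1)
  }
})

test_that("group relabeling leaves gf and pb p-values unchanged in law", {
  # permuting groups re-pairs the group-major draw streams, so equality is
  # distributional: p-values must agree within Monte Carlo error
  s <- subset_groups(example8, 5:8)   # equal n = 10
  perm <- c(3, 1, 4, 2)
  sp_ <- study_summary(s$n[perm], s$mu_hat[perm], s$ss[perm], s$T)
  for (f in list(gf_test, pb_test)) {
    r1 <- f(s, 1e5, seed = 8)
    r2 <- f(sp_, 1e5, seed = 8)
    expect_lt(abs(r1$p_value - r2$p_value),
              3 * sqrt(r1$mc_se^2 + r2$mc_se^2) + 1e-12)
  }
})

test_that("mc_se predicts seed-to-seed spread of gf_test", {
  s <- subset_groups(example8, 1:7)
  runs <- lapply(1:10, function(sd) gf_test(s, 20000, seed = 100 + sd))
  ps <- vapply(runs, `[[`, 0, "p_value")
  se_rep <- vapply(runs, `[[`, 0, "mc_se")
  ratio <- sd(ps) / mean(se_rep)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("degenerate and unsupported inputs are refused loudly", {
  szero <- study_summary(n = c(5, 5), mu_hat = c(0, 1), ss = c(0, 3), T = 2)
  expect_error(gf_test(szero, 2000, seed = 1), "degenerate")
  expect_error(pb_test(szero, 2000, seed = 1), "degenerate")
  s3 <- study_summary(n = c(3, 5), mu_hat = c(0, 1), ss = c(2, 3), T = 2)
  expect_error(sp_test(s3, 2000, seed = 1), "n_i >= 4")
  sok <- study_summary(n = c(5, 5), mu_hat = c(0, 1), ss = c(2, 3), T = 2)
  expect_warning(gf_test(sok, 500, seed = 1), "noisy")
})

test_that("seeded tests restore the caller's RNG state", {
  set.seed(42)
  before <- .Random.seed
  invisible(gf_test(example8, 2000, seed = 9))
  expect_identical(.Random.seed, before)
  u1 <- runif(1)
  set.seed(42)
  invisible(runif(0))
  expect_identical(runif(1), u1)
})
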