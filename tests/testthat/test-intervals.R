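test_that("interval geometry is consistent and centered on mean differences", {
  s <- subset_groups(example8, 1:5)
  for (ci in list(gpq_simultaneous_ci(s, 0.95, 5000, seed = 1),
                  pb_simultaneous_ci(s, 0.95, 5000, seed = 1))) {
    expect_equal(nrow(ci), choose(5, 2))
    idx <- cbind(match(ci$i, s$group_names), match(ci$j, s$group_names))
    expect_equal(ci$center, s$mu_hat[idx[, 1]] - s$mu_hat[idx[, 2]])
    expect_equal(ci$lower, ci$center - ci$halfwidth)
    expect_equal(ci$upper, ci$center + ci$halfwidth)
    expect_true(all(ci$halfwidth > 0))
    expect_gt(attr(ci, "q"), 0)
  }
})

test_that("gpq critical quantile matches a direct quantile oracle at I = 2", {
  s <- study_summary(n = c(8, 12), mu_hat = c(0.4, -0.9), ss = c(11, 23), T = 4)
  mc <- 40000
  ci <- gpq_simultaneous_ci(s, 0.95, mc, seed = 31)
  # replay the documented draw stream and take the empirical quantile of the
  # single pair's |t-like| deviations directly
  set.seed(31)
  Z <- matrix(rnorm(mc * 2), mc, 2)
  V <- matrix(rchisq(mc * 2, rep(s$n - 1, each = mc)), mc, 2)
  D <- -Z * sqrt(sweep(1 / V, 2, s$ss / (s$T * s$n), `*`))
  vij <- sum(s$ss / (s$T * s$n * (s$n - 3)))
  tdev <- abs(D[, 1] - D[, 2]) / sqrt(vij)
  k <- ceiling(0.95 * mc)
  expect_equal(attr(ci, "q"), sort(tdev)[k])
  expect_equal(ci$halfwidth, sort(tdev)[k] * sqrt(vij))
})

test_that("pb critical quantile matches a per-pair oracle at I = 2 and
           dominates any single pair for I > 2", {
  s2 <- study_summary(n = c(8, 12), mu_hat = c(0.4, -0.9), ss = c(11, 23), T = 4)
  mc <- 40000
  ci2 <- pb_simultaneous_ci(s2, 0.95, mc, seed = 17)
  set.seed(17)
  phih <- s2$ss / (s2$n - 1)
  phiB <- matrix(rchisq(mc * 2, rep(s2$n - 1, each = mc)), mc, 2) *
    rep(phih / (s2$n - 1), each = mc)
  muB <- matrix(rnorm(mc * 2), mc, 2) * rep(sqrt(phih / (s2$T * s2$n)), each = mc)
  vB <- sweep(phiB, 2, (s2$n - 1) / (s2$T * s2$n * (s2$n - 3)), `*`)
  m <- abs(muB[, 1] - muB[, 2]) / sqrt(vB[, 1] + vB[, 2])
  expect_equal(attr(ci2, "q"), sort(m)[ceiling(0.95 * mc)])
  # max over pairs dominates each component pair (same draws, I = 4)
  s4 <- subset_groups(example8, c(1, 2, 5, 6))
  qmax <- attr(pb_simultaneous_ci(s4, 0.95, 20000, seed = 23), "q")
  for (pair in list(c(1, 2), c(1, 3), c(3, 4))) {
    qp <- attr(pb_simultaneous_ci(subset_groups(s4, pair), 0.95, 20000,
                                  seed = 23), "q")
    # different draw layout, so compare as quantile dominance, not draws
    expect_gt(qmax, 0.95 * qp)
  }
})

test_that("quantiles grow as alpha shrinks, on the same draw stream", {
  s <- subset_groups(example8, 1:4)
  q05 <- attr(gpq_simultaneous_ci(s, 0.95, 20000, seed = 2), "q")
  q50 <- attr(gpq_simultaneous_ci(s, 0.50, 20000, seed = 2), "q")
  expect_gt(q05, q50)
  q05b <- attr(pb_simultaneous_ci(s, 0.95, 20000, seed = 2), "q")
  q50b <- attr(pb_simultaneous_ci(s, 0.50, 20000, seed = 2), "q")
  expect_gt(q05b, q50b)
})

test_that("halfwidths shrink when every group doubles its subjects", {
  s <- subset_groups(example8, 1:4)
  # rescale ss so phi_hat^2 = ss/(n-1) is unchanged at the doubled n
  s2 <- study_summary(2 * s$n, s$mu_hat, s$ss * (2 * s$n - 1) / (s$n - 1), s$T)
  for (f in c(gpq_simultaneous_ci, pb_simultaneous_ci)) {
    h1 <- f(s, 0.95, 20000, seed = 6)$halfwidth
    h2 <- f(s2, 0.95, 20000, seed = 6)$halfwidth
    expect_true(all(h2 < h1))
  }
})

test_that("interval rejection agrees with sp_test when all pairs exclude zero", {
  # weak duality: datasets whose GPQ intervals all exclude 0 should be
  # rejected by sp_test at the same level nearly always
  set.seed(77)
  T <- 4; n <- rep(10, 3); mu <- c(0, 2.2, 4.4); phi2 <- rep(1, 3)
  hits <- 0L; rejs <- 0L
  for (r in 1:120) {
    Y <- lapply(1:3, function(i) sim_subject_means(1, n[i], mu[i], phi2[i], T))
    mh <- vapply(Y, rowMeans, 0)
    ss <- vapply(seq_along(Y), function(i) reduce_rows(Y[[i]], T)$ss, 0)
    s <- study_summary(n, mh, ss, T)
    ci <- gpq_simultaneous_ci(s, 0.95, 2000, seed = 1000 + r)
    if (all(ci$lower > 0 | ci$upper < 0)) {
      hits <- hits + 1L
      p <- sp_test(s, 2000, seed = 2000 + r)$p_value
      rejs <- rejs + (p <= 0.05)
    }
  }
  expect_gt(hits, 20)            # the effect sizes make exclusion common
  expect_gte(rejs / hits, 0.95)
})

test_that("interval procedures refuse small groups", {
  s <- study_summary(n = c(3, 10), mu_hat = c(0, 1), ss = c(2, 9), T = 4)
  expect_error(gpq_simultaneous_ci(s, 0.95, 2000, seed = 1), "n_i >= 4")
  expect_error(pb_simultaneous_ci(s, 0.95, 2000, seed = 1), "n_i >= 4")
  sok <- subset_groups(example8, 1:3)
  expect_error(gpq_simultaneous_ci(sok, 1.2, 2000, seed = 1), "level")
})
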