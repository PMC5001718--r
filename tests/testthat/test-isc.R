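test_that("voxelwise correlation matches the textbook formula", {
  # printed toy pair, brute-force covariance/sd oracle
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 4)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  a <- volume4d(array(x, c(1, 1, 1, 4)), 2)
  b <- volume4d(array(y, c(1, 1, 1, 4)), 2)
  expect_equal(as.numeric(voxelwise_correlation(a, b)$values), r_oracle,
               tolerance = 1e-15)
  # 1000 random series pairs against the two-pass formula
  set.seed(20)
  T_ <- 50; V <- 1000
  ma <- matrix(stats::rnorm(V * T_), V); mb <- matrix(stats::rnorm(V * T_), V)
  va <- volume4d(array(ma, c(10, 10, 10, T_)), 2)
  vb <- volume4d(array(mb, c(10, 10, 10, T_)), 2)
  r <- voxelwise_correlation(va, vb)$values
  oracle <- vapply(seq_len(V), function(i) {
    u <- ma[i, ] - mean(ma[i, ]); w <- mb[i, ] - mean(mb[i, ])
    sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  }, numeric(1))
  expect_lt(max(abs(as.numeric(r) - oracle)), 1e-12)
})

test_that("correlation fixed points, flags and input checks", {
  set.seed(3)
  m <- matrix(stats::rnorm(20 * 30), 20)
  v <- volume4d(array(m, c(4, 5, 1, 30)), 2)
  expect_lt(max(abs(voxelwise_correlation(v, v)$values - 1)), 1e-12)
  vm <- volume4d(array(-(m - rowMeans(m)), c(4, 5, 1, 30)), 2)
  expect_true(all(abs(voxelwise_correlation(v, vm)$values + 1) < 1e-12))
  # zero-variance voxel flagged NA
  m2 <- m; m2[7, ] <- 5
  v2 <- volume4d(array(m2, c(4, 5, 1, 30)), 2)
  rr <- voxelwise_correlation(v2, v)$values
  expect_true(is.na(rr[7]))
  expect_equal(sum(is.na(rr)), 1L)
  short <- volume4d(array(m[, 1:10], c(4, 5, 1, 10)), 2)
  expect_error(voxelwise_correlation(v, short), "length")
  vdis <- volume4d(array(m, c(4, 5, 1, 30)), 2,
                   mask = array(FALSE, c(4, 5, 1)))
  expect_error(voxelwise_correlation(v, vdis), "disjoint")
})

test_that("Fisher z is atanh with dof metadata and flagging at |r| = 1", {
  vals <- array(c(0, 0.5, -0.5, 1), c(4, 1, 1))
  rmap <- stat_map(vals, "r", array(TRUE, c(4, 1, 1)))
  z <- fisher_z(rmap, 160)
  expect_equal(z$values[1:3], c(0, 0.5493061443, -0.5493061443),
               tolerance = 1e-9)
  expect_true(is.na(z$values[4]))
  expect_identical(z$dof, 159L)
  # atanh then tanh is the identity on (-5, 5)
  zz <- seq(-4.9, 4.9, length.out = 101)
  expect_lt(max(abs(atanh(tanh(zz)) - zz)), 1e-12)
})

test_that("Benjamini-Hochberg matches the hand step-up", {
  res <- bh_fdr(c(0.001, 0.01, 0.02, 0.04), q_level = 0.03)
  # hand step-up: 0.02 <= 3 * 0.03 / 4 = 0.0225 rejects the first three;
  # 0.04 > 0.03 does not
  expect_identical(res$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$q, c(0.004, 0.02, 4 * 0.02 / 3, 0.04), tolerance = 1e-12)
  expect_true(all(bh_fdr(rep(0, 5), 0.03)$reject))
  expect_false(any(bh_fdr(rep(1, 5), 0.03)$reject))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the one-sample group test matches t.test and flags zero variance", {
  grid <- c(3, 3, 1); nv <- prod(grid)
  set.seed(8)
  zvals <- matrix(stats::rnorm(nv * 9, mean = 0.3, sd = 0.2), nv, 9)
  zmaps <- lapply(1:9, function(s)
    stat_map(array(zvals[, s], grid), "z", array(TRUE, grid), dof = 159))
  gt <- intra_subject_group_test(zmaps)
  # independent oracle: stats::t.test per voxel
  for (i in c(1, 5, 9)) {
    tt <- stats::t.test(zvals[i, ])
    expect_equal(gt$t_map$values[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(gt$p_map$values[i], tt$p.value, tolerance = 1e-12)
  }
  expect_identical(gt$dof, 8L)
  # near-constant strong effect: t ~ mean/(sd/sqrt(n)) and rejection
  z2 <- matrix(0.5 + stats::rnorm(nv * 9, sd = 0.01), nv, 9)
  zm2 <- lapply(1:9, function(s)
    stat_map(array(z2[, s], grid), "z", array(TRUE, grid), dof = 159))
  gt2 <- intra_subject_group_test(zm2)
  expect_gt(min(gt2$t_map$values), 50)
  expect_true(all(gt2$sig_mask))
  # all-zero maps: no rejections, zero-variance flagged
  zm0 <- lapply(1:3, function(s)
    stat_map(array(0, grid), "z", array(TRUE, grid), dof = 159))
  gt0 <- intra_subject_group_test(zm0)
  expect_false(any(gt0$sig_mask))
  expect_true(all(is.na(gt0$t_map$values)))
  expect_error(intra_subject_group_test(zm0[1:2]), "3 subjects")
})

test_that("the parametric pipeline controls FDR under the null", {
  grid <- c(10, 10, 10)
  set.seed(30)
  rates <- replicate(20, {
    zm <- lapply(1:9, function(s)
      stat_map(array(stats::rnorm(1000, sd = 0.1), grid), "z",
               array(TRUE, grid), dof = 99))
    mean(intra_subject_group_test(zm, q_level = 0.03)$sig_mask)
  })
  expect_lte(mean(rates), 0.03)
})

test_that("inter-subject correlation produces all pairs and a mean z map", {
  set.seed(9)
  grid <- c(4, 4, 2); T_ <- 60
  base <- array(stats::rnorm(prod(grid) * T_), c(grid, T_))
  same <- lapply(1:3, function(i) volume4d(base, 2))
  isc <- inter_subject_correlation(same)
  expect_length(isc$pair_maps, 3L)  # 3 * 2 / 2
  expect_true(all(vapply(isc$pair_maps, function(m)
    max(abs(m$values - 1)) < 1e-12, logical(1))))
  # independent subjects: mean z near zero
  T2 <- 100
  indep <- lapply(1:5, function(i)
    volume4d(array(stats::rnorm(prod(grid) * T2), c(grid, T2)), 2))
  isc2 <- inter_subject_correlation(indep)
  expect_length(isc2$pair_maps, 10L)  # 5 * 4 / 2
  n_eff <- length(isc2$pair_maps) * (T2 - 3)
  expect_lt(mean(abs(isc2$mean_z$values)), 3 / sqrt(n_eff) * 5)
  expect_error(inter_subject_correlation(indep[1]), "2 subjects")
})

test_that("circular-shift null is calibrated and powered", {
  # type-I error at alpha = 0.05 under independent noise
  set.seed(40)
  rates <- vapply(1:6, function(rep) {
    tr <- ground_truth(grid_shape = c(8, 8, 4), n_timepoints = 160,
                       effect_amplitudes = c(content = 0), seed = 200 + rep)
    vols <- generate_subject_sessions(tr, 5, 1)
    cs <- circular_shift_null(vols, n_null_samples = 1e4, seed = rep,
                              n_sample_voxels = 64)
    mean(cs$p_pair <= 0.05)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.015)
  # power: shared signal at amplitude 2 x noise
  tr <- ground_truth(grid_shape = c(8, 8, 4), n_timepoints = 160,
                     effect_amplitudes = c(content = 2), seed = 42)
  vols <- generate_subject_sessions(tr, 4, 1)
  cs <- circular_shift_null(vols, n_null_samples = 1e5, seed = 3,
                            n_sample_voxels = 64)
  expect_lt(max(cs$p_map$values[tr$active_voxel_mask]), 0.001)
  # p floor: smallest achievable p is 1/(1 + n_null)
  expect_gte(min(cs$p_pair), 1 / (1 + length(cs$null_pair)))
  expect_error(circular_shift_null(vols, 100, 1), "1000")
  expect_error(circular_shift_null(vols[1], 1e4, 1), "2 subjects")
})

test_that("nuisance regression orthogonalizes and is idempotent", {
  set.seed(12)
  T_ <- 80; grid <- c(4, 4, 1)
  x <- stats::rnorm(T_)
  # voxel 1: pure regressor; others: 2x + noise
  m <- matrix(2 * rep(x, each = 16) + stats::rnorm(16 * T_), 16)
  m[1, ] <- x
  vol <- volume4d(array(m, c(grid, T_)), 2)
  res <- nuisance_regression(vol, list(x))
  rm_ <- matrix(res$data, 16)
  expect_lt(max(abs(rm_[1, ])), 1e-10)
  for (i in 2:16)
    expect_lt(abs(stats::cor(rm_[i, ], x)), 1e-10)
  # residuals orthogonal to the regressor (normal-equations oracle)
  X <- cbind(1, x)
  oracle <- m[5, ] - X %*% solve(crossprod(X), crossprod(X, m[5, ]))
  expect_equal(rm_[5, ], as.numeric(oracle), tolerance = 1e-10)
  # idempotence: regressing out again changes nothing
  res2 <- nuisance_regression(res, list(x))
  expect_equal(res2$data, res$data, tolerance = 1e-10)
  # a regressor orthogonal to a voxel leaves the demeaned series
  y <- stats::rnorm(T_)
  y <- unname(stats::residuals(stats::lm(y ~ x)))  # orthogonal to x, intercept
  vol2 <- volume4d(array(rep(y, each = 16), c(grid, T_)), 2)
  res3 <- nuisance_regression(vol2, list(x))
  expect_equal(matrix(res3$data, 16)[3, ], y - mean(y), tolerance = 1e-10)
  # rank-deficient design identified
  expect_error(nuisance_regression(vol, list(x, 2 * x)), "collinear")
})

test_that("regressor correlation maps recover the driving voxels", {
  tr <- ground_truth(grid_shape = c(8, 8, 4), n_timepoints = 200,
                     effect_amplitudes = c(content = 2), seed = 77)
  vols <- generate_subject_sessions(tr, 5, 1)
  regs <- lapply(vols, function(v) tr$shared_signal)
  out <- regressor_correlation_map(vols, regs, p_thresh = 0.011,
                                   q_level = 0.03)
  expect_gte(mean(out$sig_mask[tr$active_voxel_mask]), 0.95)
  expect_lte(mean(out$sig_mask[!tr$active_voxel_mask]), 0.05)
  # white-noise regressor: rejections at or below the FDR level on average
  set.seed(50)
  rates <- replicate(10, {
    regs0 <- lapply(vols, function(v) stats::rnorm(200))
    mean(regressor_correlation_map(vols, regs0)$sig_mask)
  })
  expect_lte(mean(rates), 0.03)
  expect_error(regressor_correlation_map(vols, regs[1:2]), "one regressor")
  expect_error(regressor_correlation_map(vols,
                                         lapply(vols, function(v) rep(1, 200))),
               "zero-variance")
})

test_that("reproducibility differences detect paired and group contrasts", {
  grid <- c(4, 4, 2); msk <- array(TRUE, grid)
  set.seed(60)
  mkz <- function(mu) stat_map(array(stats::rnorm(32, mu, 0.05), grid),
                               "z", msk, dof = 99)
  z_hi <- lapply(1:6, function(i) mkz(0.6))
  z_lo <- lapply(1:6, function(i) mkz(0.3))
  d <- reproducibility_difference(z_hi, z_lo, "paired", p_thresh = 0.03)
  expect_true(all(d$sig_mask))
  expect_identical(d$dof, 5L)
  expect_equal(mean(d$diff_map$values), 0.3, tolerance = 0.05)
  # identical inputs: zero difference, no rejections
  d0 <- reproducibility_difference(z_hi, z_hi, "paired")
  expect_true(all(d0$diff_map$values == 0))
  expect_false(any(d0$sig_mask))
  # two-sample pooled dof = n1 + n2 - 2, cross-checked against t.test
  g2 <- lapply(1:9, function(i) mkz(0.5))
  g1 <- lapply(1:6, function(i) mkz(0.5))
  d2 <- reproducibility_difference(g2, g1, "two_sample")
  expect_identical(d2$dof, 13L)
  a <- vapply(g2, function(m) m$values[2, 2, 1], numeric(1))
  b <- vapply(g1, function(m) m$values[2, 2, 1], numeric(1))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(d2$t_map$values[2, 2, 1], unname(tt$statistic),
               tolerance = 1e-12)
  expect_error(reproducibility_difference(z_hi[1], z_lo[1], "paired"),
               "2 pairs")
})
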