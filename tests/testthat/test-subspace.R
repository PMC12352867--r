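test_that("principal angles: identity, orthogonality, symmetry, invariance", {
  set.seed(4)
  A <- random_frame(9, 3)
  # acos near cos = 1 amplifies double round-off to ~1e-6 degrees
  expect_equal(principal_angles(A, A), c(0, 0, 0), tolerance = 1e-5)
  # disjoint coordinate triples in 6-dim space are orthogonal
  E1 <- diag(6)[, 1:3]; E2 <- diag(6)[, 4:6]
  expect_equal(principal_angles(E1, E2), c(90, 90, 90), tolerance = 1e-10)
  B <- random_frame(9, 3)
  expect_equal(principal_angles(A, B), principal_angles(B, A), tolerance = 1e-9)
  # invariance to right-multiplication by a 3x3 rotation
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(principal_angles(A %*% R, B), principal_angles(A, B),
               tolerance = 1e-8)
  expect_error(principal_angles(A * 2, B), "not orthonormal")
})

test_that("principal angles match an independent eigenvalue oracle", {
  # oracle: cos^2(theta_k) are the eigenvalues of (A'B)(B'A)
  set.seed(5)
  for (rep in 1:20) {
    A <- random_frame(5, 3); B <- random_frame(5, 3)
    M <- crossprod(A, B)
    ev <- sort(eigen(M %*% t(M), symmetric = TRUE)$values, decreasing = TRUE)
    oracle <- acos(pmin(sqrt(pmax(ev, 0)), 1)) * 180 / pi
    got <- principal_angles(A, B)
    # cosines agree to 1e-8; the angles themselves to acos round-off
    expect_equal(cos(got * pi / 180), cos(oracle * pi / 180), tolerance = 1e-8)
    expect_equal(got, oracle, tolerance = 1e-4)
  }
})

test_that("three components capture all variance of the four condition means", {
  ser <- tiny_series()
  err <- abs(colSums(ser$explained_variance) - ser$total_variance)
  expect_lt(max(err), 1e-8 * max(ser$total_variance))
  for (t in c(1, 500, 1500)) {
    W <- ser$bases[, , t]
    expect_equal(crossprod(W), diag(3), tolerance = 1e-10)
  }
})

test_that("rank-deficient condition means get a deterministic completed frame", {
  P <- matrix(1, 4, 6)  # four identical points: rank 0
  ib <- instaspace:::instantaneous_basis_from_points(P)
  expect_equal(ib$explained_variance, c(0, 0, 0))
  expect_equal(ib$W, diag(6)[, 1:3])  # canonical completion
  expect_error(instaspace:::instantaneous_basis_from_points(matrix(1, 4, 2)),
               "too small")
})

test_that("noise-free planted rotation is recovered exactly", {
  gt <- tiny_exec()$truth
  tens <- tensor_from_courses(gt$mean_courses, gt$time_map)
  ser <- instantaneous_subspaces(tens)
  # restrict to steps with planted condition dependence (after the
  # instruction-response latency the envelope is positive)
  cols <- which(gt$cd_envelope > 0.05)
  for (cc in cols[round(seq(1, length(cols), length.out = 9))]) {
    err <- principal_angles(ser$bases[, , cc], planted_basis(gt, cc))[1]
    expect_lt(err, 1e-6)
  }
})

test_that("chance angles: degenerate case, monotonicity, oracle agreement", {
  expect_error(chance_angles(2), "n_dim")
  ch3 <- chance_angles(3, n_draws = 50)
  expect_equal(ch3$mean, 0, tolerance = 1e-6)  # only one 3-subspace exists
  m <- vapply(c(5, 10, 50), function(n) chance_angles(n, n_draws = 300)$mean,
              numeric(1))
  expect_true(all(diff(m) > 0))  # angles approach 90 deg as N grows
  # two 3-spaces in 4-dim space always share a >= 2-dim intersection, so the
  # first principal angle is identically zero
  expect_lt(chance_angles(4, n_draws = 200)$mean, 1e-4)
  # independent oracle sampler: polar decomposition of a Gaussian matrix
  set.seed(6)
  W0 <- random_frame(8, 3)
  oracle <- replicate(2000, {
    G <- matrix(rnorm(24), 8, 3)
    s <- svd(G)
    principal_angles(W0, s$u %*% t(s$v))[1]
  })
  ch <- chance_angles(8, n_draws = 2000)
  se <- sqrt(stats::var(oracle) / 2000 + ch$sd^2 / 2000)
  expect_lt(abs(ch$mean - mean(oracle)), 4 * se)
})

test_that("angle course: bounds, reference trough, and static planted subspace", {
  tens <- tiny_tensor()
  ac <- angle_course(tens, "M", n_folds = 4, trials_per_object = 10,
                     n_chance = 200, seed = 2)
  expect_true(all(ac$mean >= 0 & ac$mean <= 90))
  expect_true(all(ac$sd >= 0))
  ref_col <- tensor_col(tens, "M", 0)
  far_col <- tensor_col(tens, "I", -400)
  expect_lt(ac$mean[1, ref_col], ac$mean[1, far_col])
  # static planted subspace: first angle stays low everywhere CD exists
  gt0 <- generate_session(tiny_cfg(subspace_rotation_rate = 0,
                                   trials_per_object = 2), "execution")$truth
  tens0 <- tensor_from_courses(gt0$mean_courses, gt0$time_map)
  ac0 <- angle_course(tens0, "M", n_folds = 2, trials_per_object = 1,
                      n_chance = 0, seed = 1)
  cols <- which(gt0$cd_envelope > 0.05)
  expect_lt(max(ac0$mean[1, cols]), 1e-4)  # acos round-off scale in degrees
})

test_that("degenerate cross-context call reproduces the within-context course", {
  tens <- tiny_tensor()
  a1 <- angle_course(tens, "H", n_folds = 2, trials_per_object = 8,
                     n_chance = 0, seed = 3)
  a2 <- cross_context_angles(tens, tens, "H", n_folds = 2,
                             trials_per_object = 8, n_chance = 0, seed = 3)
  expect_identical(a1$mean, a2$mean)
})

test_that("mismatched time bases are rejected", {
  tens <- tiny_tensor()
  short <- tens
  short$time_map <- tens$time_map[1:100, ]
  short$data <- lapply(tens$data, function(a) a[, , 1:100, drop = FALSE])
  expect_error(angle_course(tens, "M", ref_tensor = short), "time base")
})
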