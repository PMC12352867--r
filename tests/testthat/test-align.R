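test_that("CCA self-alignment and invariance to invertible transforms", {
  set.seed(13)
  L <- matrix(rnorm(1200), 3, 400)
  r <- cca_align(L, L)
  expect_equal(r$cc, c(1, 1, 1), tolerance = 1e-10)
  G <- matrix(rnorm(9), 3, 3)
  expect_equal(cca_align(L, G %*% L)$cc, c(1, 1, 1), tolerance = 1e-10)
  # general invariance: transforming either input leaves all CCs unchanged
  L2 <- matrix(rnorm(1200), 3, 400)
  base <- cca_align(L, L2)$cc
  H <- matrix(rnorm(9), 3, 3)
  expect_equal(cca_align(G %*% L, H %*% L2)$cc, base, tolerance = 1e-10)
  expect_true(all(diff(base) <= 1e-12))  # sorted descending
})

test_that("CCA matches the covariance-eigenvalue oracle and stats::cancor", {
  set.seed(14)
  for (rep in 1:5) {
    LA <- matrix(rnorm(1200), 3, 400)
    LB <- 0.6 * LA + matrix(rnorm(1200, sd = 0.7), 3, 400)
    r <- cca_align(LA, LB)
    Sa <- stats::cov(t(LA)); Sb <- stats::cov(t(LB))
    Sab <- stats::cov(t(LA), t(LB))
    ev <- eigen(solve(Sa) %*% Sab %*% solve(Sb) %*% t(Sab))$values
    oracle <- sort(sqrt(pmax(Re(ev), 0)), decreasing = TRUE)
    expect_equal(r$cc, oracle, tolerance = 1e-10)
    expect_equal(r$cc, stats::cancor(t(LA), t(LB))$cor, tolerance = 1e-10)
    # aligned latents are diagonal-correlated: off-diagonal inner products ~ 0
    S <- r$aligned_A %*% t(r$aligned_B)
    expect_lt(max(abs(S[upper.tri(S) | lower.tri(S)])), 1e-10)
  }
})

test_that("rank-deficient latents are rejected with advice", {
  L <- matrix(rnorm(1200), 3, 400)
  L[3, ] <- L[1, ] + L[2, ]  # collinear
  expect_error(cca_align(L, matrix(rnorm(1200), 3, 400)), "rank-deficient")
})

test_that("sessions with too few trials are excluded from CCA", {
  tens <- tiny_tensor()
  few <- tens
  few$data$button <- few$data$button[, 1:8, , drop = FALSE]
  expect_error(bootstrap_cca(few, tens, "H", trials_per_object = 20,
                             n_iter = 2), "button.*fewer than 20")
})

test_that("identical resamples give perfect within-group alignment", {
  gt <- tiny_exec()$truth
  tens <- tensor_from_courses(gt$mean_courses, gt$time_map)
  out <- within_group_cca(tens, "H", trials_per_object = 1, n_iter = 3)
  expect_equal(unname(out$mean), c(1, 1, 1), tolerance = 1e-8)
})

test_that("bootstrap CCA: execution/observation alignment tracks planted relations", {
  out <- bootstrap_cca(tiny_tensor(), tiny_tensor_obs(), "H",
                       trials_per_object = 10, n_iter = 30,
                       comparison = "MN:E/O", seed = 5)
  expect_true(all(out$cc >= -1 & out$cc <= 1))
  expect_true(all(apply(out$cc, 1, function(x) all(diff(x) <= 1e-12))))
  null <- bootstrap_cca(tiny_tensor(), tiny_tensor_obs(), "H",
                        trials_per_object = 10, n_iter = 30,
                        comparison = "null", seed = 5, permute_objects = TRUE)
  # shared latent relations: true alignment beats the permutation null
  expect_gt(out$mean[1], stats::quantile(null$cc[, 1], 0.9))
})

test_that("within-group consistency decreases from execution to observation", {
  ee <- within_group_cca(tiny_tensor(), "H", trials_per_object = 10,
                         n_iter = 25, comparison = "MN:E/E", seed = 6)
  oo <- within_group_cca(tiny_tensor_obs(), "H", trials_per_object = 10,
                         n_iter = 25, comparison = "MN:O/O", seed = 6)
  # lower observation modulation amplitude -> less consistent co-modulation
  expect_gt(ee$mean[1], oo$mean[1])
})

test_that("outcome comparison: Kruskal-Wallis with hand-computed oracle", {
  mk <- function(vals) {
    structure(list(comparison = "x", segment_event = "H",
                   cc = cbind(vals, vals, vals),
                   mean = rep(mean(vals), 3), sd = rep(stats::sd(vals), 3),
                   n_iter = length(vals)), class = "cca_outcome")
  }
  # three planted groups, n = 5 each, no ties
  g1 <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  g2 <- g1 + 0.02
  g3 <- g1 + 0.6
  cmp <- compare_outcomes(list(a = mk(g1), b = mk(g2), c = mk(g3)))
  vals <- c(g1, g2, g3)
  r <- rank(vals)
  Rbar <- tapply(r, rep(1:3, each = 5), sum)
  H <- 12 / (15 * 16) * sum(Rbar^2 / 5) - 3 * 16  # classic KW statistic
  expect_equal(cmp$kruskal$statistic[1], H, tolerance = 1e-10)
  expect_lt(cmp$kruskal$p_value[1], 0.05)
  # two identical distributions: no detected difference
  cmp2 <- compare_outcomes(list(a = mk(g1), b = mk(g1)))
  expect_gt(cmp2$kruskal$p_value[1], 0.05)
  # groups offset by a large constant: decisive difference
  big <- compare_outcomes(list(a = mk(rnorm(30, 0, .01)),
                               b = mk(rnorm(30, 5, .01))))
  expect_lt(big$kruskal$p_value[1], 0.001)
  expect_error(compare_outcomes(list(a = mk(g1))), "at least two")
})
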