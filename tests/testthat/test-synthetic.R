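test_that("generation is deterministic given (seed, context)", {
  cfg <- tiny_cfg(trials_per_object = 3)
  a <- generate_session(cfg, "execution")
  b <- generate_session(cfg, "execution")
  expect_identical(a$bundle$trials, b$bundle$trials)
  expect_identical(a$bundle$spikes, b$bundle$spikes)
  o <- generate_session(cfg, "observation")
  expect_false(identical(a$bundle$trials, o$bundle$trials))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_units = 10, n_mn = 12, n_ae = 0, n_ao = 0, n_ns = 0),
               "config error")
  expect_error(synth_config(n_mn = 8, n_ae = 34), "n_mn")
  expect_error(synth_config(context_overlap = 1.5), "context_overlap")
  expect_error(synth_config(cd_amplitude_exec = -1), "non-negative")
})

test_that("planted bases are orthonormal at every sampled step", {
  gt <- tiny_exec()$truth
  for (col in round(seq(1, nrow(gt$time_map), length.out = 7))) {
    B <- planted_basis(gt, col, "all")
    expect_equal(crossprod(B), diag(3), tolerance = 1e-10)
    expect_equal(crossprod(planted_basis(gt, col, "MN")), diag(3),
                 tolerance = 1e-10)
  }
})

test_that("context_overlap controls the planted execution/observation geometry", {
  cfg1 <- tiny_cfg(context_overlap = 1, trials_per_object = 2)
  e1 <- generate_session(cfg1, "execution")$truth
  o1 <- generate_session(cfg1, "observation")$truth
  cfg0 <- tiny_cfg(context_overlap = 0, trials_per_object = 2)
  e0 <- generate_session(cfg0, "execution")$truth
  o0 <- generate_session(cfg0, "observation")$truth
  # compare at matched (event, offset) pairs: the contexts' aligned axes
  # have slightly different lengths (their own realized medians)
  marks <- list(c("I", 100), c("G", -200), c("M", 50), c("H", 150))
  for (mk in marks) {
    col_e <- tensor_col(e1$time_map, mk[[1]], as.numeric(mk[[2]]))
    col_o <- tensor_col(o1$time_map, mk[[1]], as.numeric(mk[[2]]))
    # overlap 1: identical planted MN bases at every matched step
    expect_equal(planted_basis(e1, col_e, "MN"), planted_basis(o1, col_o, "MN"),
                 tolerance = 1e-10)
    # overlap 0: orthogonal MN subspaces
    col_e0 <- tensor_col(e0$time_map, mk[[1]], as.numeric(mk[[2]]))
    col_o0 <- tensor_col(o0$time_map, mk[[1]], as.numeric(mk[[2]]))
    ang <- principal_angles(planted_basis(e0, col_e0, "MN"),
                            planted_basis(o0, col_o0, "MN"))
    expect_equal(ang, rep(90, 3), tolerance = 1e-6)
  }
})

test_that("planted_first_angle oracle behaves as constructed", {
  gt <- tiny_exec()$truth
  expect_equal(planted_first_angle(gt, 1500, 1500), 0, tolerance = 1e-8)
  # zero rotation rate: 0 degrees everywhere
  gt0 <- generate_session(tiny_cfg(subspace_rotation_rate = 0,
                                   trials_per_object = 2), "execution")$truth
  expect_equal(planted_first_angle(gt0, 600, nrow(gt0$time_map) - 10), 0,
               tolerance = 1e-8)
  # explicit planar rotation by 30 degrees
  A <- random_frame(12, 6)
  B0 <- A[, 1:3]
  B30 <- A[, 1:3] * cos(pi / 6) + A[, 4:6] * sin(pi / 6)
  expect_equal(principal_angles(B0, B30), rep(30, 3), tolerance = 1e-8)
  expect_error(planted_first_angle(gt, 1, 10 * nrow(gt$time_map)),
               "out of range")
})

test_that("zero condition-dependent amplitude leaves object means equal", {
  gs <- generate_session(tiny_cfg(cd_amplitude_exec = 0, trials_per_object = 15,
                                  seed = 5), "execution")
  st <- compute_epoch_stats(gs$bundle)
  tens <- align_concatenate(bin_and_smooth(gs$bundle), st)
  cs <- condition_split(tens)
  # CD residual RMS is small relative to the CI course RMS
  cd_rms <- max(vapply(cs$cd_courses, function(m) sqrt(mean(m^2)), 1))
  ci_rms <- sqrt(mean(cs$ci_course^2))
  expect_lt(cd_rms / ci_rms, 0.25)  # residual is trial-averaged Poisson noise
  # and below a session with real planted condition dependence
  cs_cd <- condition_split(tiny_tensor())
  cd_rms_cd <- max(vapply(cs_cd$cd_courses, function(m) sqrt(mean(m^2)), 1))
  ci_rms_cd <- sqrt(mean(cs_cd$ci_course^2))
  expect_lt(cd_rms / ci_rms, cd_rms_cd / ci_rms_cd)
})

test_that("spiking is Poisson-dispersed (Fano factor near 1)", {
  gs <- generate_session(tiny_cfg(trials_per_object = 25, seed = 8), "execution")
  b <- gs$bundle
  tr <- b$trials
  # pre-instruction window: planted intensity is the constant base rate
  counts <- vapply(b$units$unit_id, function(u) {
    st <- b$spikes[[u]]
    vapply(seq_len(nrow(tr)), function(k)
      sum(st >= tr$instruction_on[k] - 450 & st < tr$instruction_on[k] - 50),
      1)
  }, numeric(nrow(tr)))
  fano <- apply(counts, 2, function(x) stats::var(x) / max(mean(x), 1e-9))
  expect_gt(mean(fano), 0.8)
  expect_lt(mean(fano), 1.2)
})

test_that("observation trajectories separate less than execution ones", {
  gr_e <- separation_grid(tiny_tensor())
  gr_o <- separation_grid(tiny_tensor_obs())
  # own-subspace separation at movement and hold: observation < execution
  expect_lt(gr_o["M", "M"], gr_e["M", "M"])
  expect_lt(gr_o["H", "H"], gr_e["H", "H"])
})
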