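test_that("a single spike smooths to a unit-mass Gaussian bump", {
  b <- manual_bundle(delays = 800, spikes_fun = function(i, tr) tr$go[1] + 100.3)
  rs <- bin_and_smooth(b, sigma = 50)
  r <- rs$trials[[1]]$rates[1, ]
  expect_equal(sum(r) / 1000, 1, tolerance = 1e-6)  # integrates to one spike
  peak_bin <- which.max(r)
  expect_equal(peak_bin, floor(b$trials$go[1] + 100.3) - rs$trials[[1]]$t0 + 1)
  # profile matches the normalized Gaussian kernel
  expect_equal(r[peak_bin] / 1000,
               dnorm(0, 0, 50) / sum(dnorm(-200:200, 0, 50)),
               tolerance = 1e-6)
})

test_that("a constant-rate Poisson unit smooths to a flat course at its rate", {
  rate <- 40
  set.seed(1)
  b <- manual_bundle(delays = 800, spikes_fun = function(i, tr) {
    n <- rpois(1, rate * (tr$end[1] - tr$start[1]) / 1000)
    sort(runif(n, tr$start[1], tr$end[1]))
  })
  r <- bin_and_smooth(b, sigma = 50)$trials[[1]]$rates[1, ]
  mid <- r[500:(length(r) - 500)]  # away from edges
  expect_equal(mean(mid), rate, tolerance = 0.15 * rate)
  expect_lt(stats::sd(mid), 0.35 * rate)
})

test_that("smoothing is linear: two spikes 1 ms apart carry the same mass as a doublet", {
  b1 <- manual_bundle(delays = 800, spikes_fun = function(i, tr) tr$go[1] + c(0.2, 1.2))
  b2 <- manual_bundle(delays = 800, spikes_fun = function(i, tr) tr$go[1] + c(0.2, 0.7))
  m1 <- sum(bin_and_smooth(b1)$trials[[1]]$rates)
  m2 <- sum(bin_and_smooth(b2)$trials[[1]]$rates)
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("sigma must be positive", {
  expect_error(bin_and_smooth(tiny_exec()$bundle, sigma = 0), "positive")
})

test_that("square-root transform is exact and guards against negatives", {
  expect_equal(sqrt_transform(0), 0)
  expect_equal(sqrt_transform(25), 5)
  expect_error(sqrt_transform(-1), "negative")
  rs <- bin_and_smooth(manual_bundle(delays = 600))
  rs2 <- sqrt_transform(rs)
  expect_true(rs2$sqrt)
  expect_error(sqrt_transform(rs2), "already")
})

test_that("square root stabilizes Poisson variance across rates", {
  set.seed(2)
  lo <- sqrt(rpois(4000, 5))
  hi <- sqrt(rpois(4000, 50))
  ratio <- stats::var(hi) / stats::var(lo)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("aligned axis window arithmetic and time map are exact", {
  # identical trial timing: delay 1000, reaction 300 -> r2 = 150
  b <- manual_bundle(delays = rep(1000, 8), reaction = 300)
  st <- compute_epoch_stats(b)
  tm <- build_time_map(st)
  # I (1000) + G (1000 + 150) + M (150 + 200) + H (400)
  expect_equal(nrow(tm), 2900)
  expect_equal(tm$event[1], "I")
  expect_equal(tm$offset[1], -500)
  expect_equal(tm$offset[tm$event == "G"][1], -1000)
  expect_equal(max(tm$offset[tm$event == "G"]), 149)
  expect_equal(range(tm$offset[tm$event == "H"]), c(-200, 199))
  tens <- align_concatenate(bin_and_smooth(b), st)
  expect_equal(dim(tens$data$sphere), c(1, 2, 2900))
  # silent unit: all-zero tensor of the correct shape
  expect_true(all(tens$data$sphere == 0))
})

test_that("trials too short for a snippet are excluded with a warning", {
  b <- manual_bundle(delays = c(1500, 1500, 1500, 1500, 200),
                     objects = c(OBJECTS, "sphere"))
  st <- compute_epoch_stats(b)
  expect_warning(tens <- align_concatenate(bin_and_smooth(b), st), "t05")
  expect_equal(dim(tens$data$sphere)[2], 1)
})

test_that("preprocessing is deterministic", {
  b <- tiny_exec()$bundle
  t1 <- align_concatenate(sqrt_transform(bin_and_smooth(b)), tiny_stats())
  expect_identical(t1$data, tiny_tensor()$data)
})

test_that("condition split: CI is the object mean and CD residuals cancel", {
  tens <- tiny_tensor()
  cs <- condition_split(tens)
  resid <- Reduce(`+`, cs$cd_courses)
  expect_lt(max(abs(resid)), 1e-10)
  om <- object_means(tens)
  expect_equal(cs$ci_course, Reduce(`+`, om) / 4, tolerance = 1e-12)
  # identical activity across objects: all CD courses exactly zero
  tm <- tens$time_map
  flat <- matrix(1.5, 6, nrow(tm))
  teq <- tensor_from_courses(list(sphere = flat, button = flat,
                                  coax = flat, perp = flat), tm)
  cs2 <- condition_split(teq)
  expect_true(all(cs2$cd_courses$button == 0))
})

test_that("planted condition-dependent amplitude scales recovered CD norm", {
  norms <- vapply(c(2, 8), function(a) {
    gs <- generate_session(tiny_cfg(cd_amplitude_exec = a, trials_per_object = 12,
                                    seed = 13), "execution")
    st <- compute_epoch_stats(gs$bundle)
    tens <- align_concatenate(bin_and_smooth(gs$bundle), st)
    cs <- condition_split(tens)
    cols <- tensor_col(tens, "M", 0):tensor_col(tens, "M", 150)
    sqrt(mean(vapply(cs$cd_courses, function(m) mean(m[, cols]^2), 1)))
  }, numeric(1))
  # CD magnitude increases strongly with planted amplitude
  expect_gt(norms[2] / norms[1], 2)
})
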