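test_that("write/read round-trip is lossless for every field", {
  gs <- generate_session(
    synth_config(n_units = 13, n_mn = 12, n_ae = 0, n_ao = 0, n_ns = 1,
                 trials_per_object = 2, delay_range = c(500, 900), seed = 7),
    "execution")
  b <- gs$bundle
  d <- withr::local_tempdir()
  write_session(b, d)
  b2 <- read_session(d)
  expect_identical(b2$session_id, b$session_id)
  expect_identical(b2$context, b$context)
  expect_identical(b2$units, b$units)
  expect_equal(b2$trials, b$trials)
  expect_identical(b2$spikes, b$spikes)  # byte-stable numeric round trip
  # write -> read -> write yields identical files
  d2 <- withr::local_tempdir()
  write_session(b2, d2)
  for (f in c("meta.json", "trials.csv", "spikes.csv"))
    expect_identical(readLines(file.path(d, f)), readLines(file.path(d2, f)))
})

test_that("an empty-trials bundle writes and reads an empty trials table", {
  tr <- data.frame(trial_id = character(), object = character(),
                   success = logical())
  for (e in instaspace:::EVENTS) tr[[e]] <- numeric()
  b <- session_bundle("empty", "execution",
                      data.frame(unit_id = "u01", area = "PMv"),
                      list(u01 = numeric(0)), tr)
  d <- withr::local_tempdir()
  write_session(b, d)
  b2 <- read_session(d)
  expect_equal(nrow(b2$trials), 0)
  expect_equal(length(b2$spikes$u01), 0)
})

test_that("spike table row count equals total spike count", {
  b <- tiny_exec()$bundle
  d <- withr::local_tempdir()
  write_session(b, d)
  sp <- read.csv(file.path(d, "spikes.csv"))
  expect_equal(nrow(sp), sum(vapply(b$spikes, length, 1L)))
})

test_that("validation rejects malformed bundles, naming the trial", {
  b <- manual_bundle(delays = c(600, 700))
  tr <- b$trials
  tr$go[2] <- tr$instruction_off[2] - 10  # go precedes instruction_off
  expect_error(session_bundle("bad", "execution", b$units, b$spikes, tr),
               "t02.*not strictly increasing|not strictly increasing.*t02")
  tr2 <- b$trials
  tr2$object[1] <- "banana"
  expect_error(session_bundle("bad", "execution", b$units, b$spikes, tr2),
               "unknown object")
  expect_error(session_bundle("bad", "execution", b$units,
                              list(u01 = c(-5, 10)), b$trials),
               "negative spike times")
  expect_warning(
    b3 <- session_bundle("warn", "execution", b$units,
                         list(u01 = c(50, 10, 30)), b$trials),
    "unsorted")
  expect_identical(b3$spikes$u01, c(10, 30, 50))
})

test_that("missing bundle path raises an I/O error", {
  expect_error(read_session(file.path(tempdir(), "no-such-bundle")),
               "missing meta.json")
})

test_that("epoch statistics: medians pooled and per object", {
  b <- manual_bundle(delays = c(500, 1000, 2000, 800),
                     objects = c("sphere", "button", "coax", "perp"))
  st <- compute_epoch_stats(b)
  expect_equal(st$median_delay, 900)  # median of {500, 1000, 2000, 800}
  expect_equal(st$median_reaction, 300)
  expect_equal(st$median_movement, 400)
  # identical timing across trials: per-object equals pooled
  b2 <- manual_bundle(delays = rep(1000, 8))
  st2 <- compute_epoch_stats(b2)
  expect_true(all(st2$per_object$median_delay == st2$median_delay))
  expect_true(all(st2$per_object$median_reaction == st2$median_reaction))
})

test_that("epoch statistics ignore unsuccessful trials and trial order", {
  b <- manual_bundle(delays = c(500, 1000, 2000, 600, 9999, 9999, 9999, 9999),
                     objects = rep(c("sphere", "button", "coax", "perp"), 2),
                     success = c(rep(TRUE, 4), rep(FALSE, 4)))
  st <- compute_epoch_stats(b)
  expect_equal(st$median_delay, 800)  # unsuccessful 9999s excluded
  perm <- c(3, 1, 4, 2, 5, 8, 6, 7)
  b2 <- b
  b2$trials <- b$trials[perm, ]
  expect_equal(compute_epoch_stats(b2)$median_delay, st$median_delay)
  expect_equal(compute_epoch_stats(b2)$per_object, st$per_object)
})

test_that("an object with zero successful trials is reported by name", {
  b <- manual_bundle(delays = rep(700, 4),
                     objects = c("sphere", "button", "coax", "perp"),
                     success = c(TRUE, TRUE, TRUE, FALSE))
  expect_error(compute_epoch_stats(b), "perp")
})

test_that("median delay of a large uniform sample is near the range center", {
  gs <- generate_session(tiny_cfg(trials_per_object = 50, seed = 9), "execution")
  st <- compute_epoch_stats(gs$bundle)
  # delays uniform on [500, 1000]: median 750, MC tolerance for n = 200
  expect_lt(abs(st$median_delay - 750), 60)
})
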