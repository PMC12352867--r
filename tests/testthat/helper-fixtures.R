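# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# Small synthetic session: quick enough for per-module tests.
tiny_cfg <- function(...) {
  defaults <- list(n_units = 20, n_mn = 12, n_ae = 6, n_ao = 1, n_ns = 1,
                   trials_per_object = 10, delay_range = c(500, 1000),
                   seed = 42)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

tiny_exec <- function() memo("tiny_exec", generate_session(tiny_cfg(), "execution"))
tiny_obs <- function() memo("tiny_obs", generate_session(tiny_cfg(), "observation"))

tiny_stats <- function() memo("tiny_stats", compute_epoch_stats(tiny_exec()$bundle))

tiny_tensor <- function() memo("tiny_tensor", {
  align_concatenate(sqrt_transform(bin_and_smooth(tiny_exec()$bundle)),
                    tiny_stats())
})

tiny_tensor_obs <- function() memo("tiny_tensor_obs", {
  align_concatenate(sqrt_transform(bin_and_smooth(tiny_obs()$bundle)),
                    tiny_stats())
})

tiny_series <- function() memo("tiny_series", instantaneous_subspaces(tiny_tensor()))

# Hand-built bundle with fully controlled event times. `delays` gives the
# instruction_off -> go duration per trial; objects cycle through the four.
manual_bundle <- function(delays, reaction = 300, movement = 400,
                          objects = NULL, success = NULL,
                          spikes_fun = NULL, n_units = 1,
                          context = "execution") {
  n <- length(delays)
  objects <- objects %||% rep(OBJECTS, length.out = n)
  success <- success %||% rep(TRUE, n)
  start <- cumsum(c(0, rep(8000, n - 1)))
  instruction_on <- start + 700
  instruction_off <- instruction_on + 500
  go <- instruction_off + delays
  move_on <- go + reaction
  hold_on <- move_on + movement
  hold_off <- hold_on + 1000
  end <- hold_off + 300
  trials <- data.frame(trial_id = sprintf("t%02d", seq_len(n)),
                       object = objects, success = success,
                       start = start, instruction_on = instruction_on,
                       instruction_off = instruction_off, go = go,
                       move_on = move_on, hold_on = hold_on,
                       hold_off = hold_off, end = end)
  units <- data.frame(unit_id = sprintf("u%02d", seq_len(n_units)),
                      area = rep(c("PMv", "PMd"), length.out = n_units))
  spikes <- stats::setNames(lapply(seq_len(n_units), function(i) {
    if (is.null(spikes_fun)) numeric(0) else spikes_fun(i, trials)
  }), units$unit_id)
  session_bundle("manual", context, units, spikes, trials)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
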