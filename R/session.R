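#' Construct a session bundle
#'
#' A session bundle holds everything recorded in one session and one
#' behavioral context (execution or observation): per-unit spike times,
#' per-trial behavioral event markers, object labels, and unit metadata.
#' It is the unit of data every downstream stage consumes.
#'
#' Times are in milliseconds on a common session clock. Each trial carries
#' the eight behavioral events `start < instruction_on < instruction_off <
#' go < move_on < hold_on < hold_off < end`.
#'
#' @param session_id Character scalar identifying the session.
#' @param context `"execution"` or `"observation"`.
#' @param units `data.frame` with columns `unit_id` (character) and `area`
#'   (`"PMv"` or `"PMd"`).
#' @param spikes Named list (names = `unit_id`) of numeric spike-time
#'   vectors in ms. Unsorted vectors are sorted with a warning.
#' @param trials `data.frame` with columns `trial_id`, `object` (one of
#'   sphere/button/coax/perp), `success` (logical), and one numeric column
#'   per behavioral event (ms).
#' @param monkey Optional subject label.
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(session_id, context, units, spikes, trials,
                           monkey = NA_character_) {
  b <- structure(list(session_id = as.character(session_id),
                      context = match.arg(context, CONTEXTS),
                      monkey = as.character(monkey),
                      units = as.data.frame(units),
                      spikes = spikes,
                      trials = as.data.frame(trials)),
                 class = "session_bundle")
  validate_bundle(b)
}

#' Validate a session bundle
#'
#' Checks the structural invariants: all eight events present and strictly
#' increasing within every trial, object labels drawn from the four task
#' objects, spike times non-negative, sorted (sorted in place with a warning
#' if not) and within the session span.
#'
#' @param bundle A [session_bundle()].
#' @return The (possibly spike-sorted) bundle, invisibly classed.
#' @export
validate_bundle <- function(bundle) {
  tr <- bundle$trials
  missing_ev <- setdiff(EVENTS, names(tr))
  if (length(missing_ev))
    stop("trials table lacks event column(s): ", paste(missing_ev, collapse = ", "))
  bad_obj <- setdiff(unique(as.character(tr$object)), OBJECTS)
  if (length(bad_obj))
    stop("unknown object label(s): ", paste(bad_obj, collapse = ", "))
  for (i in seq_len(nrow(tr))) {
    ev <- as.numeric(tr[i, EVENTS])
    if (any(diff(ev) <= 0))
      stop(sprintf("trial '%s': event times not strictly increasing (%s)",
                   tr$trial_id[i],
                   paste(EVENTS[which(diff(ev) <= 0) + 1L], collapse = ", ")))
  }
  if (!setequal(names(bundle$spikes), bundle$units$unit_id))
    stop("spike list names do not match unit_id metadata")
  span_end <- if (nrow(tr)) max(tr$end) else Inf
  for (u in names(bundle$spikes)) {
    st <- bundle$spikes[[u]]
    if (length(st) == 0) next
    if (any(st < 0)) stop(sprintf("unit '%s': negative spike times", u))
    if (is.unsorted(st)) {
      warning(sprintf("unit '%s': spike times unsorted; sorting", u))
      bundle$spikes[[u]] <- sort(st)
    }
    if (max(st) > span_end)
      stop(sprintf("unit '%s': spike time beyond session end", u))
  }
  bundle
}

#' Successful trials of a bundle
#' @param bundle A [session_bundle()].
#' @return The trials `data.frame` restricted to `success == TRUE`.
#' @export
successful_trials <- function(bundle) {
  bundle$trials[as.logical(bundle$trials$success), , drop = FALSE]
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %s [%s]  %d units, %d trials (%d successful)\n",
              x$session_id, x$context, nrow(x$units), nrow(x$trials),
              sum(x$trials$success)))
  invisible(x)
}

#' Write a session bundle to disk
#'
#' One directory per bundle: `meta.json` (ids, context, unit metadata),
#' `trials.csv` (one row per trial, one column per event time in ms) and
#' `spikes.csv` (`unit_id`, `spike_time_ms`). Numeric spike times are
#' written with 17 significant digits so that `read_session()` round-trips
#' every field exactly.
#'
#' @param bundle A validated [session_bundle()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(bundle, path) {
  validate_bundle(bundle)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)
  meta <- list(session_id = bundle$session_id, context = bundle$context,
               monkey = bundle$monkey,
               units = bundle$units[, c("unit_id", "area")])
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tr <- bundle$trials[, c("trial_id", "object", "success", EVENTS)]
  data.table::fwrite(tr, file.path(path, "trials.csv"))
  n_sp <- vapply(bundle$spikes, length, 1L)
  sp <- data.table::data.table(
    unit_id = rep(names(bundle$spikes), n_sp),
    spike_time_ms = sprintf("%.17g", unlist(bundle$spikes, use.names = FALSE)))
  data.table::fwrite(sp, file.path(path, "spikes.csv"))
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]; the returned bundle is validated, so a
#' malformed event ordering raises an error naming the offending trial.
#' Unsuccessful trials are retained and flagged, not dropped.
#'
#' @param path Bundle directory written by [write_session()].
#' @return A [session_bundle()].
#' @export
read_session <- function(path) {
  meta_p <- file.path(path, "meta.json")
  if (!file.exists(meta_p)) stop("not a session bundle (missing meta.json): ", path)
  meta <- jsonlite::read_json(meta_p, simplifyVector = TRUE)
  units <- as.data.frame(meta$units)
  if (nrow(units) == 0) units <- data.frame(unit_id = character(), area = character())
  tr <- as.data.frame(data.table::fread(file.path(path, "trials.csv"),
                                        colClasses = list(character = "trial_id")))
  if (nrow(tr)) {
    tr$trial_id <- as.character(tr$trial_id)
    tr$object <- as.character(tr$object)
    tr$success <- as.logical(tr$success)
  } else {
    tr <- data.frame(trial_id = character(), object = character(),
                     success = logical())
    for (e in EVENTS) tr[[e]] <- numeric()
  }
  sp <- as.data.frame(data.table::fread(file.path(path, "spikes.csv"),
                                        colClasses = list(character = "unit_id")))
  spikes <- stats::setNames(
    lapply(units$unit_id, function(u) {
      as.numeric(sp$spike_time_ms[sp$unit_id == u])
    }), units$unit_id)
  session_bundle(meta$session_id, meta$context, units, spikes, tr,
                 monkey = meta$monkey %||% NA_character_)
}

#' Per-session epoch-duration statistics
#'
#' Computes, over successful trials, the delay (`go - instruction_off`),
#' reaction (`move_on - go`) and movement (`hold_on - move_on`) durations,
#' and returns their medians pooled across objects (the session-level values
#' used to build the common aligned time base) as well as per object.
#'
#' @param bundle A [session_bundle()].
#' @return An object of class `epoch_stats` with fields `median_delay`,
#'   `median_reaction`, `median_movement`, `per_object` (data.frame), `n_trials`.
#' @export
compute_epoch_stats <- function(bundle) {
  tr <- successful_trials(bundle)
  if (nrow(tr) == 0) stop("no successful trials")
  for (ob in OBJECTS) {
    if (!any(tr$object == ob))
      stop("object with zero successful trials: ", ob)
  }
  delay <- tr$go - tr$instruction_off
  reaction <- tr$move_on - tr$go
  movement <- tr$hold_on - tr$move_on
  per_obj <- do.call(rbind, lapply(OBJECTS, function(ob) {
    k <- tr$object == ob
    data.frame(object = ob,
               median_delay = stats::median(delay[k]),
               median_reaction = stats::median(reaction[k]),
               median_movement = stats::median(movement[k]))
  }))
  structure(list(median_delay = stats::median(delay),
                 median_reaction = stats::median(reaction),
                 median_movement = stats::median(movement),
                 per_object = per_obj,
                 n_trials = nrow(tr)),
            class = "epoch_stats")
}

#' @export
print.epoch_stats <- function(x, ...) {
  cat(sprintf(
    "<epoch_stats> median delay %.0f ms, reaction %.0f ms, movement %.0f ms (%d trials)\n",
    x$median_delay, x$median_reaction, x$median_movement, x$n_trials))
  invisible(x)
}
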