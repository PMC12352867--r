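#' Bin spike trains at 1 ms and smooth with a Gaussian kernel
#'
#' Spikes of every unit are binned into half-open 1 ms bins `[t, t+1)` over
#' each trial's span and convolved with a Gaussian kernel of standard
#' deviation `sigma` (truncated at 4 sigma, normalized to unit area so
#' total spike mass is conserved away from edges). Convolution extends
#' beyond the trial span with zeros and is not renormalized at edges.
#'
#' @param bundle A [session_bundle()].
#' @param sigma Kernel standard deviation in ms (default 50).
#' @param successful_only Keep only successful trials (default TRUE).
#' @return A `rate_set`: per-trial smoothed firing-rate matrices
#'   (units x 1 ms bins, spikes/s) plus trial metadata. Feed to
#'   [sqrt_transform()] then [align_concatenate()].
#' @export
bin_and_smooth <- function(bundle, sigma = 50, successful_only = TRUE) {
  if (sigma <= 0) stop("sigma must be positive")
  tr <- if (successful_only) successful_trials(bundle) else bundle$trials
  hw <- ceiling(4 * sigma)
  kern <- stats::dnorm(seq(-hw, hw), 0, sigma)
  kern <- kern / sum(kern)
  unit_ids <- bundle$units$unit_id
  trials <- vector("list", nrow(tr))
  for (k in seq_len(nrow(tr))) {
    t0 <- floor(tr$start[k])
    t1 <- ceiling(tr$end[k])
    nb <- t1 - t0
    counts <- matrix(0, length(unit_ids), nb)
    for (i in seq_along(unit_ids)) {
      st <- bundle$spikes[[unit_ids[i]]]
      st <- st[st >= t0 & st < t1]
      if (length(st))
        counts[i, ] <- tabulate(floor(st - t0) + 1L, nbins = nb)
    }
    rates <- smooth_rows(counts, kern, hw) * 1000  # per-ms mass -> spikes/s
    trials[[k]] <- list(trial_id = tr$trial_id[k], object = tr$object[k],
                        t0 = t0, events = as.numeric(tr[k, EVENTS]),
                        rates = rates)
  }
  structure(list(unit_ids = unit_ids, sigma = sigma, sqrt = FALSE,
                 session_id = bundle$session_id, context = bundle$context,
                 trials = trials),
            class = "rate_set")
}

# Centered FFT convolution of each row with a symmetric kernel of half-width
# hw, zero-padded beyond the data.
smooth_rows <- function(M, kern, hw) {
  n <- ncol(M)
  out <- matrix(0, nrow(M), n)
  for (i in seq_len(nrow(M))) {
    x <- M[i, ]
    if (!any(x != 0)) next
    full <- stats::convolve(c(numeric(hw), x, numeric(hw)), kern, type = "filter")
    full[full < 0] <- 0  # FFT round-off can leave ~ -1e-17
    out[i, ] <- full
  }
  out
}

#' Square-root transform firing rates
#'
#' Applied after smoothing, elementwise, to render trial-to-trial variance
#' similar from low to high firing rates.
#'
#' @param rates A `rate_set` from [bin_and_smooth()], or a non-negative
#'   numeric vector/matrix.
#' @return Object of the same shape with square-rooted values (and, for a
#'   `rate_set`, the `sqrt` flag set).
#' @export
sqrt_transform <- function(rates) {
  if (inherits(rates, "rate_set")) {
    if (isTRUE(rates$sqrt)) stop("sqrt transform already applied")
    rates$trials <- lapply(rates$trials, function(tl) {
      tl$rates <- sqrt_transform(tl$rates)
      tl
    })
    rates$sqrt <- TRUE
    return(rates)
  }
  if (any(rates < 0)) stop("negative rates passed to sqrt_transform")
  sqrt(rates)
}

#' Time map of the concatenated aligned axis
#'
#' The aligned axis concatenates four event-aligned snippets: instruction
#' onset I `[-500, +500)`, go cue G `[-median_delay, +median_reaction/2)`,
#' movement onset M `[-median_reaction/2, +200)` and hold H `[-200, +200)`,
#' in that order, at 1 ms resolution. Each column is labelled with its
#' (event, offset) pair; medians are the session-level (object-pooled)
#' values so that all four objects share one time base.
#'
#' @param stats An `epoch_stats` from [compute_epoch_stats()].
#' @return `data.frame(event, offset)` with `nrow = T` and attributes
#'   `delay` and `r2` (half the median reaction, rounded).
#' @export
build_time_map <- function(stats) {
  d <- round(stats$median_delay)
  r2 <- round(stats$median_reaction / 2)
  tm <- rbind(
    data.frame(event = "I", offset = -500:499),
    data.frame(event = "G", offset = seq(-d, r2 - 1)),
    data.frame(event = "M", offset = seq(-r2, 199)),
    data.frame(event = "H", offset = -200:199))
  attr(tm, "delay") <- d
  attr(tm, "r2") <- r2
  tm
}

#' Align, clip, and concatenate rate courses into per-object tensors
#'
#' For every trial, clips the four event-aligned snippets defined by
#' [build_time_map()] from the smoothed (and usually square-root
#' transformed) rate courses and concatenates them in order I, G, M, H.
#' Trials whose span cannot supply a full snippet are excluded with a
#' warning. Results are grouped by object into `units x trials x time`
#' arrays sharing a single time base.
#'
#' @param rates A `rate_set` ([bin_and_smooth()] / [sqrt_transform()]).
#' @param stats An `epoch_stats`; pass the same object for both contexts of
#'   a session when cross-context comparisons are planned.
#' @return An `aligned_tensor`: list with `data` (per-object N x K x T
#'   arrays), `time_map`, `stats`, `unit_ids`, transform flags.
#' @export
align_concatenate <- function(rates, stats) {
  stopifnot(inherits(rates, "rate_set"))
  tm <- build_time_map(stats)
  d <- attr(tm, "delay"); r2 <- attr(tm, "r2")
  Tn <- nrow(tm)
  ev_anchor <- c(I = 2L, G = 4L, M = 5L, H = 6L)  # index into EVENTS
  per_obj <- stats::setNames(vector("list", 4), OBJECTS)
  ids_obj <- stats::setNames(vector("list", 4), OBJECTS)
  windows <- list(I = c(-500L, 499L), G = c(-d, r2 - 1L),
                  M = c(-r2, 199L), H = c(-200L, 199L))
  for (tl in rates$trials) {
    ev <- tl$events
    nb <- ncol(tl$rates)
    cols <- integer(0)
    ok <- TRUE
    for (e in names(windows)) {
      anchor <- round(ev[ev_anchor[[e]]])
      w <- windows[[e]]
      idx <- (anchor + w[1]):(anchor + w[2]) - tl$t0 + 1L
      if (idx[1] < 1L || idx[length(idx)] > nb) { ok <- FALSE; break }
      cols <- c(cols, idx)
    }
    if (!ok) {
      warning(sprintf("trial '%s' too short for a snippet; excluded", tl$trial_id))
      next
    }
    per_obj[[tl$object]] <- c(per_obj[[tl$object]], list(tl$rates[, cols, drop = FALSE]))
    ids_obj[[tl$object]] <- c(ids_obj[[tl$object]], tl$trial_id)
  }
  data <- lapply(per_obj, function(mats) {
    if (is.null(mats) || length(mats) == 0)
      return(array(0, c(length(rates$unit_ids), 0, Tn)))
    arr <- array(0, c(length(rates$unit_ids), length(mats), Tn))
    for (k in seq_along(mats)) arr[, k, ] <- mats[[k]]
    arr
  })
  structure(list(data = data, time_map = tm, stats = stats,
                 unit_ids = rates$unit_ids, sigma = rates$sigma,
                 sqrt = rates$sqrt, session_id = rates$session_id,
                 context = rates$context,
                 trial_ids = ids_obj),
            class = "aligned_tensor")
}

#' @export
print.aligned_tensor <- function(x, ...) {
  ks <- vapply(x$data, function(a) dim(a)[2], 1)
  cat(sprintf("<aligned_tensor> %d units x T=%d; trials per object: %s\n",
              length(x$unit_ids), nrow(x$time_map),
              paste(sprintf("%s=%d", names(ks), ks), collapse = ", ")))
  invisible(x)
}

#' Column index of an (event, offset) pair on the aligned axis
#' @param tensor An `aligned_tensor` (or its `time_map`).
#' @param event One of `"I"`, `"G"`, `"M"`, `"H"`.
#' @param offset Offset in ms relative to the event.
#' @return Integer column index.
#' @export
tensor_col <- function(tensor, event, offset) {
  tm <- if (inherits(tensor, "aligned_tensor")) tensor$time_map else tensor
  i <- which(tm$event == event & tm$offset == offset)
  if (length(i) != 1) stop(sprintf("no aligned column for (%s, %+d ms)", event, offset))
  i
}

#' Per-object trial-averaged courses
#' @param tensor An `aligned_tensor`.
#' @return Named list of `N x T` matrices (mean across trials per object).
#' @export
object_means <- function(tensor) {
  lapply(tensor$data, function(a) {
    if (dim(a)[2] == 0) stop("object with zero trials in tensor")
    if (dim(a)[2] == 1) return(a[, 1, ])
    colMeans(aperm(a, c(2, 1, 3)))
  })
}

#' Split trial-averaged activity into condition-independent and
#' condition-dependent components
#'
#' The condition-independent (CI) course is the unweighted mean of the four
#' per-object trial-averaged courses; each object's condition-dependent
#' (CD) course is its average minus the CI course, so the four CD courses
#' sum to zero at every (unit, time) by construction.
#'
#' @param tensor An `aligned_tensor` with at least one trial per object.
#' @return List with `ci_course` (`N x T`) and `cd_courses` (named list of
#'   `N x T`).
#' @export
condition_split <- function(tensor) {
  om <- object_means(tensor)
  ci <- Reduce(`+`, om) / length(om)
  cd <- lapply(om, function(m) m - ci)
  list(ci_course = ci, cd_courses = cd)
}

#' Build an aligned tensor directly from noise-free per-object courses
#'
#' Wraps externally supplied `N x T` courses (e.g. the generator's planted
#' condition means) as a single-trial-per-object `aligned_tensor`, so the
#' subspace stages can run on noise-free input.
#'
#' @param courses Named list (sphere/button/coax/perp) of `N x T` matrices.
#' @param time_map A time map ([build_time_map()]) with `T` rows.
#' @param stats Optional `epoch_stats` to carry along.
#' @return An `aligned_tensor` with `K = 1` per object.
#' @export
tensor_from_courses <- function(courses, time_map, stats = NULL) {
  stopifnot(setequal(names(courses), OBJECTS))
  Tn <- nrow(time_map)
  N <- nrow(courses[[1]])
  data <- lapply(courses[OBJECTS], function(m) {
    stopifnot(ncol(m) == Tn)
    array(m, c(N, 1, Tn))
  })
  structure(list(data = data, time_map = time_map, stats = stats,
                 unit_ids = sprintf("u%03d", seq_len(N)),
                 sigma = NA_real_, sqrt = FALSE,
                 session_id = "courses", context = NA_character_,
                 trial_ids = lapply(data, function(x) "mean")),
            class = "aligned_tensor")
}

#' Restrict an aligned tensor to a subset of units
#' @param tensor An `aligned_tensor`.
#' @param units Integer indices or unit ids.
#' @return An `aligned_tensor` over the selected units.
#' @export
subset_units <- function(tensor, units) {
  idx <- if (is.character(units)) match(units, tensor$unit_ids) else as.integer(units)
  if (anyNA(idx)) stop("unknown unit id(s)")
  tensor$data <- lapply(tensor$data, function(a) a[idx, , , drop = FALSE])
  tensor$unit_ids <- tensor$unit_ids[idx]
  tensor
}
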