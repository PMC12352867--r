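#' Clip 100 ms trajectory segments at a behavioral event
#'
#' Takes the 100 aligned-axis columns starting at the event time (offsets
#' 0..99 ms). For the go cue, whose own snippet extends only half the
#' median reaction time past the event, rows continue into the adjacent
#' movement-aligned snippet: the concatenated axis is contiguous through
#' G..M, so exactly 100 rows are always returned.
#'
#' @param tensor An `aligned_tensor`.
#' @param event `"I"`, `"G"`, `"M"` or `"H"`.
#' @param level `"trial-averaged"` (one segment per object) or
#'   `"single-trial"`.
#' @return A `trajectory_segments` object: named per-object list of
#'   `100 x N x K` arrays (`K = 1` when trial-averaged).
#' @export
clip_segments <- function(tensor, event = c("I", "G", "M", "H"),
                          level = c("trial-averaged", "single-trial")) {
  event <- match.arg(event)
  level <- match.arg(level)
  start_col <- tensor_col(tensor, event, 0)
  cols <- start_col:(start_col + 99L)
  if (max(cols) > nrow(tensor$time_map))
    stop(sprintf("segment at event %s truncated by the aligned-axis boundary", event))
  data <- lapply(tensor$data, function(a) {
    N <- dim(a)[1]; K <- dim(a)[2]
    if (K == 0) stop("object with zero trials")
    seg <- aperm(a[, , cols, drop = FALSE], c(3, 1, 2))  # 100 x N x K
    if (level == "trial-averaged") {
      avg <- apply(seg, c(1, 2), mean)
      seg <- array(avg, c(100, N, 1))
    }
    seg
  })
  structure(list(event = event, level = level, data = data,
                 unit_ids = tensor$unit_ids, context = tensor$context),
            class = "trajectory_segments")
}

#' Project a high-dimensional segment into a 3D subspace
#'
#' `L = (X - center) W`: rows are displacements from the instantaneous
#' condition-mean centroid of the target subspace's time step, projected
#' onto the orthonormal basis.
#'
#' @param seg `T x N` matrix (rows = 1 ms steps).
#' @param basis Orthonormal `N x 3` matrix.
#' @param center N-vector; the condition-mean centroid of the basis's time
#'   step (use 0 for an uncentered projection).
#' @return `T x 3` latent segment.
#' @export
project_segment <- function(seg, basis, center = 0) {
  assert_orthonormal(basis)
  if (ncol(seg) != nrow(basis)) stop("segment/basis dimension mismatch")
  sweep(seg, 2, center) %*% basis
}

#' Cumulative separation of four latent trajectory segments
#'
#' `d_ij(t)` is the 3D Euclidean distance between segments i and j at time
#' t; `D(t)` sums the six unordered pairs; `CS` is the time average of
#' `D(t)`. Larger CS means greater separation of the four object
#' trajectories in that subspace.
#'
#' @param latents List of four `T x 3` matrices (equal `T`).
#' @return List with `CS` (scalar), `D` (length-T vector), `d_ij`
#'   (`T x 6`, columns named by object pair).
#' @export
cumulative_separation <- function(latents) {
  if (length(latents) != 4) stop("exactly four latent segments required")
  Tn <- nrow(latents[[1]])
  if (!all(vapply(latents, nrow, 1L) == Tn)) stop("unequal segment lengths")
  nm <- names(latents) %||% paste0("seg", 1:4)
  pairs <- utils::combn(4, 2)
  d <- matrix(0, Tn, ncol(pairs))
  colnames(d) <- apply(pairs, 2, function(p) paste(nm[p[1]], nm[p[2]], sep = ":"))
  for (p in seq_len(ncol(pairs))) {
    diffm <- latents[[pairs[1, p]]] - latents[[pairs[2, p]]]
    d[, p] <- sqrt(rowSums(diffm^2))
  }
  D <- rowSums(d)
  list(CS = mean(D), D = D, d_ij = d)
}

#' Cumulative-separation grid across segment and subspace events
#'
#' Reproduces the segment-time x subspace-time structure: trial-averaged
#' segments clipped at each of the four events are projected into the
#' all-trial instantaneous subspace at each of the four events, and CS is
#' computed for every combination. Diagonal dominance of the grid reflects
#' the progressive shifting of the instantaneous subspace.
#'
#' @param tensor An `aligned_tensor`.
#' @param events Events to use (default all four).
#' @return 4 x 4 numeric matrix, rows = segment event, cols = subspace event.
#' @export
separation_grid <- function(tensor, events = c("I", "G", "M", "H")) {
  segs <- lapply(stats::setNames(events, events), clip_segments,
                 tensor = tensor, level = "trial-averaged")
  bases <- lapply(stats::setNames(events, events), function(e)
    instantaneous_basis(tensor, tensor_col(tensor, e, 0)))
  grid <- matrix(NA_real_, length(events), length(events),
                 dimnames = list(segment = events, subspace = events))
  for (se in events) for (be in events) {
    lat <- lapply(segs[[se]]$data, function(a)
      project_segment(a[, , 1], bases[[be]]$W, bases[[be]]$center))
    grid[se, be] <- cumulative_separation(lat)$CS
  }
  grid
}
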