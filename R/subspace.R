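#' Principal angles between two subspaces
#'
#' Canonical angles via singular value decomposition of the basis
#' inner-product matrix `t(A) %*% B`: the singular values are the ranked
#' cosines of the angles. Singular values are clipped to `[0, 1]` before
#' `acos` as a floating-point guard. 0 degrees means identical subspaces,
#' 90 degrees orthogonal.
#'
#' @param A,B Matrices with orthonormal columns (same row dimension).
#' @return Numeric vector of angles in degrees, ascending.
#' @export
principal_angles <- function(A, B) {
  if (nrow(A) != nrow(B)) stop("bases live in different ambient dimensions")
  assert_orthonormal(A, what = "A")
  assert_orthonormal(B, what = "B")
  d <- svd(crossprod(A, B), nu = 0, nv = 0)$d
  d <- pmin(pmax(d, 0), 1)
  acos(d) * 180 / pi
}

# Instantaneous basis at a single aligned column: PCA on the four object
# condition means (centered on their unweighted mean). Returns the
# orthonormal N x 3 basis (rank-deficient spans completed deterministically
# with canonical directions), the centroid, and per-component variance.
instantaneous_basis_from_points <- function(P) {
  # P: 4 x N matrix of condition means
  N <- ncol(P)
  if (N < 3) stop("ambient dimension too small (N < 3)")
  center <- colMeans(P)
  C <- sweep(P, 2, center)
  sv <- svd(C, nu = 0, nv = 3)
  d <- sv$d[1:3]
  tol <- max(sv$d[1], 0) * 1e-10
  r <- sum(d > tol)
  W <- if (r == 3) sv$v else
    complete_frame(if (r > 0) sv$v[, seq_len(r), drop = FALSE] else NULL, N, 3)
  ev <- d^2
  ev[seq_len(3) > r] <- 0
  list(W = W, center = center, explained_variance = ev,
       total_variance = sum(C^2))
}

# Condition-mean stack: 4 x N x T array of per-object trial averages.
condition_mean_stack <- function(tensor, trial_subset = NULL) {
  means <- lapply(OBJECTS, function(ob) {
    a <- tensor$data[[ob]]
    k <- if (is.null(trial_subset)) seq_len(dim(a)[2]) else trial_subset[[ob]]
    if (length(k) < 1) stop("object with no trials in subset: ", ob)
    if (length(k) == 1) a[, k, ] else colMeans(aperm(a[, k, , drop = FALSE], c(2, 1, 3)))
  })
  arr <- array(0, c(4, dim(means[[1]])[1], dim(means[[1]])[2]))
  for (i in 1:4) arr[i, , ] <- means[[i]]
  arr
}

#' Instantaneous subspace at one aligned time step
#'
#' @param tensor An `aligned_tensor`.
#' @param col Aligned-axis column index (see [tensor_col()]).
#' @param trial_subset Optional named list (per object) of trial indices;
#'   default all trials.
#' @return List with `W` (orthonormal `N x 3`), `center` (N-vector
#'   centroid of the four condition means), `explained_variance`.
#' @export
instantaneous_basis <- function(tensor, col, trial_subset = NULL) {
  P <- t(vapply(OBJECTS, function(ob) {
    a <- tensor$data[[ob]]
    k <- if (is.null(trial_subset)) seq_len(dim(a)[2]) else trial_subset[[ob]]
    if (length(k) == 1) a[, k, col] else rowMeans(a[, k, col, drop = FALSE][, , 1])
  }, numeric(length(tensor$unit_ids))))
  instantaneous_basis_from_points(P)
}

#' Time series of instantaneous condition-dependent subspaces
#'
#' At every 1 ms step of the aligned axis, averages the selected trials per
#' object to obtain four points in N-dimensional state space and performs
#' PCA on those four points (centered on their unweighted mean); the first
#' three components define the instantaneous subspace. Three components
#' capture all the variance of four points, so `explained_variance` sums to
#' the total variance of the centered condition means at every step.
#'
#' @inheritParams instantaneous_basis
#' @return A `subspace_series`: `bases` (`N x 3 x T`), `centers` (`N x T`),
#'   `explained_variance` (`3 x T`), `total_variance` (length `T`),
#'   `time_map`.
#' @export
instantaneous_subspaces <- function(tensor, trial_subset = NULL) {
  N <- length(tensor$unit_ids)
  if (N < 3) stop("ambient dimension too small (N < 3)")
  arr <- condition_mean_stack(tensor, trial_subset)
  Tn <- dim(arr)[3]
  bases <- array(0, c(N, 3, Tn))
  centers <- matrix(0, N, Tn)
  ev <- matrix(0, 3, Tn)
  tv <- numeric(Tn)
  for (t in seq_len(Tn)) {
    ib <- instantaneous_basis_from_points(arr[, , t])
    bases[, , t] <- ib$W
    centers[, t] <- ib$center
    ev[, t] <- ib$explained_variance
    tv[t] <- ib$total_variance
  }
  structure(list(bases = bases, centers = centers, explained_variance = ev,
                 total_variance = tv, time_map = tensor$time_map,
                 unit_ids = tensor$unit_ids, context = tensor$context),
            class = "subspace_series")
}

#' @export
print.subspace_series <- function(x, ...) {
  cat(sprintf("<subspace_series> N=%d, T=%d (1 ms steps)\n",
              dim(x$bases)[1], dim(x$bases)[3]))
  invisible(x)
}

#' Chance distribution of the first principal angle
#'
#' First principal angle between one fixed 3D subspace and `n_draws` 3D
#' subspaces drawn uniformly (Gaussian-QR / Haar) from an `n_dim`-dimensional
#' space; used as the chance calibration for angle time courses. Reported as
#' the mean and the mean minus 3 standard deviations.
#'
#' @param n_dim Ambient dimension (>= 3); for multi-session figures use the
#'   smallest population size across sessions.
#' @param n_draws Number of random subspaces (default 5000).
#' @param seed Seed for the draws.
#' @return List with `mean`, `sd`, `mean_minus_3sd` (degrees) and `samples`.
#' @export
chance_angles <- function(n_dim, n_draws = 5000, seed = 1L) {
  if (n_dim < 3) stop("n_dim must be >= 3")
  set.seed(derive_seed(seed, "chance_angles", n_dim))
  W0 <- random_frame(n_dim, 3)
  th1 <- vapply(seq_len(n_draws), function(i) {
    principal_angles(W0, random_frame(n_dim, 3))[1]
  }, numeric(1))
  list(mean = mean(th1), sd = stats::sd(th1),
       mean_minus_3sd = mean(th1) - 3 * stats::sd(th1), samples = th1)
}

#' Principal-angle time course against a reference instantaneous subspace
#'
#' The reference subspace is computed from ALL trials at the reference
#' event's time (offset 0). Each of `n_folds` bootstrap folds samples
#' `trials_per_object` trials per object with replacement, rebuilds the
#' whole time series of instantaneous subspaces from that 80-trial sample,
#' and records the three principal angles against the reference at every
#' step. Means and SDs are taken across folds; because the reference uses
#' all trials, the mean never reaches exactly zero at the reference time.
#'
#' @param tensor `aligned_tensor` supplying the moving series.
#' @param reference_event `"I"`, `"G"`, `"M"` or `"H"`.
#' @param ref_tensor Tensor supplying the reference subspace (defaults to
#'   `tensor`; pass the other context's tensor for cross-context courses).
#' @param n_folds Bootstrap folds (default 10).
#' @param trials_per_object Trials sampled per object per fold (default 20;
#'   if fewer are available a warning is emitted and sampling with
#'   replacement proceeds).
#' @param seed Seed for fold resampling.
#' @param n_chance Draws for the chance band ([chance_angles()]); 0 skips.
#' @param chance_ndim Ambient dimension for the chance band (default: this
#'   population's size).
#' @return An `angle_course`: `mean`/`sd` (`3 x T`, degrees), `angles`
#'   (`3 x T x n_folds`), `time_map`, chance statistics.
#' @export
angle_course <- function(tensor, reference_event = c("I", "G", "M", "H"),
                         ref_tensor = tensor, n_folds = 10,
                         trials_per_object = 20, seed = 1L,
                         n_chance = 5000, chance_ndim = NULL) {
  reference_event <- match.arg(reference_event)
  if (!identical(dim(ref_tensor$time_map), dim(tensor$time_map)) ||
      !identical(ref_tensor$time_map$event, tensor$time_map$event))
    stop("reference and moving tensors have mismatched time bases")
  ref_col <- tensor_col(ref_tensor, reference_event, 0)
  ref <- instantaneous_basis(ref_tensor, ref_col)
  Tn <- nrow(tensor$time_map)
  ang <- array(0, c(3, Tn, n_folds))
  avail <- vapply(tensor$data, function(a) dim(a)[2], 1L)
  if (any(avail < trials_per_object))
    warning("fewer available trials than trials_per_object; sampling with replacement anyway")
  for (f in seq_len(n_folds)) {
    set.seed(derive_seed(seed, "angle_course", reference_event, f))
    subset <- lapply(tensor$data, function(a)
      sample.int(dim(a)[2], trials_per_object, replace = TRUE))
    ser <- instantaneous_subspaces(tensor, subset)
    for (t in seq_len(Tn))
      ang[, t, f] <- principal_angles(ref$W, ser$bases[, , t])
  }
  m <- apply(ang, c(1, 2), mean)
  s <- apply(ang, c(1, 2), stats::sd)
  ch <- if (n_chance > 0)
    chance_angles(chance_ndim %||% length(tensor$unit_ids), n_chance, seed)
  else list(mean = NA_real_, sd = NA_real_, mean_minus_3sd = NA_real_)
  structure(list(reference = reference_event,
                 reference_context = ref_tensor$context,
                 context = tensor$context,
                 mean = m, sd = s, angles = ang,
                 time_map = tensor$time_map,
                 chance_mean = ch$mean, chance_sd = ch$sd,
                 chance_mean_minus_3sd = ch$mean_minus_3sd,
                 n_folds = n_folds, trials_per_object = trials_per_object),
            class = "angle_course")
}

#' Cross-context principal-angle time course
#'
#' Reference subspace from one context (all trials, at the reference
#' event), moving series from the other context; otherwise identical to
#' [angle_course()]. Errors if the two tensors do not share a time base.
#'
#' @param ref_tensor Tensor of the reference context.
#' @param moving_tensor Tensor of the moving context.
#' @inheritParams angle_course
#' @return An `angle_course`.
#' @export
cross_context_angles <- function(ref_tensor, moving_tensor,
                                 reference_event = c("I", "G", "M", "H"),
                                 ...) {
  angle_course(moving_tensor, match.arg(reference_event),
               ref_tensor = ref_tensor, ...)
}

#' Write an angle course to CSV
#' @param course An `angle_course`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_angle_course <- function(course, path) {
  df <- data.frame(time_ms = seq_len(nrow(course$time_map)),
                   event = course$time_map$event,
                   offset_ms = course$time_map$offset,
                   theta1_mean = course$mean[1, ], theta1_sd = course$sd[1, ],
                   theta2_mean = course$mean[2, ], theta2_sd = course$sd[2, ],
                   theta3_mean = course$mean[3, ], theta3_sd = course$sd[3, ],
                   chance_mean = course$chance_mean,
                   chance_m3sd = course$chance_mean_minus_3sd)
  data.table::fwrite(df, path)
  invisible(path)
}
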