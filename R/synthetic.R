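#' Configuration for the synthetic session generator
#'
#' The generator emulates one recording session of the delayed
#' reach-grasp-manipulate task: 4 objects, a randomized 500-2000 ms delay,
#' reaction and movement epochs of a few hundred ms, and a unit population
#' split into mirror (MN), execution-only (AE), observation-only (AO) and
#' unmodulated (NS) classes. Firing rates are a shared condition-independent
#' envelope plus object-specific condition-dependent components confined to
#' a planted orthonormal 3D basis that rotates progressively through the
#' trial; spikes are drawn as an inhomogeneous Poisson process.
#'
#' @param n_units Total units. Defaults mirror a typical session.
#' @param n_mn,n_ae,n_ao,n_ns Class counts, summing to `n_units`.
#'   `n_mn >= 12` (the planted mirror-population geometry needs a 12-dim
#'   ambient frame) and `n_ae` is 0 or `>= 6`.
#' @param trials_per_object Successful trials per object.
#' @param delay_range Two-element vector, uniform preparatory-delay range (ms).
#' @param reaction_mean,movement_mean Mean reaction / movement durations (ms).
#' @param base_rate Baseline firing rate (spikes/s).
#' @param ci_amplitude Peak condition-independent modulation (spikes/s).
#' @param cd_amplitude_exec,cd_amplitude_obs Condition-dependent modulation
#'   scale (spikes/s) during execution / observation; observation is lower,
#'   as observed empirically.
#' @param subspace_rotation_rate Progressive rotation of the planted
#'   condition-dependent basis, radians per canonical ms.
#' @param context_overlap In `[0, 1]`: principal-angle cosine between the
#'   planted execution and observation mirror-population bases
#'   (0 = orthogonal subspaces, 1 = identical). Latent object weights are
#'   shared across contexts regardless, so latent *relations* always match.
#' @param seed Integer seed; the full session is deterministic given
#'   `(seed, context)`.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_units = 50, n_mn = 24, n_ae = 18, n_ao = 4,
                         n_ns = 4, trials_per_object = 20,
                         delay_range = c(500, 2000),
                         reaction_mean = 300, movement_mean = 400,
                         base_rate = 16, ci_amplitude = 10,
                         cd_amplitude_exec = 12, cd_amplitude_obs = 8,
                         subspace_rotation_rate = 5e-4,
                         context_overlap = 0.2, seed = 1L) {
  cfg <- list(n_units = n_units, n_mn = n_mn, n_ae = n_ae, n_ao = n_ao,
              n_ns = n_ns, trials_per_object = trials_per_object,
              delay_range = delay_range, reaction_mean = reaction_mean,
              movement_mean = movement_mean, base_rate = base_rate,
              ci_amplitude = ci_amplitude,
              cd_amplitude_exec = cd_amplitude_exec,
              cd_amplitude_obs = cd_amplitude_obs,
              subspace_rotation_rate = subspace_rotation_rate,
              context_overlap = context_overlap, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  counts <- c(cfg$n_mn, cfg$n_ae, cfg$n_ao, cfg$n_ns)
  if (any(counts < 0) || cfg$n_units <= 0)
    stop("config error: negative or zero unit counts")
  if (sum(counts) != cfg$n_units)
    stop("config error: class counts do not sum to n_units")
  if (cfg$n_mn < 12)
    stop("config error: n_mn must be >= 12 (planted geometry needs a 12-dim frame)")
  if (cfg$n_ae != 0 && cfg$n_ae < 6)
    stop("config error: n_ae must be 0 or >= 6")
  if (cfg$context_overlap < 0 || cfg$context_overlap > 1)
    stop("config error: context_overlap must lie in [0, 1]")
  if (any(c(cfg$base_rate, cfg$ci_amplitude, cfg$cd_amplitude_exec,
            cfg$cd_amplitude_obs) < 0))
    stop("config error: rates and amplitudes must be non-negative")
  if (diff(cfg$delay_range) < 0 || cfg$delay_range[1] <= 0)
    stop("config error: invalid delay_range")
  invisible(cfg)
}

#' Read a synthetic configuration from a JSON or YAML file
#' @param path File whose top-level fields mirror [synth_config()] arguments.
#' @return A `synth_config`.
#' @export
read_synth_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synth_config, vals)
}

# Latent weight vectors of the four objects: an irregular (asymmetrically
# scaled, re-centered) tetrahedron in R^3. Mean zero so the condition means
# stay centered on the condition-independent course; spanning exactly 3
# dims; deliberately *not* equidistant, so that the relational geometry
# among objects is informative (no relabeling of objects is a linear
# isometry of latent space — real neural representations are likewise
# asymmetric).
object_weights <- function() {
  W <- cbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  W <- sweep(W, 2, c(1.25, 0.7, 1.1, 0.85), `*`)
  W <- W - rowMeans(W)
  colnames(W) <- OBJECTS
  W
}

# Rotated 3-frame inside a 6-dim ambient frame A (n x 6): paired Givens
# rotation of columns (1,4), (2,5), (3,6) by theta.
rotated_basis <- function(A, theta) {
  A[, 1:3] * cos(theta) + A[, 4:6] * sin(theta)
}

# Structural (context-shared) parameters: frames, unit classes, gains.
synth_structure <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "frames"))
  n <- cfg$n_units
  classes <- rep(c("MN", "AE", "AO", "NS"),
                 c(cfg$n_mn, cfg$n_ae, cfg$n_ao, cfg$n_ns))
  idx <- split(seq_len(n), factor(classes, levels = c("MN", "AE", "AO", "NS")))
  Q_mn <- random_frame(cfg$n_mn, 12L)
  A_exec <- Q_mn[, 1:6]    # ambient frame of the execution MN basis
  A_obsx <- Q_mn[, 7:12]   # extra dims mixed in for the observation basis
  A_ae <- if (cfg$n_ae >= 6) random_frame(cfg$n_ae, 6L) else NULL
  list(classes = classes, idx = idx,
       A_exec = A_exec, A_obsx = A_obsx, A_ae = A_ae,
       base = cfg$base_rate * stats::runif(n, 0.7, 1.3),
       ci_gain = abs(stats::rnorm(n, 1, 0.3)),
       area = sample(c("PMv", "PMd"), n, replace = TRUE),
       w = object_weights())
}

# Planted MN basis (n_mn x 3, orthonormal) at rotation angle theta for a
# context; the observation basis mixes in obs-specific dimensions so that
# its principal-angle cosines with the execution basis all equal
# context_overlap, while rotating at the same rate.
mn_basis_at <- function(st, theta, context, overlap) {
  Be <- rotated_basis(st$A_exec, theta)
  if (context == "execution") return(Be)
  Co <- rotated_basis(st$A_obsx, theta)
  overlap * Be + sqrt(1 - overlap^2) * Co
}

# Full-population effective condition-dependent basis (N x 3, orthonormal):
# block-weighted combination of the MN and (execution only) AE bases.
full_basis_at <- function(st, cfg, theta, context) {
  n <- cfg$n_units
  B <- matrix(0, n, 3)
  Bmn <- mn_basis_at(st, theta, context, cfg$context_overlap)
  B[st$idx$MN, ] <- sqrt(cfg$n_mn) * Bmn
  if (context == "execution" && cfg$n_ae >= 6)
    B[st$idx$AE, ] <- sqrt(cfg$n_ae) * rotated_basis(st$A_ae, theta)
  nr <- sqrt(colSums(B^2))
  sweep(B, 2, nr, `/`)
}

# Canonical anchor rotation angles at the four alignment events. Rotation
# starts at instruction onset and proceeds at a constant rate against
# canonical (median-duration) elapsed time, so the angle at each behavioral
# event is identical across trials regardless of that trial's epoch
# durations.
anchor_angles <- function(cfg) {
  r <- cfg$subspace_rotation_rate
  delay_c <- mean(cfg$delay_range)
  thI <- 0
  thG <- r * (500 + delay_c)
  thM <- thG + r * cfg$reaction_mean
  thH <- thM + r * cfg$movement_mean
  c(I = thI, G = thG, M = thM, H = thH)
}

# Piecewise-linear profile through per-trial event anchors; flat outside.
trial_profile <- function(times, anchors_x, anchors_y) {
  stats::approx(anchors_x, anchors_y, xout = times, rule = 2)$y
}

# Condition-dependent latent amplitude envelope a(t): zero before the
# instruction onset, rising from ~60 ms after it (typical premotor
# signal-related latency) to half amplitude during the instruction epoch,
# then to full amplitude between go cue and movement onset, sustained
# through the final hold.
cd_envelope <- function(times, ev) {
  trial_profile(times,
                c(ev[["instruction_on"]] + 60, ev[["instruction_on"]] + 260,
                  ev[["go"]], ev[["move_on"]], ev[["hold_on"]],
                  ev[["hold_off"]]),
                c(0, 0.5, 0.5, 1, 1, 0.5))
}

# Condition-independent envelope: brief bump after the instruction, rise
# before movement onset, peak mid-movement, decay during the final hold.
ci_envelope <- function(times, ev) {
  midmove <- (ev[["move_on"]] + ev[["hold_on"]]) / 2
  trial_profile(times,
                c(ev[["instruction_on"]], ev[["instruction_on"]] + 100,
                  ev[["instruction_on"]] + 400, ev[["go"]], ev[["move_on"]],
                  midmove, ev[["hold_on"]], ev[["hold_off"]],
                  ev[["hold_off"]] + 300),
                c(0, 0.35, 0.10, 0.15, 0.7, 1, 0.6, 0.2, 0))
}

# Per-object temporal signature of the three latent channels: slow smooth
# modulations (period several hundred ms) around 1 with object-specific
# phases, shared across contexts. This gives each object's latent
# trajectory a distinctive time course, so that the *relations* among
# object representations carry more than directional information (real
# movements likewise differ in their time courses, not only their mean
# states). tau is time since instruction onset in ms.
cd_signature <- function(tau, object) {
  o <- match(object, OBJECTS)
  # periods chosen slow enough to survive the 50 ms Gaussian smoothing yet
  # fast enough to give distinct within-segment slopes
  # Two incommensurate frequencies per channel with fixed scattered phases
  # (rows = objects, cols = channels). Rationale: the *relations* among the
  # four object representations must be carried by their within-segment
  # time courses, not only by their mean positions — four mean-zero static
  # points are linearly mappable onto any relabeling of themselves, so
  # static offsets cannot identify object correspondence. Two frequencies
  # populate the ~3 temporal degrees of freedom that survive a 100 ms
  # window smoothed at sigma = 50 ms, and the small constant part keeps
  # static offsets from dominating.
  # phases fixed so that the four objects' joint (offset, time-course)
  # constellations identify the object correspondence: under every
  # derangement of labels the best achievable canonical correlation of the
  # noise-free latents stays well below 1
  periods_a <- c(180, 230, 300)
  periods_b <- c(300, 380, 470)
  phase_a <- matrix(c(0.299660, 0.108680, 0.907108, 0.635056,
                      0.981884, 0.013674, 0.307657, 0.624106,
                      0.594967, 0.012089, 0.448569, 0.989983), 4, 3)
  phase_b <- matrix(c(0.224893, 0.874898, 0.243399, 0.844878,
                      0.505414, 0.087091, 0.878551, 0.672299,
                      0.232081, 0.022023, 0.864846, 0.816430), 4, 3)
  t(vapply(1:3, function(j)
    0.3 + 1.25 * (sin(2 * pi * (tau / periods_a[j] + phase_a[o, j])) +
                    sin(2 * pi * (tau / periods_b[j] + phase_b[o, j]))),
    numeric(length(tau))))
}

# Rotation angle profile for one trial: linear between event anchors.
theta_profile <- function(times, ev, th) {
  trial_profile(times,
                c(ev[["instruction_on"]], ev[["go"]], ev[["move_on"]],
                  ev[["hold_on"]]),
                th[c("I", "G", "M", "H")])
}

# Piecewise-linear warp of one trial's clock onto the canonical trial's
# clock, pinned at the behavioral events. Time-varying planted structure is
# evaluated on the canonical clock so that its phase at (and around) each
# event is identical across trials despite the randomized epoch durations.
canonical_warp <- function(times, ev, ev_canon) {
  keys <- c("instruction_on", "instruction_off", "go", "move_on", "hold_on",
            "hold_off")
  trial_profile(times, ev[keys], ev_canon[keys])
}

#' Generate a synthetic session with planted latent structure
#'
#' Draws trial event sequences, builds per-unit inhomogeneous Poisson
#' intensities `lambda_n(t) = base_n + ci_gain_n * CI(t) + CD_n(object, t)`
#' (rectified at zero), samples spikes at 1 ms resolution, and returns both
#' the resulting [session_bundle()] and a ground-truth object holding the
#' planted bases, unit classes, and noise-free condition-mean rate courses
#' on the session's aligned time axis.
#'
#' The condition-dependent component for the mirror population lives in a
#' planted orthonormal basis that rotates progressively (see
#' [synth_config()]); AE units carry an execution-only component in their
#' own rotating basis, and have `CD = CI = 0` during observation.
#'
#' @param config A [synth_config()].
#' @param context `"execution"` or `"observation"`.
#' @return A list with elements `bundle` ([session_bundle()]) and `truth`
#'   (class `synth_truth`; see [planted_basis()], [planted_first_angle()]).
#' @export
generate_session <- function(config, context = c("execution", "observation")) {
  context <- match.arg(context)
  cfg <- validate_synth_config(config)
  st <- synth_structure(cfg)
  th <- anchor_angles(cfg)
  cd_amp <- if (context == "execution") cfg$cd_amplitude_exec else cfg$cd_amplitude_obs
  ci_scale <- if (context == "execution") 1 else 0.6
  n <- cfg$n_units

  # Per-object condition-dependent direction generators. The latent state of
  # object o at time t is a(t) * (w_o (*) m_o(tau)) in the planted rotating
  # basis: fixed weight vector w_o, channel-wise temporal signature m_o
  # (shared across contexts, distinct per object). Expressed through the two
  # fixed frames so only cos/sin/modulation profiles vary with time:
  # CD(t) = amp * a(t) * sum_j m_oj(tau) (v1_j cos(theta) + v2_j sin(theta)).
  w <- st$w
  V <- list()  # per object: v1, v2 = N x 3 (one column per latent channel)
  Bm1 <- mn_basis_at(st, 0, context, cfg$context_overlap)
  # theta-decomposition: basis(theta) = B(0) cos(theta) + Bdot sin(theta)
  Bm2 <- mn_basis_at_deriv(st, context, cfg$context_overlap)
  for (ob in OBJECTS) {
    v1 <- matrix(0, n, 3); v2 <- matrix(0, n, 3)
    v1[st$idx$MN, ] <- sqrt(cfg$n_mn) * sweep(Bm1, 2, w[, ob], `*`)
    v2[st$idx$MN, ] <- sqrt(cfg$n_mn) * sweep(Bm2, 2, w[, ob], `*`)
    if (context == "execution" && cfg$n_ae >= 6) {
      v1[st$idx$AE, ] <- sqrt(cfg$n_ae) * sweep(st$A_ae[, 1:3], 2, w[, ob], `*`)
      v2[st$idx$AE, ] <- sqrt(cfg$n_ae) * sweep(st$A_ae[, 4:6], 2, w[, ob], `*`)
    }
    V[[ob]] <- list(v1 = v1, v2 = v2)
  }

  # CI participation by class and context: MN always; AE execution only;
  # AO observation only; NS never.
  ci_on <- switch(context,
                  execution = st$classes %in% c("MN", "AE"),
                  observation = st$classes %in% c("MN", "AO"))
  ci_vec <- cfg$ci_amplitude * st$ci_gain * ci_on * ci_scale

  set.seed(derive_seed(cfg$seed, context))
  ev_canon <- canonical_trial_events(cfg)
  k_obj <- cfg$trials_per_object
  # pseudorandom block design: one trial per object per block, shuffled
  objs <- as.vector(vapply(seq_len(k_obj), function(b) sample(OBJECTS), character(4)))
  n_tr <- length(objs)

  trials <- data.frame(trial_id = sprintf("t%03d", seq_len(n_tr)),
                       object = objs, success = TRUE)
  t_cursor <- 0
  ev_rows <- vector("list", n_tr)
  sp_acc <- replicate(n, list())
  for (k in seq_len(n_tr)) {
    start <- t_cursor
    instruction_on <- start + round(stats::runif(1, 500, 1000))
    instruction_off <- instruction_on + 500
    go <- instruction_off + round(stats::runif(1, cfg$delay_range[1], cfg$delay_range[2]))
    move_on <- go + round(max(150, stats::rnorm(1, cfg$reaction_mean, 30)))
    hold_on <- move_on + round(max(200, stats::rnorm(1, cfg$movement_mean, 40)))
    hold_off <- hold_on + 1000
    end <- hold_off + 300
    ev <- c(start = start, instruction_on = instruction_on,
            instruction_off = instruction_off, go = go, move_on = move_on,
            hold_on = hold_on, hold_off = hold_off, end = end)
    ev_rows[[k]] <- ev

    bins <- seq(start, end - 1)            # 1 ms bins [t, t+1)
    tt <- bins + 0.5                       # intensity evaluated mid-bin
    a <- cd_envelope(tt, ev)
    ci <- ci_envelope(tt, ev)
    theta <- theta_profile(tt, ev, th)
    vv <- V[[objs[k]]]
    m <- cd_signature(canonical_warp(tt, ev, ev_canon), objs[k])
    lam <- outer(st$base, rep(1, length(tt))) + ci_vec %o% ci
    for (j in 1:3)
      lam <- lam + cd_amp * (vv$v1[, j] %o% (a * m[j, ] * cos(theta)) +
                               vv$v2[, j] %o% (a * m[j, ] * sin(theta)))
    lam[lam < 0] <- 0                      # rectification before sampling
    counts <- matrix(stats::rpois(length(lam), lam * 1e-3), nrow = n)
    nz <- which(counts > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      reps <- counts[nz]
      unit_i <- rep(nz[, 1], reps)
      t_left <- rep(bins[nz[, 2]], reps)
      times <- round(t_left + stats::runif(length(t_left)), 3)
      by_unit <- split(times, unit_i)
      for (ui in names(by_unit))
        sp_acc[[as.integer(ui)]] <- c(sp_acc[[as.integer(ui)]], list(by_unit[[ui]]))
    }
    t_cursor <- end + 1000
  }
  ev_df <- as.data.frame(do.call(rbind, ev_rows))
  trials <- cbind(trials, ev_df)

  unit_ids <- sprintf("u%03d", seq_len(n))
  spikes <- stats::setNames(
    lapply(sp_acc, function(x) sort(unlist(x) %||% numeric(0))), unit_ids)
  units <- data.frame(unit_id = unit_ids, area = st$area)
  bundle <- session_bundle(sprintf("synth-s%d", cfg$seed), context,
                           units, spikes, trials, monkey = "synthetic")

  truth <- synth_truth(cfg, st, th, bundle, context, cd_amp, ci_vec, V)
  list(bundle = bundle, truth = truth)
}

# Derivative frame: basis(theta) = mn_basis_at(st, 0, ...) * cos(theta) +
# (this) * sin(theta); it is the same overlap-mix applied to columns 4:6.
mn_basis_at_deriv <- function(st, context, overlap) {
  Be <- st$A_exec[, 4:6]
  if (context == "execution") return(Be)
  overlap * Be + sqrt(1 - overlap^2) * st$A_obsx[, 4:6]
}

# Ground truth: everything needed to evaluate the planted geometry on the
# session's aligned (concatenated snippet) time axis. Envelopes and the
# rotation angle are evaluated on a *canonical* trial whose epoch durations
# come from the config (not from this context's realized medians), so the
# planted geometry at a given (event, offset) is identical across contexts
# and seeds by construction.
synth_truth <- function(cfg, st, th, bundle, context, cd_amp, ci_vec, V) {
  stats_ <- compute_epoch_stats(bundle)
  tm <- build_time_map(stats_)
  ev <- canonical_trial_events(cfg)
  tt <- aligned_wall_times(tm, ev) + 0.5
  a <- cd_envelope(tt, ev)
  ci <- ci_envelope(tt, ev)
  theta <- theta_profile(tt, ev, th)
  mean_courses <- lapply(stats::setNames(OBJECTS, OBJECTS), function(ob) {
    vv <- V[[ob]]
    m <- cd_signature(tt, ob)  # truth already lives on the canonical clock
    lam <- outer(st$base, rep(1, length(tt))) + ci_vec %o% ci
    for (j in 1:3)
      lam <- lam + cd_amp * (vv$v1[, j] %o% (a * m[j, ] * cos(theta)) +
                               vv$v2[, j] %o% (a * m[j, ] * sin(theta)))
    lam
  })
  structure(list(config = cfg, context = context, classes = st$classes,
                 structure = st, anchors = th, time_map = tm,
                 theta_course = theta, cd_envelope = a,
                 mean_courses = mean_courses, epoch_stats = stats_),
            class = "synth_truth")
}

# Events of the canonical (config-duration) trial, instruction onset at 0.
canonical_trial_events <- function(cfg) {
  d <- round(mean(cfg$delay_range)); r <- round(cfg$reaction_mean)
  m <- round(cfg$movement_mean)
  c(start = -2750, instruction_on = 0, instruction_off = 500,
    go = 500 + d, move_on = 500 + d + r, hold_on = 500 + d + r + m,
    hold_off = 500 + d + r + m + 1000, end = 500 + d + r + m + 1300)
}

# Wall-clock time (canonical trial) of each aligned column.
aligned_wall_times <- function(tm, ev) {
  anchor <- c(I = ev[["instruction_on"]], G = ev[["go"]],
              M = ev[["move_on"]], H = ev[["hold_on"]])
  anchor[tm$event] + tm$offset
}

#' Planted condition-dependent basis at an aligned time step
#'
#' Returns the noise-free orthonormal basis the generator planted, evaluated
#' at a column of the session's aligned time axis, for the full population
#' or a unit-class subpopulation.
#'
#' @param truth A `synth_truth` from [generate_session()].
#' @param col Aligned-axis column index (1-based, in `1..T`).
#' @param population `"all"`, `"MN"`, or `"AE"` (rows restricted to that
#'   class; the restriction of the planted basis to a class block is itself
#'   orthonormal).
#' @return An orthonormal matrix (`n_pop x 3`).
#' @export
planted_basis <- function(truth, col, population = c("all", "MN", "AE")) {
  population <- match.arg(population)
  Tn <- nrow(truth$time_map)
  if (col < 1 || col > Tn) stop("aligned time index out of range")
  theta <- truth$theta_course[col]
  cfg <- truth$config; st <- truth$structure
  if (population == "MN")
    return(mn_basis_at(st, theta, truth$context, cfg$context_overlap))
  if (population == "AE") {
    if (truth$context != "execution" || cfg$n_ae < 6)
      stop("AE planted basis exists only in the execution context")
    return(rotated_basis(st$A_ae, theta))
  }
  full_basis_at(st, cfg, theta, truth$context)
}

#' First principal angle between planted bases at two aligned times
#'
#' Oracle for the subspace-comparison stage: computes the first principal
#' angle between the planted (noise-free) bases at two aligned-axis time
#' steps, by the same SVD definition used for measured subspaces.
#'
#' @inheritParams planted_basis
#' @param t_ref,t Aligned-axis column indices.
#' @return Angle in degrees.
#' @export
planted_first_angle <- function(truth, t_ref, t, population = "all") {
  A <- planted_basis(truth, t_ref, population)
  B <- planted_basis(truth, t, population)
  principal_angles(A, B)[1]
}
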