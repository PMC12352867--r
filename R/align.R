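#' Align two sets of latent trajectory segments by canonical correlation
#'
#' QR + SVD construction: each latent matrix is transposed and column
#' centered, economy QR gives `t(L_A) = Q_A R_A` (the 3 columns of `Q_A`
#' an orthonormal basis for the centered latents), the SVD
#' `t(Q_A) %*% Q_B = U S t(V)` yields the transforms `M_A = solve(R_A) U`
#' and `M_B = solve(R_B) V`, and the diagonal of `S` holds the canonical
#' correlation coefficients, sorted from largest to smallest. The aligned
#' latents `t(L~_A) = t(L_A) M_A` satisfy `L~_A t(L~_B) = S` (diagonal).
#' CCs are invariant to separate invertible 3x3 linear transforms of
#' either input.
#'
#' @param L_A,L_B `3 x n` latent matrices (rows = latent dimensions,
#'   columns = time samples; for segment alignment `n = 400`, the four
#'   100-point object segments concatenated in fixed object order).
#' @param center Column-center `t(L)` before QR so coefficients are
#'   correlations (default TRUE).
#' @return List with `cc` (length 3, descending), `M_A`, `M_B` (3x3),
#'   `aligned_A`, `aligned_B` (`3 x n`).
#' @export
cca_align <- function(L_A, L_B, center = TRUE) {
  if (!all(dim(L_A) == dim(L_B))) stop("latent matrices must share dimensions")
  if (nrow(L_A) != 3) stop("latents must have 3 rows (latent dimensions)")
  tA <- t(L_A); tB <- t(L_B)
  if (center) {
    tA <- scale(tA, center = TRUE, scale = FALSE)
    tB <- scale(tB, center = TRUE, scale = FALSE)
  }
  qa <- qr_pos(tA); qb <- qr_pos(tB)
  if (min(abs(diag(qa$R))) < 1e-10 * max(abs(diag(qa$R))) ||
      min(abs(diag(qb$R))) < 1e-10 * max(abs(diag(qb$R))))
    stop("rank-deficient latents (collinear dimensions); resample or regularize")
  sv <- svd(crossprod(qa$Q, qb$Q))
  M_A <- solve(qa$R, sv$u)
  M_B <- solve(qb$R, sv$v)
  aligned_A <- t(tA %*% M_A)
  aligned_B <- t(tB %*% M_B)
  list(cc = pmin(sv$d, 1), M_A = M_A, M_B = M_B,
       aligned_A = aligned_A, aligned_B = aligned_B)
}

# A "CCA dataset": the tensor plus the all-trial instantaneous basis at
# each event time, into which that dataset's own segments are projected.
cca_dataset <- function(tensor, label = tensor$session_id) {
  list(tensor = tensor, label = label)
}

# Sessions with fewer successful trials than trials_per_object for any
# object are barred from CCA (mirrors the exclusion of a session with only
# eight button trials).
check_cca_eligible <- function(tensor, trials_per_object) {
  counts <- vapply(tensor$data, function(a) dim(a)[2], 1L)
  if (any(counts < trials_per_object))
    stop(sprintf(
      "session excluded from CCA: object(s) %s have fewer than %d successful trials",
      paste(names(counts)[counts < trials_per_object], collapse = ", "),
      trials_per_object))
  invisible(TRUE)
}

# Trial-averaged latent segments for one resample: average the sampled
# trials per object, clip 100 ms at the event, subtract the time-resolved
# across-object centroid (so the latents carry only condition-dependent
# structure, not the condition-independent drift every object shares),
# project into the dataset's own all-trial instantaneous subspace at the
# event time, and concatenate the four objects along time -> 3 x 400.
resampled_latents <- function(tensor, segment_event, sel, basis) {
  cols <- tensor_col(tensor, segment_event, 0) + 0:99
  avgs <- lapply(OBJECTS, function(ob) {
    a <- tensor$data[[ob]]
    if (length(sel[[ob]]) == 1) a[, sel[[ob]], cols] else
      colMeans(aperm(a[, sel[[ob]], cols, drop = FALSE], c(2, 1, 3)))
  })
  centroid <- Reduce(`+`, avgs) / length(avgs)  # N x 100, per time step
  segs <- lapply(avgs, function(avg) t(avg - centroid) %*% basis$W)
  t(do.call(rbind, segs))  # 3 x 400
}

#' Bootstrap CCA between two datasets
#'
#' Per iteration, each dataset independently resamples `trials_per_object`
#' trials per object with replacement, trial-averages, clips the 100 ms
#' segment at `segment_event`, projects into that dataset's own all-trial
#' instantaneous subspace at the event time, and the two stacked `3 x 400`
#' latent matrices are aligned with [cca_align()]. The distribution of
#' (CC1, CC2, CC3) over iterations quantifies alignment and its
#' variability; comparisons include between-session (MN:1/2),
#' between-context (MN:E/O) and between-population (MN/AE) alignments.
#'
#' @param dataset_a,dataset_b `aligned_tensor`s (may differ in session,
#'   context, or unit population; they need not share units).
#' @param segment_event `"I"`, `"G"`, `"M"` or `"H"`.
#' @param trials_per_object Resample size per object (default 20); a
#'   dataset whose objects have fewer successful trials is excluded with an
#'   error.
#' @param n_iter Bootstrap iterations (default 500).
#' @param comparison Label for the comparison (e.g. `"MN:E/O"`).
#' @param seed Seed; iteration substreams derive from it.
#' @param permute_objects If TRUE, dataset B's object labels are deranged
#'   (permuted with no fixed points) each iteration: the permutation null,
#'   which destroys every object correspondence while keeping all other
#'   structure intact.
#' @return A `cca_outcome`: `cc` (`n_iter x 3`), summary `mean`/`sd`,
#'   transforms of the last iteration, labels.
#' @export
bootstrap_cca <- function(dataset_a, dataset_b,
                          segment_event = c("I", "G", "M", "H"),
                          trials_per_object = 20L, n_iter = 500L,
                          comparison = "custom", seed = 1L,
                          permute_objects = FALSE) {
  segment_event <- match.arg(segment_event)
  check_cca_eligible(dataset_a, trials_per_object)
  check_cca_eligible(dataset_b, trials_per_object)
  basis_a <- instantaneous_basis(dataset_a, tensor_col(dataset_a, segment_event, 0))
  basis_b <- instantaneous_basis(dataset_b, tensor_col(dataset_b, segment_event, 0))
  counts_a <- vapply(dataset_a$data, function(a) dim(a)[2], 1L)
  counts_b <- vapply(dataset_b$data, function(a) dim(a)[2], 1L)
  cc <- matrix(NA_real_, n_iter, 3)
  last <- NULL
  for (it in seq_len(n_iter)) {
    set.seed(derive_seed(seed, "cca", comparison, segment_event, it))
    sel_a <- lapply(counts_a, function(k) sample.int(k, trials_per_object, replace = TRUE))
    sel_b <- lapply(counts_b, function(k) sample.int(k, trials_per_object, replace = TRUE))
    L_A <- resampled_latents(dataset_a, segment_event, sel_a, basis_a)
    L_B <- resampled_latents(dataset_b, segment_event, sel_b, basis_b)
    if (permute_objects) {
      # derangements only: a relabeling with fixed points keeps part of the
      # true correspondence (and the first coefficient is blind to a single
      # swapped pair), so the null must displace every object
      perm <- sample(4)
      while (any(perm == 1:4)) perm <- sample(4)
      idx <- as.vector(outer(1:100, (perm - 1) * 100, `+`))
      L_B <- L_B[, idx, drop = FALSE]
    }
    last <- cca_align(L_A, L_B)
    cc[it, ] <- last$cc
  }
  structure(list(comparison = comparison, segment_event = segment_event,
                 cc = cc, mean = colMeans(cc), sd = apply(cc, 2, stats::sd),
                 M_A = last$M_A, M_B = last$M_B,
                 n_iter = n_iter, trials_per_object = trials_per_object,
                 permuted = permute_objects),
            class = "cca_outcome")
}

#' Within-group CCA: alignment consistency of one dataset with itself
#'
#' Per iteration, two independent resamples of `trials_per_object` trials
#' per object are drawn from the SAME dataset and aligned; the resulting
#' CC distribution measures trial-to-trial consistency of the co-modulation
#' pattern (e.g. MN:E/E, MN:O/O, AE:E/E).
#'
#' @param dataset An `aligned_tensor`.
#' @inheritParams bootstrap_cca
#' @return A `cca_outcome`.
#' @export
within_group_cca <- function(dataset, segment_event = c("I", "G", "M", "H"),
                             trials_per_object = 20L, n_iter = 500L,
                             comparison = "within", seed = 1L) {
  segment_event <- match.arg(segment_event)
  check_cca_eligible(dataset, trials_per_object)
  basis <- instantaneous_basis(dataset, tensor_col(dataset, segment_event, 0))
  counts <- vapply(dataset$data, function(a) dim(a)[2], 1L)
  cc <- matrix(NA_real_, n_iter, 3)
  last <- NULL
  for (it in seq_len(n_iter)) {
    set.seed(derive_seed(seed, "cca-within", comparison, segment_event, it))
    sel_a <- lapply(counts, function(k) sample.int(k, trials_per_object, replace = TRUE))
    sel_b <- lapply(counts, function(k) sample.int(k, trials_per_object, replace = TRUE))
    L_A <- resampled_latents(dataset, segment_event, sel_a, basis)
    L_B <- resampled_latents(dataset, segment_event, sel_b, basis)
    last <- cca_align(L_A, L_B)
    cc[it, ] <- last$cc
  }
  structure(list(comparison = comparison, segment_event = segment_event,
                 cc = cc, mean = colMeans(cc), sd = apply(cc, 2, stats::sd),
                 M_A = last$M_A, M_B = last$M_B,
                 n_iter = n_iter, trials_per_object = trials_per_object,
                 permuted = FALSE),
            class = "cca_outcome")
}

#' @export
print.cca_outcome <- function(x, ...) {
  cat(sprintf("<cca_outcome> %s @ %s: CC1=%.3f±%.3f CC2=%.3f±%.3f CC3=%.3f±%.3f (%d iter)\n",
              x$comparison, x$segment_event, x$mean[1], x$sd[1],
              x$mean[2], x$sd[2], x$mean[3], x$sd[3], x$n_iter))
  invisible(x)
}

#' Compare CCA outcome distributions across groups
#'
#' Per canonical coefficient, a Kruskal-Wallis rank test across the outcome
#' groups' iteration values, followed by pairwise Tukey honestly-significant-
#' difference post hoc comparisons.
#'
#' @param outcomes Named list of `cca_outcome`s for the same segment event.
#' @return List with `kruskal` (data.frame: coefficient, statistic, df, p)
#'   and `tukey` (per-coefficient pairwise comparison tables).
#' @export
compare_outcomes <- function(outcomes) {
  if (length(outcomes) < 2) stop("need at least two outcomes to compare")
  evs <- vapply(outcomes, function(o) o$segment_event, "")
  if (length(unique(evs)) != 1) stop("outcomes come from different segment events")
  labels <- names(outcomes) %||% vapply(outcomes, function(o) o$comparison, "")
  kr <- NULL; tk <- list()
  for (j in 1:3) {
    vals <- unlist(lapply(outcomes, function(o) o$cc[, j]), use.names = FALSE)
    grp <- factor(rep(labels, vapply(outcomes, function(o) nrow(o$cc), 1L)))
    kt <- stats::kruskal.test(vals, grp)
    kr <- rbind(kr, data.frame(coefficient = paste0("CC", j),
                               statistic = unname(kt$statistic),
                               df = unname(kt$parameter),
                               p_value = kt$p.value))
    tk[[paste0("CC", j)]] <- stats::TukeyHSD(stats::aov(vals ~ grp))$grp
  }
  list(kruskal = kr, tukey = tk)
}

#' Write CCA outcomes to CSV
#' @param outcomes Named list of `cca_outcome`s.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_cca_outcomes <- function(outcomes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  summ <- NULL
  for (nm in names(outcomes)) {
    o <- outcomes[[nm]]
    p <- file.path(dir, sprintf("cca_%s_%s.csv", gsub("[/:]", "-", nm), o$segment_event))
    data.table::fwrite(data.frame(iteration = seq_len(nrow(o$cc)),
                                  cc1 = o$cc[, 1], cc2 = o$cc[, 2], cc3 = o$cc[, 3]), p)
    paths <- c(paths, p)
    summ <- rbind(summ, data.frame(label = nm, event = o$segment_event,
                                   cc1_mean = o$mean[1], cc1_sd = o$sd[1],
                                   cc2_mean = o$mean[2], cc2_sd = o$sd[2],
                                   cc3_mean = o$mean[3], cc3_sd = o$sd[3]))
  }
  sp <- file.path(dir, "cca_summary.csv")
  data.table::fwrite(summ, sp)
  invisible(c(paths, sp))
}
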