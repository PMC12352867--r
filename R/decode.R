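#' Balance trial counts across objects
#'
#' To avoid class bias, every object contributes the minimum per-object
#' number of successful trials, sampled from the available trials with
#' replacement.
#'
#' @param counts Named (or 4-long) vector of available trial counts.
#' @return Named list of sampled trial indices, one vector per object, each
#'   of length `min(counts)`.
#' @export
balance_trials <- function(counts) {
  if (any(counts < 1)) stop("every object needs at least one trial")
  m <- min(counts)
  nm <- names(counts) %||% OBJECTS[seq_along(counts)]
  stats::setNames(lapply(counts, function(k) sample.int(k, m, replace = TRUE)), nm)
}

# Default 50 ms decoding grid: anchored at each snippet's start so grid
# times map cleanly through the time map.
decode_grid <- function(time_map, step = 50L) {
  cols <- integer(0)
  for (e in unique(time_map$event)) {
    off <- time_map$offset[time_map$event == e]
    want <- seq(min(off), max(off), by = step)
    cols <- c(cols, which(time_map$event == e & time_map$offset %in% want))
  }
  data.frame(col = cols, event = time_map$event[cols],
             offset = time_map$offset[cols])
}

# Assemble the balanced single-trial latent design at one subspace: project
# each selected trial's 100 x N segment into (W, center), z-scored per
# latent dimension with the training statistics.
project_trials <- function(segs, sel, W, center) {
  X <- array(0, c(100, sum(lengths(sel)), 3))
  y <- integer(dim(X)[2])
  grp <- character(dim(X)[2])
  b <- 0L
  for (oi in seq_along(OBJECTS)) {
    ob <- OBJECTS[oi]
    a <- segs$data[[ob]]
    for (k in sel[[ob]]) {
      b <- b + 1L
      X[, b, ] <- project_segment(matrix(a[, , k], 100), W, center)
      y[b] <- oi
      grp[b] <- paste(ob, k)
    }
  }
  list(X = X, y = y, group = grp)
}

# Split selected trials 40/60, stratified by object and disjoint at the
# distinct-trial level: each distinct resampled trial id is assigned wholly
# to train or test (duplicates follow their id), filling the train side of
# every object to ~40% of that object's expanded sample so classes stay
# balanced on both sides.
split_train_test <- function(group, y, train_frac = 0.4) {
  train <- rep(FALSE, length(group))
  for (cl in unique(y)) {
    k <- which(y == cl)
    ids <- sample(unique(group[k]))
    target <- train_frac * length(k)
    tot <- 0
    for (id in ids) {
      if (tot >= target) break
      sel <- k[group[k] == id]
      train[sel] <- TRUE
      tot <- tot + length(sel)
    }
    if (all(train[k]))  # degenerate: one distinct trial for this class
      train[k[group[k] != ids[1]]] <- FALSE
  }
  if (!any(train) || all(train))
    stop("degenerate train/test split; too few distinct trials")
  train
}

train_and_score <- function(X, y, train, classifier, seed, hidden, epochs, lr) {
  mu <- apply(X[, train, , drop = FALSE], 3, mean)
  sdv <- apply(X[, train, , drop = FALSE], 3, stats::sd) + 1e-8
  for (d in 1:3) X[, , d] <- (X[, , d] - mu[d]) / sdv[d]
  if (classifier == "lstm") {
    model <- train_bilstm(X[, train, , drop = FALSE], y[train], hidden = hidden,
                          epochs = epochs, lr = lr, seed = seed)
    pred <- predict_bilstm(model, X[, !train, , drop = FALSE])
  } else {
    flat <- t(apply(X, 2, as.numeric))  # B x (100*3)
    df <- data.frame(y = factor(y, levels = 1:4), flat)
    fit <- nnet::multinom(y ~ ., data = df[train, ], trace = FALSE,
                          MaxNWts = 5000, decay = 0.1)
    pred <- as.integer(stats::predict(fit, newdata = df[!train, ]))
  }
  mean(pred == y[!train])
}

#' Sliding-subspace decoding of object identity
#'
#' Single-trial 100 ms trajectory segments clipped at `segment_event` are
#' projected into the instantaneous 3D subspace at each 50 ms grid time and
#' classified into the four objects with a bidirectional LSTM (3 inputs, 20
#' hidden units per direction) trained on 40% of a balanced trial sample;
#' the remaining 60% are decoded. Repeated over `folds` balanced resamples.
#'
#' @param tensor `aligned_tensor` supplying the segments.
#' @param series `subspace_series` supplying the instantaneous bases, or
#'   `NULL` (default): the basis at each grid time is then re-estimated
#'   per fold from the training trials only, so that under the null
#'   (no object-dependent modulation) decoding accuracy is unbiased at
#'   chance — a basis fitted on all trials aligns with the realized noise
#'   separation of the condition means and inflates accuracy. Pass an
#'   explicit series for cross-projection (bases from another dataset).
#' @param segment_event `"I"`, `"G"`, `"M"` or `"H"`.
#' @param folds Bootstrap folds (default 10).
#' @param grid Optional data.frame from an explicit grid (columns
#'   `col`, `event`, `offset`) or vector of aligned columns; default the
#'   full 50 ms grid.
#' @param classifier `"lstm"` or `"linear"` (time-flattened multinomial
#'   logistic; architecture-robustness check).
#' @param seed Seed; folds and initializations derive substreams from it.
#' @param hidden,epochs,lr LSTM training hyperparameters.
#' @return A `decode_curve`: `grid`, `accuracy` (`folds x G`),
#'   `accuracy_mean`, `accuracy_sd`, `segment_event`, `pairing`.
#' @export
slide_decode <- function(tensor, series = NULL,
                         segment_event = c("I", "G", "M", "H"),
                         folds = 10L, grid = NULL,
                         classifier = c("lstm", "linear"), seed = 1L,
                         hidden = 20L, epochs = 100L, lr = 1e-3) {
  segment_event <- match.arg(segment_event)
  classifier <- match.arg(classifier)
  if (!is.null(series) &&
      !identical(tensor$time_map$event, series$time_map$event))
    stop("tensor and subspace series have mismatched time bases")
  if (is.null(grid)) grid <- decode_grid(tensor$time_map)
  if (!is.data.frame(grid))
    grid <- data.frame(col = grid, event = tensor$time_map$event[grid],
                       offset = tensor$time_map$offset[grid])
  segs <- clip_segments(tensor, segment_event, "single-trial")
  counts <- vapply(segs$data, function(a) dim(a)[3], 1L)
  acc <- matrix(NA_real_, folds, nrow(grid))
  for (f in seq_len(folds)) {
    set.seed(derive_seed(seed, "decode", segment_event, f))
    sel <- balance_trials(counts)
    for (gidx in seq_len(nrow(grid))) {
      g <- grid$col[gidx]
      set.seed(derive_seed(seed, "decode-split", segment_event, f, g))
      if (is.null(series)) {
        # estimate the instantaneous basis from training trials only
        grp0 <- unlist(lapply(OBJECTS, function(ob)
          paste(ob, sel[[ob]])), use.names = FALSE)
        y0 <- rep(1:4, each = length(sel[[1]]))
        train <- split_train_test(grp0, y0)
        tr_sel <- lapply(seq_along(OBJECTS), function(oi) {
          k <- which(y0 == oi)
          sel[[OBJECTS[oi]]][train[k]]
        })
        names(tr_sel) <- OBJECTS
        ib <- instantaneous_basis(tensor, g, tr_sel)
        W <- ib$W; center <- ib$center
        pt <- project_trials(segs, sel, W, center)
      } else {
        pt <- project_trials(segs, sel, series$bases[, , g], series$centers[, g])
        train <- split_train_test(pt$group, pt$y)
      }
      acc[f, gidx] <- train_and_score(pt$X, pt$y, train, classifier,
                                      seed = derive_seed(seed, "lstm", segment_event, f, g),
                                      hidden, epochs, lr)
    }
  }
  structure(list(grid = grid, accuracy = acc,
                 accuracy_mean = colMeans(acc),
                 accuracy_sd = apply(acc, 2, stats::sd),
                 segment_event = segment_event,
                 pairing = if (identical(tensor$context, series$context))
                   "within" else "cross",
                 classifier = classifier, folds = folds),
            class = "decode_curve")
}

#' Chance decoding accuracy from random subspaces
#'
#' Projects the balanced single-trial segments into uniformly random 3D
#' subspaces (Gaussian-QR), trains the same classifier, and classifies the
#' held-out 60%, repeated `n_rand` times; the resulting mean and SD define
#' the chance band for [slide_decode()] curves.
#'
#' @inheritParams slide_decode
#' @param n_rand Number of random-subspace repetitions (default 500).
#' @return List with `mean`, `sd`, `samples`.
#' @export
chance_decode <- function(tensor, segment_event = c("I", "G", "M", "H"),
                          n_rand = 500L, classifier = c("lstm", "linear"),
                          seed = 1L, hidden = 20L, epochs = 100L, lr = 1e-3) {
  segment_event <- match.arg(segment_event)
  classifier <- match.arg(classifier)
  segs <- clip_segments(tensor, segment_event, "single-trial")
  counts <- vapply(segs$data, function(a) dim(a)[3], 1L)
  N <- length(tensor$unit_ids)
  accs <- vapply(seq_len(n_rand), function(r) {
    set.seed(derive_seed(seed, "chance-decode", segment_event, r))
    sel <- balance_trials(counts)
    W <- random_frame(N, 3)
    pt <- project_trials(segs, sel, W, 0)
    train <- split_train_test(pt$group, pt$y)
    train_and_score(pt$X, pt$y, train, classifier,
                    seed = derive_seed(seed, "chance-lstm", segment_event, r),
                    hidden, epochs, lr)
  }, numeric(1))
  list(mean = mean(accs), sd = stats::sd(accs), samples = accs)
}

#' Cross-context decoding
#'
#' Segments from one context projected into the other context's
#' instantaneous subspace series; identical to [slide_decode()] otherwise.
#'
#' @param tensor_a `aligned_tensor` supplying segments (context A).
#' @param series_b `subspace_series` of context B.
#' @inheritParams slide_decode
#' @return A `decode_curve` with `pairing = "cross"`.
#' @export
cross_project_decode <- function(tensor_a, series_b, segment_event, ...) {
  if (!identical(tensor_a$time_map$event, series_b$time_map$event))
    stop("contexts have mismatched time bases")
  slide_decode(tensor_a, series_b, segment_event, ...)
}

#' Write a decode curve to CSV
#' @param curve A `decode_curve`.
#' @param path Output path.
#' @param chance Optional result of [chance_decode()].
#' @return `path`, invisibly.
#' @export
write_decode_curve <- function(curve, path, chance = NULL) {
  df <- data.frame(grid_time_ms = curve$grid$col, event = curve$grid$event,
                   offset_ms = curve$grid$offset,
                   acc_mean = curve$accuracy_mean, acc_sd = curve$accuracy_sd,
                   chance_mean = chance$mean %||% NA_real_,
                   chance_sd = chance$sd %||% NA_real_)
  data.table::fwrite(df, path)
  invisible(path)
}
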