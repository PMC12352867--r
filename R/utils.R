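#' @keywords internal
"_PACKAGE"

# Canonical orderings used throughout the pipeline.
OBJECTS <- c("sphere", "button", "coax", "perp")
CONTEXTS <- c("execution", "observation")
EVENTS <- c("start", "instruction_on", "instruction_off", "go",
            "move_on", "hold_on", "hold_off", "end")
# The four alignment events: instruction onset, go cue, movement onset, hold.
ALIGN_EVENTS <- c(I = "instruction_on", G = "go", M = "move_on", H = "hold_on")

#' Derive a reproducible substream seed from a global seed and a label
#'
#' All stochastic stages draw their seeds through this helper so that a single
#' global seed fans out into named, order-independent substreams (one per
#' stage/fold/iteration). Uses a 32-bit FNV-1a hash of `paste(seed, label)`,
#' masked to a non-negative R integer.
#'
#' @param seed Integer global seed.
#' @param ... Labels (coerced to character) naming the substream.
#' @return A single integer in `[0, 2^31 - 1]`, suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(label)
  # polynomial rolling hash mod the Mersenne prime 2^31 - 1, in exact
  # double arithmetic (all intermediates < 2^53)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Draw a uniformly random orthonormal n x k frame (Gaussian QR)
#'
#' Columns are an orthonormal basis of a k-dimensional subspace drawn from the
#' rotation-invariant (Haar) distribution, obtained by QR decomposition of a
#' standard Gaussian matrix with the sign convention diag(R) > 0.
#'
#' @param n Ambient dimension.
#' @param k Subspace dimension (k <= n).
#' @return An `n x k` matrix with orthonormal columns.
#' @export
random_frame <- function(n, k) {
  stopifnot(n >= k)
  qr_pos(matrix(stats::rnorm(n * k), n, k))$Q
}

# Economy QR with positive diagonal of R (deterministic sign convention).
qr_pos <- function(M) {
  d <- qr(M)
  Q <- qr.Q(d)
  R <- qr.R(d)
  s <- sign(diag(R))
  s[s == 0] <- 1
  list(Q = sweep(Q, 2, s, `*`), R = sweep(R, 1, s, `*`))
}

# Gram-Schmidt completion: extend the (possibly empty / rank-deficient)
# column span of `B` to an orthonormal n x k frame using the lowest-index
# canonical directions orthogonalized against the span. Deterministic.
complete_frame <- function(B, n, k) {
  cols <- list()
  if (!is.null(B) && ncol(B) > 0) {
    for (j in seq_len(ncol(B))) {
      v <- B[, j]
      for (u in cols) v <- v - sum(u * v) * u
      nv <- sqrt(sum(v^2))
      if (nv > 1e-10) cols[[length(cols) + 1L]] <- v / nv
    }
  }
  i <- 1L
  while (length(cols) < k) {
    if (i > n) stop("cannot complete frame: ambient dimension too small")
    v <- numeric(n)
    v[i] <- 1
    for (u in cols) v <- v - sum(u * v) * u
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) cols[[length(cols) + 1L]] <- v / nv
    i <- i + 1L
  }
  do.call(cbind, cols[seq_len(k)])
}

# Check that a basis has orthonormal columns within tolerance.
assert_orthonormal <- function(W, tol = 1e-8, what = "basis") {
  G <- crossprod(W)
  if (max(abs(G - diag(ncol(W)))) > tol)
    stop(sprintf("%s is not orthonormal (Gram deviation %.3g > %.3g)",
                 what, max(abs(G - diag(ncol(W)))), tol))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
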