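# Compact bidirectional LSTM sequence classifier in base R.
#
# Architecture (fixed by the analysis design): D inputs per time step, H
# hidden units per direction in a single bidirectional LSTM layer, final
# forward and backward hidden states concatenated into a 2H vector, linear
# map to C classes, softmax. Trained with Adam on cross-entropy via
# backpropagation through time. Sizes here are tiny (D=3, H=20, T=100), so
# batched dense matrix algebra in R is adequate.

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(input = 3L, hidden = 20L, classes = 4L, seed = 1L) {
  set.seed(seed)
  gl <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  dir_params <- function() {
    b <- numeric(4 * hidden)
    b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias
    list(Wx = gl(input, 4 * hidden), Wh = gl(hidden, 4 * hidden), b = b)
  }
  list(fwd = dir_params(), bwd = dir_params(),
       Wout = gl(2 * hidden, classes), bout = numeric(classes),
       input = input, hidden = hidden, classes = classes)
}

# One direction forward pass. X: T x B x D array (already time-reversed for
# the backward direction). Returns final hidden state and caches for BPTT.
lstm_forward_dir <- function(X, p, hidden) {
  Tn <- dim(X)[1]; B <- dim(X)[2]; D <- dim(X)[3]
  XW <- matrix(aperm(X, c(2, 1, 3)), B * Tn, D) %*% p$Wx  # (B*T) x 4H
  H <- matrix(0, B, hidden); C <- matrix(0, B, hidden)
  gi <- 1:hidden; gf <- hidden + gi; gg <- 2 * hidden + gi; go <- 3 * hidden + gi
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    G <- XW[(t - 1) * B + seq_len(B), , drop = FALSE] + H %*% p$Wh +
      matrix(p$b, B, 4 * hidden, byrow = TRUE)
    i <- sigmoid(G[, gi, drop = FALSE]); f <- sigmoid(G[, gf, drop = FALSE])
    g <- tanh(G[, gg, drop = FALSE]);    o <- sigmoid(G[, go, drop = FALSE])
    Cprev <- C; Hprev <- H
    C <- f * C + i * g
    H <- o * tanh(C)
    cache[[t]] <- list(i = i, f = f, g = g, o = o, C = C, Cprev = Cprev,
                       Hprev = Hprev)
  }
  list(H = H, cache = cache)
}

# BPTT for one direction given the gradient at the final hidden state.
lstm_backward_dir <- function(X, p, fw, dH_T, hidden) {
  Tn <- dim(X)[1]; B <- dim(X)[2]; D <- dim(X)[3]
  gi <- 1:hidden; gf <- hidden + gi; gg <- 2 * hidden + gi; go <- 3 * hidden + gi
  dWx <- matrix(0, D, 4 * hidden); dWh <- matrix(0, hidden, 4 * hidden)
  db <- numeric(4 * hidden)
  dH <- dH_T; dC <- matrix(0, B, hidden)
  for (t in rev(seq_len(Tn))) {
    cc <- fw$cache[[t]]
    tc <- tanh(cc$C)
    do_ <- dH * tc
    dC <- dC + dH * cc$o * (1 - tc^2)
    di <- dC * cc$g
    dg <- dC * cc$i
    df <- dC * cc$Cprev
    dCprev <- dC * cc$f
    dG <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2), do_ * cc$o * (1 - cc$o))
    Xt <- matrix(X[t, , ], B, D)
    dWx <- dWx + crossprod(Xt, dG)
    dWh <- dWh + crossprod(cc$Hprev, dG)
    db <- db + colSums(dG)
    dH <- dG %*% t(p$Wh)
    dC <- dCprev
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

# Loss and gradients for a batch. X: T x B x D; y: integer classes 1..C.
bilstm_loss_grad <- function(params, X, y, grad = TRUE) {
  hidden <- params$hidden
  B <- dim(X)[2]
  Xrev <- X[rev(seq_len(dim(X)[1])), , , drop = FALSE]
  fw <- lstm_forward_dir(X, params$fwd, hidden)
  bw <- lstm_forward_dir(Xrev, params$bwd, hidden)
  Hcat <- cbind(fw$H, bw$H)
  logits <- Hcat %*% params$Wout + matrix(params$bout, B, params$classes, byrow = TRUE)
  logits <- logits - apply(logits, 1, max)
  P <- exp(logits); P <- P / rowSums(P)
  loss <- -mean(log(pmax(P[cbind(seq_len(B), y)], 1e-12)))
  if (!grad) return(list(loss = loss, probs = P))
  Y <- matrix(0, B, params$classes); Y[cbind(seq_len(B), y)] <- 1
  dlogits <- (P - Y) / B
  dWout <- crossprod(Hcat, dlogits)
  dbout <- colSums(dlogits)
  dHcat <- dlogits %*% t(params$Wout)
  gfwd <- lstm_backward_dir(X, params$fwd, fw, dHcat[, 1:hidden, drop = FALSE], hidden)
  gbwd <- lstm_backward_dir(Xrev, params$bwd, bw,
                            dHcat[, hidden + 1:hidden, drop = FALSE], hidden)
  list(loss = loss, probs = P,
       grads = list(fwd = gfwd, bwd = gbwd, Wout = dWout, bout = dbout))
}

# Adam update over the nested parameter list.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(pth) {
    g <- grads[[pth]]
    if (is.list(g)) {
      for (nm in names(g)) upd(c(pth, nm))
      return(invisible())
    }
    key <- paste(pth, collapse = ".")
    if (is.null(state$m[[key]])) {
      state$m[[key]] <<- g * 0
      state$v[[key]] <<- g * 0
    }
    state$m[[key]] <<- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <<- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / (1 - beta1^state$t)
    vhat <- state$v[[key]] / (1 - beta2^state$t)
    params[[pth]] <<- params[[pth]] - lr * mhat / (sqrt(vhat) + eps)
  }
  for (nm in c("fwd", "bwd")) for (p2 in c("Wx", "Wh", "b")) upd(c(nm, p2))
  upd("Wout"); upd("bout")
  list(params = params, state = state)
}

#' Train the bidirectional LSTM object classifier
#'
#' A 3-input, `hidden`-unit-per-direction bidirectional LSTM over
#' 100-step latent trajectory segments with a 4-class softmax readout,
#' trained with Adam on cross-entropy. Training stops early when the
#' training loss plateaus.
#'
#' @param X `T x B x D` array of training sequences.
#' @param y Integer class labels (1-based), length `B`.
#' @param hidden Hidden units per direction (default 20).
#' @param epochs Maximum epochs (default 100).
#' @param lr Learning rate (default 1e-3).
#' @param batch Minibatch size (default 16).
#' @param seed Seed for initialization and shuffling.
#' @param patience,min_delta Early stopping: stop after `patience` epochs
#'   without a `min_delta` improvement of the best training loss.
#' @return A `bilstm` model object for [predict_bilstm()].
#' @export
train_bilstm <- function(X, y, hidden = 20L, epochs = 100L, lr = 1e-3,
                         batch = 16L, seed = 1L, patience = 8L,
                         min_delta = 1e-3) {
  y <- as.integer(y)
  classes <- max(4L, max(y))
  params <- lstm_init(dim(X)[3], hidden, classes, seed = seed)
  state <- list(t = 0, m = list(), v = list())
  B <- dim(X)[2]
  best <- Inf; wait <- 0L
  set.seed(seed + 1L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(B)
    ep_loss <- 0
    for (start in seq(1, B, by = batch)) {
      idx <- ord[start:min(start + batch - 1, B)]
      lg <- bilstm_loss_grad(params, X[, idx, , drop = FALSE], y[idx])
      st <- adam_step(params, lg$grads, state, lr)
      params <- st$params; state <- st$state
      ep_loss <- ep_loss + lg$loss * length(idx)
    }
    ep_loss <- ep_loss / B
    if (ep_loss < best - min_delta) { best <- ep_loss; wait <- 0L }
    else { wait <- wait + 1L; if (wait >= patience) break }
  }
  structure(list(params = params, hidden = hidden, epochs_run = ep),
            class = "bilstm")
}

#' Classify sequences with a trained bidirectional LSTM
#' @param model A `bilstm` from [train_bilstm()].
#' @param X `T x B x D` array.
#' @return Integer vector of predicted classes (1-based).
#' @export
predict_bilstm <- function(model, X) {
  out <- bilstm_loss_grad(model$params, X, rep(1L, dim(X)[2]), grad = FALSE)
  max.col(out$probs, ties.method = "first")
}
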