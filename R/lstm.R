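# Two-layer LSTM internals: initialization, fused forward/backward (BPTT),
# single-step forward for sampling, and Adam. Everything is plain base-R
# matrix algebra; gate columns are ordered [input | forget | cell | output].
#
# Parameter shapes (U = units, V = vocabulary size):
#   lstm1: Wx1 (V x 4U), Wh1 (U x 4U), b1 (4U)   -> 4*(U*(V+U)+U) params
#   lstm2: Wx2 (U x 4U), Wh2 (U x 4U), b2 (4U)   -> 4*(U*(U+U)+U) params
#   dense: Wd  (U x V),  bd  (V)                 -> U*V+V params

PARAM_LAYER <- c(Wx1 = "lstm1", Wh1 = "lstm1", b1 = "lstm1",
                 Wx2 = "lstm2", Wh2 = "lstm2", b2 = "lstm2",
                 Wd = "dense", bd = "dense")

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# forget-gate biases start at 1 (standard LSTM practice)
lstm_init_params <- function(units, V) {
  U <- units
  b1 <- numeric(4 * U); b1[(U + 1):(2 * U)] <- 1
  b2 <- numeric(4 * U); b2[(U + 1):(2 * U)] <- 1
  list(Wx1 = glorot(V, 4 * U), Wh1 = glorot(U, 4 * U), b1 = b1,
       Wx2 = glorot(U, 4 * U), Wh2 = glorot(U, 4 * U), b2 = b2,
       Wd = glorot(U, V), bd = numeric(V))
}

layer_param_counts <- function(units, V) {
  U <- units
  c(lstm1 = 4 * (U * (V + U) + U),
    lstm2 = 4 * (U * (U + U) + U),
    dense = U * V + V)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# pack a list of 1-based index sequences (G...E) into input/target/mask
# matrices: inputs are positions 1..L-1, targets 2..L, mask 0 after the pad
pack_batch <- function(seqs) {
  lens <- lengths(seqs) - 1L
  Tm <- max(lens)
  B <- length(seqs)
  X <- matrix(1L, B, Tm)
  Y <- matrix(1L, B, Tm)
  M <- matrix(0, B, Tm)
  for (b in seq_len(B)) {
    s <- seqs[[b]]
    l <- lens[b]
    X[b, seq_len(l)] <- s[seq_len(l)]
    Y[b, seq_len(l)] <- s[1L + seq_len(l)]
    M[b, seq_len(l)] <- 1
  }
  list(X = X, Y = Y, M = M)
}

lstm_gates <- function(z, U) {
  list(i = sigmoid(z[, 1:U, drop = FALSE]),
       f = sigmoid(z[, (U + 1):(2 * U), drop = FALSE]),
       g = tanh(z[, (2 * U + 1):(3 * U), drop = FALSE]),
       o = sigmoid(z[, (3 * U + 1):(4 * U), drop = FALSE]))
}

# one fused forward+backward pass over a packed batch; returns masked-mean
# loss, top-1 correct count, unmasked position count, and (optionally) grads.
# Dropout (training only) uses the current RNG state.
lstm_batch_pass <- function(params, batch, units, dropout = 0,
                            training = FALSE, want_grads = FALSE) {
  U <- units
  X <- batch$X; Y <- batch$Y; M <- batch$M
  B <- nrow(X); Tm <- ncol(X)
  V <- nrow(params$Wx1)
  n_pos <- sum(M)

  h1 <- matrix(0, B, U); c1 <- matrix(0, B, U)
  h2 <- matrix(0, B, U); c2 <- matrix(0, B, U)
  cache <- if (want_grads) vector("list", Tm)
  loss <- 0; correct <- 0
  grads <- NULL

  keep <- 1 - dropout
  for (t in seq_len(Tm)) {
    xt <- X[, t]
    z1 <- params$Wx1[xt, , drop = FALSE] + h1 %*% params$Wh1 +
      rep(params$b1, each = B)
    g1 <- lstm_gates(z1, U)
    c1_prev <- c1
    c1 <- g1$f * c1 + g1$i * g1$g
    tc1 <- tanh(c1)
    h1_raw <- g1$o * tc1
    if (training && dropout > 0) {
      dmask <- matrix((stats::runif(B * U) < keep) / keep, B, U)
      h1d <- h1_raw * dmask
    } else {
      dmask <- NULL
      h1d <- h1_raw
    }
    h1 <- h1_raw  # undropped output feeds layer 1's own recurrence
    z2 <- h1d %*% params$Wx2 + h2 %*% params$Wh2 + rep(params$b2, each = B)
    g2 <- lstm_gates(z2, U)
    c2_prev <- c2
    c2 <- g2$f * c2 + g2$i * g2$g
    tc2 <- tanh(c2)
    h2_prev <- h2
    h2 <- g2$o * tc2
    p <- softmax_rows(h2 %*% params$Wd + rep(params$bd, each = B))

    mt <- M[, t]
    py <- p[cbind(seq_len(B), Y[, t])]
    loss <- loss - sum(log(pmax(py, 1e-12)) * mt)
    correct <- correct + sum((max.col(p, ties.method = "first") == Y[, t]) * mt)

    if (want_grads) {
      cache[[t]] <- list(xt = xt, g1 = g1, c1_prev = c1_prev, c1 = c1,
                         tc1 = tc1, h1_raw = h1_raw, dmask = dmask,
                         h1d = h1d, g2 = g2, c2_prev = c2_prev, c2 = c2,
                         tc2 = tc2, h2_prev = h2_prev, h2 = h2, p = p,
                         h1_prev = if (t == 1) matrix(0, B, U) else
                           cache[[t - 1]]$h1_raw)
    }
  }

  if (want_grads) {
    z <- function(nr, nc) matrix(0, nr, nc)
    grads <- list(Wx1 = z(V, 4 * U), Wh1 = z(U, 4 * U), b1 = numeric(4 * U),
                  Wx2 = z(U, 4 * U), Wh2 = z(U, 4 * U), b2 = numeric(4 * U),
                  Wd = z(U, V), bd = numeric(V))
    dh1_next <- z(B, U); dc1_next <- z(B, U)
    dh2_next <- z(B, U); dc2_next <- z(B, U)
    for (t in rev(seq_len(Tm))) {
      cc <- cache[[t]]
      dlogit <- cc$p
      dlogit[cbind(seq_len(B), Y[, t])] <-
        dlogit[cbind(seq_len(B), Y[, t])] - 1
      dlogit <- dlogit * (M[, t] / n_pos)
      grads$Wd <- grads$Wd + crossprod(cc$h2, dlogit)
      grads$bd <- grads$bd + colSums(dlogit)
      dh2 <- dlogit %*% t(params$Wd) + dh2_next
      # layer 2 cell backward
      do2 <- dh2 * cc$tc2
      dc2 <- dh2 * cc$g2$o * (1 - cc$tc2^2) + dc2_next
      di2 <- dc2 * cc$g2$g
      df2 <- dc2 * cc$c2_prev
      dg2 <- dc2 * cc$g2$i
      dz2 <- cbind(di2 * cc$g2$i * (1 - cc$g2$i),
                   df2 * cc$g2$f * (1 - cc$g2$f),
                   dg2 * (1 - cc$g2$g^2),
                   do2 * cc$g2$o * (1 - cc$g2$o))
      grads$Wx2 <- grads$Wx2 + crossprod(cc$h1d, dz2)
      grads$Wh2 <- grads$Wh2 + crossprod(cc$h2_prev, dz2)
      grads$b2 <- grads$b2 + colSums(dz2)
      dh2_next <- dz2 %*% t(params$Wh2)
      dc2_next <- dc2 * cc$g2$f
      dh1d <- dz2 %*% t(params$Wx2)
      dh1 <- if (is.null(cc$dmask)) dh1d else dh1d * cc$dmask
      dh1 <- dh1 + dh1_next
      # layer 1 cell backward
      do1 <- dh1 * cc$tc1
      dc1 <- dh1 * cc$g1$o * (1 - cc$tc1^2) + dc1_next
      di1 <- dc1 * cc$g1$g
      df1 <- dc1 * cc$c1_prev
      dg1 <- dc1 * cc$g1$i
      dz1 <- cbind(di1 * cc$g1$i * (1 - cc$g1$i),
                   df1 * cc$g1$f * (1 - cc$g1$f),
                   dg1 * (1 - cc$g1$g^2),
                   do1 * cc$g1$o * (1 - cc$g1$o))
      agg <- rowsum(dz1, group = cc$xt)
      rows <- as.integer(rownames(agg))
      grads$Wx1[rows, ] <- grads$Wx1[rows, ] + agg
      grads$Wh1 <- grads$Wh1 + crossprod(cc$h1_prev, dz1)
      grads$b1 <- grads$b1 + colSums(dz1)
      dh1_next <- dz1 %*% t(params$Wh1)
      dc1_next <- dc1 * cc$g1$f
    }
  }

  list(loss_sum = loss, n_pos = n_pos, correct = correct, grads = grads)
}

# evaluate mean loss / accuracy over a corpus of index sequences
lstm_evaluate <- function(params, seqs, units, batch_size = 512) {
  loss <- 0; n <- 0; correct <- 0
  for (ix in split(seq_along(seqs), ceiling(seq_along(seqs) / batch_size))) {
    batch <- pack_batch(seqs[ix])
    r <- lstm_batch_pass(params, batch, units)
    loss <- loss + r$loss_sum; n <- n + r$n_pos; correct <- correct + r$correct
  }
  c(loss = loss / n, acc = correct / n)
}

# one sampling step for B parallel chains: returns next-token probabilities
# and the updated state
lstm_step <- function(params, xt, state, units) {
  U <- units
  B <- length(xt)
  z1 <- params$Wx1[xt, , drop = FALSE] + state$h1 %*% params$Wh1 +
    rep(params$b1, each = B)
  g1 <- lstm_gates(z1, U)
  c1 <- g1$f * state$c1 + g1$i * g1$g
  h1 <- g1$o * tanh(c1)
  z2 <- h1 %*% params$Wx2 + state$h2 %*% params$Wh2 + rep(params$b2, each = B)
  g2 <- lstm_gates(z2, U)
  c2 <- g2$f * state$c2 + g2$i * g2$g
  h2 <- g2$o * tanh(c2)
  p <- softmax_rows(h2 %*% params$Wd + rep(params$bd, each = B))
  list(p = p, state = list(h1 = h1, c1 = c1, h2 = h2, c2 = c2))
}

lstm_zero_state <- function(B, units) {
  z <- matrix(0, B, units)
  list(h1 = z, c1 = z, h2 = z, c2 = z)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

# one Adam update restricted to trainable layers; frozen layers are left
# bit-identical (their gradients are simply never applied)
adam_update <- function(params, grads, opt, trainable,
                        lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  opt$t <- opt$t + 1
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    if (!trainable[[PARAM_LAYER[[nm]]]]) next
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / corr1
    vhat <- opt$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}
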