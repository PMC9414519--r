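# Straight-line, loop-based reference implementation of the composed
# forward pass (conv encoding, segment attention, bidirectional LSTM,
# fully connected transform, channel attention, softmax head), written
# independently of the package's model code. Valid for configurations with
# batch normalization off and pooling disabled (pool_width = 1); used as
# the equivalence oracle on tiny shapes.

oracle_conv_layer <- function(x, W, b, stride) {
  # x: len x cin matrix; W: k x cin x U; returns lout x U
  k <- dim(W)[1]; cin <- dim(W)[2]; U <- dim(W)[3]
  lout <- (nrow(x) - k) %/% stride + 1L
  y <- matrix(0, lout, U)
  for (u in seq_len(U)) {
    for (j in seq_len(lout)) {
      acc <- b[u]
      for (c in seq_len(cin)) {
        for (kk in seq_len(k)) {
          acc <- acc + x[(j - 1L) * stride + kk, c] * W[kk, c, u]
        }
      }
      y[j, u] <- acc
    }
  }
  y
}

oracle_conv_branch <- function(seg, branch, stride) {
  x <- matrix(seg, ncol = 1)
  for (l in seq_along(branch)) {
    x <- oracle_conv_layer(x, branch[[l]]$W, branch[[l]]$b, stride)
    x <- pmax(x, 0) * (x > -Inf)  # ReLU
    x <- matrix(x, nrow = nrow(x))
  }
  x  # J_conv x U
}

oracle_softmax <- function(s) exp(s) / sum(exp(s))

oracle_attention <- function(feat, know, W, V, b) {
  # feat: U x M; know: length M; W: (U+1) x D
  M <- ncol(feat)
  scores <- numeric(M)
  for (m in seq_len(M)) {
    col <- c(feat[, m], know[m])
    hidden <- as.numeric(t(W) %*% col) + b
    scores[m] <- sum(V * hidden)
  }
  oracle_softmax(scores)
}

oracle_lstm_dir <- function(xs, W, Uh, b) {
  # xs: list of M input vectors; returns H x M matrix of hidden states
  H <- length(b) / 4L
  h <- rep(0, H); cc <- rep(0, H)
  out <- matrix(0, H, length(xs))
  sig <- function(v) 1 / (1 + exp(-v))
  for (t in seq_along(xs)) {
    a <- as.numeric(W %*% xs[[t]] + Uh %*% h + b)
    ig <- sig(a[1:H])
    fg <- sig(a[H + 1:H])
    og <- sig(a[2 * H + 1:H])
    gg <- tanh(a[3 * H + 1:H])
    cc <- fg * cc + ig * gg
    h <- og * tanh(cc)
    out[, t] <- h
  }
  out
}

oracle_bilstm <- function(of, layers) {
  # of: U x M; returns (2H) x M after stacking all layers
  M <- ncol(of)
  x <- lapply(seq_len(M), function(m) of[, m])
  for (l in seq_along(layers)) {
    fwd <- oracle_lstm_dir(x, layers[[l]]$fw$W, layers[[l]]$fw$U,
                           layers[[l]]$fw$b)
    bwd <- oracle_lstm_dir(rev(x), layers[[l]]$bw$W, layers[[l]]$bw$U,
                           layers[[l]]$bw$b)
    bwd <- bwd[, rev(seq_len(M)), drop = FALSE]
    x <- lapply(seq_len(M), function(m) c(fwd[, m], bwd[, m]))
  }
  do.call(cbind, x)
}

# Composed forward pass for one window; model must have batchnorm = FALSE,
# pool_width = 1, variant "mvha". Inputs are the per-channel segment
# matrices plus knowledge features and covariates.
oracle_forward <- function(model, segs, afl, atr, cov) {
  p <- model$params
  CH <- length(segs)
  M <- model$M
  alpha <- vector("list", CH)
  zs <- vector("list", CH)
  for (ci in seq_len(CH)) {
    O <- matrix(0, model$config$num_filters, M)
    for (m in seq_len(M)) {
      P <- oracle_conv_branch(segs[[ci]][, m], p$conv[[ci]],
                              model$config$conv_stride)
      O[, m] <- colSums(P)   # o = sum over the J positions
    }
    alpha[[ci]] <- oracle_attention(O, afl[[ci]], p$fattn[[ci]]$W,
                                    p$fattn[[ci]]$V, p$fattn[[ci]]$b)
    of <- O * matrix(alpha[[ci]], nrow(O), M, byrow = TRUE)
    Hmat <- oracle_bilstm(of, p$lstm[[ci]])
    zs[[ci]] <- rowSums(Hmat)
  }
  Z <- do.call(cbind, zs)
  X <- t(p$fc$Wz) %*% Z
  for (cc in seq_len(ncol(X))) X[, cc] <- X[, cc] + p$fc$bz
  tscores <- numeric(CH)
  for (cc in seq_len(CH)) {
    col <- c(X[, cc], atr[cc])
    tscores[cc] <- sum(p$tattn$V * (as.numeric(t(p$tattn$W) %*% col) +
                                      p$tattn$b))
  }
  beta <- oracle_softmax(tscores)
  d <- rep(0, nrow(X))
  for (cc in seq_len(CH)) d <- d + beta[cc] * X[, cc]
  logits <- as.numeric(p$head$Why %*% d + p$head$Wtry %*% cov + p$head$by)
  list(probs = oracle_softmax(logits), alpha = alpha, beta = beta,
       logits = logits)
}
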