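# Internal neural-network primitives. Conventions:
#   * convolutional activations are arrays (length, feature, sample),
#   * everything after the encoder keeps the batch in columns,
#   * every *_fw returns the caches its *_bw needs; no global state.
# Gradients are exact analytic derivatives (validated by finite-difference
# tests); parameters never alias between forward and backward.

nn_softmax_cols <- function(s) {
  s <- sweep(s, 2, apply(s, 2, max), "-")
  e <- exp(s)
  sweep(e, 2, colSums(e), "/")
}

# ---- batch normalization over (L, U, N): statistics per feature u --------

bn_fw <- function(x, gamma, beta, run_m, run_v, train, momentum = 0.1,
                  eps = 1e-5) {
  U <- dim(x)[2]
  y <- x
  xhat <- if (train) x else NULL
  invstd <- numeric(U)
  for (u in seq_len(U)) {
    xu <- x[, u, , drop = FALSE]
    if (train) {
      m <- mean(xu)
      v <- mean((xu - m)^2)
      run_m[u] <- (1 - momentum) * run_m[u] + momentum * m
      run_v[u] <- (1 - momentum) * run_v[u] + momentum * v
    } else {
      m <- run_m[u]
      v <- run_v[u]
    }
    invstd[u] <- 1 / sqrt(v + eps)
    xh <- (xu - m) * invstd[u]
    if (train) xhat[, u, ] <- xh
    y[, u, ] <- gamma[u] * xh + beta[u]
  }
  list(y = y, xhat = xhat, invstd = invstd, run_m = run_m, run_v = run_v)
}

bn_bw <- function(gy, xhat, invstd, gamma) {
  U <- dim(gy)[2]
  gx <- gy
  ggamma <- numeric(U)
  gbeta <- numeric(U)
  for (u in seq_len(U)) {
    g <- gy[, u, , drop = FALSE]
    xh <- xhat[, u, , drop = FALSE]
    ggamma[u] <- sum(g * xh)
    gbeta[u] <- sum(g)
    gx[, u, ] <- gamma[u] * invstd[u] *
      (g - mean(g) - xh * mean(g * xh))
  }
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# ---- convolutional branch: [conv -> (bn) -> relu -> maxpool] x layers ----

conv_branch_fw <- function(x, branch, bn_state, cfg, train = FALSE,
                           keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(branch)) else NULL
  for (l in seq_along(branch)) {
    p <- branch[[l]]
    y <- cpp_conv1d_fw(x, p$W, p$b, cfg$conv_stride)
    cache <- if (keep_cache) list(x_in = x) else NULL
    if (cfg$batchnorm) {
      bn <- bn_fw(y, p$gamma, p$beta, bn_state[[l]]$m, bn_state[[l]]$v, train)
      bn_state[[l]]$m <- bn$run_m
      bn_state[[l]]$v <- bn$run_v
      if (keep_cache) {
        cache$xhat <- bn$xhat
        cache$invstd <- bn$invstd
      }
      y <- bn$y
    }
    mask <- y > 0
    y <- y * mask
    if (keep_cache) cache$mask <- mask
    if (cfg$pool_width > 1L) {
      pool <- cpp_maxpool1d_fw(y, cfg$pool_width, cfg$pool_stride)
      if (keep_cache) {
        cache$pool_idx <- pool$idx
        cache$pool_lin <- dim(y)[1]
      }
      y <- pool$y
    }
    if (keep_cache) caches[[l]] <- cache
    x <- y
  }
  list(out = x, caches = caches, bn_state = bn_state)
}

conv_branch_bw <- function(gy, caches, branch, cfg) {
  grads <- vector("list", length(branch))
  for (l in rev(seq_along(branch))) {
    p <- branch[[l]]
    cache <- caches[[l]]
    if (cfg$pool_width > 1L) {
      gy <- cpp_maxpool1d_bw(gy, cache$pool_idx, cache$pool_lin)
    }
    gy <- gy * cache$mask
    g <- list()
    if (cfg$batchnorm) {
      bn <- bn_bw(gy, cache$xhat, cache$invstd, p$gamma)
      gy <- bn$gx
      g$gamma <- bn$ggamma
      g$beta <- bn$gbeta
    }
    cv <- cpp_conv1d_bw(cache$x_in, p$W, gy, cfg$conv_stride)
    g$W <- cv$gw
    g$b <- as.numeric(cv$gb)
    grads[[l]] <- g
    gy <- cv$gx
  }
  grads
}

conv_out_length <- function(n, kernels, cfg) {
  L <- n
  for (k in kernels) {
    if (L < k) {
      stop(sprintf("kernel of width %d wider than remaining segment length %d",
                   k, L))
    }
    L <- (L - k) %/% cfg$conv_stride + 1L
    if (cfg$pool_width > 1L) {
      if (L < cfg$pool_width) {
        stop(sprintf("pooling window %d wider than remaining length %d",
                     cfg$pool_width, L))
      }
      L <- (L - cfg$pool_width) %/% cfg$pool_stride + 1L
    }
  }
  as.integer(L)
}

# ---- knowledge-feature attention (shared by segment and channel level) ---
# inputs: features arr (U, M, B), knowledge A (M, B); scorer
#   score_mb = V' (W' [arr_col; A_mb] + b), weights = softmax over dim M.

attn_fw <- function(arr, A, W, V, b, keep_cache = FALSE) {
  d <- dim(arr)
  Om <- rbind(matrix(arr, d[1], d[2] * d[3]), as.vector(A))
  S1 <- W %*% Om + b   # W stored already transposed-friendly? see note below
  sc <- matrix(crossprod(V, S1), d[2], d[3])
  wts <- nn_softmax_cols(sc)
  att <- arr * array(rep(wts, each = d[1]), dim = d)
  out <- list(weights = wts, attended = att)
  if (keep_cache) {
    out$Om <- Om
    out$S1 <- S1
  }
  out
}

# NOTE: the scorer's first layer is stored as the (D x (U+1)) matrix that
# left-multiplies the concatenated column, i.e. already "W transposed" in the
# usual W'O notation; shapes are documented at the build site.

attn_bw <- function(g_att, arr, wts, Om, S1, W, V) {
  d <- dim(arr)
  g_w <- matrix(colSums(matrix(g_att * arr, d[1], d[2] * d[3])), d[2], d[3])
  g_arr <- g_att * array(rep(wts, each = d[1]), dim = d)
  # softmax backward per column
  gsc <- wts * sweep(g_w, 2, colSums(wts * g_w), "-")
  gv <- as.vector(gsc)
  gV <- as.numeric(S1 %*% gv)
  gS1 <- matrix(V, ncol = 1) %*% matrix(gv, nrow = 1)
  gW <- gS1 %*% t(Om)
  gb <- rowSums(gS1)
  gOm <- crossprod(W, gS1)
  g_arr <- g_arr + array(gOm[seq_len(d[1]), , drop = FALSE], dim = d)
  list(g_arr = g_arr, gW = gW, gV = gV, gb = gb)
}

# ---- LSTM (Eqs of the gated recursion; gate order i, f, o, g) ------------

lstm_dir_fw <- function(x, W, Uh, b, keep_cache = FALSE) {
  d <- dim(x)
  Din <- d[1]; M <- d[2]; B <- d[3]
  H <- nrow(W) %/% 4L
  h <- matrix(0, H, B)
  cc <- matrix(0, H, B)
  hseq <- array(0, dim = c(H, M, B))
  steps <- if (keep_cache) vector("list", M) else NULL
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (t in seq_len(M)) {
    xt <- matrix(x[, t, ], Din, B)
    a <- W %*% xt + Uh %*% h + b
    ig <- 1 / (1 + exp(-a[i1, , drop = FALSE]))
    fg <- 1 / (1 + exp(-a[i2, , drop = FALSE]))
    og <- 1 / (1 + exp(-a[i3, , drop = FALSE]))
    gg <- tanh(a[i4, , drop = FALSE])
    c_prev <- cc
    h_prev <- h
    cc <- fg * c_prev + ig * gg
    tc <- tanh(cc)
    h <- og * tc
    hseq[, t, ] <- h
    if (keep_cache) {
      steps[[t]] <- list(xt = xt, ig = ig, fg = fg, og = og, gg = gg,
                         c_prev = c_prev, h_prev = h_prev, tc = tc)
    }
  }
  list(h = hseq, steps = steps)
}

lstm_dir_bw <- function(gh_seq, steps, W, Uh) {
  M <- dim(gh_seq)[2]
  B <- dim(gh_seq)[3]
  H <- nrow(W) %/% 4L
  Din <- ncol(W)
  gW <- matrix(0, 4L * H, Din)
  gU <- matrix(0, 4L * H, H)
  gb <- numeric(4L * H)
  gx <- array(0, dim = c(Din, M, B))
  gh_next <- matrix(0, H, B)
  gc_next <- matrix(0, H, B)
  for (t in rev(seq_len(M))) {
    s <- steps[[t]]
    gh <- matrix(gh_seq[, t, ], H, B) + gh_next
    gog <- gh * s$tc
    gc <- gc_next + gh * s$og * (1 - s$tc^2)
    gfg <- gc * s$c_prev
    gig <- gc * s$gg
    ggg <- gc * s$ig
    gc_next <- gc * s$fg
    ga <- rbind(gig * s$ig * (1 - s$ig),
                gfg * s$fg * (1 - s$fg),
                gog * s$og * (1 - s$og),
                ggg * (1 - s$gg^2))
    gW <- gW + tcrossprod(ga, s$xt)
    gU <- gU + tcrossprod(ga, s$h_prev)
    gb <- gb + rowSums(ga)
    gx[, t, ] <- crossprod(W, ga)
    gh_next <- crossprod(Uh, ga)
  }
  list(gx = gx, gW = gW, gU = gU, gb = gb)
}

bilstm_fw <- function(x, layers, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  M <- dim(x)[2]
  for (l in seq_along(layers)) {
    p <- layers[[l]]
    fw <- lstm_dir_fw(x, p$fw$W, p$fw$U, p$fw$b, keep_cache)
    bw <- lstm_dir_fw(x[, rev(seq_len(M)), , drop = FALSE],
                      p$bw$W, p$bw$U, p$bw$b, keep_cache)
    hb <- bw$h[, rev(seq_len(M)), , drop = FALSE]
    H <- dim(fw$h)[1]
    out <- array(0, dim = c(2L * H, M, dim(x)[3]))
    out[seq_len(H), , ] <- fw$h
    out[H + seq_len(H), , ] <- hb
    if (keep_cache) caches[[l]] <- list(fw = fw$steps, bw = bw$steps)
    x <- out
  }
  list(h = x, caches = caches)
}

bilstm_bw <- function(gh, caches, layers) {
  M <- dim(gh)[2]
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    p <- layers[[l]]
    H <- nrow(p$fw$W) %/% 4L
    g_fw <- gh[seq_len(H), , , drop = FALSE]
    g_bw <- gh[H + seq_len(H), , , drop = FALSE][, rev(seq_len(M)), ,
                                                 drop = FALSE]
    bf <- lstm_dir_bw(g_fw, caches[[l]]$fw, p$fw$W, p$fw$U)
    bb <- lstm_dir_bw(g_bw, caches[[l]]$bw, p$bw$W, p$bw$U)
    grads[[l]] <- list(fw = list(W = bf$gW, U = bf$gU, b = bf$gb),
                       bw = list(W = bb$gW, U = bb$gU, b = bb$gb))
    gh <- bf$gx + bb$gx[, rev(seq_len(M)), , drop = FALSE]
  }
  list(gx = gh, grads = grads)
}

# ---- optimizers: parameter/gradient trees walked recursively -------------

tree_zeros <- function(p) {
  if (is.numeric(p)) return(p * 0)
  lapply(p, tree_zeros)
}

tree_add <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  for (k in seq_along(a)) a[[k]] <- tree_add(a[[k]], b[[k]])
  a
}

tree_scale <- function(a, s) {
  if (is.numeric(a)) return(a * s)
  lapply(a, tree_scale, s = s)
}

opt_init <- function(params, optimizer) {
  switch(optimizer,
         adam = list(t = 0L, m = tree_zeros(params), v = tree_zeros(params)),
         adagrad = list(v = tree_zeros(params)),
         sgd = list())
}

opt_step <- function(params, grads, state, optimizer, lr) {
  if (optimizer == "adam") {
    state$t <- state$t + 1L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    corr <- lr * sqrt(1 - b2^state$t) / (1 - b1^state$t)
    walk <- function(p, g, m, v) {
      if (is.numeric(p)) {
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g * g
        p <- p - corr * m / (sqrt(v) + eps)
        return(list(p = p, m = m, v = v))
      }
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
      }
      list(p = p, m = m, v = v)
    }
    r <- walk(params, grads, state$m, state$v)
    state$m <- r$m; state$v <- r$v
    return(list(params = r$p, state = state))
  }
  if (optimizer == "adagrad") {
    eps <- 1e-10
    walk <- function(p, g, v) {
      if (is.numeric(p)) {
        v <- v + g * g
        p <- p - lr * g / (sqrt(v) + eps)
        return(list(p = p, v = v))
      }
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], v[[k]])
        p[[k]] <- r$p; v[[k]] <- r$v
      }
      list(p = p, v = v)
    }
    r <- walk(params, grads, state$v)
    state$v <- r$v
    return(list(params = r$p, state = state))
  }
  # plain sgd
  list(params = tree_add(params, tree_scale(grads, -lr)), state = state)
}

tree_count <- function(p) {
  if (is.numeric(p)) return(length(p))
  sum(vapply(p, tree_count, numeric(1)))
}
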