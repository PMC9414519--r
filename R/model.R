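#' Model configuration for the hybrid attentive network
#'
#' Architecture defaults follow the reference configuration: a 3-layer 1-D
#' CNN with kernel widths 10, 5, 3 for high-frequency channels and a 2-layer
#' CNN with widths 5, 2 for numeric channels (8 filters each, stride 1,
#' batch normalization + ReLU + width-2 max pooling between layers), a
#' 3-layer bidirectional LSTM with 16 hidden units per direction, and
#' dropout 0.5 on the fully connected prediction layer only.
#'
#' @param num_filters Number of convolution filters `U` per layer.
#' @param conv_kernels_highfreq Integer kernel widths of the high-frequency
#'   branch, one per layer.
#' @param conv_kernels_numeric Kernel widths of the numeric branch.
#' @param conv_stride Convolution stride (1 or 2).
#' @param pool_width,pool_stride Max-pooling window and stride applied after
#'   every convolutional layer; `pool_width = 1` disables pooling.
#' @param batchnorm Apply batch normalization between convolutional layers.
#' @param lstm_layers Number of stacked bidirectional LSTM layers.
#' @param lstm_hidden Hidden units per direction; the encoder output width is
#'   `J = 2 * lstm_hidden`.
#' @param attn_hidden_fl,attn_hidden_tr Hidden widths `D` of the two-layer
#'   attention scorers (fluctuant / trend).
#' @param fc_out Output width `I` of the fully connected transform.
#' @param dropout Dropout rate in `[0, 1)` for the prediction layer.
#' @param statistic_set Segment statistics whose consecutive differences
#'   enter the prediction head as covariates (subset of max/mean/min).
#' @param seed Integer seed for random parameter initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(num_filters = 8L,
                         conv_kernels_highfreq = c(10L, 5L, 3L),
                         conv_kernels_numeric = c(5L, 2L),
                         conv_stride = 1L,
                         pool_width = 2L, pool_stride = 2L,
                         batchnorm = TRUE,
                         lstm_layers = 3L, lstm_hidden = 16L,
                         attn_hidden_fl = 8L, attn_hidden_tr = 8L,
                         fc_out = 16L, dropout = 0.5,
                         statistic_set = "mean", seed = 1L) {
  cfg <- list(num_filters = as.integer(num_filters),
              conv_kernels_highfreq = as.integer(conv_kernels_highfreq),
              conv_kernels_numeric = as.integer(conv_kernels_numeric),
              conv_stride = as.integer(conv_stride),
              pool_width = as.integer(pool_width),
              pool_stride = as.integer(pool_stride),
              batchnorm = isTRUE(batchnorm),
              lstm_layers = as.integer(lstm_layers),
              lstm_hidden = as.integer(lstm_hidden),
              attn_hidden_fl = as.integer(attn_hidden_fl),
              attn_hidden_tr = as.integer(attn_hidden_tr),
              fc_out = as.integer(fc_out), dropout = as.numeric(dropout),
              statistic_set = match.arg(statistic_set,
                                        c("max", "mean", "min"),
                                        several.ok = TRUE),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(num_filters > 0, all(conv_kernels_highfreq > 0),
              all(conv_kernels_numeric > 0), conv_stride %in% c(1L, 2L),
              pool_width >= 1, pool_stride >= 1, lstm_layers > 0,
              lstm_hidden > 0, attn_hidden_fl > 0, attn_hidden_tr > 0,
              fc_out > 0, dropout >= 0, dropout < 1)
  })
  structure(cfg, class = "model_config")
}

MODEL_VARIANTS <- c("mvha", "cnn_ecg", "cnn_lstm", "cnn_fattn",
                    "clstm_fattn", "clstm_tattn")

variant_flags <- function(variant) {
  switch(variant,
    mvha        = list(lstm = TRUE,  fattn = TRUE,  tattn = TRUE,
                       cov = TRUE,  head = "hybrid",   ecg_only = FALSE),
    cnn_lstm    = list(lstm = TRUE,  fattn = FALSE, tattn = FALSE,
                       cov = FALSE, head = "hybrid",   ecg_only = FALSE),
    clstm_fattn = list(lstm = TRUE,  fattn = TRUE,  tattn = FALSE,
                       cov = FALSE, head = "hybrid",   ecg_only = FALSE),
    clstm_tattn = list(lstm = TRUE,  fattn = FALSE, tattn = TRUE,
                       cov = TRUE,  head = "hybrid",   ecg_only = FALSE),
    cnn_ecg     = list(lstm = FALSE, fattn = FALSE, tattn = FALSE,
                       cov = FALSE, head = "flat_ecg", ecg_only = TRUE),
    cnn_fattn   = list(lstm = FALSE, fattn = TRUE,  tattn = FALSE,
                       cov = FALSE, head = "flat_all", ecg_only = FALSE),
    stop("unknown model variant: ", variant))
}

runif_mat <- function(nr, nc, lim) matrix(runif(nr * nc, -lim, lim), nr, nc)

#' Build the hybrid attentive model (or a variant)
#'
#' Wires, per channel, a kind-appropriate convolutional branch, the
#' segment-level fluctuant attention and a bidirectional LSTM; the channel
#' encodings are stacked, passed through a fully connected transform, fused
#' by the channel-level trend attention and fed to a softmax prediction head
#' together with the segment-difference covariates. Parameter initialization
#' is uniform in `(-1/sqrt(fan_in), 1/sqrt(fan_in))`, seeded from
#' `config$seed`, so two builds with the same seed are identical.
#'
#' @param config A [model_config()].
#' @param channel_specs List of [channel_spec()] objects in channel order.
#' @param M Number of segments per window.
#' @param step_seconds Segment length in seconds (fixes per-channel segment
#'   sample counts together with the channel sampling rates).
#' @param variant One of `"mvha"` (full model), `"cnn_ecg"`, `"cnn_lstm"`,
#'   `"cnn_fattn"`, `"clstm_fattn"`, `"clstm_tattn"`. See
#'   [ablation_variant()].
#' @return An object of class `vitalattn_model`.
#' @export
build_model <- function(config, channel_specs, M, step_seconds = 60,
                        variant = "mvha") {
  stopifnot(inherits(config, "model_config"), M >= 1)
  flags <- variant_flags(variant)
  M <- as.integer(M)
  kinds <- vapply(channel_specs, `[[`, character(1), "kind")
  if (flags$ecg_only) {
    use <- which(kinds == "high_frequency")[1]
    if (is.na(use)) stop("variant needs a high-frequency channel")
  } else {
    use <- seq_along(channel_specs)
  }
  specs_used <- channel_specs[use]
  CHu <- length(specs_used)
  U <- config$num_filters
  cfg_conv <- config[c("conv_stride", "pool_width", "pool_stride",
                       "batchnorm")]
  n_seg <- integer(CHu)
  kernels <- vector("list", CHu)
  J_conv <- integer(CHu)
  for (i in seq_len(CHu)) {
    sp <- specs_used[[i]]
    n <- step_seconds * sp$sampling_rate
    if (abs(n - round(n)) > 1e-9) {
      stop(sprintf("channel %s: step of %g s is not a whole number of samples",
                   sp$name, step_seconds))
    }
    n_seg[i] <- as.integer(round(n))
    kernels[[i]] <- if (sp$kind == "high_frequency") {
      config$conv_kernels_highfreq
    } else {
      config$conv_kernels_numeric
    }
    J_conv[i] <- tryCatch(conv_out_length(n_seg[i], kernels[[i]], cfg_conv),
                          error = function(e) {
                            stop(sprintf("channel %s: %s", sp$name,
                                         conditionMessage(e)), call. = FALSE)
                          })
  }
  J <- 2L * config$lstm_hidden
  I <- config$fc_out
  K <- (M - 1L) * CHu * length(config$statistic_set)

  set.seed(config$seed)
  params <- list()
  params$conv <- lapply(seq_len(CHu), function(i) {
    cin <- 1L
    lapply(kernels[[i]], function(k) {
      lim <- 1 / sqrt(k * cin)
      layer <- list(W = array(runif(k * cin * U, -lim, lim),
                              dim = c(k, cin, U)),
                    b = runif(U, -lim, lim))
      if (config$batchnorm) {
        layer$gamma <- rep(1, U)
        layer$beta <- rep(0, U)
      }
      cin <<- U
      layer
    })
  })
  if (flags$fattn) {
    lim1 <- 1 / sqrt(U + 1)
    lim2 <- 1 / sqrt(config$attn_hidden_fl)
    params$fattn <- lapply(seq_len(CHu), function(i) {
      list(W = runif_mat(U + 1L, config$attn_hidden_fl, lim1),
           V = runif(config$attn_hidden_fl, -lim2, lim2),
           b = runif(config$attn_hidden_fl, -lim1, lim1))
    })
  }
  if (flags$lstm) {
    H <- config$lstm_hidden
    liml <- 1 / sqrt(H)
    params$lstm <- lapply(seq_len(CHu), function(i) {
      lapply(seq_len(config$lstm_layers), function(l) {
        din <- if (l == 1L) U else J
        list(fw = list(W = runif_mat(4L * H, din, liml),
                       U = runif_mat(4L * H, H, liml),
                       b = runif(4L * H, -liml, liml)),
             bw = list(W = runif_mat(4L * H, din, liml),
                       U = runif_mat(4L * H, H, liml),
                       b = runif(4L * H, -liml, liml)))
      })
    })
  }
  if (flags$head == "hybrid") {
    limz <- 1 / sqrt(J)
    params$fc <- list(Wz = runif_mat(J, I, limz), bz = runif(I, -limz, limz))
    if (flags$tattn) {
      limt <- 1 / sqrt(I + 1)
      limv <- 1 / sqrt(config$attn_hidden_tr)
      params$tattn <- list(W = runif_mat(I + 1L, config$attn_hidden_tr, limt),
                           V = runif(config$attn_hidden_tr, -limv, limv),
                           b = runif(config$attn_hidden_tr, -limt, limt))
    }
    limh <- 1 / sqrt(I)
    params$head <- list(Why = runif_mat(2L, I, limh))
    if (flags$cov) params$head$Wtry <- runif_mat(2L, K, 1 / sqrt(K))
    params$head$by <- runif(2L, -limh, limh)
  } else {
    flat_dim <- if (flags$head == "flat_ecg") U * M else U * CHu
    limf <- 1 / sqrt(flat_dim)
    params$head <- list(W = runif_mat(2L, flat_dim, limf),
                        by = runif(2L, -limf, limf))
  }
  bn_state <- if (config$batchnorm) {
    lapply(seq_len(CHu), function(i) {
      lapply(kernels[[i]], function(k) list(m = rep(0, U), v = rep(1, U)))
    })
  } else {
    NULL
  }
  structure(list(config = config, channel_specs = channel_specs,
                 use_channels = use, specs_used = specs_used,
                 M = M, step_seconds = step_seconds, variant = variant,
                 flags = flags, n_seg = n_seg, kernels = kernels,
                 J_conv = J_conv, J = J, I = I, K = K,
                 params = params, bn_state = bn_state),
            class = "vitalattn_model")
}

#' @export
print.vitalattn_model <- function(x, ...) {
  cat(sprintf("<vitalattn model \"%s\": %d channel(s), M=%d, %d parameters>\n",
              x$variant, length(x$specs_used), x$M, count_parameters(x)))
  invisible(x)
}

canon_variant <- function(name) {
  key <- gsub("[^a-z]", "", tolower(name))
  canon <- c(mvha = "mvha", cnnecg = "cnn_ecg", cnnlstm = "cnn_lstm",
             cnnfattn = "cnn_fattn", clstmfattn = "clstm_fattn",
             clstmtattn = "clstm_tattn")
  if (!key %in% names(canon)) {
    stop("unknown model variant: ", name, " (expected one of ",
         paste(c("CNN (ECG)", "CNN-LSTM", "CNN-FAttn", "CLSTM-FAttn",
                 "CLSTM-TAttn", "MVHA"), collapse = ", "), ")")
  }
  unname(canon[key])
}

#' Build one of the baseline/ablation variants
#'
#' The five baselines remove parts of the full hybrid model:
#' `cnn_ecg` runs the high-frequency branch alone with a flattened softmax
#' head; `cnn_lstm` is the hybrid with both attentions replaced by uniform
#' weighting; `cnn_fattn` keeps the convolutional encoders and fluctuant
#' attention but drops the LSTM; `clstm_fattn` keeps only the fluctuant
#' attention (uniform channel weights); `clstm_tattn` keeps only the trend
#' attention (uniform segment weights). Names are matched case-insensitively
#' ignoring punctuation, so `"CLSTM-FAttn"` works.
#'
#' @param name Variant name.
#' @inheritParams build_model
#' @return A `vitalattn_model`.
#' @export
ablation_variant <- function(name, config, channel_specs, M,
                             step_seconds = 60) {
  build_model(config, channel_specs, M, step_seconds,
              variant = canon_variant(name))
}

#' Count learnable parameters
#'
#' Sums the lengths of all parameter tensors of a model, or of any nested
#' list of numeric arrays. Batch-normalization running statistics are not
#' learnable and are excluded.
#'
#' @param x A `vitalattn_model` or a (nested) list of numeric arrays.
#' @return Integer count.
#' @examples
#' count_parameters(list(W = matrix(0, 2, 3), b = numeric(2))) # 8
#' @export
count_parameters <- function(x) {
  if (inherits(x, "vitalattn_model")) x <- x$params
  as.integer(tree_count(x))
}

arr3_sum_mid <- function(h) {
  d <- dim(h)
  matrix(colSums(matrix(aperm(h, c(2, 1, 3)), d[2])), d[1], d[3])
}

arr3_bcast_mid <- function(m, mid) {
  aperm(array(m, dim = c(nrow(m), ncol(m), mid)), c(1, 3, 2))
}

# Full forward pass over a prepared batch. `batch` carries, for every used
# channel, the segment array (n_seg x M x B) and the SD knowledge matrix
# (M x B), plus the trend knowledge (CHu x B), covariates (K x B) and labels.
mvha_forward <- function(model, batch, train = FALSE,
                         keep_cache = train) {
  flags <- model$flags
  cfgc <- model$config[c("conv_stride", "pool_width", "pool_stride",
                         "batchnorm")]
  CHu <- length(model$specs_used)
  U <- model$config$num_filters
  M <- model$M
  B <- dim(batch$x[[1]])[3]
  cache <- list(conv = vector("list", CHu), fattn = vector("list", CHu),
                lstm = vector("list", CHu), O = vector("list", CHu),
                OF = vector("list", CHu))
  alpha <- vector("list", CHu)
  bn_state <- model$bn_state
  z_list <- vector("list", CHu)
  flat_parts <- vector("list", CHu)
  for (ci in seq_len(CHu)) {
    n <- model$n_seg[ci]
    xin <- batch$x[[ci]]
    dim(xin) <- c(n, 1L, M * B)
    cv <- conv_branch_fw(xin, model$params$conv[[ci]],
                         if (cfgc$batchnorm) bn_state[[ci]] else NULL,
                         cfgc, train = train, keep_cache = keep_cache)
    if (cfgc$batchnorm) bn_state[[ci]] <- cv$bn_state
    if (keep_cache) cache$conv[[ci]] <- cv$caches
    o <- colSums(cv$out)                       # (U, M*B)
    O <- array(o, dim = c(U, M, B))
    if (keep_cache) {
      cache$O[[ci]] <- O
      cache$Jc[[ci]] <- dim(cv$out)[1]
    }
    if (flags$head == "flat_ecg") O_ecg <- O
    if (flags$fattn) {
      p <- model$params$fattn[[ci]]
      at <- attn_fw(O, batch$afl[[ci]], t(p$W), p$V, p$b,
                    keep_cache = keep_cache)
      alpha[[ci]] <- at$weights
      OF <- at$attended
      if (keep_cache) cache$fattn[[ci]] <- at[c("Om", "S1")]
    } else {
      alpha[[ci]] <- matrix(1 / M, M, B)
      OF <- O / M
    }
    if (keep_cache) cache$OF[[ci]] <- OF
    if (flags$lstm) {
      ls <- bilstm_fw(OF, model$params$lstm[[ci]], keep_cache = keep_cache)
      if (keep_cache) cache$lstm[[ci]] <- ls$caches
      z_list[[ci]] <- arr3_sum_mid(ls$h)       # (J, B)
    } else {
      flat_parts[[ci]] <- arr3_sum_mid(OF)     # (U, B)
    }
  }
  out <- list(alpha = alpha, bn_state = bn_state)
  if (flags$head == "hybrid") {
    J <- model$J
    Z <- array(0, dim = c(J, CHu, B))
    for (ci in seq_len(CHu)) Z[, ci, ] <- z_list[[ci]]
    Zmat <- matrix(Z, J, CHu * B)
    Xmat <- crossprod(model$params$fc$Wz, Zmat) + model$params$fc$bz
    X <- array(Xmat, dim = c(model$I, CHu, B))
    if (flags$tattn) {
      p <- model$params$tattn
      ta <- attn_fw(X, batch$atr, t(p$W), p$V, p$b, keep_cache = keep_cache)
      beta <- ta$weights
      d <- arr3_sum_mid(ta$attended)
      if (keep_cache) cache$tattn <- ta[c("Om", "S1")]
    } else {
      beta <- matrix(1 / CHu, CHu, B)
      d <- arr3_sum_mid(X) / CHu
    }
    if (train && model$config$dropout > 0) {
      mask <- matrix((runif(model$I * B) >= model$config$dropout) /
                       (1 - model$config$dropout), model$I, B)
      d_used <- d * mask
      if (keep_cache) cache$drop_mask <- mask
    } else {
      d_used <- d
    }
    logits <- model$params$head$Why %*% d_used + model$params$head$by
    if (flags$cov) {
      logits <- logits + model$params$head$Wtry %*% batch$cov
    }
    out$beta <- beta
    out$d <- d
    if (keep_cache) {
      cache$Z <- Z
      cache$X <- X
      cache$d_used <- d_used
    }
  } else {
    if (flags$head == "flat_ecg") {
      flat <- matrix(O_ecg, U * M, B)
    } else {
      flat <- do.call(rbind, flat_parts)
    }
    logits <- model$params$head$W %*% flat + model$params$head$by
    out$beta <- matrix(1 / CHu, CHu, B)
    if (keep_cache) cache$flat <- flat
  }
  out$logits <- logits
  out$probs <- nn_softmax_cols(logits)
  if (keep_cache) out$cache <- cache
  out
}

tree_align <- function(g, p) {
  if (is.numeric(p)) return(g)
  out <- vector("list", length(p))
  names(out) <- names(p)
  for (k in seq_along(p)) {
    key <- if (!is.null(names(p)) && nzchar(names(p)[k])) names(p)[k] else k
    out[[k]] <- tree_align(g[[key]], p[[k]])
  }
  out
}

# Analytic gradients of the mean- (or sum-) reduced cross-entropy loss with
# respect to every learnable tensor; mirrors the params tree exactly.
mvha_backward <- function(model, batch, fw, reduction = "mean") {
  flags <- model$flags
  cfgc <- model$config[c("conv_stride", "pool_width", "pool_stride",
                         "batchnorm")]
  CHu <- length(model$specs_used)
  U <- model$config$num_filters
  M <- model$M
  B <- ncol(fw$probs)
  cache <- fw$cache
  Y <- matrix(0, 2L, B)
  Y[cbind(batch$labels + 1L, seq_len(B))] <- 1
  dlogits <- fw$probs - Y
  if (reduction == "mean") dlogits <- dlogits / B
  grads <- list()
  gOF <- vector("list", CHu)
  if (flags$head == "hybrid") {
    d_used <- cache$d_used
    grads$head <- list(Why = tcrossprod(dlogits, d_used))
    if (flags$cov) grads$head$Wtry <- tcrossprod(dlogits, batch$cov)
    grads$head$by <- rowSums(dlogits)
    gd <- crossprod(model$params$head$Why, dlogits)
    if (!is.null(cache$drop_mask)) gd <- gd * cache$drop_mask
    X <- cache$X
    if (flags$tattn) {
      g_att <- arr3_bcast_mid(gd, CHu)
      p <- model$params$tattn
      ab <- attn_bw(g_att, X, fw$beta, cache$tattn$Om, cache$tattn$S1,
                    t(p$W), p$V)
      gX <- ab$g_arr
      grads$tattn <- list(W = t(ab$gW), V = ab$gV, b = ab$gb)
    } else {
      gX <- arr3_bcast_mid(gd, CHu) / CHu
    }
    gXmat <- matrix(gX, model$I, CHu * B)
    Zmat <- matrix(cache$Z, model$J, CHu * B)
    grads$fc <- list(Wz = tcrossprod(Zmat, gXmat), bz = rowSums(gXmat))
    gZmat <- model$params$fc$Wz %*% gXmat
    gZ <- array(gZmat, dim = c(model$J, CHu, B))
    grads$lstm <- vector("list", CHu)
    for (ci in seq_len(CHu)) {
      gz <- matrix(gZ[, ci, ], model$J, B)
      gh <- arr3_bcast_mid(gz, M)
      lb <- bilstm_bw(gh, cache$lstm[[ci]], model$params$lstm[[ci]])
      grads$lstm[[ci]] <- lb$grads
      gOF[[ci]] <- lb$gx
    }
  } else {
    grads$head <- list(W = tcrossprod(dlogits, cache$flat),
                       by = rowSums(dlogits))
    gflat <- crossprod(model$params$head$W, dlogits)
    if (flags$head == "flat_ecg") {
      gO_flat <- array(gflat, dim = c(U, M, B))
    } else {
      for (ci in seq_len(CHu)) {
        gr <- gflat[(ci - 1L) * U + seq_len(U), , drop = FALSE]
        gOF[[ci]] <- arr3_bcast_mid(gr, M)
      }
    }
  }
  grads$conv <- vector("list", CHu)
  if (flags$fattn) grads$fattn <- vector("list", CHu)
  for (ci in seq_len(CHu)) {
    O <- cache$O[[ci]]
    if (flags$head == "flat_ecg") {
      gO <- gO_flat
    } else if (flags$fattn) {
      p <- model$params$fattn[[ci]]
      ab <- attn_bw(gOF[[ci]], O, fw$alpha[[ci]], cache$fattn[[ci]]$Om,
                    cache$fattn[[ci]]$S1, t(p$W), p$V)
      gO <- ab$g_arr
      grads$fattn[[ci]] <- list(W = t(ab$gW), V = ab$gV, b = ab$gb)
    } else {
      gO <- gOF[[ci]] / M
    }
    Jc <- cache$Jc[[ci]]
    gP <- array(rep(matrix(gO, U, M * B), each = Jc),
                dim = c(Jc, U, M * B))
    grads$conv[[ci]] <- conv_branch_bw(gP, cache$conv[[ci]],
                                       model$params$conv[[ci]], cfgc)
  }
  tree_align(grads, model$params)
}

#' Cross-entropy loss
#'
#' Computes `-sum_i y_i * log(yhat_i)` over a batch of predicted class
#' distributions, with predicted probabilities clipped below at `1e-12` to
#' avoid `log(0)`. The `"mean"` reduction divides the batch sum by the
#' number of instances and is the form minimized during training.
#'
#' @param true_labels Either a `2 x B` one-hot matrix (instances in columns)
#'   or a length-`B` vector of 0/1 labels.
#' @param probs `2 x B` matrix of predicted class probabilities (columns on
#'   the simplex), or a length-2 vector for a single instance.
#' @param reduction `"sum"` (the mini-batch sum) or `"mean"`.
#' @return A single nonnegative number.
#' @examples
#' ce_loss(1, c(0.5, 0.5)) # log(2)
#' @export
ce_loss <- function(true_labels, probs, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 1)
  B <- ncol(probs)
  if (is.null(dim(true_labels))) {
    if (length(true_labels) == B && all(true_labels %in% c(0, 1))) {
      Y <- matrix(0, 2L, B)
      Y[cbind(as.integer(true_labels) + 1L, seq_len(B))] <- 1
    } else if (B == 1L && length(true_labels) == 2L) {
      Y <- matrix(true_labels, ncol = 1)
    } else {
      stop("true_labels must be 0/1 labels or a one-hot matrix")
    }
  } else {
    Y <- true_labels
  }
  if (!all(dim(Y) == dim(probs))) stop("shape mismatch between labels and probs")
  total <- -sum(Y * log(pmax(probs, 1e-12)))
  if (reduction == "mean") total / B else total
}

# ---- exported single-window building blocks ------------------------------

as_cfg_conv <- function(stride, pool_width, pool_stride, batchnorm) {
  list(conv_stride = as.integer(stride), pool_width = as.integer(pool_width),
       pool_stride = as.integer(pool_stride), batchnorm = isTRUE(batchnorm))
}

#' Convolutional encoding of one channel's segments
#'
#' Maps each of the `M` equal-length segments of one channel through the
#' branch's stacked 1-D convolutions (with optional batch normalization,
#' ReLU and max pooling after each layer) to a `U x J_conv` feature map,
#' then sums the feature map along the `J_conv` axis to a length-`U` vector;
#' the `M` vectors are returned stacked as the `U x M` matrix `O`.
#'
#' @param segments `n x M` numeric matrix (one segment per column) or a list
#'   of `M` equal-length numeric vectors.
#' @param branch List of layer parameter lists, each with `W`
#'   (`kernel x in_features x U` array), `b` (length `U`), and — when
#'   `batchnorm` — `gamma`/`beta` (length `U`).
#' @param stride Convolution stride.
#' @param pool_width,pool_stride Max pooling geometry (`pool_width = 1`
#'   disables pooling).
#' @param batchnorm Apply batch normalization (batch statistics over the
#'   `M` segments).
#' @return `U x M` matrix `O`.
#' @export
conv_encode <- function(segments, branch, stride = 1, pool_width = 2,
                        pool_stride = 2, batchnorm = FALSE) {
  if (is.list(segments)) {
    n <- unique(lengths(segments))
    if (length(n) != 1L) stop("segments must have equal length")
    segments <- matrix(unlist(segments), nrow = n)
  }
  n <- nrow(segments)
  M <- ncol(segments)
  cfg <- as_cfg_conv(stride, pool_width, pool_stride, batchnorm)
  kernels <- vapply(branch, function(p) dim(p$W)[1], integer(1))
  conv_out_length(n, kernels, cfg)  # validates receptive field
  x <- array(segments, dim = c(n, 1L, M))
  U <- dim(branch[[1]]$W)[3]
  bn_state <- lapply(branch, function(p) list(m = rep(0, U), v = rep(1, U)))
  out <- conv_branch_fw(x, branch, bn_state, cfg, train = batchnorm,
                        keep_cache = FALSE)$out
  colSums(out)
}

#' Fluctuant (segment-level) attention
#'
#' Concatenates the per-segment standard-deviation knowledge features as an
#' extra row of the convolutional output `O`, scores every segment through a
#' two-layer network `score_k = V' (W' o_k + b)` and softmax-normalizes the
#' scores into the attention weights `alpha`; the attended output scales
#' each column of `O` by its weight.
#'
#' @param O `U x M` convolutional output.
#' @param a_fl Length-`M` vector of per-segment standard deviations.
#' @param W `(U+1) x D` first-layer weights; `V` length-`D` second-layer
#'   weights; `b` length-`D` bias.
#' @return List with `alpha` (length-`M` simplex vector) and `of`
#'   (`U x M` attended output).
#' @export
fluct_attention <- function(O, a_fl, W, V, b) {
  stopifnot(is.matrix(O), length(a_fl) == ncol(O),
            nrow(W) == nrow(O) + 1L, ncol(W) == length(V),
            length(b) == length(V))
  at <- attn_fw(array(O, dim = c(dim(O), 1L)), matrix(a_fl, ncol = 1),
                t(W), V, b)
  list(alpha = as.numeric(at$weights),
       of = matrix(at$attended, nrow(O), ncol(O)))
}

#' Bidirectional LSTM encoding of the attended segment sequence
#'
#' Runs the standard gated LSTM recursion (sigmoid input/forget/output
#' gates, tanh candidate and cell activation, zero initial states) forward
#' and backward over the `M` attended feature vectors, in `length(layers)`
#' stacked layers, concatenating the two directions' per-step outputs.
#'
#' @param of `U x M` matrix of attended feature vectors (one per segment).
#' @param layers List of layer parameter lists, each with `fw` and `bw`
#'   sublists holding `W` (`4H x D_in`), `U` (`4H x H`) and `b` (length
#'   `4H`), gate order input/forget/output/candidate.
#' @return List with `H` (`J x M` matrix, `J = 2H`) and `z` (length-`J`
#'   row-sum of `H` over time).
#' @export
bilstm_encode <- function(of, layers) {
  stopifnot(is.matrix(of))
  if (ncol(layers[[1]]$fw$W) != nrow(of)) {
    stop("input width does not match first LSTM layer")
  }
  h <- bilstm_fw(array(of, dim = c(dim(of), 1L)), layers)$h
  H <- matrix(h, dim(h)[1], dim(h)[2])
  list(H = H, z = rowSums(H))
}

#' Fully connected transform of the stacked channel encodings
#'
#' Computes `X = Wz' Z` with the bias `bz` added to every column
#' (broadcast).
#'
#' @param Z `J x CH` matrix of per-channel encodings.
#' @param Wz `J x I` weight matrix; `bz` length-`I` bias.
#' @return `I x CH` matrix `X`.
#' @export
fc_transform <- function(Z, Wz, bz) {
  stopifnot(is.matrix(Z), nrow(Wz) == nrow(Z), length(bz) == ncol(Wz))
  crossprod(Wz, Z) + bz
}

#' Trend (channel-level) attention
#'
#' Concatenates the per-channel trend knowledge features as an extra row of
#' `X`, scores every channel through a two-layer network and
#' softmax-normalizes into the weights `beta`; the fused representation is
#' the weighted sum `d = sum_c beta_c x_c`.
#'
#' @param X `I x CH` transformed channel encodings.
#' @param a_tr Length-`CH` vector of trend knowledge features.
#' @param W `(I+1) x D` first-layer weights; `V` length-`D` second-layer
#'   weights; `b` length-`D` bias.
#' @return List with `beta` (length-`CH` simplex vector) and `d` (length-`I`
#'   fused vector).
#' @export
trend_attention <- function(X, a_tr, W, V, b) {
  stopifnot(is.matrix(X), length(a_tr) == ncol(X),
            nrow(W) == nrow(X) + 1L, ncol(W) == length(V),
            length(b) == length(V))
  at <- attn_fw(array(X, dim = c(dim(X), 1L)), matrix(a_tr, ncol = 1),
                t(W), V, b)
  list(beta = as.numeric(at$weights),
       d = as.numeric(arr3_sum_mid(at$attended)))
}

#' Softmax prediction head
#'
#' Computes the two class logits `W_hy d + W_try tr + b_y` and their softmax
#' probabilities `(P(no intervention), P(intervention))`. At an exact
#' 0.5/0.5 tie the predicted label is class 0.
#'
#' @param d Length-`I` fused representation.
#' @param trend_covariates Flattened segment-difference covariates, or
#'   `NULL` when the head carries no covariate term.
#' @param Why `2 x I` weights; `Wtry` `2 x K` covariate weights (or `NULL`);
#'   `by` length-2 bias.
#' @return List with `probs` (length-2 simplex vector) and `label` (0 or 1).
#' @export
prediction_head <- function(d, trend_covariates = NULL, Why, Wtry = NULL,
                            by) {
  stopifnot(ncol(Why) == length(d), length(by) == 2L)
  logits <- as.numeric(Why %*% d + by)
  if (!is.null(Wtry)) {
    if (is.null(trend_covariates) ||
        ncol(Wtry) != length(trend_covariates)) {
      stop("covariate length does not match Wtry")
    }
    logits <- logits + as.numeric(Wtry %*% trend_covariates)
  }
  probs <- as.numeric(nn_softmax_cols(matrix(logits, ncol = 1)))
  list(probs = probs, label = which.max(probs) - 1L)
}

# ---- checkpoints ---------------------------------------------------------

ser_tree <- function(p) {
  if (is.numeric(p)) {
    return(list(.dim = as.integer(dim(p) %||% length(p)),
                .values = as.numeric(p)))
  }
  lapply(p, ser_tree)
}

deser_tree <- function(s) {
  if (!is.null(s$.dim)) {
    v <- as.numeric(s$.values)
    if (length(s$.dim) > 1L) dim(v) <- s$.dim
    return(v)
  }
  lapply(s, deser_tree)
}

flatten_shapes <- function(p, prefix = "") {
  if (is.numeric(p)) {
    return(setNames(paste(dim(p) %||% length(p), collapse = "x"), prefix))
  }
  nms <- names(p) %||% as.character(seq_along(p))
  nms[!nzchar(nms)] <- as.character(which(!nzchar(nms)))
  unlist(lapply(seq_along(p), function(k) {
    flatten_shapes(p[[k]], paste0(prefix, if (nzchar(prefix)) "." else "",
                                  nms[k]))
  }))
}

#' Save a model checkpoint as plain text
#'
#' Writes the configuration, channel specification, all parameter tensors
#' and batch-normalization running statistics into a directory
#' (`config.yaml`, `params.json`, `bn_state.json`) together with a
#' `parameters.txt` sidecar listing every tensor name and shape for easy
#' diffing.
#'
#' @param model A `vitalattn_model`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- lapply(model$channel_specs, function(ch) {
    list(name = ch$name, kind = ch$kind, sampling_rate = ch$sampling_rate)
  })
  yaml::write_yaml(list(config = unclass(model$config),
                        variant = model$variant, M = model$M,
                        step_seconds = model$step_seconds,
                        channels = specs),
                   file.path(dir, "config.yaml"))
  jsonlite::write_json(ser_tree(model$params), file.path(dir, "params.json"),
                       digits = NA, auto_unbox = FALSE)
  if (!is.null(model$bn_state)) {
    jsonlite::write_json(ser_tree(model$bn_state),
                         file.path(dir, "bn_state.json"),
                         digits = NA, auto_unbox = FALSE)
  }
  shapes <- flatten_shapes(model$params)
  writeLines(sprintf("%-60s %s", names(shapes), shapes),
             file.path(dir, "parameters.txt"))
  invisible(dir)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param dir Checkpoint directory.
#' @return A `vitalattn_model`.
#' @export
load_checkpoint <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- do.call(model_config, meta$config)
  specs <- lapply(meta$channels, function(e) {
    channel_spec(e$name, e$kind, e$sampling_rate)
  })
  model <- build_model(cfg, specs, meta$M, meta$step_seconds,
                       variant = meta$variant)
  raw <- jsonlite::read_json(file.path(dir, "params.json"),
                             simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  model$params <- tree_align(deser_tree(raw), model$params)
  bn_path <- file.path(dir, "bn_state.json")
  if (file.exists(bn_path)) {
    raw_bn <- jsonlite::read_json(bn_path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = FALSE)
    model$bn_state <- tree_align(deser_tree(raw_bn), model$bn_state)
  }
  model
}
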