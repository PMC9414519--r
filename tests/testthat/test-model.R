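zero_tree <- function(p) {
  if (is.numeric(p)) return(p * 0)
  lapply(p, zero_tree)
}

test_that("conv_encode follows the sum-over-positions contract", {
  # all-zero weights map anything to zero
  branch <- list(list(W = array(0, c(3, 1, 2)), b = c(0, 0)))
  segs <- matrix(rnorm(30), 10, 3)
  O <- conv_encode(segs, branch, pool_width = 1, pool_stride = 1)
  expect_equal(O, matrix(0, 2, 3), ignore_attr = TRUE)
  expect_equal(ncol(O), 3L)   # one column per segment

  # averaging kernel on a constant segment: every position equals v, and the
  # column sum over the J = n - k + 1 positions is J * v
  k <- 4; n <- 12; v <- 2.5
  branch <- list(list(W = array(1 / k, c(k, 1, 1)), b = 0))
  O <- conv_encode(matrix(v, n, 2), branch, pool_width = 1, pool_stride = 1)
  expect_equal(as.numeric(O), rep((n - k + 1) * v, 2), tolerance = 1e-12)

  # kernel wider than the segment is rejected
  expect_error(conv_encode(matrix(1, 3, 2),
                           list(list(W = array(1, c(5, 1, 1)), b = 0))),
               "wider")
})

test_that("fluct_attention yields simplex weights and the hand-softmax case", {
  # identical columns (same features, same SD): uniform weights
  O <- matrix(rep(c(1, 2), 4), 2, 4)
  fa <- fluct_attention(O, rep(0.7, 4), W = matrix(rnorm(6), 3, 2),
                        V = rnorm(2), b = rnorm(2))
  expect_equal(fa$alpha, rep(0.25, 4), tolerance = 1e-12)
  expect_equal(sum(fa$alpha), 1, tolerance = 1e-9)
  expect_true(all(fa$alpha >= 0))

  # U = 1, M = 2, D = 1: scores (1, 2) give softmax (1/(1+e), e/(1+e))
  fa2 <- fluct_attention(matrix(c(1, 2), 1, 2), c(0, 0),
                         W = matrix(c(1, 1), 2, 1), V = 1, b = 0)
  expect_equal(fa2$alpha, c(1 / (1 + exp(1)), exp(1) / (1 + exp(1))),
               tolerance = 1e-9)
  expect_equal(fa2$of, matrix(c(1, 2) * fa2$alpha, 1, 2),
               tolerance = 1e-12)
})

test_that("fluct_attention is monotone in the SD feature when wired through", {
  # pass-through of the knowledge row with equal feature columns: weights
  # must strictly increase with segment SD
  U <- 2; M <- 5
  O <- matrix(1, U, M)
  sds <- c(0.1, 0.5, 1, 2, 3.5)
  fa <- fluct_attention(O, sds, W = matrix(c(0, 0, 1), U + 1, 1), V = 1,
                        b = 0)
  expect_true(all(diff(fa$alpha[order(sds)]) > 0))
})

test_that("bilstm_encode matches the hand-unrolled recursion", {
  # zero weights: every gate is sigma(0) = 0.5 but the candidate tanh(0) = 0,
  # so cell and hidden states stay exactly zero
  U <- 2; M <- 3; H <- 3
  zero_layer <- list(fw = list(W = matrix(0, 4 * H, U),
                               U = matrix(0, 4 * H, H), b = rep(0, 4 * H)),
                     bw = list(W = matrix(0, 4 * H, U),
                               U = matrix(0, 4 * H, H), b = rep(0, 4 * H)))
  enc <- bilstm_encode(matrix(rnorm(U * M), U, M), list(zero_layer))
  expect_equal(enc$H, matrix(0, 2 * H, M))
  expect_equal(enc$z, rep(0, 2 * H))

  # random small weights vs an independently coded step-by-step recursion
  set.seed(42)
  layers <- lapply(1:2, function(l) {
    din <- if (l == 1) U else 2 * H
    list(fw = list(W = matrix(rnorm(4 * H * din, sd = 0.3), 4 * H, din),
                   U = matrix(rnorm(4 * H * H, sd = 0.3), 4 * H, H),
                   b = rnorm(4 * H, sd = 0.1)),
         bw = list(W = matrix(rnorm(4 * H * din, sd = 0.3), 4 * H, din),
                   U = matrix(rnorm(4 * H * H, sd = 0.3), 4 * H, H),
                   b = rnorm(4 * H, sd = 0.1)))
  })
  of <- matrix(rnorm(U * M), U, M)
  enc <- bilstm_encode(of, layers)
  Href <- oracle_bilstm(of, layers)
  expect_equal(enc$H, Href, tolerance = 1e-6)
  expect_equal(enc$z, rowSums(Href), tolerance = 1e-6)

  # shape contract under the reference width: J = 2 * 16
  cfg <- model_config(seed = 2)
  m <- build_model(cfg, tiny_specs(), M = 3, step_seconds = 60)
  enc2 <- bilstm_encode(matrix(rnorm(cfg$num_filters * 3),
                               cfg$num_filters, 3), m$params$lstm[[1]])
  expect_equal(dim(enc2$H), c(32L, 3L))
})

test_that("fc_transform is a transposed product with broadcast bias", {
  Z <- matrix(rnorm(8), 4, 2)
  expect_equal(fc_transform(Z, diag(4), rep(0, 4)), Z, ignore_attr = TRUE)
  v <- rnorm(3)
  X <- fc_transform(Z, matrix(0, 4, 3), v)
  expect_equal(X, cbind(v, v), ignore_attr = TRUE)
  Wz <- matrix(rnorm(12), 4, 3)
  bz <- rnorm(3)
  ref <- t(Wz) %*% Z
  ref[, 1] <- ref[, 1] + bz
  ref[, 2] <- ref[, 2] + bz
  expect_equal(fc_transform(Z, Wz, bz), ref, tolerance = 1e-9)
})

test_that("trend_attention fuses channels on the simplex", {
  X <- matrix(rep(rnorm(3), 4), 3, 4)
  ta <- trend_attention(X, rep(0.5, 4), W = matrix(rnorm(8), 4, 2),
                        V = rnorm(2), b = rnorm(2))
  expect_equal(ta$beta, rep(0.25, 4), tolerance = 1e-12)
  expect_equal(sum(ta$beta), 1, tolerance = 1e-9)

  # CH = 2, I = 1 with scores (0, log 3): beta = (0.25, 0.75)
  X2 <- matrix(c(0, log(3)), 1, 2)
  ta2 <- trend_attention(X2, c(0, 0), W = matrix(c(1, 0), 2, 1), V = 1,
                         b = 0)
  expect_equal(ta2$beta, c(0.25, 0.75), tolerance = 1e-9)
  expect_equal(ta2$d, 0.25 * X2[, 1] + 0.75 * X2[, 2], tolerance = 1e-9)
})

test_that("prediction head computes softmax logits with class-0 tie break", {
  ph <- prediction_head(rnorm(4), NULL, Why = matrix(0, 2, 4), by = c(0, 0))
  expect_equal(ph$probs, c(0.5, 0.5))
  expect_identical(ph$label, 0L)
  ph2 <- prediction_head(rep(0, 2), NULL, Why = matrix(0, 2, 2),
                         by = c(log(3), 0))
  expect_equal(ph2$probs, c(0.75, 0.25), tolerance = 1e-12)
  expect_error(prediction_head(rnorm(2), c(1, 2), Why = matrix(0, 2, 2),
                               Wtry = matrix(0, 2, 3), by = c(0, 0)),
               "covariate")
})

test_that("cross-entropy closed forms and reductions", {
  expect_equal(ce_loss(1, c(0, 1)), 0)
  expect_equal(ce_loss(1, c(0.5, 0.5)), log(2))
  probs <- matrix(0.5, 2, 2)
  expect_equal(ce_loss(c(0, 1), probs, "sum"), 2 * log(2))
  expect_equal(ce_loss(c(0, 1), probs, "mean"), log(2))
  expect_error(ce_loss(matrix(1, 2, 3), matrix(0.5, 2, 2)), "mismatch")
})

test_that("builds are seeded-deterministic and parameter counting is exact", {
  expect_equal(count_parameters(list(W = matrix(0, 2, 3), b = numeric(2))),
               8L)
  cfg <- tiny_config(seed = 9)
  m1 <- build_model(cfg, tiny_specs(), M = 3, step_seconds = 6)
  m2 <- build_model(cfg, tiny_specs(), M = 3, step_seconds = 6)
  expect_identical(m1$params, m2$params)
  # the trend-attention block and covariate head add parameters
  mf <- build_model(cfg, tiny_specs(), M = 3, step_seconds = 6,
                    variant = "clstm_fattn")
  expect_gt(count_parameters(m1), count_parameters(mf))
})

test_that("build rejects kernels wider than the segment", {
  cfg <- model_config(seed = 1)   # high-frequency kernels 10, 5, 3
  specs <- list(channel_spec("ECG", "high_frequency", 1.5),
                channel_spec("HR", "numeric", 1))
  # 1.5 Hz x 2 s = 3 samples < kernel 10
  expect_error(build_model(cfg, specs, M = 3, step_seconds = 2), "wider")
})

test_that("ablation variants respect their input contracts", {
  expect_error(ablation_variant("CLSTM-XAttn", tiny_config(), tiny_specs(),
                                3, 6), "unknown")
  # CNN (ECG) uses only the high-frequency channel
  m <- ablation_variant("CNN (ECG)", tiny_config(), tiny_specs(), 3, 6)
  expect_length(m$specs_used, 1L)
  expect_identical(m$specs_used[[1]]$name, "ECG")
  w <- random_tiny_window(W = 18, seed = 3)
  expect_length(predict(m, list(w)), 1L)
})

test_that("full model equals CLSTM-FAttn when trend attention is silenced", {
  cfg <- tiny_config(seed = 13)
  specs <- tiny_specs()
  mv <- build_model(cfg, specs, M = 3, step_seconds = 6, variant = "mvha")
  fa <- build_model(cfg, specs, M = 3, step_seconds = 6,
                    variant = "clstm_fattn")
  # share every common tensor, zero the trend scorer (constant scores give
  # uniform beta) and the covariate head
  fa$params$conv <- mv$params$conv
  fa$params$fattn <- mv$params$fattn
  fa$params$lstm <- mv$params$lstm
  fa$params$fc <- mv$params$fc
  fa$params$head$Why <- mv$params$head$Why
  fa$params$head$by <- mv$params$head$by
  mv$params$tattn <- zero_tree(mv$params$tattn)
  mv$params$head$Wtry <- mv$params$head$Wtry * 0
  w <- random_tiny_window(W = 18, seed = 5)
  expect_equal(predict(mv, list(w)), predict(fa, list(w)),
               tolerance = 1e-12)
})

test_that("composed forward pass matches the straight-line oracle to 1e-6", {
  cfg <- tiny_config(seed = 31)
  specs <- tiny_specs()
  m <- build_model(cfg, specs, M = 3, step_seconds = 6)
  w <- random_tiny_window(W = 18, seed = 8)
  sw <- segment_window(w, 6)
  afl <- fluct_knowledge(sw)
  atr <- as.numeric(trend_knowledge(sw))
  cov <- as.vector(unclass(segment_diffs(sw, cfg$statistic_set)))
  ref <- oracle_forward(m, sw$segments,
                        list(afl[1, ], afl[2, ]), atr, cov)
  prob <- predict(m, list(w))
  expect_equal(prob, ref$probs[2], tolerance = 1e-6)
  rep <- export_attention(m, list(w))
  expect_equal(rep$alpha_table$alpha,
               c(ref$alpha[[1]], ref$alpha[[2]]), tolerance = 1e-6)
  expect_equal(rep$beta_table$beta, ref$beta, tolerance = 1e-6)
})

test_that("forward pass is reproducible and simplex-valid on random inputs", {
  cfg <- tiny_config(seed = 17)
  m <- build_model(cfg, tiny_specs(), M = 3, step_seconds = 6)
  batch <- random_batch(m, B = 4, seed = 6)
  fw1 <- vitalattn:::mvha_forward(m, batch)
  fw2 <- vitalattn:::mvha_forward(m, batch)
  expect_identical(fw1$probs, fw2$probs)
  expect_equal(colSums(fw1$probs), rep(1, 4), tolerance = 1e-9)
  for (a in fw1$alpha) {
    expect_equal(colSums(a), rep(1, 4), tolerance = 1e-6)
    expect_true(all(a >= 0))
  }
  expect_equal(colSums(fw1$beta), rep(1, 4), tolerance = 1e-6)
})

test_that("analytic gradients agree with finite differences", {
  # central differences with a kink guard: elements whose one-sided
  # differences disagree sit on a ReLU/pooling non-differentiability and
  # carry no information about gradient correctness
  cfg <- tiny_config(seed = 11)
  m <- build_model(cfg, tiny_specs(), M = 3, step_seconds = 6)
  batch <- random_batch(m, B = 3, seed = 12)
  ns <- asNamespace("vitalattn")
  fw <- ns$mvha_forward(m, batch, train = TRUE, keep_cache = TRUE)
  grads <- ns$mvha_backward(m, batch, fw, reduction = "mean")
  loss_at <- function(model) {
    f <- ns$mvha_forward(model, batch, train = TRUE, keep_cache = FALSE)
    ce_loss(batch$labels, f$probs, "mean")
  }
  flat <- function(p, prefix = "") {
    if (is.numeric(p)) return(setNames(list(p), prefix))
    nms <- names(p) %||% as.character(seq_along(p))
    nms[!nzchar(nms)] <- as.character(which(!nzchar(nms)))
    do.call(c, lapply(seq_along(p), function(k) {
      flat(p[[k]], paste0(prefix, "/", nms[k]))
    }))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  fp <- flat(m$params)
  fg <- flat(grads)
  expect_identical(names(fp), names(fg))
  set.seed(77)
  eps <- 1e-4
  checked <- 0L
  for (rep in 1:40) {
    ti <- sample(length(fp), 1)
    el <- sample(length(fp[[ti]]), 1)
    path <- strsplit(names(fp)[ti], "/", fixed = TRUE)[[1]][-1]
    shift <- function(delta) {
      mm <- m
      setval <- function(lst, path) {
        key <- path[1]
        idx <- suppressWarnings(as.integer(key))
        k <- if (!is.na(idx) && (is.null(names(lst)) ||
                                 !key %in% names(lst))) idx else key
        if (length(path) == 1) {
          v <- lst[[k]]
          v[el] <- v[el] + delta
          lst[[k]] <- v
        } else {
          lst[[k]] <- setval(lst[[k]], path[-1])
        }
        lst
      }
      mm$params <- setval(mm$params, path)
      mm
    }
    l0 <- loss_at(m)
    lp <- loss_at(shift(+eps))
    lm <- loss_at(shift(-eps))
    lp2 <- loss_at(shift(+eps / 2))
    lm2 <- loss_at(shift(-eps / 2))
    fd_fwd <- (lp - l0) / eps
    fd_bwd <- (l0 - lm) / eps
    scale <- max(1, abs(fd_fwd), abs(fd_bwd))
    if (abs(fd_fwd - fd_bwd) / scale > 1e-3) next  # kink: skip
    d1 <- (lp - lm) / (2 * eps)
    d2 <- (lp2 - lm2) / eps
    # a differentiable point gives scale-consistent central differences;
    # disagreement marks a kink crossing inside the stencil
    if (abs(d1 - d2) > 1e-5 * scale) next
    # Richardson-extrapolated central difference (O(eps^4) truncation)
    num <- (4 * d2 - d1) / 3
    ana <- fg[[ti]][el]
    expect_lt(abs(num - ana) / max(1, abs(num), abs(ana)), 1e-4)
    checked <- checked + 1L
  }
  expect_gte(checked, 25L)
})

test_that("checkpoints round-trip parameters and predictions", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(seed = 23, batchnorm = TRUE, pool_width = 2)
  m <- build_model(cfg, tiny_specs(), M = 3, step_seconds = 12)
  save_checkpoint(m, dir)
  expect_true(file.exists(file.path(dir, "parameters.txt")))
  m2 <- load_checkpoint(dir)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  w <- random_tiny_window(W = 36, seed = 19)
  expect_equal(predict(m2, list(w)), predict(m, list(w)), tolerance = 1e-12)
})
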