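#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 0.002,
#' mini-batches of 128, and a random 70/10/20 train/validation/test split.
#' Early stopping monitors validation loss and the checkpoint with the best
#' validation loss is returned.
#'
#' @param optimizer One of `"adam"`, `"sgd"`, `"adagrad"`.
#' @param learning_rate Positive step size.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum number of passes over the training set.
#' @param split Named fractions `train`, `val`, `test`; must sum to 1.
#' @param seed Integer seed governing the split, shuffling and dropout.
#' @param patience Epochs without validation improvement tolerated before
#'   stopping.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "sgd", "adagrad"),
                         learning_rate = 0.002, batch_size = 128L,
                         epochs = 8L,
                         split = c(train = 0.7, val = 0.1, test = 0.2),
                         seed = 1L, patience = 3L) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            all(c("train", "val", "test") %in% names(split)),
            abs(sum(split) - 1) < 1e-9, all(split >= 0))
  structure(list(optimizer = optimizer,
                 learning_rate = as.numeric(learning_rate),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), split = split,
                 seed = as.integer(seed), patience = as.integer(patience)),
            class = "train_config")
}

#' Split windows into train/validation/test sets at window-pair granularity
#'
#' The two sibling windows cut from one event (its negative first half and
#' positive second half) always travel to the same subset, preventing the
#' leakage that would arise if one event's halves straddled the split.
#' Shuffling is seeded from `config$seed`.
#'
#' @param windows List of `labeled_window` objects.
#' @param config A [train_config()] supplying split fractions and seed.
#' @return List with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(windows, config = train_config()) {
  if (length(windows) < 10L) stop("need at least 10 windows to split")
  pairs <- vapply(windows, `[[`, character(1), "pair_id")
  ids <- unique(pairs)
  set.seed(config$seed)
  ids <- sample(ids)
  np <- length(ids)
  n_tr <- floor(config$split[["train"]] * np)
  n_val <- floor(config$split[["val"]] * np)
  grp <- list(train = ids[seq_len(n_tr)],
              val = if (n_val > 0) ids[n_tr + seq_len(n_val)] else character(0),
              test = ids[setdiff(seq_len(np), seq_len(n_tr + n_val))])
  lapply(grp, function(g) windows[pairs %in% g])
}

# Segment every window once and precompute the knowledge features the model
# consumes; returns one entry per window, aligned with the model's channel
# subset.
prepare_dataset <- function(windows, model) {
  use <- model$use_channels
  stats <- model$config$statistic_set
  lapply(windows, function(w) {
    sw <- segment_window(w, model$step_seconds)
    if (sw$M != model$M) {
      stop(sprintf("window %s has M=%d segments, model expects %d",
                   w$window_id, sw$M, model$M))
    }
    segs <- sw$segments[use]
    afl <- lapply(segs, pop_sd_cols)
    sw_used <- sw
    sw_used$segments <- segs
    sw_used$channels <- sw$channels[use]
    atr <- as.numeric(trend_knowledge(sw_used))
    cov <- if (model$M >= 2L) {
      as.vector(unclass(segment_diffs(sw_used, stats)))
    } else {
      numeric(0)
    }
    list(x = segs, afl = afl, atr = atr, cov = cov,
         label = as.integer(w$label), window_id = w$window_id)
  })
}

make_batch <- function(prep, idx, model) {
  B <- length(idx)
  CHu <- length(model$specs_used)
  M <- model$M
  x <- vector("list", CHu)
  afl <- vector("list", CHu)
  for (ci in seq_len(CHu)) {
    n <- model$n_seg[ci]
    xa <- array(0, dim = c(n, M, B))
    fa <- matrix(0, M, B)
    for (b in seq_len(B)) {
      xa[, , b] <- prep[[idx[b]]]$x[[ci]]
      fa[, b] <- prep[[idx[b]]]$afl[[ci]]
    }
    x[[ci]] <- xa
    afl[[ci]] <- fa
  }
  atr <- vapply(idx, function(i) prep[[i]]$atr, numeric(CHu))
  if (is.null(dim(atr))) atr <- matrix(atr, nrow = CHu)
  cov <- vapply(idx, function(i) prep[[i]]$cov, numeric(model$K))
  if (is.null(dim(cov))) cov <- matrix(cov, nrow = model$K)
  list(x = x, afl = afl, atr = atr, cov = cov,
       labels = vapply(idx, function(i) prep[[i]]$label, integer(1)))
}

dataset_loss <- function(model, prep, batch_size = 64L) {
  n <- length(prep)
  total <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    batch <- make_batch(prep, idx, model)
    fw <- mvha_forward(model, batch, train = FALSE, keep_cache = FALSE)
    total <- total + ce_loss(batch$labels, fw$probs, "sum")
  }
  total / n
}

#' Train a model by mini-batch gradient descent on the cross-entropy loss
#'
#' Minimizes the mean-reduced cross-entropy with the configured optimizer,
#' records per-epoch training and validation loss, and returns the
#' parameters of the epoch with the best validation loss (early stopping
#' after `patience` epochs without improvement). All shuffling and dropout
#' randomness derives from `config$seed`, so a fixed seed reproduces the
#' run exactly.
#'
#' @param model A `vitalattn_model` from [build_model()] or
#'   [ablation_variant()].
#' @param train_windows,val_windows Lists of `labeled_window`s; `val_windows`
#'   may be empty, in which case the final parameters are returned.
#' @param config A [train_config()].
#' @return A list of class `vitalattn_fit` with elements `model` (trained)
#'   and `history` (data frame of epoch, train_loss, val_loss).
#' @export
train_model <- function(model, train_windows, val_windows = list(),
                        config = train_config()) {
  stopifnot(inherits(model, "vitalattn_model"), length(train_windows) > 0)
  prep_tr <- prepare_dataset(train_windows, model)
  prep_val <- if (length(val_windows)) {
    prepare_dataset(val_windows, model)
  } else {
    NULL
  }
  set.seed(config$seed)
  state <- opt_init(model$params, config$optimizer)
  n <- length(prep_tr)
  best_val <- Inf
  best_params <- model$params
  best_bn <- model$bn_state
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      batch <- make_batch(prep_tr, idx, model)
      fw <- mvha_forward(model, batch, train = TRUE)
      loss <- ce_loss(batch$labels, fw$probs, "mean")
      if (!is.finite(loss)) {
        stop(sprintf(
          "training diverged: non-finite loss at epoch %d (lr=%g); %s",
          epoch, config$learning_rate,
          "reduce the learning rate or inspect the inputs"))
      }
      ep_loss <- ep_loss + loss * length(idx)
      model$bn_state <- fw$bn_state
      grads <- mvha_backward(model, batch, fw, reduction = "mean")
      rm(fw, batch)   # drop forward caches before the optimizer step
      st <- opt_step(model$params, grads, state, config$optimizer,
                     config$learning_rate)
      model$params <- st$params
      state <- st$state
    }
    gc(verbose = FALSE)
    val_loss <- if (!is.null(prep_val)) dataset_loss(model, prep_val) else NA
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = ep_loss / n,
                                val_loss = val_loss))
    if (!is.null(prep_val)) {
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_params <- model$params
        best_bn <- model$bn_state
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > config$patience) break
      }
    }
  }
  if (!is.null(prep_val)) {
    model$params <- best_params
    model$bn_state <- best_bn
  }
  structure(list(model = model, history = history), class = "vitalattn_fit")
}

#' @export
print.vitalattn_fit <- function(x, ...) {
  cat(sprintf("<vitalattn fit: \"%s\", %d epoch(s)>\n", x$model$variant,
              nrow(x$history)))
  print(x$history, row.names = FALSE)
  invisible(x)
}

#' Predict intervention probabilities for labeled windows
#'
#' @param object A trained `vitalattn_model`.
#' @param windows List of `labeled_window`s.
#' @param type `"prob"` for the positive-class probability, `"class"` for
#'   the 0/1 label at the 0.5 threshold.
#' @param batch_size Windows per forward pass.
#' @param ... Unused.
#' @return Numeric (or integer) vector, one value per window.
#' @export
predict.vitalattn_model <- function(object, windows, type = c("prob", "class"),
                                    batch_size = 64L, ...) {
  type <- match.arg(type)
  prep <- prepare_dataset(windows, object)
  scores <- numeric(length(prep))
  for (start in seq(1L, length(prep), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(prep))
    fw <- mvha_forward(object, make_batch(prep, idx, object),
                       train = FALSE, keep_cache = FALSE)
    scores[idx] <- fw$probs[2L, ]
  }
  if (type == "class") as.integer(scores > 0.5) else scores
}

#' Classification metrics for binary scores
#'
#' Accuracy at the 0.5 probability threshold, ROC-AUC computed with midrank
#' tie handling (trapezoidal ROC integration), and the F1 score of the
#' positive class (defined as 0 when precision and recall are both 0).
#'
#' @param labels 0/1 vector of true labels (both classes must occur, else
#'   the AUC is undefined).
#' @param scores Positive-class probabilities or scores.
#' @return List of class `vitalattn_metrics` with `accuracy`, `roc_auc`,
#'   `f1`.
#' @export
classification_metrics <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), length(labels) > 0)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("test set contains a single class; ROC-AUC is undefined")
  }
  pred <- as.integer(scores > 0.5)
  accuracy <- mean(pred == labels)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  roc <- pROC::roc(response = labels, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  structure(list(accuracy = accuracy, roc_auc = as.numeric(pROC::auc(roc)),
                 f1 = f1),
            class = "vitalattn_metrics")
}

#' @export
print.vitalattn_metrics <- function(x, ...) {
  cat(sprintf("ACC %.4f  ROC-AUC %.4f  F1 %.4f\n", x$accuracy, x$roc_auc,
              x$f1))
  invisible(x)
}

#' Evaluate a trained model on a test set
#'
#' @param model A trained `vitalattn_model`.
#' @param windows Non-empty list of `labeled_window`s containing both
#'   classes.
#' @param batch_size Windows per forward pass.
#' @return A `vitalattn_metrics` object (accuracy, ROC-AUC, F1).
#' @export
evaluate_model <- function(model, windows, batch_size = 64L) {
  stopifnot(length(windows) > 0)
  labels <- vapply(windows, `[[`, integer(1), "label")
  scores <- predict(model, windows, type = "prob", batch_size = batch_size)
  classification_metrics(labels, scores)
}

variant_display <- c(cnn_ecg = "CNN (ECG)", cnn_lstm = "CNN-LSTM",
                     cnn_fattn = "CNN-FAttn", clstm_fattn = "CLSTM-FAttn",
                     clstm_tattn = "CLSTM-TAttn", mvha = "MVHA")

#' Train and evaluate all model variants under one split and seed
#'
#' Trains the five baselines and the full hybrid model on an identical
#' train/validation/test split and reports test-set accuracy, ROC-AUC and
#' F1 per variant. Deterministic for fixed configuration seeds.
#'
#' @param windows List of `labeled_window`s (the full dataset).
#' @param mconfig A [model_config()].
#' @param tconfig A [train_config()].
#' @param variants Variant names to include (default: all six).
#' @param step_seconds Segment length used throughout.
#' @return Data frame with columns `model`, `accuracy`, `roc_auc`, `f1`.
#' @export
run_ablation_suite <- function(windows, mconfig = model_config(),
                               tconfig = train_config(),
                               variants = names(variant_display),
                               step_seconds = 60) {
  splits <- split_dataset(windows, tconfig)
  W <- windows[[1]]$window_seconds
  M <- as.integer(round(W / step_seconds))
  specs <- windows[[1]]$channels
  rows <- lapply(variants, function(v) {
    model <- ablation_variant(v, mconfig, specs, M, step_seconds)
    fit <- train_model(model, splits$train, splits$val, tconfig)
    met <- evaluate_model(fit$model, splits$test)
    data.frame(model = variant_display[[canon_variant(v)]],
               accuracy = met$accuracy, roc_auc = met$roc_auc, f1 = met$f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export attention weights with highlight categories
#'
#' Runs forward passes over the given windows and tabulates the
#' segment-level weights `alpha` (per window and channel) and channel-level
#' weights `beta` (per window). Each `alpha` cell is categorized for
#' heatmap-style display: `"high"` above 0.15, `"medium"` between 0.1 and
#' 0.15 (inclusive), `"low"` below 0.1. Variants without a given attention
#' report its uniform weights.
#'
#' @param model A trained `vitalattn_model`.
#' @param windows List of `labeled_window`s.
#' @param batch_size Windows per forward pass.
#' @return List of class `attention_report` with `alpha_table`
#'   (`window_id`, `channel`, `k`, `alpha`, `category`) and `beta_table`
#'   (`window_id`, `channel`, `beta`).
#' @export
export_attention <- function(model, windows, batch_size = 64L) {
  prep <- prepare_dataset(windows, model)
  n <- length(prep)
  CHu <- length(model$specs_used)
  chn <- vapply(model$specs_used, `[[`, character(1), "name")
  M <- model$M
  ids <- vapply(prep, `[[`, character(1), "window_id")
  alpha_rows <- vector("list", n)
  beta_rows <- vector("list", n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- mvha_forward(model, make_batch(prep, idx, model),
                       train = FALSE, keep_cache = FALSE)
    for (b in seq_along(idx)) {
      i <- idx[b]
      a <- vapply(seq_len(CHu), function(ci) fw$alpha[[ci]][, b],
                  numeric(M))
      alpha_rows[[i]] <- data.frame(
        window_id = ids[i], channel = rep(chn, each = M),
        k = rep(seq_len(M), CHu), alpha = as.vector(a),
        stringsAsFactors = FALSE)
      beta_rows[[i]] <- data.frame(window_id = ids[i], channel = chn,
                                   beta = fw$beta[, b],
                                   stringsAsFactors = FALSE)
    }
  }
  alpha_table <- do.call(rbind, alpha_rows)
  alpha_table$category <- attention_category(alpha_table$alpha)
  structure(list(alpha_table = alpha_table,
                 beta_table = do.call(rbind, beta_rows)),
            class = "attention_report")
}

#' Categorize attention weights for display
#'
#' `"high"` for weights strictly above 0.15, `"medium"` for weights between
#' 0.1 and 0.15 inclusive, `"low"` otherwise.
#'
#' @param alpha Numeric vector of attention weights.
#' @return Character vector of categories.
#' @export
attention_category <- function(alpha) {
  ifelse(alpha > 0.15, "high", ifelse(alpha >= 0.1, "medium", "low"))
}

#' @export
print.attention_report <- function(x, ...) {
  cat(sprintf("<attention report: %d alpha rows, %d beta rows>\n",
              nrow(x$alpha_table), nrow(x$beta_table)))
  invisible(x)
}

#' Measure how well the attention recovers injected anomalies
#'
#' On the positive windows of a synthetic dataset, checks (a) how often the
#' argmax of the channel-averaged segment attention falls inside the
#' injected fluctuation segment set and (b) whether the injected trend
#' channel attains the highest mean channel attention.
#'
#' @param model A trained `vitalattn_model`.
#' @param windows Held-out windows (only positives are used).
#' @param truth The `synth_truth` from [generate_dataset()].
#' @return List with `localization_rate`, `beta_means` (named, sorted
#'   decreasing) and `trend_channel_top` (logical).
#' @export
attention_recovery <- function(model, windows, truth) {
  pos <- windows[vapply(windows, `[[`, integer(1), "label") == 1L]
  stopifnot(length(pos) > 0)
  rep <- export_attention(model, pos)
  a <- rep$alpha_table
  hits <- vapply(split(a, a$window_id), function(d) {
    mean_a <- tapply(d$alpha, d$k, mean)
    as.integer(names(which.max(mean_a))) %in% truth$fluct_segments
  }, logical(1))
  b <- rep$beta_table
  beta_means <- sort(tapply(b$beta, b$channel, mean), decreasing = TRUE)
  list(localization_rate = mean(hits),
       beta_means = beta_means,
       trend_channel_top = names(beta_means)[1] == truth$trend_channel)
}
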