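# Shared fixture builders; everything is generated in code under fixed
# seeds — no data files.

tiny_specs <- function() {
  list(channel_spec("ECG", "high_frequency", 10),
       channel_spec("HR", "numeric", 1))
}

# A small configuration whose shapes fit short tiny-test segments and whose
# forward pass the straight-line oracle can mirror (no batchnorm, no pool).
tiny_config <- function(seed = 1L, dropout = 0, batchnorm = FALSE,
                        pool_width = 1L) {
  model_config(num_filters = 2L, conv_kernels_highfreq = c(4L, 3L),
               conv_kernels_numeric = c(3L, 2L), pool_width = pool_width,
               pool_stride = pool_width, batchnorm = batchnorm,
               lstm_layers = 2L, lstm_hidden = 3L, attn_hidden_fl = 2L,
               attn_hidden_tr = 2L, fc_out = 3L, dropout = dropout,
               seed = seed)
}

# Build a labeled window directly from per-channel series.
make_window <- function(series, specs, label = 1L, W = NULL,
                        id = "w1", pair = "p1",
                        half = if (label == 1L) "second" else "first") {
  if (is.null(W)) W <- length(series[[1]]) / specs[[1]]$sampling_rate
  vitalattn:::new_labeled_window(specs, series, label = label,
                                 source_event_time = W, half = half,
                                 window_seconds = W, window_id = id,
                                 pair_id = pair)
}

# Random tiny window on the tiny_specs grid: W seconds, ECG 10 Hz + HR 1 Hz.
random_tiny_window <- function(W = 18, seed = 1L, label = 1L, id = "w1",
                               pair = "p1") {
  set.seed(seed)
  specs <- tiny_specs()
  series <- list(ECG = rnorm(W * 10), HR = 70 + rnorm(W))
  make_window(series, specs, label = label, W = W, id = id, pair = pair)
}

# Random model-ready batch for a tiny model (shapes drawn from the model).
random_batch <- function(model, B = 2L, seed = 1L) {
  set.seed(seed)
  M <- model$M
  CHu <- length(model$specs_used)
  list(x = lapply(model$n_seg, function(n) array(rnorm(n * M * B),
                                                 dim = c(n, M, B))),
       afl = lapply(seq_len(CHu), function(i) matrix(abs(rnorm(M * B)), M, B)),
       atr = matrix(runif(CHu * B), CHu, B),
       cov = matrix(rnorm(model$K * B), model$K, B),
       labels = rep_len(c(0L, 1L), B))
}

# Reduced-rate generator configuration for fast pipeline tests: same channel
# structure and anomaly semantics as the default, high-frequency channel at
# a lower rate so many training runs fit in the test budget.
fast_synth_config <- function(n_events = 40L, seed = 1L, ecg_rate = 10) {
  synth_config(
    n_events = n_events,
    channels = list(channel_spec("ECG", "high_frequency", ecg_rate),
                    channel_spec("HR", "numeric", 1),
                    channel_spec("Pulse", "numeric", 1),
                    channel_spec("Resp", "numeric", 1),
                    channel_spec("SpO2", "numeric", 1)),
    seed = seed)
}
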