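default_channels <- function() {
  list(channel_spec("ECG", "high_frequency", 125),
       channel_spec("HR", "numeric", 1),
       channel_spec("Pulse", "numeric", 1),
       channel_spec("Resp", "numeric", 1),
       channel_spec("SpO2", "numeric", 1))
}

default_baseline <- function() {
  list(ECG  = list(mean = 0,  drift_amp = 0.05, noise_sd = 0.08,
                   spike_amp = 1.1, spike_rate = 1.2),
       HR   = list(mean = 80, drift_amp = 1.5, noise_sd = 2),
       Pulse = list(mean = 80, drift_amp = 1.5, noise_sd = 2),
       Resp = list(mean = 18, drift_amp = 1.0, noise_sd = 1.2),
       SpO2 = list(mean = 97, drift_amp = 0.4, noise_sd = 0.5))
}

#' Configuration of the synthetic vital-sign generator
#'
#' The generator emulates ICU-style monitoring around intervention events:
#' per event it produces a 30-minute multichannel stretch whose first
#' 15-minute half is clean baseline (negative window) and whose second half,
#' which abuts the intervention, carries the configured anomalies (positive
#' window). The baseline of every channel is a mean level plus a slow
#' sinusoidal drift plus white noise; the high-frequency channel additionally
#' carries a periodic spike train as an ECG stand-in. Anomalies are
#' localized variance bursts (noise SD multiplied by `m_f` inside target
#' one-minute segments) and a sigmoid level shift of `m_t` times the
#' channel's clean range in one target channel.
#'
#' @param n_events Number of intervention events (window pairs).
#' @param channels List of [channel_spec()]s; default one 125 Hz ECG plus
#'   HR, Pulse, Resp and SpO2 at 1 Hz.
#' @param baseline Named per-channel list of `mean`, `drift_amp`, `noise_sd`
#'   (plus `spike_amp`, `spike_rate` for high-frequency channels); defaults
#'   chosen as plausible adult resting values.
#' @param fluct_anomaly List with `segments` (target 1-minute segment
#'   indices within the positive window, default 11:13), `m_f` (SD
#'   multiplier > 1, default 4) and `channels` (names; `NULL` = all).
#' @param trend_anomaly List with `channel` (default `"HR"`) and `m_t`
#'   (level-shift fraction of the channel's clean range, in `[0, 1]`,
#'   default 0.5).
#' @param missing_rate Fraction of samples dropped (then re-imputable), in
#'   `[0, 1)`; default 0.
#' @param pre_event_seconds Extraction window per event (default 1800 s).
#' @param step_seconds Segment length used to place fluctuation bursts.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_events = 100L, channels = default_channels(),
                         baseline = default_baseline(),
                         fluct_anomaly = list(segments = 11:13, m_f = 4,
                                              channels = NULL),
                         trend_anomaly = list(channel = "HR", m_t = 0.5),
                         missing_rate = 0, pre_event_seconds = 1800,
                         step_seconds = 60, seed = 1L) {
  stopifnot(n_events >= 1, length(channels) >= 1)
  nms <- vapply(channels, `[[`, character(1), "name")
  if (!all(nms %in% names(baseline))) {
    stop("baseline must provide parameters for every channel")
  }
  if (is.null(fluct_anomaly$m_f) || fluct_anomaly$m_f <= 1) {
    stop("fluctuation SD multiplier m_f must exceed 1")
  }
  if (is.null(trend_anomaly$m_t) || trend_anomaly$m_t < 0 ||
      trend_anomaly$m_t > 1) {
    stop("trend shift fraction m_t must lie in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  W <- pre_event_seconds / 2
  M <- W / step_seconds
  if (length(fluct_anomaly$segments) &&
      any(fluct_anomaly$segments > M | fluct_anomaly$segments < 1)) {
    stop(sprintf("fluctuation segment indices must lie in 1..%d", as.integer(M)))
  }
  if (!is.null(trend_anomaly$channel) &&
      !trend_anomaly$channel %in% nms) {
    stop("trend_anomaly$channel is not a channel of this configuration")
  }
  if (is.null(fluct_anomaly$channels)) fluct_anomaly$channels <- nms
  structure(list(n_events = as.integer(n_events), channels = channels,
                 baseline = baseline, fluct_anomaly = fluct_anomaly,
                 trend_anomaly = trend_anomaly,
                 missing_rate = as.numeric(missing_rate),
                 pre_event_seconds = as.numeric(pre_event_seconds),
                 step_seconds = as.numeric(step_seconds),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# One event's full 2W-second multichannel stretch; RNG state is consumed in
# a fixed channel order so datasets are reproducible element-wise.
gen_event <- function(config) {
  W <- config$pre_event_seconds / 2
  total <- 2 * W
  step <- config$step_seconds
  series <- list()
  for (ch in config$channels) {
    bl <- config$baseline[[ch$name]]
    r <- ch$sampling_rate
    n <- round(total * r)
    t <- seq_len(n) / r
    period <- runif(1, 300, 900)
    phase <- runif(1, 0, 2 * pi)
    drift <- bl$drift_amp * sin(2 * pi * t / period + phase)
    noise <- rnorm(n, 0, bl$noise_sd)
    sig <- bl$mean + drift
    if (ch$kind == "high_frequency" && !is.null(bl$spike_amp)) {
      per <- 1 / bl$spike_rate
      ph <- t %% per
      dist <- pmin(ph, per - ph)
      sig <- sig + bl$spike_amp * exp(-dist^2 / (2 * 0.03^2))
    }
    if (ch$name %in% config$fluct_anomaly$channels) {
      for (k in config$fluct_anomaly$segments) {
        from <- W + (k - 1) * step
        idx <- (round(from * r) + 1L):round((from + step) * r)
        noise[idx] <- noise[idx] * config$fluct_anomaly$m_f
      }
    }
    sig <- sig + noise
    if (!is.null(config$trend_anomaly$channel) &&
        ch$name == config$trend_anomaly$channel &&
        config$trend_anomaly$m_t > 0) {
      mag <- config$trend_anomaly$m_t * (max(sig) - min(sig))
      shift <- mag * plogis((t - 1.5 * W) / 60)
      shift[t <= W] <- 0
      sig <- sig + shift
    }
    if (config$missing_rate > 0) {
      drop <- which(runif(n) < config$missing_rate)
      if (length(drop) > n - 4L) drop <- drop[seq_len(n - 4L)]
      sig[drop] <- NA_real_
    }
    series[[ch$name]] <- sig
  }
  series
}

#' Generate a labeled synthetic dataset with ground-truth anomaly locations
#'
#' For every event the clean first half becomes a negative window and the
#' anomaly-bearing second half a positive window, so classes are exactly
#' balanced by construction. When `missing_rate > 0` the dropped samples are
#' re-imputed with [impute_missing()] unless `impute = FALSE`.
#'
#' @param config A [synth_config()].
#' @param impute Re-impute inserted missing values (default `TRUE`).
#' @return List with `windows` (list of `labeled_window`s, a negative and a
#'   positive one per event) and `truth` — a `synth_truth` object holding a
#'   per-window anomaly table (`window_id`, `anomaly`, `channel`,
#'   `segment`, `magnitude`) plus the injected segment set, channel set,
#'   trend channel and magnitudes.
#' @export
generate_dataset <- function(config, impute = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  W <- config$pre_event_seconds / 2
  windows <- vector("list", 2L * config$n_events)
  rows <- list()
  for (i in seq_len(config$n_events)) {
    series <- gen_event(config)
    if (config$missing_rate > 0 && impute) {
      for (j in seq_along(series)) {
        series[[j]] <- impute_missing(series[[j]],
                                      config$channels[[j]]$sampling_rate)
      }
    }
    for (half in c("first", "second")) {
      lab <- if (half == "first") 0L else 1L
      sl <- lapply(seq_along(config$channels), function(j) {
        r <- config$channels[[j]]$sampling_rate
        slice_channel(series[[j]], r, if (half == "first") 0 else W,
                      if (half == "first") W else 2 * W)
      })
      names(sl) <- names(series)
      id <- sprintf("e%04d_%s", i, if (half == "first") "neg" else "pos")
      windows[[2L * (i - 1L) + (lab + 1L)]] <- new_labeled_window(
        channels = config$channels, series = sl, label = lab,
        source_event_time = 2 * W, half = half, window_seconds = W,
        window_id = id, pair_id = sprintf("e%04d", i))
      if (lab == 1L) {
        for (chn in config$fluct_anomaly$channels) {
          for (k in config$fluct_anomaly$segments) {
            rows[[length(rows) + 1L]] <- data.frame(
              window_id = id, anomaly = "fluct", channel = chn, segment = k,
              magnitude = config$fluct_anomaly$m_f, stringsAsFactors = FALSE)
          }
        }
        if (!is.null(config$trend_anomaly$channel) &&
            config$trend_anomaly$m_t > 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            window_id = id, anomaly = "trend",
            channel = config$trend_anomaly$channel, segment = NA_integer_,
            magnitude = config$trend_anomaly$m_t, stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- structure(list(table = do.call(rbind, rows),
                          fluct_segments = config$fluct_anomaly$segments,
                          fluct_channels = config$fluct_anomaly$channels,
                          trend_channel = config$trend_anomaly$channel,
                          m_f = config$fluct_anomaly$m_f,
                          m_t = config$trend_anomaly$m_t),
                     class = "synth_truth")
  list(windows = windows, truth = truth)
}

#' Write synthetic records in the manifest format of [read_record()]
#'
#' Each event becomes one record directory (`e0001/`, ...) holding a
#' `manifest.yaml`, one `time,value` CSV per channel and the event timestamp
#' at the end of the record; a top-level `truth.csv` lists the injected
#' anomalies. Reading a record back and running
#' [extract_labeled_windows()] reproduces the generator's window pair.
#'
#' @param config A [synth_config()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synth_records <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  total <- config$pre_event_seconds
  rows <- list()
  for (i in seq_len(config$n_events)) {
    series <- gen_event(config)
    rdir <- file.path(dir, sprintf("e%04d", i))
    dir.create(rdir, showWarnings = FALSE)
    entries <- list()
    for (j in seq_along(config$channels)) {
      ch <- config$channels[[j]]
      fn <- paste0(tolower(ch$name), ".csv")
      data.table::fwrite(
        data.table::data.table(time = seq_along(series[[j]]) / ch$sampling_rate,
                               value = series[[j]]),
        file.path(rdir, fn))
      entries[[j]] <- list(name = ch$name, kind = ch$kind,
                           sampling_rate = ch$sampling_rate, path = fn)
    }
    yaml::write_yaml(list(channels = entries, events = list(total)),
                     file.path(rdir, "manifest.yaml"))
    for (chn in config$fluct_anomaly$channels) {
      for (k in config$fluct_anomaly$segments) {
        rows[[length(rows) + 1L]] <- data.frame(
          record = sprintf("e%04d", i), anomaly = "fluct", channel = chn,
          segment = k, stringsAsFactors = FALSE)
      }
    }
    if (!is.null(config$trend_anomaly$channel) && config$trend_anomaly$m_t > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        record = sprintf("e%04d", i), anomaly = "trend",
        channel = config$trend_anomaly$channel, segment = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  data.table::fwrite(do.call(rbind, rows), file.path(dir, "truth.csv"))
  invisible(dir)
}

#' A tiny fixed worked example with hand-computed feature tables
#'
#' Builds a deterministic two-channel window (a 4 Hz waveform channel and a
#' 1 Hz numeric channel, three 2-second segments) together with its
#' knowledge-feature values worked out by hand, for use in unit tests and
#' documentation.
#'
#' @return List with `window` (a `segmented_window`, label 1) and
#'   `expected` — a list holding `a_fl` (per-segment SDs), `a_tr`
#'   (trend features) and `diffs` (consecutive segment-statistic
#'   differences for mean, max and min).
#' @export
generate_worked_example <- function() {
  channels <- list(channel_spec("ECG", "high_frequency", 4),
                   channel_spec("HR", "numeric", 1))
  series <- list(ECG = c(0, 1, 0, 1, 0, 1, 0, 1,
                         0, 3, 0, 3, 0, 3, 0, 3,
                         2, 2, 2, 2, 2, 2, 2, 2),
                 HR = c(80, 82, 84, 86, 90, 78))
  w <- new_labeled_window(channels, series, label = 1L,
                          source_event_time = 6, half = "second",
                          window_seconds = 6, window_id = "worked_example",
                          pair_id = "worked")
  sw <- segment_window(w, step_seconds = 2)
  expected <- list(
    a_fl = rbind(ECG = c(0.5, 1.5, 0), HR = c(1, 1, 6)),
    a_tr = c(ECG = 0.5, HR = 1 / 3),
    diffs = list(mean = rbind(ECG = c(1, 0.5), HR = c(4, 1)),
                 max = rbind(ECG = c(2, 1), HR = c(4, 4)),
                 min = rbind(ECG = c(0, 2), HR = c(4, 6))))
  list(window = sw, expected = expected)
}
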