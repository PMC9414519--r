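#' Describe a single monitoring channel
#'
#' A channel is either a high-frequency waveform (e.g. ECG sampled at 125 Hz)
#' or a numeric vital-sign series (e.g. heart rate at 1 Hz).
#'
#' @param name Channel identifier, e.g. `"ECG"` or `"HR"`.
#' @param kind Either `"high_frequency"` or `"numeric"`.
#' @param sampling_rate Samples per second (Hz); must be positive.
#' @return An object of class `channel_spec`.
#' @examples
#' channel_spec("ECG", "high_frequency", 125)
#' @export
channel_spec <- function(name, kind = c("high_frequency", "numeric"),
                         sampling_rate) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number (Hz)")
  }
  structure(list(name = name, kind = kind,
                 sampling_rate = as.numeric(sampling_rate)),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel %s: %s @ %g Hz>\n", x$name, x$kind, x$sampling_rate))
  invisible(x)
}

#' Assemble a multichannel physiological record
#'
#' Bundles per-channel sample series (missing values as `NA`) with the
#' timestamps of intervention events. All channels must cover the same time
#' span (to within one sample period of the coarsest channel) and every
#' high-frequency channel must be sampled faster than every numeric channel.
#'
#' @param channels List of [channel_spec()] objects, in a fixed order.
#' @param series Named or ordered list of numeric vectors, one per channel;
#'   sample `i` of a channel at rate `r` is taken at time `i / r` seconds.
#' @param event_times Strictly increasing numeric vector of intervention
#'   timestamps (seconds from record start), each within the record span.
#' @return An object of class `mc_record`.
#' @export
multichannel_record <- function(channels, series, event_times = numeric(0)) {
  if (length(channels) == 0L) stop("record has no channels")
  stopifnot(all(vapply(channels, inherits, logical(1), "channel_spec")))
  if (length(series) != length(channels)) {
    stop("series must supply one sample vector per channel")
  }
  nms <- vapply(channels, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate channel names")
  if (!is.null(names(series))) series <- series[nms]
  names(series) <- nms
  rates <- vapply(channels, `[[`, numeric(1), "sampling_rate")
  kinds <- vapply(channels, `[[`, character(1), "kind")
  if (any(kinds == "high_frequency") && any(kinds == "numeric")) {
    if (min(rates[kinds == "high_frequency"]) <= max(rates[kinds == "numeric"])) {
      stop("high-frequency channels must be sampled faster than numeric channels")
    }
  }
  durations <- vapply(seq_along(channels), function(i) {
    length(series[[i]]) / rates[i]
  }, numeric(1))
  tol <- 1 / min(rates) + 1e-9
  if (max(durations) - min(durations) > tol) {
    stop(sprintf(
      "inconsistent channel durations: %.1f s vs %.1f s (beyond one sample period)",
      min(durations), max(durations)))
  }
  span <- min(durations)
  event_times <- as.numeric(event_times)
  if (length(event_times)) {
    if (any(diff(event_times) <= 0)) stop("event_times must be strictly increasing")
    if (any(event_times <= 0 | event_times > span + tol)) {
      stop("event_times must lie within the record time span")
    }
  }
  structure(list(channels = channels, series = series,
                 event_times = event_times, span_seconds = span),
            class = "mc_record")
}

#' @export
print.mc_record <- function(x, ...) {
  cat(sprintf("<multichannel record: %d channels, %.0f s, %d event(s)>\n",
              length(x$channels), x$span_seconds, length(x$event_times)))
  for (ch in x$channels) {
    cat(sprintf("  %-8s %-14s %g Hz\n", ch$name, ch$kind, ch$sampling_rate))
  }
  invisible(x)
}

#' Read a multichannel record from a manifest file
#'
#' The manifest is a small YAML file listing, for every channel, its name,
#' kind, sampling rate, and the path (relative to the manifest) of a
#' two-column delimited text file with a `time,value` header. Event
#' timestamps are listed under `events`. Missing samples are empty fields or
#' `NA` in the value column.
#'
#' @param manifest_path Path to the manifest YAML file.
#' @return An [multichannel_record()] object with channels in manifest order.
#' @export
read_record <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest file not found: ", manifest_path)
  man <- yaml::read_yaml(manifest_path)
  if (is.null(man$channels) || length(man$channels) == 0L) {
    stop("manifest lists no channels")
  }
  base <- dirname(manifest_path)
  channels <- vector("list", length(man$channels))
  series <- vector("list", length(man$channels))
  for (i in seq_along(man$channels)) {
    entry <- man$channels[[i]]
    for (f in c("name", "kind", "sampling_rate", "path")) {
      if (is.null(entry[[f]])) stop("manifest channel entry missing field: ", f)
    }
    channels[[i]] <- channel_spec(entry$name, entry$kind, entry$sampling_rate)
    path <- file.path(base, entry$path)
    if (!file.exists(path)) {
      stop(sprintf("data file for channel \"%s\" not found: %s", entry$name, path))
    }
    tab <- data.table::fread(path, header = TRUE, showProgress = FALSE)
    if (!all(c("time", "value") %in% names(tab))) {
      stop(sprintf("channel \"%s\": expected columns time,value", entry$name))
    }
    series[[i]] <- as.numeric(tab$value)
  }
  multichannel_record(channels, series,
                      event_times = as.numeric(unlist(man$events)))
}

#' Impute missing samples with a piecewise cubic spline
#'
#' Interior missing values (`NA`) are filled by a natural piecewise cubic
#' spline through the observed samples; missing values before the first or
#' after the last observation are held at the nearest observed value, since
#' cubic extrapolation is unreliable at the boundaries. Observed values are
#' never altered, and a complete series is returned unchanged.
#'
#' @param series Numeric vector with missing entries marked `NA`.
#' @param sampling_rate Samples per second; fixes the time axis of the spline.
#' @return The completed numeric vector.
#' @export
impute_missing <- function(series, sampling_rate = 1) {
  stopifnot(is.numeric(series), length(series) > 0L)
  obs <- which(!is.na(series))
  if (length(obs) == 0L) stop("cannot impute an all-missing series")
  if (length(obs) < 4L) {
    stop("cubic spline imputation needs at least 4 observed values")
  }
  if (length(obs) == length(series)) return(series)
  t <- seq_along(series) / sampling_rate
  out <- series
  lo <- obs[1L]
  hi <- obs[length(obs)]
  interior <- which(is.na(series) & seq_along(series) > lo & seq_along(series) < hi)
  if (length(interior)) {
    out[interior] <- spline(x = t[obs], y = series[obs], xout = t[interior],
                            method = "natural")$y
  }
  if (lo > 1L) out[seq_len(lo - 1L)] <- series[lo]
  if (hi < length(series)) out[(hi + 1L):length(series)] <- series[hi]
  out
}

new_labeled_window <- function(channels, series, label, source_event_time,
                               half, window_seconds, window_id, pair_id) {
  structure(list(channels = channels, series = series, label = label,
                 source_event_time = source_event_time, half = half,
                 window_seconds = window_seconds, window_id = window_id,
                 pair_id = pair_id),
            class = "labeled_window")
}

#' @export
print.labeled_window <- function(x, ...) {
  cat(sprintf("<labeled window %s: %.0f s, label %d (%s half)>\n",
              x$window_id, x$window_seconds, x$label, x$half))
  invisible(x)
}

slice_channel <- function(values, rate, from, to) {
  # half-open interval (from, to]: sample i sits at time i / rate
  i0 <- from * rate
  i1 <- to * rate
  if (abs(i0 - round(i0)) > 1e-6 || abs(i1 - round(i1)) > 1e-6) {
    stop("window boundaries do not align with the sampling grid")
  }
  values[(round(i0) + 1L):round(i1)]
}

#' Extract labeled observation windows around intervention events
#'
#' For every event preceded by `pre_event_seconds` of recording and with no
#' other event inside its extraction window, the pre-event stretch is halved:
#' the first half becomes a negative window (label 0, no intervention
#' imminent) and the second half, which abuts the intervention, a positive
#' window (label 1). Events too close to the start of the record are skipped
#' with a warning; events whose extraction window contains another event are
#' dropped so that each window reflects exactly one intervention.
#'
#' @param record An [multichannel_record()].
#' @param pre_event_seconds Length of the pre-event extraction window
#'   (default 1800 s = 30 min, giving two 15-min halves).
#' @return A list of `labeled_window` objects (possibly empty); sibling
#'   windows from one event share a `pair_id`.
#' @export
extract_labeled_windows <- function(record, pre_event_seconds = 1800) {
  stopifnot(inherits(record, "mc_record"), pre_event_seconds > 0)
  W <- pre_event_seconds / 2
  out <- list()
  for (i in seq_along(record$event_times)) {
    te <- record$event_times[i]
    if (te - pre_event_seconds < -1e-9) {
      warning(sprintf(
        "event at t=%g s skipped: needs %g s of history before it", te,
        pre_event_seconds), call. = FALSE)
      next
    }
    others <- record$event_times[-i]
    if (any(others > te - pre_event_seconds & others <= te)) next
    for (half in c("first", "second")) {
      from <- if (half == "first") te - 2 * W else te - W
      series <- lapply(seq_along(record$channels), function(j) {
        slice_channel(record$series[[j]], record$channels[[j]]$sampling_rate,
                      from, from + W)
      })
      names(series) <- names(record$series)
      out[[length(out) + 1L]] <- new_labeled_window(
        channels = record$channels, series = series,
        label = if (half == "first") 0L else 1L,
        source_event_time = te, half = half, window_seconds = W,
        window_id = sprintf("e%d_%s", i, if (half == "first") "neg" else "pos"),
        pair_id = sprintf("e%d", i))
    }
  }
  out
}

#' Split a labeled window into equal-length segments
#'
#' Cuts every channel of the window into `M = W / step_seconds` consecutive,
#' non-overlapping segments; segment `k` covers the half-open interval
#' `((k-1) * step, k * step]` within the window. A window length that is not
#' an exact multiple of the step is an error rather than being truncated,
#' since truncation would silently change `M` and all downstream shapes.
#'
#' @param window A `labeled_window`.
#' @param step_seconds Segment length in seconds (default 60).
#' @return An object of class `segmented_window`; for each channel the
#'   segments are held as a `samples x M` matrix whose columns concatenate
#'   back to the original series exactly.
#' @export
segment_window <- function(window, step_seconds = 60) {
  stopifnot(inherits(window, "labeled_window"), step_seconds > 0)
  W <- window$window_seconds
  M <- W / step_seconds
  if (abs(M - round(M)) > 1e-9) {
    stop(sprintf("window length %g s is not divisible by step %g s", W,
                 step_seconds))
  }
  M <- as.integer(round(M))
  segments <- lapply(seq_along(window$channels), function(j) {
    r <- window$channels[[j]]$sampling_rate
    n <- step_seconds * r
    if (abs(n - round(n)) > 1e-9) {
      stop(sprintf("channel %s: step of %g s is not a whole number of samples",
                   window$channels[[j]]$name, step_seconds))
    }
    matrix(window$series[[j]], nrow = round(n), ncol = M)
  })
  names(segments) <- names(window$series)
  structure(list(channels = window$channels, segments = segments,
                 step_seconds = step_seconds, M = M, label = window$label,
                 window_id = window$window_id),
            class = "segmented_window")
}

#' @export
print.segmented_window <- function(x, ...) {
  cat(sprintf("<segmented window %s: %d channels x %d segments of %g s, label %d>\n",
              x$window_id %||% "?", length(x$channels), x$M, x$step_seconds,
              x$label))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize labeled windows to a directory of delimited files
#'
#' Writes one long-format CSV per window (`channel,time,value`), a label
#' index `index.csv` (`window_id,label,event_time,half`) and a
#' `windows.yaml` manifest with the channel specifications, so the set can
#' be re-read with [read_windows()].
#'
#' @param windows List of `labeled_window` objects.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_windows <- function(windows, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stopifnot(length(windows) > 0L)
  specs <- lapply(windows[[1L]]$channels, function(ch) {
    list(name = ch$name, kind = ch$kind, sampling_rate = ch$sampling_rate)
  })
  yaml::write_yaml(list(channels = specs,
                        window_seconds = windows[[1L]]$window_seconds),
                   file.path(dir, "windows.yaml"))
  idx <- data.table::data.table(
    window_id = vapply(windows, `[[`, character(1), "window_id"),
    label = vapply(windows, `[[`, integer(1), "label"),
    event_time = vapply(windows, `[[`, numeric(1), "source_event_time"),
    half = vapply(windows, `[[`, character(1), "half"),
    pair_id = vapply(windows, `[[`, character(1), "pair_id"))
  data.table::fwrite(idx, file.path(dir, "index.csv"))
  for (w in windows) {
    parts <- lapply(seq_along(w$channels), function(j) {
      r <- w$channels[[j]]$sampling_rate
      data.table::data.table(channel = w$channels[[j]]$name,
                             time = seq_along(w$series[[j]]) / r,
                             value = w$series[[j]])
    })
    data.table::fwrite(data.table::rbindlist(parts),
                       file.path(dir, paste0(w$window_id, ".csv")))
  }
  invisible(dir)
}

#' Read labeled windows previously written by [write_windows()]
#'
#' @param dir Directory containing `windows.yaml`, `index.csv` and one CSV
#'   per window.
#' @return A list of `labeled_window` objects.
#' @export
read_windows <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "windows.yaml"))
  channels <- lapply(man$channels, function(e) {
    channel_spec(e$name, e$kind, e$sampling_rate)
  })
  idx <- data.table::fread(file.path(dir, "index.csv"), showProgress = FALSE)
  lapply(seq_len(nrow(idx)), function(i) {
    tab <- data.table::fread(file.path(dir, paste0(idx$window_id[i], ".csv")),
                             showProgress = FALSE)
    series <- lapply(channels, function(ch) tab$value[tab$channel == ch$name])
    names(series) <- vapply(channels, `[[`, character(1), "name")
    new_labeled_window(channels, series, label = as.integer(idx$label[i]),
                       source_event_time = idx$event_time[i],
                       half = idx$half[i],
                       window_seconds = man$window_seconds,
                       window_id = idx$window_id[i], pair_id = idx$pair_id[i])
  })
}
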