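#' Population standard deviation of one segment
#'
#' Computes `sqrt(mean((s - mean(s))^2))` — the population form with
#' denominator `|s|`, no Bessel correction — which is the fluctuation
#' statistic fed to the segment-level attention scorer.
#'
#' @param segment Non-empty numeric vector.
#' @return A single nonnegative number.
#' @examples
#' segment_sd(c(1, 2, 3, 4)) # sqrt(1.25)
#' @export
segment_sd <- function(segment) {
  if (!is.numeric(segment) || length(segment) == 0L) {
    stop("segment must be a non-empty numeric vector")
  }
  if (anyNA(segment)) stop("segment contains missing values; impute first")
  sqrt(mean((segment - mean(segment))^2))
}

pop_sd_cols <- function(m) {
  # column-wise population SD of a samples x M matrix
  cm <- colMeans(m)
  sqrt(colMeans(m * m) - cm * cm)
}

#' Per-segment fluctuation knowledge features
#'
#' Returns the `CH x M` matrix whose entry `(c, k)` is the population
#' standard deviation of segment `k` of channel `c`. These are the
#' "fluctuant" knowledge features concatenated onto the convolutional
#' features inside the segment-level attention scorer.
#'
#' @param segments A `segmented_window` from [segment_window()].
#' @return Numeric matrix (channels in rows, segments in columns) of class
#'   `fluct_knowledge`.
#' @export
fluct_knowledge <- function(segments) {
  stopifnot(inherits(segments, "segmented_window"))
  vals <- t(vapply(segments$segments, function(m) pmax(pop_sd_cols(m), 0),
                   numeric(segments$M)))
  rownames(vals) <- names(segments$segments)
  colnames(vals) <- paste0("s", seq_len(segments$M))
  structure(vals, class = c("fluct_knowledge", class(vals)))
}

#' Min-max scale a series to [0, 1]
#'
#' Applies `(x - min) / (max - min)`. A constant series, whose range is
#' zero, maps to all zeros rather than dividing by zero.
#'
#' @param series Non-empty numeric vector.
#' @return Numeric vector of the same length with values in `[0, 1]`.
#' @export
minmax_scale <- function(series) {
  if (!is.numeric(series) || length(series) == 0L) {
    stop("series must be a non-empty numeric vector")
  }
  if (anyNA(series)) stop("series contains missing values; impute first")
  rng <- range(series)
  if (rng[2] == rng[1]) return(rep(0, length(series)))
  (series - rng[1]) / (rng[2] - rng[1])
}

#' Per-channel trend knowledge features
#'
#' For each channel the window is first min-max scaled (so channels with
#' different physical units and amplitudes become comparable), the mean of
#' every scaled segment is taken, and the largest absolute difference
#' between any two segment means — equivalently `max(means) - min(means)` —
#' is returned. A channel with a pronounced level shift scores near 1; a
#' flat channel scores near 0. With a single segment the feature is 0.
#'
#' @param segments A `segmented_window`.
#' @return Named nonnegative numeric vector of length `CH`, each entry in
#'   `[0, 1]`, of class `trend_knowledge`.
#' @export
trend_knowledge <- function(segments) {
  stopifnot(inherits(segments, "segmented_window"))
  vals <- vapply(segments$segments, function(m) {
    if (ncol(m) < 2L) return(0)
    scaled <- matrix(minmax_scale(as.vector(m)), nrow = nrow(m))
    means <- colMeans(scaled)
    max(means) - min(means)
  }, numeric(1))
  structure(vals, class = "trend_knowledge")
}

#' Absolute differences of segment statistics between consecutive segments
#'
#' For every channel, statistic `rho` and segment index `kt` in
#' `1..M-1`, computes `|rho(s[kt+1]) - rho(s[kt])|` on the raw (unscaled)
#' segment values. These differences are flattened into the covariate vector
#' of the prediction head.
#'
#' @param segments A `segmented_window` with at least two segments.
#' @param statistic_set Non-empty subset of `c("max", "mean", "min")`.
#' @return A 3-d array `CH x (M-1) x length(statistic_set)` of class
#'   `trend_diffs` with a `statistic_set` attribute.
#' @export
segment_diffs <- function(segments, statistic_set = "mean") {
  stopifnot(inherits(segments, "segmented_window"))
  if (segments$M < 2L) stop("segment differences need at least 2 segments")
  if (length(statistic_set) == 0L) stop("statistic_set must be non-empty")
  statistic_set <- match.arg(statistic_set, c("max", "mean", "min"),
                             several.ok = TRUE)
  CH <- length(segments$segments)
  out <- array(0, dim = c(CH, segments$M - 1L, length(statistic_set)),
               dimnames = list(names(segments$segments),
                               paste0("kt", seq_len(segments$M - 1L)),
                               statistic_set))
  for (s in seq_along(statistic_set)) {
    fn <- switch(statistic_set[s], max = function(m) apply(m, 2, max),
                 min = function(m) apply(m, 2, min), mean = colMeans)
    for (c in seq_len(CH)) {
      stat <- fn(segments$segments[[c]])
      out[c, , s] <- abs(diff(stat))
    }
  }
  structure(out, statistic_set = statistic_set,
            class = c("trend_diffs", "array"))
}

#' Export knowledge features of one window as a long table
#'
#' @param segments A `segmented_window`.
#' @param statistic_set Passed to [segment_diffs()] (used only when `M >= 2`).
#' @return A `data.frame` with columns `window_id`, `channel`, `feature`
#'   (`"fluct_sd"`, `"trend_range"` or `"diff_<stat>"`), `k` and `value`.
#' @export
feature_table <- function(segments, statistic_set = "mean") {
  afl <- fluct_knowledge(segments)
  atr <- trend_knowledge(segments)
  id <- segments$window_id %||% NA_character_
  rows <- list(
    data.frame(window_id = id, channel = rep(rownames(afl), ncol(afl)),
               feature = "fluct_sd", k = rep(seq_len(ncol(afl)),
                                             each = nrow(afl)),
               value = as.vector(afl), stringsAsFactors = FALSE),
    data.frame(window_id = id, channel = names(atr), feature = "trend_range",
               k = NA_integer_, value = as.numeric(atr),
               stringsAsFactors = FALSE))
  if (segments$M >= 2L) {
    d <- segment_diffs(segments, statistic_set)
    for (s in seq_len(dim(d)[3])) {
      rows[[length(rows) + 1L]] <- data.frame(
        window_id = id, channel = rep(rownames(d), ncol(d)),
        feature = paste0("diff_", dimnames(d)[[3]][s]),
        k = rep(seq_len(ncol(d)), each = nrow(d)),
        value = as.vector(d[, , s]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.fluct_knowledge <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.trend_knowledge <- function(x, ...) {
  print(setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}
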