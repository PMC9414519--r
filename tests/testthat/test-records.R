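test_that("manifest round trip preserves channels, series and events", {
  dir <- withr::local_tempdir()
  set.seed(4)
  ecg <- rnorm(600)   # 10 Hz, 60 s
  hr <- 70 + rnorm(60)
  data.table::fwrite(data.table::data.table(time = (1:600) / 10, value = ecg),
                     file.path(dir, "ecg.csv"))
  data.table::fwrite(data.table::data.table(time = 1:60, value = hr),
                     file.path(dir, "hr.csv"))
  yaml::write_yaml(list(
    channels = list(
      list(name = "ECG", kind = "high_frequency", sampling_rate = 10,
           path = "ecg.csv"),
      list(name = "HR", kind = "numeric", sampling_rate = 1,
           path = "hr.csv")),
    events = list(60)), file.path(dir, "manifest.yaml"))
  rec <- read_record(file.path(dir, "manifest.yaml"))
  expect_s3_class(rec, "mc_record")
  expect_length(rec$channels, 2L)
  expect_equal(rec$series$ECG, ecg)
  expect_equal(rec$series$HR, hr)
  expect_equal(rec$event_times, 60)
})

test_that("manifest errors name the offending channel or inconsistency", {
  dir <- withr::local_tempdir()
  data.table::fwrite(data.table::data.table(time = 1:60, value = rnorm(60)),
                     file.path(dir, "hr.csv"))
  yaml::write_yaml(list(
    channels = list(
      list(name = "ECG", kind = "high_frequency", sampling_rate = 10,
           path = "missing_ecg.csv"),
      list(name = "HR", kind = "numeric", sampling_rate = 1,
           path = "hr.csv")),
    events = list()), file.path(dir, "manifest.yaml"))
  expect_error(read_record(file.path(dir, "manifest.yaml")), "ECG")

  yaml::write_yaml(list(channels = list(), events = list()),
                   file.path(dir, "manifest.yaml"))
  expect_error(read_record(file.path(dir, "manifest.yaml")), "no channels")

  # inconsistent durations beyond one sample period
  expect_error(
    multichannel_record(tiny_specs(),
                        list(ECG = rnorm(1800 * 10), HR = rnorm(1700))),
    "duration")
})

test_that("record invariants: event ordering and rate hierarchy enforced", {
  specs <- tiny_specs()
  series <- list(ECG = rnorm(600), HR = rnorm(60))
  expect_error(multichannel_record(specs, series, event_times = c(50, 40)),
               "increasing")
  expect_error(multichannel_record(specs, series, event_times = 100),
               "span")
  slow_hf <- list(channel_spec("ECG", "high_frequency", 1),
                  channel_spec("HR", "numeric", 2))
  expect_error(
    multichannel_record(slow_hf, list(ECG = rnorm(60), HR = rnorm(120))),
    "faster")
})

test_that("cubic spline imputation fills interior gaps and holds boundaries", {
  # complete series returned unchanged (and idempotence)
  x <- c(1, 2, 3, 4, 5)
  expect_identical(impute_missing(x, 1), x)
  expect_identical(impute_missing(impute_missing(x, 1), 1),
                   impute_missing(x, 1))

  # collinear observations: a cubic spline through points on a line is the
  # line, so the gap at t = 2 is filled with exactly 2
  y <- c(0, 1, NA, 3, 4)
  expect_equal(impute_missing(y, 1)[3], 2, tolerance = 1e-9)
  expect_equal(impute_missing(y, 1)[-3], y[-3])

  # leading missing values held at the first observation
  z <- c(NA, NA, 7, 8, 9, 10)
  expect_equal(impute_missing(z, 1)[1:2], c(7, 7))
  ztail <- c(7, 8, 9, 10, NA)
  expect_equal(impute_missing(ztail, 1)[5], 10)

  expect_error(impute_missing(c(NA, 1, 2, 3, NA), 1), "at least 4")
  expect_error(impute_missing(rep(NA_real_, 10), 1), "all-missing")
})

test_that("window extraction labels the pre-event halves and skips bad events", {
  specs <- tiny_specs()
  set.seed(11)
  series <- list(ECG = rnorm(18000), HR = rnorm(1800))
  rec <- multichannel_record(specs, series, event_times = 1800)
  ws <- extract_labeled_windows(rec, pre_event_seconds = 1800)
  expect_length(ws, 2L)
  expect_equal(vapply(ws, `[[`, integer(1), "label"), c(0L, 1L))
  expect_equal(vapply(ws, `[[`, character(1), "half"), c("first", "second"))
  # first half is samples (0, 900], second (900, 1800]
  expect_equal(ws[[1]]$series$ECG, series$ECG[1:9000])
  expect_equal(ws[[2]]$series$ECG, series$ECG[9001:18000])
  expect_equal(ws[[1]]$series$HR, series$HR[1:900])
  # per-channel lengths are exactly W x rate
  for (w in ws) {
    expect_identical(lengths(w$series),
                     c(ECG = 9000L, HR = 900L))
  }

  # two events inside one extraction window: both dropped
  rec2 <- multichannel_record(specs, series, event_times = c(1750, 1800))
  expect_length(suppressWarnings(
    extract_labeled_windows(rec2, 1800)), 0L)

  # event too close to record start: warning, empty result
  rec3 <- multichannel_record(specs, series, event_times = 1000)
  expect_warning(ws3 <- extract_labeled_windows(rec3, 1800), "history")
  expect_length(ws3, 0L)
})

test_that("extraction emits balanced classes by construction", {
  specs <- tiny_specs()
  set.seed(2)
  series <- list(ECG = rnorm(72000), HR = rnorm(7200))
  rec <- multichannel_record(specs, series, event_times = c(1800, 5000, 7200))
  ws <- extract_labeled_windows(rec, 1800)
  labs <- vapply(ws, `[[`, integer(1), "label")
  expect_equal(sum(labs == 0L), sum(labs == 1L))
})

test_that("segmentation yields the documented per-rate segment sizes", {
  specs <- list(channel_spec("ECG", "high_frequency", 125),
                channel_spec("HR", "numeric", 1))
  set.seed(3)
  w <- make_window(list(ECG = rnorm(900 * 125), HR = rnorm(900)), specs,
                   W = 900)
  sw <- segment_window(w, step_seconds = 60)
  expect_equal(sw$M, 15L)
  expect_equal(nrow(sw$segments$ECG), 7500L)
  expect_equal(nrow(sw$segments$HR), 60L)
  expect_error(segment_window(w, step_seconds = 7), "divisible")
})

test_that("concatenated segments reproduce every channel exactly", {
  for (seed in 1:3) {
    w <- random_tiny_window(W = 24, seed = seed)
    sw <- segment_window(w, step_seconds = 6)
    for (ch in names(w$series)) {
      expect_identical(as.vector(sw$segments[[ch]]), w$series[[ch]])
    }
  }
})

test_that("windows serialize to delimited files and read back equal", {
  dir <- withr::local_tempdir()
  ws <- list(random_tiny_window(W = 12, seed = 1, label = 0L, id = "e1_neg",
                                pair = "e1"),
             random_tiny_window(W = 12, seed = 2, label = 1L, id = "e1_pos",
                                pair = "e1"))
  write_windows(ws, dir)
  expect_true(file.exists(file.path(dir, "index.csv")))
  back <- read_windows(dir)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$series$ECG, ws[[i]]$series$ECG, tolerance = 1e-9)
    expect_identical(back[[i]]$label, ws[[i]]$label)
    expect_identical(back[[i]]$window_id, ws[[i]]$window_id)
  }
})
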