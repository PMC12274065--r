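make_accel <- function(x, fs = 100) {
  motion_signal(cbind(x, x, x), fs, mode = "accelerometer")
}

test_that("band-pass filter rejects DC, passes the band, kills drift", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)

  const <- filter_accelerometer(make_accel(rep(1, length(t)), fs))
  mid <- seq(5 * fs, 55 * fs)
  expect_lt(max(abs(const$channels[mid, 1])), 1e-2)
  expect_lt(abs(mean(const$channels[mid, 1])), 1e-6)

  s5 <- filter_accelerometer(make_accel(sin(2 * pi * 5 * t), fs))
  expect_equal(max(abs(s5$channels[mid, 1])), 1, tolerance = 0.05)

  t2 <- seq(0, 120, by = 1 / fs)
  slow <- filter_accelerometer(make_accel(sin(2 * pi * 0.05 * t2), fs))
  mid2 <- seq(20 * fs, 100 * fs)
  expect_lt(max(abs(slow$channels[mid2, 1])), 0.1)   # > 90% attenuation

  expect_error(
    filter_accelerometer(motion_signal(cbind(t, t, t)[1:100, ], 50,
                                       mode = "accelerometer"),
                         high_hz = 30),
    "twice the upper cutoff")
})

test_that("instantaneous activity is the across-axis RMS", {
  m <- motion_signal(matrix(c(3, 4, 0), nrow = 1), 100,
                     mode = "accelerometer")
  a <- instantaneous_activity(m)
  expect_equal(a$values, 5 / sqrt(3), tolerance = 1e-12)

  v <- instantaneous_activity(motion_signal(rep(0, 100), 20, mode = "video"))
  expect_true(all(v$values == 0))
})

test_that("3x3 median filtering removes isolated single-pixel flicker", {
  f1 <- matrix(0, 10, 10)
  f2 <- f1; f2[5, 5] <- 100          # one-pixel flicker
  expect_equal(video_frame_activity(list(f1, f2)), 0)

  f3 <- f1; f3[4:6, 4:6] <- 100      # extended motion survives
  expect_gt(video_frame_activity(list(f1, f3)), 0)
})

test_that("windowed index follows the mean-by-STD definition", {
  fs <- 20
  act <- structure(list(values = rep(2, 60 * fs), sample_rate_hz = fs,
                        t0_s = 0), class = "activity_series")
  idx <- windowed_index(act)
  expect_length(idx$raw_index, 29L)                 # floor((60-4)/2)+1
  expect_true(all(idx$raw_index == 0))              # constant => STD 0
  expect_equal(idx$window_starts_s, seq(0, 56, by = 2))

  act0 <- structure(list(values = rep(0, 10 * fs), sample_rate_hz = fs,
                         t0_s = 0), class = "activity_series")
  expect_true(all(windowed_index(act0)$raw_index == 0))

  short <- structure(list(values = rep(1, 3 * fs), sample_rate_hz = fs,
                          t0_s = 0), class = "activity_series")
  expect_error(windowed_index(short), "shorter than one window")
})

test_that("normalization maps the baseline mean to 1 and the floor to 0", {
  fs <- 20
  set.seed(1)
  v <- c(abs(rnorm(600 * fs, 1, 0.3)), abs(rnorm(600 * fs, 0.01, 0.003)))
  act <- structure(list(values = v, sample_rate_hz = fs, t0_s = 0),
                   class = "activity_series")
  idx <- normalize_index(windowed_index(act), c(0, 600))
  expect_equal(mean(idx$norm_index[idx$is_baseline_window]), 1,
               tolerance = 1e-6)
  expect_true(all(idx$norm_index >= 0))

  # affine map: raw midway between floor and baseline mean -> 0.5
  mid <- (idx$floor + idx$baseline_mean_raw) / 2
  expect_equal((mid - idx$floor) / (idx$baseline_mean_raw - idx$floor), 0.5)

  flat <- structure(list(values = rep(1, 200 * fs), sample_rate_hz = fs,
                         t0_s = 0), class = "activity_series")
  expect_error(normalize_index(windowed_index(flat), c(0, 120)),
               "degenerate baseline")
})

test_that("planted quiescence is classified as one LOM episode near truth", {
  mp <- motion_gen_params(total_s = 2400, baseline_duration_s = 600,
                          episodes = data.frame(onset_s = 900,
                                                duration_s = 120,
                                                level = 0.02),
                          sample_rate_hz = 20)
  res <- activity_pipeline(gen_motion_trace(11, mp, mode = "video"),
                           injection_time_s = 600, horizon_s = 1800)
  lom <- res$states$episodes[res$states$episodes$label == "LOM", ]
  expect_equal(nrow(lom), 1L)
  expect_lte(abs(lom$start_s - 900), 2)
  expect_lte(abs(lom$end_s - 1020), 2)
  expect_equal(res$metrics$latency_fLOM_s, lom$start_s - 600)
})

test_that("a post-injection trace at baseline level stays walking", {
  mp <- motion_gen_params(total_s = 1800, baseline_duration_s = 600,
                          sample_rate_hz = 20)
  res <- activity_pipeline(gen_motion_trace(2, mp, mode = "video"),
                           injection_time_s = 600, horizon_s = 1200)
  expect_true(all(res$states$labels == "walking"))
  expect_true(is.na(res$metrics$latency_fLOM_s))
  expect_true(is.na(res$metrics$total_LOM_s))
})

test_that("a 40 s dip fails the 60 s non-walking gate and is not LOM", {
  mp <- motion_gen_params(total_s = 1800, baseline_duration_s = 600,
                          episodes = data.frame(onset_s = 900,
                                                duration_s = 40,
                                                level = 0.02),
                          sample_rate_hz = 20)
  res <- activity_pipeline(gen_motion_trace(4, mp, mode = "video"),
                           injection_time_s = 600, horizon_s = 1200)
  expect_equal(sum(res$states$episodes$label == "LOM"), 0L)
  expect_equal(sum(res$states$episodes$label == "nonwalking"), 0L)
})

test_that("LOM metrics follow episode arithmetic and horizon clipping", {
  st <- structure(list(
    window_starts_s = seq(0, 1598, by = 2), step_s = 2,
    labels = character(0),
    episodes = data.frame(
      start_s = c(0, 600, 900, 1200),
      end_s = c(600, 900, 1200, 1500),
      label = c("walking", "LOM", "walking", "LOM")),
    injection_time_s = 0), class = "locomotor_states")
  m <- lom_metrics(st, injection_time_s = 0, horizon_s = 3600)
  expect_equal(m$latency_fLOM_s, 600)
  expect_equal(m$duration_fLOM_s, 300)
  expect_equal(m$total_LOM_s, 600)

  clipped <- lom_metrics(st, injection_time_s = 0, horizon_s = 1350)
  expect_equal(clipped$total_LOM_s, 300 + 150)   # second episode clipped

  st$episodes <- st$episodes[st$episodes$label != "LOM", ]
  none <- lom_metrics(st, 0)
  expect_true(all(is.na(unlist(none))))
})

test_that("the LOM pipeline is invariant to positive gain of the trace", {
  mp <- motion_gen_params(total_s = 2400, baseline_duration_s = 600,
                          episodes = data.frame(onset_s = 1000,
                                                duration_s = 150,
                                                level = 0.02),
                          sample_rate_hz = 20)
  m <- gen_motion_trace(8, mp, mode = "video")
  res1 <- activity_pipeline(m, injection_time_s = 600, horizon_s = 1800)
  m$channels <- m$channels * 37.5
  res2 <- activity_pipeline(m, injection_time_s = 600, horizon_s = 1800)
  expect_identical(res1$states$labels, res2$states$labels)
  expect_equal(res1$metrics, res2$metrics)
  expect_equal(res1$series$norm_index, res2$series$norm_index,
               tolerance = 1e-9)
})

test_that("lengthening a planted episode never decreases total LOM", {
  totals <- vapply(c(90, 120, 180, 300), function(dur) {
    mp <- motion_gen_params(total_s = 2400, baseline_duration_s = 600,
                            episodes = data.frame(onset_s = 900,
                                                  duration_s = dur,
                                                  level = 0.02),
                            sample_rate_hz = 20)
    res <- activity_pipeline(gen_motion_trace(5, mp, mode = "video"),
                             injection_time_s = 600, horizon_s = 1800)
    res$metrics$total_LOM_s
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})
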