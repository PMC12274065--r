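#' Zero-phase band-pass filter an accelerometer signal
#'
#' Applies a fifth-order Butterworth band-pass (default 0.5-20 Hz) forward
#' and backward (`signal::filtfilt`) to each axis, removing the DC/gravity
#' component with no group delay.
#'
#' @param signal A 3-channel accelerometer [motion_signal()].
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Butterworth order.
#' @return A filtered [motion_signal()] (truth attributes carried over).
#' @export
filter_accelerometer <- function(signal, low_hz = 0.5, high_hz = 20,
                                 order = 5) {
  stopifnot(inherits(signal, "motion_signal"))
  if (signal$mode != "accelerometer") {
    stop("filter_accelerometer expects an accelerometer signal", call. = FALSE)
  }
  fs <- signal$sample_rate_hz
  if (fs <= 2 * high_hz) {
    stop("sample rate (", fs, " Hz) must exceed twice the upper cutoff (",
         high_hz, " Hz); check the recording rate", call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  ## demeaning first keeps filtfilt edge transients from re-injecting DC
  ch <- apply(signal$channels, 2,
              function(x) signal::filtfilt(bf, x - mean(x)))
  motion_signal(ch, fs, mode = "accelerometer", t0_s = signal$t0_s,
                truth = signal$truth)
}

#' Instantaneous activity from a motion signal
#'
#' Accelerometer mode: the across-axis root mean square of the (filtered)
#' x, y, z channels at each sample. Video mode: the per-frame motion
#' scalar is passed through (values must be non-negative).
#'
#' @param signal A [motion_signal()]; accelerometer input should already be
#'   band-pass filtered (see [filter_accelerometer()]).
#' @return An `activity_series` (values, sample rate, t0).
#' @export
instantaneous_activity <- function(signal) {
  stopifnot(inherits(signal, "motion_signal"))
  if (signal$mode == "accelerometer") {
    if (ncol(signal$channels) != 3L) {
      stop("accelerometer mode requires exactly 3 channels", call. = FALSE)
    }
    v <- sqrt(rowMeans(signal$channels^2))
  } else {
    v <- signal$channels
    if (any(v < 0)) stop("video motion scalars must be non-negative",
                         call. = FALSE)
  }
  structure(list(values = v, sample_rate_hz = signal$sample_rate_hz,
                 t0_s = signal$t0_s),
            class = "activity_series")
}

#' Per-frame video motion operator
#'
#' The frame-level front end of the video pipeline: absolute frame-by-frame
#' intensity difference, 3x3 median filtering (which removes isolated
#' single-pixel changes), then the count of displaced pixels (filtered
#' difference above `threshold`).
#'
#' @param frames List of numeric matrices (equal dimensions).
#' @param threshold Displacement threshold on the filtered difference.
#' @return Numeric vector of length `length(frames) - 1`.
#' @export
video_frame_activity <- function(frames, threshold = 0) {
  stopifnot(is.list(frames), length(frames) >= 2L)
  vapply(seq_len(length(frames) - 1L), function(i) {
    d <- abs(frames[[i + 1L]] - frames[[i]])
    sum(median_filter_3x3(d) > threshold)
  }, numeric(1))
}

median_filter_3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  stack <- array(0, dim = c(nr, nc, 9L))
  k <- 0L
  for (dr in 0:2) for (dc in 0:2) {
    k <- k + 1L
    stack[, , k] <- p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  }
  apply(stack, c(1, 2), stats::median)
}

#' Windowed mean-by-STD activity index
#'
#' Slides windows of `window_s` seconds with the given overlap (default
#' 4 s, 50%, i.e. a 2 s step) over the instantaneous activity, anchored at
#' the first sample, and computes the raw index mean(window) x SD(window):
#' sustained activity weighted by its variability, so both stillness and
#' perfectly constant output score 0.
#'
#' @param activity An `activity_series` from [instantaneous_activity()].
#' @param window_s Window length in seconds.
#' @param overlap Fractional overlap between consecutive windows.
#' @return An `activity_index` with window starts/centers and `raw_index`;
#'   `norm_index` is filled by [normalize_index()].
#' @export
windowed_index <- function(activity, window_s = 4, overlap = 0.5) {
  stopifnot(inherits(activity, "activity_series"))
  fs <- activity$sample_rate_hz
  v <- activity$values
  wlen <- round(window_s * fs)
  step <- round(window_s * (1 - overlap) * fs)
  if (length(v) < wlen) {
    stop("activity series shorter than one window (", window_s, " s)",
         call. = FALSE)
  }
  starts <- seq.int(1L, length(v) - wlen + 1L, by = step)
  raw <- vapply(starts, function(i) {
    w <- v[i:(i + wlen - 1L)]
    mean(w) * stats::sd(w)
  }, numeric(1))
  start_s <- activity$t0_s + (starts - 1L) / fs
  structure(list(window_starts_s = start_s,
                 window_centers_s = start_s + window_s / 2,
                 raw_index = raw, norm_index = NULL,
                 window_s = window_s, overlap = overlap,
                 step_s = window_s * (1 - overlap),
                 baseline_interval_s = NULL),
            class = "activity_index")
}

#' @export
print.activity_index <- function(x, ...) {
  cat(sprintf("<activity_index> %d windows of %g s (step %g s)%s\n",
              length(x$raw_index), x$window_s, x$step_s,
              if (is.null(x$norm_index)) " [raw]" else " [normalized]"))
  invisible(x)
}

#' Normalize the activity index to the walking baseline
#'
#' Affine normalization so that complete cessation of activity maps to
#' about 0 and the pre-injection walking baseline averages exactly 1:
#' `norm = (raw - floor) / (baseline_mean - floor)`, clipped at 0, where
#' `floor` is the 1st percentile of the raw index over the whole recording
#' (a robust stand-in for a true zero-activity segment) and
#' `baseline_mean` is the mean raw index over windows fully inside the
#' baseline interval.
#'
#' @param series An `activity_index` from [windowed_index()].
#' @param baseline_interval_s Length-2 numeric, the baseline `[start, end)`
#'   in seconds; must span at least 60 s.
#' @param floor_quantile Quantile of the raw index used as the cessation
#'   floor.
#' @return The `activity_index` with `norm_index` filled in.
#' @export
normalize_index <- function(series, baseline_interval_s,
                            floor_quantile = 0.01) {
  stopifnot(inherits(series, "activity_index"),
            length(baseline_interval_s) == 2L)
  b0 <- baseline_interval_s[1]; b1 <- baseline_interval_s[2]
  if (b1 - b0 < 60) stop("baseline interval must span at least 60 s",
                         call. = FALSE)
  base <- series$window_starts_s >= b0 &
    series$window_starts_s + series$window_s <= b1
  if (!any(base)) stop("no windows fall inside the baseline interval",
                       call. = FALSE)
  flo <- as.numeric(stats::quantile(series$raw_index, floor_quantile,
                                    names = FALSE))
  bmean <- mean(series$raw_index[base])
  if (bmean <= flo) {
    stop("degenerate baseline: mean baseline index does not exceed the ",
         "cessation floor", call. = FALSE)
  }
  series$norm_index <- pmax((series$raw_index - flo) / (bmean - flo), 0)
  series$baseline_interval_s <- c(b0, b1)
  series$is_baseline_window <- base
  series$floor <- flo
  series$baseline_mean_raw <- bmean
  series
}

#' Classify windows into walking / non-walking / LOM
#'
#' Windows are walking by default. Maximal runs of consecutive windows with
#' normalized activity below the lower bound of the baseline's 95%
#' confidence band that last at least `nonwalk_min_s` become non-walking;
#' within a non-walking run, maximal sub-runs below `lom_level` lasting at
#' least `lom_min_s` are reclassified as loss of movement (LOM). The
#' baseline bound is the empirical 2.5th percentile of baseline window
#' values by default (`ci_method = "empirical"`), or mean - 1.96 SD with
#' `ci_method = "parametric"`. Run durations are counted in window steps;
#' episode boundaries snap to window starts, so boundary placement is
#' accurate to one step (2 s at the defaults). Adjacent sub-threshold runs
#' separated by a single supra-threshold window are not merged.
#'
#' @param series A normalized `activity_index` (see [normalize_index()]).
#' @param injection_time_s Injection time in seconds; must lie within the
#'   classified span.
#' @param lom_level Normalized-activity threshold for LOM (default 0.25).
#' @param nonwalk_min_s Minimum non-walking run duration (default 60 s).
#' @param lom_min_s Minimum LOM run duration (default 30 s).
#' @param ci_method Baseline lower-bound estimator (see above).
#' @return A `locomotor_states` object: per-window `labels`, an `episodes`
#'   data frame (`start_s`, `end_s`, `label`) tiling the classified span,
#'   and the thresholds used.
#' @export
classify_states <- function(series, injection_time_s, lom_level = 0.25,
                            nonwalk_min_s = 60, lom_min_s = 30,
                            ci_method = c("empirical", "parametric")) {
  stopifnot(inherits(series, "activity_index"))
  if (is.null(series$norm_index)) {
    stop("series must be normalized first (normalize_index)", call. = FALSE)
  }
  ci_method <- match.arg(ci_method)
  ws <- series$window_starts_s
  step <- series$step_s
  span <- c(ws[1], ws[length(ws)] + step)
  if (injection_time_s < span[1] || injection_time_s > span[2]) {
    stop("injection time outside the classified span", call. = FALSE)
  }
  bvals <- series$norm_index[series$is_baseline_window]
  thr <- if (ci_method == "empirical") {
    as.numeric(stats::quantile(bvals, 0.025, names = FALSE))
  } else {
    mean(bvals) - 1.96 * stats::sd(bvals)
  }

  n <- length(ws)
  labels <- rep("walking", n)
  low <- series$norm_index < thr
  r <- rle(low)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  k_nonwalk <- ceiling(nonwalk_min_s / step)
  k_lom <- ceiling(lom_min_s / step)
  for (j in which(r$values & r$lengths >= k_nonwalk)) {
    i0 <- starts_i[j]; i1 <- ends_i[j]
    labels[i0:i1] <- "nonwalking"
    deep <- series$norm_index[i0:i1] < lom_level
    r2 <- rle(deep)
    e2 <- cumsum(r2$lengths); s2 <- e2 - r2$lengths + 1L
    for (m in which(r2$values & r2$lengths >= k_lom)) {
      labels[(i0 + s2[m] - 1L):(i0 + e2[m] - 1L)] <- "LOM"
    }
  }

  rl <- rle(labels)
  re <- cumsum(rl$lengths); rs <- re - rl$lengths + 1L
  episodes <- data.frame(start_s = ws[rs], end_s = ws[re] + step,
                         label = rl$values, stringsAsFactors = FALSE)
  structure(list(window_starts_s = ws, step_s = step, labels = labels,
                 episodes = episodes, injection_time_s = injection_time_s,
                 nonwalk_threshold = thr, lom_level = lom_level,
                 nonwalk_min_s = nonwalk_min_s, lom_min_s = lom_min_s),
            class = "locomotor_states")
}

#' @export
print.locomotor_states <- function(x, ...) {
  tab <- table(x$labels)
  cat("<locomotor_states>", length(x$labels), "windows:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  nlom <- sum(x$episodes$label == "LOM")
  cat("  ", nlom, "LOM episode(s); non-walking threshold",
      sprintf("%.3f", x$nonwalk_threshold), "\n")
  invisible(x)
}

#' Latency, duration and total time of loss of movement
#'
#' The first LOM (fLOM) is the first LOM episode with onset at or after the
#' injection. Latency is its onset minus the injection time; duration is
#' that episode's full length; total LOM is the summed LOM time clipped to
#' the analysis horizon `[injection, injection + horizon_s)`. With no LOM
#' episode all three are `NA` (missing, never 0).
#'
#' @param states A `locomotor_states` from [classify_states()].
#' @param injection_time_s Injection time (seconds).
#' @param horizon_s Analysis horizon after injection (default 3600 s).
#' @return A one-row data frame with `latency_fLOM_s`, `duration_fLOM_s`,
#'   `total_LOM_s`.
#' @export
lom_metrics <- function(states, injection_time_s, horizon_s = 3600) {
  stopifnot(inherits(states, "locomotor_states"))
  ep <- states$episodes
  lom <- ep[ep$label == "LOM" & ep$start_s >= injection_time_s, , drop = FALSE]
  h1 <- injection_time_s + horizon_s
  if (nrow(lom) == 0L) {
    return(data.frame(latency_fLOM_s = NA_real_, duration_fLOM_s = NA_real_,
                      total_LOM_s = NA_real_))
  }
  first <- lom[which.min(lom$start_s), ]
  clip <- pmin(lom$end_s, h1) - pmax(lom$start_s, injection_time_s)
  data.frame(latency_fLOM_s = first$start_s - injection_time_s,
             duration_fLOM_s = first$end_s - first$start_s,
             total_LOM_s = sum(pmax(clip, 0)))
}

#' Run the full motion-to-LOM pipeline
#'
#' Convenience wrapper: band-pass filter (accelerometer mode only),
#' instantaneous activity, windowed mean-by-STD index, baseline
#' normalization, state classification and LOM metrics.
#'
#' @param motion A [motion_signal()].
#' @param injection_time_s Injection time (seconds).
#' @param baseline_interval_s Baseline `[start, end)`; defaults to the
#'   10 minutes (or whatever precedes injection) before injection.
#' @param horizon_s Analysis horizon (seconds).
#' @param ... Passed to [classify_states()].
#' @return List with elements `series`, `states`, `metrics`.
#' @export
activity_pipeline <- function(motion, injection_time_s,
                              baseline_interval_s = c(max(0, injection_time_s - 600),
                                                      injection_time_s),
                              horizon_s = 3600, ...) {
  if (motion$mode == "accelerometer") motion <- filter_accelerometer(motion)
  act <- instantaneous_activity(motion)
  idx <- windowed_index(act)
  idx <- normalize_index(idx, baseline_interval_s)
  st <- classify_states(idx, injection_time_s, ...)
  list(series = idx, states = st,
       metrics = lom_metrics(st, injection_time_s, horizon_s))
}
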