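#' Read a spikes table
#'
#' Reads a tab-delimited spikes file with required header
#' `unit_id<TAB>time_s`, one row per spike, times in seconds. Times must be
#' strictly increasing within each unit.
#'
#' @param path Path to a TSV file.
#' @return Named list of [spike_train()] objects, one per unit, in order of
#'   first appearance.
#' @export
read_spikes <- function(path) {
  df <- read_tsv_checked(path, c("unit_id", "time_s"))
  df$unit_id <- as.character(df$unit_id)
  units <- unique(df$unit_id)
  out <- lapply(units, function(u) {
    t <- df$time_s[df$unit_id == u]
    if (anyNA(t) || any(t < 0) || (length(t) > 1 && any(diff(t) <= 0))) {
      stop("validation error in ", path, ": unit '", u,
           "' has non-monotone or negative spike times", call. = FALSE)
    }
    spike_train(u, t)
  })
  names(out) <- units
  out
}

#' Read an epochs table
#'
#' Tab-delimited with header `start_s`, `end_s`, `label`. Unknown labels
#' and overlapping same-label rows are rejected.
#'
#' @param path Path to a TSV file.
#' @return An [epoch_set()].
#' @export
read_epochs <- function(path) {
  df <- read_tsv_checked(path, c("start_s", "end_s", "label"))
  x <- df
  class(x) <- c("epoch_set", "data.frame")
  d <- validate_epoch_set(x)
  if (nrow(d) > 0L) {
    stop("validation error in ", path, ": ",
         paste(d$rule, collapse = "; "), call. = FALSE)
  }
  epoch_set(df$start_s, df$end_s, df$label)
}

#' Read a motion signal
#'
#' Comma-delimited with header either `time_s,ax_g,ay_g,az_g`
#' (accelerometer) or `time_s,motion` (video motion scalar). Sampling must
#' be uniform; the rate is inferred from the time column.
#'
#' @param path Path to a CSV file.
#' @return A [motion_signal()].
#' @export
read_motion <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  acc_cols <- c("time_s", "ax_g", "ay_g", "az_g")
  vid_cols <- c("time_s", "motion")
  if (identical(hdr, acc_cols)) mode <- "accelerometer"
  else if (identical(hdr, vid_cols)) mode <- "video"
  else stop("format error in ", path, " line 1: header must be '",
            paste(acc_cols, collapse = ","), "' or '",
            paste(vid_cols, collapse = ","), "'", call. = FALSE)
  df <- utils::read.csv(path)
  if (nrow(df) < 2L) stop("format error in ", path, ": need >= 2 samples",
                          call. = FALSE)
  dt <- diff(df$time_s)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) {
    stop("validation error in ", path, ": non-uniform sampling", call. = FALSE)
  }
  rate <- 1 / dt[1]
  ch <- if (mode == "accelerometer") as.matrix(df[, acc_cols[-1]]) else df$motion
  motion_signal(ch, sample_rate_hz = rate, mode = mode, t0_s = df$time_s[1])
}

#' Read a pulse-train table
#'
#' Tab-delimited with header `onset_s`, `width_s`.
#'
#' @param path Path to a TSV file.
#' @return A [pulse_protocol()].
#' @export
read_pulses <- function(path) {
  df <- read_tsv_checked(path, c("onset_s", "width_s"))
  pulse_protocol(df$onset_s, df$width_s, meta = list(kind = "file", path = path))
}

#' Read a validated session from disk
#'
#' @param paths Named list of file paths with elements `spikes`, `epochs`,
#'   and optionally `motion` and `pulses`.
#' @param config Named list of session settings; `injection_time_s` is
#'   honored when present.
#' @return A validated [session()]; a violated invariant raises an error.
#' @export
read_session <- function(paths, config = list()) {
  s <- session(
    spike_trains = if (!is.null(paths$spikes)) read_spikes(paths$spikes) else list(),
    epochs = if (!is.null(paths$epochs)) read_epochs(paths$epochs) else NULL,
    motion = if (!is.null(paths$motion)) read_motion(paths$motion) else NULL,
    pulses = if (!is.null(paths$pulses)) read_pulses(paths$pulses) else NULL,
    injection_time_s = config$injection_time_s,
    config = config)
  d <- validate_session(s)
  if (nrow(d) > 0L) {
    stop("invalid session: ", paste(d$rule, collapse = "; "), call. = FALSE)
  }
  s
}

#' Write a results table as TSV
#'
#' Writes any non-empty data frame with a header row, tab delimiter,
#' deterministic column order (as given) and numeric values at 6
#' significant digits, so `read.delim()` round-trips the values.
#'
#' @param metrics A non-empty data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_results <- function(metrics, path) {
  metrics <- as.data.frame(metrics)
  if (nrow(metrics) == 0L || ncol(metrics) == 0L) {
    stop("refusing to write an empty results table", call. = FALSE)
  }
  out <- metrics
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- trimws(formatC(out[[j]], digits = 6, format = "g"))
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Write spike trains as a spikes TSV
#'
#' @param trains List of [spike_train()] objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_spikes <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(tr) {
    data.frame(unit_id = tr$unit_id, time_s = tr$spike_times_s,
               stringsAsFactors = FALSE)
  }))
  write_results(df, path)
}

#' Write an epoch set as TSV
#' @param epochs An [epoch_set()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_epochs <- function(epochs, path) {
  write_results(as.data.frame(epochs), path)
}

#' Write a motion signal as CSV
#' @param signal A [motion_signal()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_motion <- function(signal, path) {
  n <- n_samples(signal)
  t <- signal$t0_s + (seq_len(n) - 1L) / signal$sample_rate_hz
  if (signal$mode == "accelerometer") {
    df <- data.frame(time_s = t, ax_g = signal$channels[, 1],
                     ay_g = signal$channels[, 2], az_g = signal$channels[, 3])
  } else {
    df <- data.frame(time_s = t, motion = signal$channels)
  }
  for (j in seq_along(df)) {
    df[[j]] <- trimws(formatC(df[[j]], digits = 8, format = "g"))
  }
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a pulse protocol as TSV
#' @param pulses A [pulse_protocol()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_pulses <- function(pulses, path) {
  write_results(data.frame(onset_s = pulses$onsets_s,
                           width_s = pulses$width_s), path)
}

read_tsv_checked <- function(path, expected_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, expected_cols)) {
    stop("format error in ", path, " line 1: expected header '",
         paste(expected_cols, collapse = "\t"), "', found '",
         paste(hdr, collapse = "\t"), "'", call. = FALSE)
  }
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`, optionally grouped under `[section]`
#' headers; blank lines and `#` comments ignored. Values are parsed as
#' numeric when possible and comma-separated values become vectors. The
#' result is a nested list `config$section$key` (top-level keys before any
#' section land at the top level).
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  out <- list()
  sec <- NULL
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      sec <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (is.null(out[[sec]])) out[[sec]] <- list()
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("format error in ", path, " line ", i,
           ": expected 'key = value'", call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(num)) num else parts
    if (is.null(sec)) out[[key]] <- parsed else out[[sec]][[key]] <- parsed
  }
  out
}
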