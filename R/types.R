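#' Recognized brain/behavior state labels
#'
#' Epoch tables may only use these labels; unknown labels are rejected at
#' read/construction time so that mislabeled rows cannot silently leak out
#' of state statistics.
#'
#' @return Character vector of the permitted epoch labels.
#' @export
state_labels <- function() {
  c("walk", "wake", "NREM", "REM", "fLOM", "LOM", "nonwalk")
}

#' Construct a single-unit spike train
#'
#' @param unit_id Single string identifying the unit.
#' @param spike_times_s Numeric vector of spike times in seconds from
#'   recording start, strictly increasing and non-negative.
#' @param p2v_width_us Optional peak-to-valley spike width in microseconds
#'   (must be positive when given); used for regular- vs narrow-spiking
#'   classification.
#' @param truth Optional list of generator ground truth (see
#'   [gen_spike_train()]); `NULL` for recorded data.
#'
#' @return An object of class `spike_train`.
#' @seealso [detect_bursts()], [autocorrelogram()]
#' @export
spike_train <- function(unit_id, spike_times_s, p2v_width_us = NULL,
                        truth = NULL) {
  x <- structure(
    list(unit_id = as.character(unit_id),
         spike_times_s = as.numeric(spike_times_s),
         p2v_width_us = if (is.null(p2v_width_us)) NULL else
           as.numeric(p2v_width_us),
         truth = truth),
    class = "spike_train")
  d <- validate_spike_train(x)
  if (nrow(d) > 0L) {
    stop("invalid spike_train '", x$unit_id, "': ",
         paste(d$rule, collapse = "; "), call. = FALSE)
  }
  x
}

validate_spike_train <- function(x) {
  d <- empty_diagnostics()
  id <- x$unit_id
  if (length(id) != 1L || is.na(id) || !nzchar(id)) {
    d <- add_diagnostic(d, "unit_id", "unit_id must be a non-empty string")
  }
  t <- x$spike_times_s
  if (anyNA(t)) {
    d <- add_diagnostic(d, "spike_times_s",
                        paste0("unit ", id, ": spike times contain NA"))
  } else {
    if (any(t < 0)) {
      d <- add_diagnostic(d, "spike_times_s",
                          paste0("unit ", id, ": negative spike times"))
    }
    if (length(t) > 1L && any(diff(t) <= 0)) {
      d <- add_diagnostic(d, "spike_times_s",
                          paste0("unit ", id,
                                 ": spike times not strictly increasing"))
    }
  }
  w <- x$p2v_width_us
  if (!is.null(w) && (length(w) != 1L || is.na(w) || w <= 0)) {
    d <- add_diagnostic(d, "p2v_width_us",
                        paste0("unit ", id, ": width must be a single",
                               " positive value"))
  }
  d
}

#' @export
print.spike_train <- function(x, ...) {
  n <- length(x$spike_times_s)
  dur <- if (n) max(x$spike_times_s) else 0
  cat("<spike_train> unit", x$unit_id, "-", n, "spikes")
  if (n) cat(sprintf(", span %.1f s, mean rate %.2f Hz", dur, n / max(dur, 1e-9)))
  if (!is.null(x$p2v_width_us)) cat(sprintf(", p2v width %g us", x$p2v_width_us))
  if (!is.null(x$truth)) cat(" [synthetic, ground truth attached]")
  cat("\n")
  invisible(x)
}

#' Construct a labeled epoch set
#'
#' Epochs are half-open intervals `[start_s, end_s)` labeling brain or
#' behavior states. A time point t belongs to an epoch iff
#' `start_s <= t < end_s`, so a spike exactly at an epoch end falls in the
#' following epoch. Epochs sharing a label must not overlap.
#'
#' @param start_s,end_s Numeric vectors of epoch boundaries in seconds.
#' @param label Character vector of state labels; see [state_labels()].
#'
#' @return An object of class `epoch_set` (a data frame with columns
#'   `start_s`, `end_s`, `label`).
#' @export
epoch_set <- function(start_s, end_s, label) {
  x <- data.frame(start_s = as.numeric(start_s),
                  end_s = as.numeric(end_s),
                  label = as.character(label),
                  stringsAsFactors = FALSE)
  class(x) <- c("epoch_set", "data.frame")
  d <- validate_epoch_set(x)
  if (nrow(d) > 0L) {
    stop("invalid epoch_set: ", paste(d$rule, collapse = "; "),
         call. = FALSE)
  }
  x
}

validate_epoch_set <- function(x) {
  d <- empty_diagnostics()
  if (nrow(x) == 0L) return(d)
  bad <- which(!(x$end_s > x$start_s))
  for (i in bad) {
    d <- add_diagnostic(d, "epochs",
                        paste0("row ", i, ": end_s must exceed start_s"))
  }
  unk <- which(!(x$label %in% state_labels()))
  for (i in unk) {
    d <- add_diagnostic(d, "epochs",
                        paste0("row ", i, ": unknown label '", x$label[i], "'"))
  }
  for (lb in unique(x$label)) {
    idx <- which(x$label == lb)
    if (length(idx) < 2L) next
    o <- idx[order(x$start_s[idx])]
    if (any(x$start_s[o][-1] < x$end_s[o][-length(o)])) {
      d <- add_diagnostic(d, "epochs",
                          paste0("label '", lb,
                                 "': same-label epochs overlap"))
    }
  }
  d
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>", nrow(x), "epochs,",
      sprintf("%.1f s labeled", sum(x$end_s - x$start_s)), "\n")
  tab <- tapply(x$end_s - x$start_s, x$label, sum)
  for (lb in names(tab)) cat(sprintf("  %-8s %8.1f s\n", lb, tab[[lb]]))
  invisible(x)
}

#' Total labeled duration per state
#'
#' @param epochs An [epoch_set()].
#' @param label Optional label to restrict to.
#' @return Named numeric vector of summed epoch durations (seconds).
#' @export
epoch_durations <- function(epochs, label = NULL) {
  if (!is.null(label)) epochs <- epochs[epochs$label %in% label, , drop = FALSE]
  if (nrow(epochs) == 0L) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(epochs$end_s - epochs$start_s, epochs$label, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Test half-open epoch membership
#'
#' Returns, for each time, the row index of the containing epoch among the
#' epochs of one label, or `NA` if uncontained. Containment is half-open:
#' `start <= t < end`.
#'
#' @param times_s Numeric vector of times (seconds).
#' @param epochs An [epoch_set()] whose rows share a label (or any
#'   non-overlapping set).
#' @return Integer vector of row indices into `epochs` (NA = outside).
#' @export
epoch_membership <- function(times_s, epochs) {
  if (nrow(epochs) == 0L) return(rep(NA_integer_, length(times_s)))
  o <- order(epochs$start_s)
  starts <- epochs$start_s[o]
  ends <- epochs$end_s[o]
  idx <- findInterval(times_s, starts)
  inside <- idx >= 1L & times_s < ends[pmax(idx, 1L)]
  out <- rep(NA_integer_, length(times_s))
  out[inside] <- o[idx[inside]]
  out
}

#' Construct a motion signal
#'
#' @param channels Numeric matrix with 3 columns (accelerometer mode,
#'   axes in g) or a numeric vector (video mode, per-frame motion scalar).
#' @param sample_rate_hz Sampling rate; accelerometer mode requires
#'   at least 50 Hz.
#' @param mode `"accelerometer"` or `"video"`.
#' @param t0_s Time of the first sample (seconds).
#' @param truth Optional generator ground truth (see [gen_motion_trace()]).
#'
#' @return An object of class `motion_signal`.
#' @export
motion_signal <- function(channels, sample_rate_hz,
                          mode = c("accelerometer", "video"), t0_s = 0,
                          truth = NULL) {
  mode <- match.arg(mode)
  if (mode == "accelerometer") {
    channels <- as.matrix(channels)
    if (ncol(channels) != 3L) {
      stop("accelerometer mode requires exactly 3 channels", call. = FALSE)
    }
    if (sample_rate_hz < 50) {
      stop("accelerometer mode requires sample_rate_hz >= 50", call. = FALSE)
    }
  } else {
    channels <- as.numeric(channels)
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be positive", call. = FALSE)
  }
  structure(list(channels = channels, sample_rate_hz = sample_rate_hz,
                 mode = mode, t0_s = t0_s, truth = truth),
            class = "motion_signal")
}

n_samples <- function(signal) {
  if (signal$mode == "accelerometer") nrow(signal$channels)
  else length(signal$channels)
}

#' @export
print.motion_signal <- function(x, ...) {
  n <- n_samples(x)
  cat(sprintf("<motion_signal> %s mode, %d samples @ %g Hz (%.1f s from t0=%g)\n",
              x$mode, n, x$sample_rate_hz, n / x$sample_rate_hz, x$t0_s))
  if (!is.null(x$truth)) {
    cat("  synthetic;", nrow(x$truth$episodes), "planted episode(s)\n")
  }
  invisible(x)
}

#' Construct a stimulation pulse protocol
#'
#' @param onsets_s Strictly increasing pulse onset times (seconds).
#' @param width_s Pulse duration(s) in seconds; scalar or per-pulse.
#'   Pulses must not overlap: `onset[i] + width[i] <= onset[i+1]`.
#' @param meta List of protocol metadata (kind and parameters).
#'
#' @return An object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(onsets_s, width_s, meta = list()) {
  onsets_s <- as.numeric(onsets_s)
  width_s <- as.numeric(width_s)
  if (length(width_s) == 1L) width_s <- rep(width_s, length(onsets_s))
  if (length(width_s) != length(onsets_s)) {
    stop("width_s must be scalar or match onsets_s in length", call. = FALSE)
  }
  if (any(width_s <= 0)) stop("pulse widths must be positive", call. = FALSE)
  if (length(onsets_s) > 1L) {
    if (any(diff(onsets_s) <= 0)) {
      stop("pulse onsets must be strictly increasing", call. = FALSE)
    }
    if (any(onsets_s[-length(onsets_s)] + width_s[-length(width_s)] >
            onsets_s[-1] + 1e-12)) {
      stop("pulses overlap: onset[i] + width must not exceed onset[i+1]",
           call. = FALSE)
    }
  }
  structure(list(onsets_s = onsets_s, width_s = width_s, meta = meta),
            class = "pulse_protocol")
}

#' @export
print.pulse_protocol <- function(x, ...) {
  kind <- if (!is.null(x$meta$kind)) x$meta$kind else "custom"
  cat(sprintf("<pulse_protocol> %s: %d pulses, total ON %.3f s\n",
              kind, length(x$onsets_s), sum(x$width_s)))
  invisible(x)
}

#' Bundle recording components into a session
#'
#' @param spike_trains List of [spike_train()] objects.
#' @param epochs An [epoch_set()].
#' @param motion A [motion_signal()], or `NULL`.
#' @param pulses Optional [pulse_protocol()].
#' @param injection_time_s Optional injection time (seconds); required by
#'   the loss-of-movement analysis.
#' @param config Optional named list of analysis settings.
#'
#' @return An object of class `session`.
#' @export
session <- function(spike_trains = list(), epochs = NULL, motion = NULL,
                    pulses = NULL, injection_time_s = NULL, config = list()) {
  structure(list(spike_trains = spike_trains, epochs = epochs,
                 motion = motion, pulses = pulses,
                 injection_time_s = injection_time_s, config = config),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat("<session>", length(x$spike_trains), "unit(s);",
      if (is.null(x$epochs)) "no epochs" else paste(nrow(x$epochs), "epochs"),
      ";", if (is.null(x$motion)) "no motion signal" else "motion signal",
      "\n")
  invisible(x)
}

empty_diagnostics <- function() {
  data.frame(field = character(0), rule = character(0),
             stringsAsFactors = FALSE)
}

add_diagnostic <- function(d, field, rule) {
  rbind(d, data.frame(field = field, rule = rule, stringsAsFactors = FALSE))
}

#' Validate a session and list violated invariants
#'
#' Checks the invariants of every component (spike times strictly
#' increasing and non-negative, epoch intervals well formed with known
#' labels and no same-label overlap, pulse non-overlap) plus
#' cross-component rules: all referenced times must lie within the
#' recording span and, when present, the injection time must too. Returns
#' diagnostics instead of raising, so a session can be screened in full.
#'
#' @param x A [session()].
#' @return A data frame with columns `field` and `rule`; zero rows iff all
#'   invariants hold.
#' @export
validate_session <- function(x) {
  d <- empty_diagnostics()
  for (tr in x$spike_trains) d <- rbind(d, validate_spike_train(tr))
  if (!is.null(x$epochs)) d <- rbind(d, validate_epoch_set(x$epochs))

  span_end <- session_span(x)
  if (!is.null(x$motion) && !is.null(x$epochs) && nrow(x$epochs)) {
    if (any(x$epochs$end_s > span_end + 1e-9)) {
      d <- add_diagnostic(d, "epochs",
                          "epoch extends beyond the recording span")
    }
  }
  if (!is.null(x$motion)) {
    for (tr in x$spike_trains) {
      t <- tr$spike_times_s
      if (length(t) && max(t) > span_end + 1e-9) {
        d <- add_diagnostic(d, "spike_trains",
                            paste0("unit ", tr$unit_id,
                                   ": spike beyond the recording span"))
      }
    }
  }
  if (!is.null(x$injection_time_s)) {
    if (x$injection_time_s < 0 || x$injection_time_s > span_end) {
      d <- add_diagnostic(d, "injection_time_s",
                          "injection time outside the recording span")
    }
  }
  d
}

session_span <- function(x) {
  ends <- c(0)
  if (!is.null(x$motion)) {
    ends <- c(ends, x$motion$t0_s + n_samples(x$motion) / x$motion$sample_rate_hz)
  }
  if (!is.null(x$epochs) && nrow(x$epochs)) ends <- c(ends, max(x$epochs$end_s))
  for (tr in x$spike_trains) {
    if (length(tr$spike_times_s)) ends <- c(ends, max(tr$spike_times_s))
  }
  max(ends)
}
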