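#' Spike-train autocorrelogram
#'
#' One-sided lag histogram of all ordered spike pairs at 1 ms resolution,
#' zero-lag self-pairs excluded. Bin `k` covers lags `[k - 0.5, k + 0.5)`
#' ms for `k = 1..max_lag_ms`; lags below 0.5 ms are discarded. Counts are
#' raw pair counts (the burst indices below are count ratios, so rate
#' normalization would cancel).
#'
#' @param train A [spike_train()] with at least 2 spikes.
#' @param max_lag_ms Maximum lag in ms.
#' @return An object of class `acg`: `counts` (length `max_lag_ms`),
#'   `lags_ms`, `bin_ms = 1`, `n_spikes`.
#' @export
autocorrelogram <- function(train, max_lag_ms = 100) {
  stopifnot(inherits(train, "spike_train"))
  t <- train$spike_times_s
  n <- length(t)
  if (n < 2L) stop("autocorrelogram needs at least 2 spikes", call. = FALSE)
  max_lag_ms <- as.integer(max_lag_ms)
  lim <- (max_lag_ms + 0.5) / 1000
  hi <- findInterval(t + lim, t)
  m <- pmax(hi - seq_len(n), 0L)
  ii <- rep.int(seq_len(n), m)
  jj <- sequence(m) + ii
  lag_ms <- (t[jj] - t[ii]) * 1000
  k <- as.integer(floor(lag_ms + 0.5))
  k <- k[k >= 1L & k <= max_lag_ms]
  as_acg(tabulate(k, nbins = max_lag_ms), n_spikes = n)
}

#' Construct an autocorrelogram object from bin counts
#'
#' For analytically constructed histograms (tests, closed-form checks).
#'
#' @param counts Non-negative integer counts for lag bins 1..length(counts)
#'   ms (bin k covers `[k - 0.5, k + 0.5)` ms).
#' @param n_spikes Optional number of spikes behind the histogram.
#' @return An object of class `acg`.
#' @export
as_acg <- function(counts, n_spikes = NA_integer_) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("autocorrelogram counts must be >= 0",
                            call. = FALSE)
  structure(list(counts = counts, lags_ms = seq_along(counts), bin_ms = 1,
                 max_lag_ms = length(counts), n_spikes = n_spikes),
            class = "acg")
}

#' @export
print.acg <- function(x, ...) {
  cat(sprintf("<acg> 1 ms bins to %d ms, %d pairs\n",
              x$max_lag_ms, sum(x$counts)))
  invisible(x)
}

#' Autocorrelogram burst index
#'
#' Subtracts the 40-50 ms baseline (mean count) from the 0-10 ms peak
#' (maximum single bin, earliest on ties). A positive amplitude is
#' normalized to the peak and a negative one to the baseline, giving an
#' index in `[-1, 1]`: +1 means all short-lag mass with an empty baseline,
#' 0 a flat correlogram, negative values a short-lag trough.
#'
#' @param acg An `acg` covering at least 50 ms.
#' @return Numeric index in `[-1, 1]`. A histogram with zero peak and zero
#'   baseline returns 0 with a warning (degenerate input).
#' @export
burst_index <- function(acg) {
  stopifnot(inherits(acg, "acg"))
  if (acg$max_lag_ms < 50) stop("autocorrelogram must cover >= 50 ms",
                                call. = FALSE)
  peak <- max(acg$counts[1:10])
  baseline <- mean(acg$counts[40:50])
  amp <- peak - baseline
  if (peak == 0 && baseline == 0) {
    warning("degenerate autocorrelogram: empty peak and baseline windows")
    return(0)
  }
  if (amp > 0) amp / peak else if (amp < 0) amp / baseline else 0
}

#' Short-to-long lag bursting ratio
#'
#' Ratio of autocorrelogram counts at lags under 10 ms to counts at lags
#' over 50 ms. An empty long-lag window yields `Inf` with a warning.
#'
#' @param acg An `acg` covering more than 50 ms.
#' @return Non-negative number (possibly `Inf`).
#' @export
bursting_ratio_index <- function(acg) {
  stopifnot(inherits(acg, "acg"))
  if (acg$max_lag_ms <= 50) stop("autocorrelogram must cover > 50 ms",
                                 call. = FALSE)
  num <- sum(acg$counts[1:9])
  den <- sum(acg$counts[51:acg$max_lag_ms])
  if (den == 0) {
    warning("no counts above 50 ms; bursting ratio is infinite")
    return(Inf)
  }
  num / den
}

#' Detect low-threshold bursts in a spike train
#'
#' A burst is a maximal run of at least `min_spikes` spikes whose
#' consecutive ISIs are all at most `isi_max_ms`, and whose first spike is
#' preceded by at least `silence_min_ms` of silence (the first spike of the
#' train qualifies). Spikes not in any burst are tonic; bursts and tonic
#' spikes partition the train exactly.
#'
#' @param train A [spike_train()].
#' @param isi_max_ms Maximum intra-burst ISI (ms).
#' @param silence_min_ms Minimum pre-burst silence (ms).
#' @param min_spikes Minimum spikes per burst.
#' @return An object of class `burst_set`: `onsets_s`, `n_spikes` and
#'   `intra_isis_ms` per burst, `is_burst_spike` (logical over all spikes),
#'   `tonic_spike_times_s`, and the criteria used.
#' @export
detect_bursts <- function(train, isi_max_ms = 10, silence_min_ms = 50,
                          min_spikes = 2L) {
  stopifnot(inherits(train, "spike_train"))
  t <- train$spike_times_s
  n <- length(t)
  isi_max <- isi_max_ms / 1000
  sil <- silence_min_ms / 1000

  onsets <- numeric(0)
  sizes <- integer(0)
  isis <- list()
  is_burst <- logical(n)

  if (n >= min_spikes) {
    short <- diff(t) <= isi_max
    r <- rle(short)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- starts_i[j]            # first ISI of the run
      i1 <- ends_i[j] + 1L         # last spike of the run
      if ((i1 - i0 + 1L) < min_spikes) next
      if (i0 > 1L && (t[i0] - t[i0 - 1L]) < sil) next
      onsets <- c(onsets, t[i0])
      sizes <- c(sizes, i1 - i0 + 1L)
      isis <- c(isis, list(diff(t[i0:i1]) * 1000))
      is_burst[i0:i1] <- TRUE
    }
  }
  structure(list(onsets_s = onsets, n_spikes = sizes, intra_isis_ms = isis,
                 is_burst_spike = is_burst,
                 tonic_spike_times_s = t[!is_burst],
                 unit_id = train$unit_id,
                 criteria = list(isi_max_ms = isi_max_ms,
                                 silence_min_ms = silence_min_ms,
                                 min_spikes = min_spikes)),
            class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("<burst_set> unit %s: %d burst(s), %d burst spikes, %d tonic spikes\n",
              x$unit_id, length(x$onsets_s), sum(x$n_spikes),
              length(x$tonic_spike_times_s)))
  invisible(x)
}

#' Per-state tonic and burst firing metrics
#'
#' Rates use the summed occupied duration of each state label as the
#' denominator. Tonic rate counts non-burst spikes only; the burst spike
#' rate counts spikes inside bursts; their sum is the total rate. A burst
#' event is attributed to the epoch containing its onset. A unit is flagged
#' bursting in a state when it shows more than 1 burst event per 10
#' minutes, i.e. a burst event rate above `bursting_events_per_10min / 10`
#' per minute (strict inequality).
#'
#' @param train A [spike_train()].
#' @param bursts A `burst_set` from [detect_bursts()] on the same train.
#' @param epochs An [epoch_set()].
#' @param bursting_events_per_10min Threshold on events per 10 min for the
#'   `is_bursting` flag (default 1, strict).
#' @return Data frame, one row per state present in `epochs`: `unit_id`,
#'   `state`, `duration_s`, `total_rate_hz`, `tonic_rate_hz`,
#'   `burst_spike_rate_hz`, `burst_event_rate_per_min`,
#'   `burst_to_total_ratio`, `is_bursting`.
#' @export
state_firing_metrics <- function(train, bursts, epochs,
                                 bursting_events_per_10min = 1) {
  stopifnot(inherits(train, "spike_train"), inherits(bursts, "burst_set"),
            inherits(epochs, "epoch_set"))
  if (nrow(epochs) == 0L) stop("epoch set is empty", call. = FALSE)
  t <- train$spike_times_s
  states <- unique(epochs$label)
  rows <- lapply(states, function(lb) {
    ep <- epochs[epochs$label == lb, , drop = FALSE]
    dur <- sum(ep$end_s - ep$start_s)
    inside <- !is.na(epoch_membership(t, ep))
    n_tot <- sum(inside)
    n_burst_sp <- sum(inside & bursts$is_burst_spike)
    n_events <- sum(!is.na(epoch_membership(bursts$onsets_s, ep)))
    ev_per_min <- n_events / (dur / 60)
    data.frame(unit_id = train$unit_id, state = lb, duration_s = dur,
               total_rate_hz = n_tot / dur,
               tonic_rate_hz = (n_tot - n_burst_sp) / dur,
               burst_spike_rate_hz = n_burst_sp / dur,
               burst_event_rate_per_min = ev_per_min,
               burst_to_total_ratio = if (n_tot > 0) n_burst_sp / n_tot else NA_real_,
               is_bursting = ev_per_min > bursting_events_per_10min / 10,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify a unit as regular- or narrow-spiking
#'
#' Regular-spiking (RS) iff the peak-to-valley width strictly exceeds
#' 250 microseconds; narrow-spiking (NS) otherwise. A missing width gives
#' `NA` (unclassified).
#'
#' @param p2v_width_us Peak-to-valley width(s) in microseconds (vectorized).
#' @param threshold_us Classification boundary.
#' @return Character vector of `"RS"` / `"NS"` (`NA` when width missing).
#' @export
classify_cell_type <- function(p2v_width_us, threshold_us = 250) {
  out <- ifelse(is.na(p2v_width_us), NA_character_,
                ifelse(p2v_width_us > threshold_us, "RS", "NS"))
  if (any(!is.na(p2v_width_us) & p2v_width_us <= 0)) {
    stop("spike widths must be positive", call. = FALSE)
  }
  out
}

#' Wake-referenced Z-score of state firing
#'
#' Discretizes the home-cage wake epochs into bins of `bin_s` seconds
#' (full bins only, per epoch), takes the mean and SD of the per-bin firing
#' rate, and expresses the mean firing rate over the target epochs in those
#' SD units: `z = (target_rate - mean_wake) / sd_wake`. Labels follow the
#' two-sided 5% normal bounds: `increase` iff z > 1.96, `decrease` iff
#' z < -1.96, else `no_change`.
#'
#' @param train A [spike_train()].
#' @param wake_epochs Epochs of the reference wake state; must yield at
#'   least 10 bins.
#' @param target_epochs Epochs of the target state (e.g. fLOM).
#' @param bin_s Wake discretization bin (seconds).
#' @return List: `z`, `label`, `wake_mean_hz`, `wake_sd_hz`,
#'   `target_rate_hz`, `n_bins`. Zero wake SD yields `z = NA` and label
#'   `"undefined"` with a warning.
#' @export
zscore_vs_wake <- function(train, wake_epochs, target_epochs, bin_s = 10) {
  stopifnot(inherits(train, "spike_train"))
  t <- train$spike_times_s
  rates <- numeric(0)
  for (i in seq_len(nrow(wake_epochs))) {
    st <- wake_epochs$start_s[i]; en <- wake_epochs$end_s[i]
    nb <- floor((en - st) / bin_s)
    if (nb < 1L) next
    edges <- st + bin_s * (0:nb)
    cnt <- tabulate(findInterval(t[t >= st & t < edges[nb + 1L]], edges),
                    nbins = nb)
    rates <- c(rates, cnt / bin_s)
  }
  if (length(rates) < 10L) {
    stop("wake occupancy must provide at least 10 bins of ", bin_s, " s",
         call. = FALSE)
  }
  mu <- mean(rates); sdv <- stats::sd(rates)
  dur <- sum(target_epochs$end_s - target_epochs$start_s)
  target <- sum(!is.na(epoch_membership(t, target_epochs))) / dur
  if (sdv == 0) {
    warning("zero wake-rate SD: Z-score undefined")
    return(list(z = NA_real_, label = "undefined", wake_mean_hz = mu,
                wake_sd_hz = sdv, target_rate_hz = target,
                n_bins = length(rates)))
  }
  z <- (target - mu) / sdv
  label <- if (z > 1.96) "increase" else if (z < -1.96) "decrease" else "no_change"
  list(z = z, label = label, wake_mean_hz = mu, wake_sd_hz = sdv,
       target_rate_hz = target, n_bins = length(rates))
}

#' Peristimulus histogram and response fidelity
#'
#' Collects spike latencies relative to each pulse onset within
#' `[0, window_ms)`, bins them at `bin_ms`, and summarizes stimulation
#' fidelity: the fraction of pulses evoking at least one spike in the
#' window, the median first-spike latency, and the first-spike jitter (SD
#' of first-spike latency).
#'
#' @param train A [spike_train()].
#' @param pulses A [pulse_protocol()] with at least one pulse.
#' @param window_ms Response window after pulse onset (ms, > 0).
#' @param bin_ms Histogram bin width (ms).
#' @return List: `counts` (per bin), `bin_edges_ms`, `fidelity`,
#'   `latency_ms` (median first-spike latency, `NA` if no responses),
#'   `jitter_ms`, `n_pulses`.
#' @export
peristimulus_histogram <- function(train, pulses, window_ms = 20, bin_ms = 1) {
  stopifnot(inherits(train, "spike_train"), inherits(pulses, "pulse_protocol"))
  if (length(pulses$onsets_s) < 1L) stop("need at least one pulse",
                                         call. = FALSE)
  if (window_ms <= 0) stop("response window must be positive", call. = FALSE)
  t <- train$spike_times_s
  w <- window_ms / 1000
  first <- rep(NA_real_, length(pulses$onsets_s))
  all_lat <- numeric(0)
  for (k in seq_along(pulses$onsets_s)) {
    o <- pulses$onsets_s[k]
    lat <- (t[t >= o & t < o + w] - o) * 1000
    if (length(lat)) {
      first[k] <- lat[1]
      all_lat <- c(all_lat, lat)
    }
  }
  edges <- seq(0, window_ms, by = bin_ms)
  counts <- if (length(all_lat)) {
    tabulate(findInterval(all_lat, edges), nbins = length(edges) - 1L)
  } else integer(length(edges) - 1L)
  resp <- !is.na(first)
  list(counts = counts, bin_edges_ms = edges,
       fidelity = mean(resp),
       latency_ms = if (any(resp)) stats::median(first[resp]) else NA_real_,
       jitter_ms = if (sum(resp) > 1L) stats::sd(first[resp]) else
         if (any(resp)) 0 else NA_real_,
       n_pulses = length(pulses$onsets_s))
}
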