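#' Tonic stimulation protocol
#'
#' Regular pulse train on the protocol clock (first pulse at t = 0): onsets
#' at 0, ipi, 2 ipi, ... strictly below `duration_s`. The default 50 ms
#' inter-pulse interval gives 20 Hz tonic-like stimulation; the optogenetic
#' experiments use 6.25 ms pulses, the electrical ones 100 us.
#'
#' @param ipi_ms Inter-pulse interval (ms).
#' @param width_ms Pulse width (ms); must be below `ipi_ms`.
#' @param duration_s Protocol duration (s).
#' @return A [pulse_protocol()] with `meta$kind = "tonic"`.
#' @export
tonic_protocol <- function(ipi_ms = 50, width_ms = 6.25, duration_s) {
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (width_ms >= ipi_ms) {
    stop("pulse width (", width_ms, " ms) must be below the inter-pulse ",
         "interval (", ipi_ms, " ms)", call. = FALSE)
  }
  ipi <- ipi_ms / 1000
  n <- ceiling(duration_s / ipi)
  onsets <- (seq_len(n) - 1L) * ipi
  onsets <- onsets[onsets < duration_s]
  pulse_protocol(onsets, width_ms / 1000,
                 meta = list(kind = "tonic", ipi_ms = ipi_ms,
                             width_ms = width_ms, rate_hz = 1000 / ipi_ms,
                             duration_s = duration_s))
}

#' Burst-like stimulation protocol
#'
#' Groups of `n_pulses` pulses at `intra_ipi_ms` spacing (4 ms default,
#' i.e. 250 Hz within the burst), one group every `inter_burst_s` seconds,
#' starting at t = 0.
#'
#' @param n_pulses Pulses per burst (>= 2).
#' @param intra_ipi_ms Intra-burst inter-pulse interval (ms).
#' @param inter_burst_s Interval between burst onsets (s).
#' @param width_ms Pulse width (ms); must be below `intra_ipi_ms`.
#' @param duration_s Protocol duration (s); burst onsets strictly below it.
#' @return A [pulse_protocol()] with `meta$kind = "burst"` and
#'   `meta$intra_burst_rate_hz`.
#' @export
burst_protocol <- function(n_pulses = 4L, intra_ipi_ms = 4, inter_burst_s = 1,
                           width_ms = 0.1, duration_s) {
  if (n_pulses < 2L) stop("a burst needs at least 2 pulses", call. = FALSE)
  if (width_ms >= intra_ipi_ms) {
    stop("pulse width must be below the intra-burst interval", call. = FALSE)
  }
  span <- ((n_pulses - 1L) * intra_ipi_ms + width_ms) / 1000
  if (span >= inter_burst_s) {
    stop("burst span (", signif(span, 3), " s) must be below the ",
         "inter-burst interval (", inter_burst_s, " s)", call. = FALSE)
  }
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  nb <- ceiling(duration_s / inter_burst_s)
  burst_onsets <- (seq_len(nb) - 1L) * inter_burst_s
  burst_onsets <- burst_onsets[burst_onsets < duration_s]
  within <- (seq_len(n_pulses) - 1L) * intra_ipi_ms / 1000
  onsets <- as.numeric(outer(within, burst_onsets, "+"))
  pulse_protocol(sort(onsets), width_ms / 1000,
                 meta = list(kind = "burst", n_pulses = n_pulses,
                             intra_ipi_ms = intra_ipi_ms,
                             intra_burst_rate_hz = 1000 / intra_ipi_ms,
                             inter_burst_s = inter_burst_s,
                             width_ms = width_ms, duration_s = duration_s,
                             n_bursts = length(burst_onsets)))
}

#' Phasic ON-OFF stimulation protocol
#'
#' Alternating ON periods of `on_s` seconds and OFF periods of `off_s`
#' seconds, starting ON at t = 0 (the 1 s ON-OFF default is a 50% duty
#' cycle). The final ON pulse is truncated at `duration_s` when the
#' protocol ends mid-pulse.
#'
#' @param on_s,off_s ON and OFF durations (s, > 0).
#' @param duration_s Protocol duration (s).
#' @return A [pulse_protocol()] with `meta$kind = "phasic_onoff"` and
#'   `meta$duty_cycle`.
#' @export
phasic_onoff_protocol <- function(on_s = 1, off_s = 1, duration_s) {
  if (on_s <= 0 || off_s <= 0) stop("on_s and off_s must be positive",
                                    call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  cyc <- on_s + off_s
  nc <- ceiling(duration_s / cyc)
  onsets <- (seq_len(nc) - 1L) * cyc
  onsets <- onsets[onsets < duration_s]
  widths <- pmin(on_s, duration_s - onsets)
  pulse_protocol(onsets, widths,
                 meta = list(kind = "phasic_onoff", on_s = on_s, off_s = off_s,
                             duration_s = duration_s,
                             duty_cycle = on_s / cyc))
}
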