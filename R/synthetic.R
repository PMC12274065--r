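#' Per-state spike generation parameters
#'
#' Bundles, per brain state, the tonic firing rate and the low-threshold
#' burst statistics used by [gen_spike_train()]. Tonic spikes follow a
#' dead-time renewal process: after each tonic spike the unit is silent for
#' `tonic_min_isi_ms`, then fires with constant hazard chosen so the
#' long-run rate equals `tonic_rate_hz` exactly. The dead time keeps the
#' tonic ISI regime (> 10 ms) disjoint from the burst ISI regime
#' (`intra_burst_isi_ms_range`, within 0-10 ms), mirroring the bimodal ISI
#' structure of thalamic relay cells. Burst onsets are a Poisson process
#' thinned so every burst is preceded by at least `pre_burst_silence_ms` of
#' silence.
#'
#' @param tonic_rate_hz Named numeric vector (names from [state_labels()])
#'   of tonic rates in spikes/s.
#' @param burst_event_rate_per_min Named numeric vector of burst-onset
#'   rates per minute.
#' @param spikes_per_burst_range Integer low..high spikes per burst (>= 2).
#' @param intra_burst_isi_ms_range Intra-burst ISI range in ms, within
#'   (0, 10].
#' @param pre_burst_silence_ms Enforced silence before each burst onset
#'   (>= 50 ms).
#' @param refractory_ms Absolute refractory period (> 0 ms), a floor on
#'   every generated ISI.
#' @param tonic_min_isi_ms Dead time of the tonic renewal process (ms);
#'   must be at least `refractory_ms`.
#'
#' @return An object of class `spike_gen_params`.
#' @export
spike_gen_params <- function(tonic_rate_hz, burst_event_rate_per_min,
                             spikes_per_burst_range = c(2L, 5L),
                             intra_burst_isi_ms_range = c(3, 5),
                             pre_burst_silence_ms = 100,
                             refractory_ms = 1,
                             tonic_min_isi_ms = 12) {
  stopifnot(length(spikes_per_burst_range) == 2L,
            length(intra_burst_isi_ms_range) == 2L)
  if (any(tonic_rate_hz < 0) || any(burst_event_rate_per_min < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  if (intra_burst_isi_ms_range[1] <= 0 || intra_burst_isi_ms_range[2] > 10 ||
      intra_burst_isi_ms_range[1] > intra_burst_isi_ms_range[2]) {
    stop("intra_burst_isi_ms_range must lie within (0, 10]", call. = FALSE)
  }
  if (spikes_per_burst_range[1] < 2L) {
    stop("bursts need at least 2 spikes", call. = FALSE)
  }
  if (pre_burst_silence_ms < 50) {
    stop("pre_burst_silence_ms must be >= 50", call. = FALSE)
  }
  if (refractory_ms <= 0) stop("refractory_ms must be positive", call. = FALSE)
  if (tonic_min_isi_ms < refractory_ms) {
    stop("tonic_min_isi_ms must be >= refractory_ms", call. = FALSE)
  }
  structure(list(tonic_rate_hz = tonic_rate_hz,
                 burst_event_rate_per_min = burst_event_rate_per_min,
                 spikes_per_burst_range = as.integer(spikes_per_burst_range),
                 intra_burst_isi_ms_range = intra_burst_isi_ms_range,
                 pre_burst_silence_ms = pre_burst_silence_ms,
                 refractory_ms = refractory_ms,
                 tonic_min_isi_ms = tonic_min_isi_ms),
            class = "spike_gen_params")
}

#' Default generation parameters per genotype
#'
#' Wild-type (WT) burst event rates for wake (0.16/min), fLOM (0.79/min)
#' and NREM (5.76/min) follow the reported state averages; the remaining
#' burst rates and the per-state tonic rates are free parameters chosen to
#' reproduce the qualitative ordering walk = wake > REM > fLOM ~ NREM.
#' KO-like units never burst: all burst rates are forced to zero.
#'
#' @param genotype `"WT"` (bursting) or `"KO"` (non-bursting).
#' @return A [spike_gen_params()] object.
#' @export
default_spike_gen_params <- function(genotype = c("WT", "KO")) {
  genotype <- match.arg(genotype)
  tonic <- c(walk = 20, wake = 20, NREM = 3, REM = 8,
             fLOM = 5, LOM = 5, nonwalk = 10)
  burst <- c(walk = 0.16, wake = 0.16, NREM = 5.76, REM = 0.16,
             fLOM = 0.79, LOM = 0.79, nonwalk = 0.16)
  if (genotype == "KO") burst[] <- 0
  spike_gen_params(tonic, burst)
}

#' Generate a contiguous brain-state schedule
#'
#' Tiles `[0, total_s)` with epochs whose labels are drawn from
#' `state_menu` (no immediate repeats when the menu allows) and whose
#' durations are exponential with mean `mean_epoch_s`, floored at
#' `min_epoch_s`; the last epoch is truncated so the tiling is exact.
#'
#' @param seed Integer seed; fixed seed gives an identical schedule.
#' @param total_s Total duration to tile (> 0).
#' @param state_menu Character vector of labels from [state_labels()].
#' @param mean_epoch_s,min_epoch_s Epoch duration parameters (seconds).
#' @return An [epoch_set()] tiling `[0, total_s)` with no gaps.
#' @export
gen_state_schedule <- function(seed, total_s, state_menu,
                               mean_epoch_s = 120, min_epoch_s = 30) {
  if (length(state_menu) == 0L) stop("state_menu must be non-empty",
                                     call. = FALSE)
  if (!all(state_menu %in% state_labels())) {
    stop("state_menu contains unknown labels", call. = FALSE)
  }
  if (total_s <= 0) stop("total_s must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  starts <- numeric(0); ends <- numeric(0); labs <- character(0)
  t <- 0; prev <- ""
  while (t < total_s) {
    cand <- setdiff(state_menu, prev)
    if (length(cand) == 0L) cand <- state_menu
    lab <- cand[sample.int(length(cand), 1L)]
    dur <- min_epoch_s + stats::rexp(1, 1 / max(mean_epoch_s - min_epoch_s, 1))
    end <- min(t + dur, total_s)
    starts <- c(starts, t); ends <- c(ends, end); labs <- c(labs, lab)
    t <- end; prev <- lab
  }
  ## merge adjacent same-label epochs (arises when the menu has one state)
  keep <- c(TRUE, labs[-1] != labs[-length(labs)])
  grp <- cumsum(keep)
  epoch_set(tapply(starts, grp, min), tapply(ends, grp, max),
            labs[keep])
}

#' Generate a synthetic spike train with attached ground truth
#'
#' For each scheduled epoch, tonic spikes are drawn from the dead-time
#' renewal process of [spike_gen_params()] at the state's tonic rate (the
#' dead time is carried across epoch boundaries), and burst onsets from a
#' Poisson process at the state's burst event rate. Onsets are thinned so
#' consecutive bursts are separated by at least the pre-burst silence, each
#' burst receives 2-5 spikes at intra-burst ISIs inside the configured
#' range, and tonic spikes falling within `pre_burst_silence_ms` before an
#' onset or inside a burst are removed, so every planted burst satisfies
#' the detector's criteria by construction. The sampled onsets (after
#' thinning) are returned as ground truth for recovery tests.
#'
#' @param seed Integer seed.
#' @param schedule An [epoch_set()]; states missing from `params` get rate 0.
#' @param params A [spike_gen_params()]; defaults to the genotype defaults.
#' @param genotype `"WT"` or `"KO"`; KO forces all burst rates to zero.
#' @param unit_id Identifier for the generated unit.
#' @return A [spike_train()] whose `truth` field holds `genotype` and
#'   `bursts`, a data frame of planted onsets, spike counts and burst ends.
#' @export
gen_spike_train <- function(seed, schedule,
                            params = default_spike_gen_params(genotype),
                            genotype = c("WT", "KO"),
                            unit_id = NULL) {
  genotype <- match.arg(genotype)
  stopifnot(inherits(params, "spike_gen_params"))
  if (genotype == "KO") params$burst_event_rate_per_min[] <- 0
  set.seed(as.integer(seed))

  d <- params$tonic_min_isi_ms / 1000
  refr <- params$refractory_ms / 1000
  sil <- params$pre_burst_silence_ms / 1000
  isi_lo <- params$intra_burst_isi_ms_range[1] / 1000
  isi_hi <- params$intra_burst_isi_ms_range[2] / 1000
  nsp_rng <- params$spikes_per_burst_range
  max_span <- (nsp_rng[2] - 1L) * isi_hi

  rate_of <- function(v, lab) if (lab %in% names(v)) unname(v[lab]) else 0

  lam_all <- vapply(schedule$label, function(lb)
    rate_of(params$tonic_rate_hz, lb), numeric(1))
  if (any(lam_all * d >= 1)) {
    stop("tonic rate too high to honor the ", params$tonic_min_isi_ms,
         " ms tonic dead time", call. = FALSE)
  }

  ## burst onsets: per-epoch Poisson candidates, pooled then thinned
  cand <- numeric(0)
  for (i in seq_len(nrow(schedule))) {
    r <- rate_of(params$burst_event_rate_per_min, schedule$label[i]) / 60
    if (r <= 0) next
    st <- schedule$start_s[i]; en <- schedule$end_s[i]
    n <- stats::rpois(1L, r * (en - st))
    if (n == 0L) next
    o <- st + sort(stats::runif(n)) * (en - st)
    cand <- c(cand, o[o + max_span <= en])
  }
  cand <- sort(cand)
  keep <- logical(length(cand))
  last_end <- -Inf
  for (k in seq_along(cand)) {
    if (cand[k] - last_end >= sil) {
      keep[k] <- TRUE
      last_end <- cand[k] + max_span
    }
  }
  onsets <- cand[keep]

  burst_spikes <- numeric(0)
  n_per <- integer(0)
  ends <- numeric(0)
  if (length(onsets)) {
    n_per <- sample(seq(nsp_rng[1], nsp_rng[2]), length(onsets), replace = TRUE)
    for (k in seq_along(onsets)) {
      isis <- stats::runif(n_per[k] - 1L, isi_lo, isi_hi)
      sp <- onsets[k] + c(0, cumsum(isis))
      burst_spikes <- c(burst_spikes, sp)
      ends[k] <- sp[length(sp)]
    }
  }

  ## tonic spikes: dead-time renewal, dead time carried across epochs
  tonic <- numeric(0)
  last <- -Inf
  for (i in seq_len(nrow(schedule))) {
    lam <- lam_all[i]
    if (lam <= 0) next
    st <- schedule$start_s[i]; en <- schedule$end_s[i]
    haz <- lam / (1 - lam * d)
    s0 <- max(st, last + d)
    cur <- s0 - d
    while (cur < en) {
      m <- max(16L, ceiling((en - cur) * lam * 1.5 + 10 * sqrt((en - cur) * lam + 1)))
      gaps <- d + stats::rexp(m, haz)
      ts <- cur + cumsum(gaps)
      tonic <- c(tonic, ts[ts < en])
      cur <- ts[length(ts)]
    }
    if (length(tonic)) last <- max(last, tonic[length(tonic)])
  }
  tonic <- sort(tonic)

  ## clear tonic spikes around planted bursts
  if (length(onsets) && length(tonic)) {
    ws <- onsets - sil
    we <- ends + refr
    idx <- findInterval(tonic, ws)
    drop <- idx >= 1L & tonic <= we[pmax(idx, 1L)]
    tonic <- tonic[!drop]
  }

  times <- sort(c(tonic, burst_spikes))
  if (is.null(unit_id)) unit_id <- sprintf("%s_u%03d", genotype, seed %% 1000L)
  truth <- list(genotype = genotype,
                bursts = data.frame(onset_s = onsets,
                                    n_spikes = if (length(onsets)) n_per else integer(0),
                                    end_s = if (length(onsets)) ends else numeric(0)),
                params = params)
  spike_train(unit_id, times, truth = truth)
}

#' Motion-trace generation parameters
#'
#' @param total_s Total trace duration (seconds).
#' @param baseline_duration_s Walking baseline length at the start of the
#'   trace (the pre-injection treadmill period).
#' @param baseline_mean Mean motion level of the walking baseline
#'   (g for accelerometer mode, arbitrary units for video).
#' @param rel_noise_sd Relative SD of the autocorrelated envelope
#'   fluctuation around the local mean.
#' @param smooth_s Moving-average width (seconds) applied to the white
#'   noise that drives the envelope (0.5 s gives slow, gait-like
#'   fluctuation).
#' @param quiescent_frac Sensor-noise floor during quiescence, as a
#'   fraction of `baseline_mean`.
#' @param episodes Data frame with columns `onset_s`, `duration_s` and
#'   `level` (motion level as a fraction of baseline; use
#'   `quiescent_frac` for full quiescence, or any value < 0.25 for a "low"
#'   episode). Episodes must start after the baseline, not overlap, and
#'   end within the trace.
#' @param sample_rate_hz Sampling rate (>= 50 required for accelerometer
#'   mode).
#' @param carrier_hz Stride-like oscillation frequency carried by the
#'   accelerometer channels.
#' @return An object of class `motion_gen_params`.
#' @export
motion_gen_params <- function(total_s = 4200, baseline_duration_s = 600,
                              baseline_mean = 0.1, rel_noise_sd = 0.2,
                              smooth_s = 0.5, quiescent_frac = 0.02,
                              episodes = data.frame(onset_s = numeric(0),
                                                    duration_s = numeric(0),
                                                    level = numeric(0)),
                              sample_rate_hz = 100, carrier_hz = 3) {
  episodes <- as.data.frame(episodes)
  if (nrow(episodes)) {
    if (any(episodes$level < 0)) stop("episode levels must be non-negative",
                                      call. = FALSE)
    if (any(episodes$onset_s < baseline_duration_s)) {
      stop("episodes must start after the baseline", call. = FALSE)
    }
    if (any(episodes$onset_s + episodes$duration_s > total_s)) {
      stop("episode extends beyond the trace end", call. = FALSE)
    }
    o <- order(episodes$onset_s)
    e <- episodes[o, ]
    if (nrow(e) > 1L &&
        any(e$onset_s[-1] < (e$onset_s + e$duration_s)[-nrow(e)])) {
      stop("episodes must not overlap", call. = FALSE)
    }
  }
  structure(list(total_s = total_s, baseline_duration_s = baseline_duration_s,
                 baseline_mean = baseline_mean, rel_noise_sd = rel_noise_sd,
                 smooth_s = smooth_s, quiescent_frac = quiescent_frac,
                 episodes = episodes, sample_rate_hz = sample_rate_hz,
                 carrier_hz = carrier_hz),
            class = "motion_gen_params")
}

#' Generate a synthetic motion trace with planted episodes
#'
#' Builds a positive scalar motion envelope: a walking baseline of stable
#' mean with autocorrelated fluctuation (white noise smoothed over
#' `smooth_s`), dropped to the planted level inside each episode
#' (quiescence = sensor-noise floor at `quiescent_frac` of baseline). In
#' video mode the envelope itself is the motion scalar. In accelerometer
#' mode three axis channels carry the envelope on stride-like sinusoidal
#' carriers phased 120 degrees apart, so the across-axis RMS at each sample
#' equals the scalar envelope exactly. The planted episode table and the
#' envelope are attached as ground truth.
#'
#' @param seed Integer seed; fixed seed gives a bit-identical trace.
#' @param params A [motion_gen_params()].
#' @param mode `"accelerometer"` or `"video"`.
#' @return A [motion_signal()] with `truth = list(episodes, envelope)`.
#' @export
gen_motion_trace <- function(seed, params, mode = c("accelerometer", "video")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "motion_gen_params"))
  set.seed(as.integer(seed))
  fs <- params$sample_rate_hz
  n <- round(params$total_s * fs)
  t <- (seq_len(n) - 1L) / fs

  w <- ceiling(params$smooth_s * fs)
  z <- stats::rnorm(n + 2L * w)
  z <- as.numeric(stats::filter(z, rep(1 / w, w), sides = 2))
  z <- z[(w + 1L):(w + n)]
  z <- z / stats::sd(z, na.rm = TRUE)

  lev <- rep(1, n)
  ep <- params$episodes
  for (k in seq_len(nrow(ep))) {
    lo <- pmin(pmax(ep$level[k], params$quiescent_frac), 1)
    sel <- t >= ep$onset_s[k] & t < ep$onset_s[k] + ep$duration_s[k]
    lev[sel] <- lo
  }
  env <- params$baseline_mean * lev * pmax(1 + params$rel_noise_sd * z, 0.05)

  truth <- list(episodes = ep, envelope = env)
  if (mode == "video") {
    return(motion_signal(env, fs, mode = "video", truth = truth))
  }
  theta <- 2 * pi * params$carrier_hz * t
  ch <- sqrt(2) * cbind(sin(theta), sin(theta + 2 * pi / 3),
                        sin(theta + 4 * pi / 3))
  motion_signal(env * ch, fs, mode = "accelerometer", truth = truth)
}

#' Generate a shuffled set of spike widths for cell-type fixtures
#'
#' Draws `n_wide` peak-to-valley widths uniformly from `wide_range_us` and
#' `n_narrow` from `narrow_range_us`, then shuffles. Both ranges must lie
#' strictly on one side of the 250 us classification boundary.
#'
#' @param seed Integer seed.
#' @param n_wide,n_narrow Counts per class.
#' @param wide_range_us Range above 250 us (regular-spiking-like).
#' @param narrow_range_us Range below 250 us (narrow-spiking-like).
#' @return Numeric vector of widths with a `truth` attribute giving the
#'   latent class (`"wide"`/`"narrow"`) of each entry.
#' @export
gen_waveform_widths <- function(seed, n_wide, n_narrow,
                                wide_range_us = c(300, 500),
                                narrow_range_us = c(150, 220)) {
  if (wide_range_us[1] <= 250) {
    stop("wide_range_us must lie strictly above 250 us", call. = FALSE)
  }
  if (narrow_range_us[2] >= 250) {
    stop("narrow_range_us must lie strictly below 250 us", call. = FALSE)
  }
  set.seed(as.integer(seed))
  w <- c(stats::runif(n_wide, wide_range_us[1], wide_range_us[2]),
         stats::runif(n_narrow, narrow_range_us[1], narrow_range_us[2]))
  cls <- c(rep("wide", n_wide), rep("narrow", n_narrow))
  o <- sample.int(length(w))
  structure(w[o], truth = cls[o])
}
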