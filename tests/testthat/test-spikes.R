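test_that("autocorrelogram bins ordered pair lags at 1 ms", {
  acg <- autocorrelogram(make_train(c(1.000, 1.005)))
  expect_equal(acg$counts[5], 1)
  expect_equal(sum(acg$counts), 1)

  comb <- autocorrelogram(make_train(seq(0, 2, by = 0.020)))
  hit <- which(comb$counts > 0)
  expect_true(all(hit %% 20 == 0))
  expect_equal(comb$counts[20], 100)   # 101 spikes -> 100 adjacent pairs

  expect_error(autocorrelogram(make_train(1)), "at least 2 spikes")
})

test_that("a long Poisson train has a flat autocorrelogram", {
  set.seed(42)
  tots <- numeric(100)
  agg <- numeric(100)
  for (s in 1:100) {
    t <- cumsum(rexp(6000, 10))
    agg <- agg + autocorrelogram(make_train(t))$counts
  }
  # Poisson: expected counts equal in every bin; compare short vs long lags
  early <- mean(agg[1:20]); late <- mean(agg[81:100])
  expect_lt(abs(early - late) / late, 0.02)
  expect_lt((max(agg) - min(agg)) / mean(agg), 0.1)
})

test_that("burst index matches its closed forms and stays in [-1, 1]", {
  flat <- as_acg(rep(7, 100))
  expect_equal(burst_index(flat), 0)

  pos <- as_acg(c(rep(0, 4), 100, rep(0, 95)))
  expect_equal(burst_index(pos), 1)

  neg <- as_acg(c(rep(10, 10), rep(0, 29), rep(20, 11), rep(0, 50)))
  expect_equal(burst_index(neg), -0.5)        # (10 - 20) / 20

  expect_warning(z <- burst_index(as_acg(rep(0, 100))), "degenerate")
  expect_equal(z, 0)

  set.seed(3)
  for (i in 1:50) {
    bi <- burst_index(as_acg(rpois(100, 5)))
    expect_gte(bi, -1); expect_lte(bi, 1)
  }
})

test_that("bursting ratio compares sub-10 ms to supra-50 ms counts", {
  flat <- as_acg(rep(3, 100))
  expect_equal(bursting_ratio_index(flat), 9 / 50)

  lowonly <- as_acg(c(rep(5, 9), rep(0, 91)))
  expect_warning(r <- bursting_ratio_index(lowonly), "infinite")
  expect_equal(r, Inf)

  highonly <- as_acg(c(rep(0, 50), rep(4, 50)))
  expect_equal(bursting_ratio_index(highonly), 0)
})

test_that("burst detection applies the ISI, size and silence criteria", {
  b <- detect_bursts(make_train(c(1.000, 1.004, 1.008, 2.000)))
  expect_equal(b$onsets_s, 1.000)
  expect_equal(b$n_spikes, 3L)
  expect_equal(b$tonic_spike_times_s, 2.000)

  # 30 ms pre-gap < 50 ms: the short-ISI pair is not a burst
  none <- detect_bursts(make_train(c(1.000, 1.030, 1.038)))
  expect_length(none$onsets_s, 0L)

  slow <- detect_bursts(make_train(seq(1, 10)))
  expect_length(slow$onsets_s, 0L)
  expect_length(slow$tonic_spike_times_s, 10L)

  # first spike of the train can start a burst
  first <- detect_bursts(make_train(c(0.000, 0.005, 1.000)))
  expect_equal(first$onsets_s, 0)
})

test_that("burst detection matches the brute-force criterion scan", {
  for (s in 1:200) {
    t <- random_test_train(s)
    got <- detect_bursts(make_train(t))
    ref <- brute_force_bursts(t)
    expect_equal(got$onsets_s, ref$onsets)
    expect_equal(got$n_spikes, ref$sizes)
    expect_equal(which(got$is_burst_spike), ref$members)
    # partition invariant
    expect_equal(sum(got$n_spikes) + length(got$tonic_spike_times_s),
                 length(t))
  }
})

test_that("state metrics use occupied time and onset-based event counts", {
  ep <- epoch_set(0, 60, "wake")
  t <- seq(0.25, 59.75, by = 0.5)          # 120 tonic spikes in 60 s
  tr <- make_train(t)
  m <- state_firing_metrics(tr, detect_bursts(tr), ep)
  expect_equal(m$tonic_rate_hz, 2)
  expect_equal(m$burst_spike_rate_hz, 0)
  expect_equal(m$burst_event_rate_per_min, 0)
  expect_false(m$is_bursting)

  # 12 bursts in 10 min -> 1.2 events/min, bursting
  onsets <- seq(10, 560, by = 50)
  tb <- sort(c(onsets, onsets + 0.004))
  trb <- make_train(tb)
  mb <- state_firing_metrics(trb, detect_bursts(trb),
                             epoch_set(0, 600, "NREM"))
  expect_equal(mb$burst_event_rate_per_min, 1.2)
  expect_true(mb$is_bursting)
  expect_equal(mb$total_rate_hz, mb$tonic_rate_hz + mb$burst_spike_rate_hz)
  expect_equal(mb$burst_to_total_ratio, 1)

  # burst events are attributed to the epoch containing their onset
  ep2 <- epoch_set(c(0, 300), c(300, 600), c("wake", "NREM"))
  m2 <- state_firing_metrics(trb, detect_bursts(trb), ep2)
  expect_equal(sum(m2$burst_event_rate_per_min * m2$duration_s / 60), 12)
})

test_that("synthetic NREM trains recover the generator burst rate", {
  sch <- epoch_set(0, 600, "NREM")
  err <- vapply(1:20, function(s) {
    tr <- gen_spike_train(s, sch, genotype = "WT")
    m <- state_firing_metrics(tr, detect_bursts(tr), sch)
    m$burst_event_rate_per_min - nrow(tr$truth$bursts) / 10
  }, numeric(1))
  expect_true(all(abs(err) < 0.2))   # detector reproduces attached truth
})

test_that("cell-type split is strict at 250 us", {
  expect_equal(classify_cell_type(c(300, 200, 250)), c("RS", "NS", "NS"))
  expect_true(is.na(classify_cell_type(NA_real_)))
  w <- gen_waveform_widths(1, 36, 3)
  cls <- classify_cell_type(w)
  expect_equal(mean(cls == "RS") * 100, 92.3, tolerance = 0.01)
})

test_that("wake-referenced Z-scores follow the binned-rate formula", {
  # wake: 10 s bins alternating 8 and 12 Hz -> mean 10, SD ~2.06
  wake_t <- unlist(lapply(0:19, function(k) {
    n <- if (k %% 2 == 0) 80 else 120
    k * 10 + seq(0, 10 - 1e-6, length.out = n)
  }))
  tr <- make_train(sort(wake_t))
  wake_ep <- epoch_set(0, 200, "wake")
  mu <- 10; sdv <- stats::sd(rep(c(8, 12), 10))

  tgt_lo <- epoch_set(200, 300, "fLOM")   # no spikes there -> rate 0
  z <- zscore_vs_wake(tr, wake_ep, tgt_lo)
  expect_equal(z$wake_mean_hz, mu)
  expect_equal(z$z, (0 - mu) / sdv, tolerance = 1e-9)
  expect_equal(z$label, "decrease")

  # target equal to the wake mean -> no change at z = 0
  tr2 <- make_train(c(sort(wake_t), seq(200.05, 300, by = 0.1)))
  z2 <- zscore_vs_wake(tr2, wake_ep, tgt_lo)
  expect_equal(z2$z, 0, tolerance = 1e-6)
  expect_equal(z2$label, "no_change")

  # label breakpoints sit exactly at +-1.96
  lab <- function(z) if (z > 1.96) "increase" else
    if (z < -1.96) "decrease" else "no_change"
  for (zz in c(-2.2, -1.9601, -1.96, 0, 1.96, 1.9601, 2.2)) {
    tgt_rate <- mu + zz * sdv
    n_t <- round(tgt_rate * 100)
    tr3 <- make_train(c(sort(wake_t),
                        seq(200.0005, 300 - 1e-9, length.out = n_t)))
    z3 <- zscore_vs_wake(tr3, wake_ep, tgt_lo)
    expect_equal(z3$label, lab(z3$z))
  }

  expect_error(zscore_vs_wake(tr, epoch_set(0, 50, "wake"), tgt_lo),
               "at least 10 bins")
})

test_that("peristimulus statistics capture fidelity, latency and jitter", {
  pulses <- tonic_protocol(ipi_ms = 1000, width_ms = 5, duration_s = 20)
  tr <- make_train(pulses$onsets_s + 0.0053)
  ps <- peristimulus_histogram(tr, pulses, window_ms = 20)
  expect_equal(ps$fidelity, 1)
  expect_equal(ps$latency_ms, 5.3, tolerance = 1e-9)
  expect_lt(ps$jitter_ms, 1e-9)
  expect_equal(ps$counts[6], 20)   # bin [5, 6) ms

  far <- make_train(pulses$onsets_s + 0.5)
  ps0 <- peristimulus_histogram(far, pulses, window_ms = 20)
  expect_equal(ps0$fidelity, 0)
  expect_true(is.na(ps0$latency_ms))

  half <- make_train(pulses$onsets_s[seq(1, 19, by = 2)] + 0.003)
  ps5 <- peristimulus_histogram(half, pulses, window_ms = 20)
  expect_equal(ps5$fidelity, 0.5)

  expect_error(peristimulus_histogram(tr, pulses, window_ms = 0), "positive")
})
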