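# Independent brute-force burst scan: for every spike, test the burst
# criteria explicitly (left-maximality, ISI chain, pre-burst silence) by
# direct per-spike iteration, with no shared code with detect_bursts().
brute_force_bursts <- function(times, isi_max_ms = 10, silence_min_ms = 50,
                               min_spikes = 2L) {
  isi_max <- isi_max_ms / 1000
  sil <- silence_min_ms / 1000
  n <- length(times)
  onsets <- numeric(0)
  sizes <- integer(0)
  members <- integer(0)
  i <- 1L
  while (i <= n) {
    left_max <- i == 1L || (times[i] - times[i - 1L]) > isi_max
    if (left_max) {
      j <- i
      while (j < n && (times[j + 1L] - times[j]) <= isi_max) j <- j + 1L
      if ((j - i + 1L) >= min_spikes &&
          (i == 1L || (times[i] - times[i - 1L]) >= sil)) {
        onsets <- c(onsets, times[i])
        sizes <- c(sizes, j - i + 1L)
        members <- c(members, i:j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(onsets = onsets, sizes = sizes, members = members)
}

# Random spike train with a deliberate mixture of long gaps, borderline
# gaps and sub-10-ms ISIs so that every branch of the criteria is hit.
random_test_train <- function(seed, max_spikes = 200L) {
  set.seed(seed)
  n <- sample.int(max_spikes, 1L)
  isis <- sample(c(stats::rexp(n, 1 / 0.2),
                   stats::runif(n, 0.001, 0.009),
                   stats::runif(n, 0.009, 0.012),
                   stats::runif(n, 0.030, 0.070)),
                 n, replace = TRUE)
  cumsum(isis)
}

# Constructed session pieces used across tests
make_train <- function(times, id = "u1", width = NULL) {
  spike_train(id, times, p2v_width_us = width)
}
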