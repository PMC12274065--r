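fake_metrics <- function(rates, states) {
  data.frame(state = states, total_rate_hz = rates, stringsAsFactors = FALSE)
}

test_that("state correlation is -1 for monotone decreasing rates", {
  m <- fake_metrics(c(20, 15, 8, 3), c("walk", "wake", "REM", "NREM"))
  sc <- state_correlation(m)
  expect_equal(sc$rho, -1)
  expect_equal(sc$n, 4)
})

test_that("permuted rates show no spurious state correlation", {
  set.seed(10)
  rhos <- replicate(40, {
    states <- sample(rep(c("walk", "wake", "REM", "NREM"), 50))
    state_correlation(fake_metrics(rnorm(200, 10, 3), states))$rho
  })
  expect_lt(mean(abs(rhos)), 0.08)
  ps <- replicate(40, {
    states <- sample(rep(c("walk", "wake", "REM", "NREM"), 50))
    state_correlation(fake_metrics(rnorm(200, 10, 3), states))$p
  })
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("synthetic WT defaults give a negative state correlation", {
  sch <- gen_state_schedule(21, 2400, c("walk", "wake", "REM", "NREM"))
  rows <- do.call(rbind, lapply(1:6, function(s) {
    tr <- gen_spike_train(100 + s, sch, genotype = "WT")
    state_firing_metrics(tr, detect_bursts(tr), sch)
  }))
  sc <- state_correlation(rows)
  expect_lt(sc$rho, 0)
  expect_lt(sc$p, 0.05)
})

test_that("constant rates yield an undefined correlation with a warning", {
  m <- fake_metrics(rep(5, 8), rep(c("walk", "NREM"), 4))
  expect_warning(sc <- state_correlation(m), "constant")
  expect_true(is.na(sc$rho))
})

test_that("Levene statistic is 0 for identical samples and detects spread", {
  x <- rnorm(50)
  lv <- variance_homogeneity(x, x)
  expect_equal(lv$statistic, 0)

  set.seed(2)
  pow <- mean(replicate(200, {
    variance_homogeneity(rnorm(100), rnorm(100, sd = 3))$p < 0.05
  }))
  expect_gt(pow, 0.9)

  expect_error(variance_homogeneity(1, rnorm(5)), "at least 2")
})

test_that("Levene agrees with a direct absolute-deviation ANOVA", {
  set.seed(5)
  x <- rnorm(40); y <- rnorm(35, sd = 2)
  lv <- variance_homogeneity(x, y)
  dev <- c(abs(x - mean(x)), abs(y - mean(y)))
  g <- factor(rep(1:2, c(40, 35)))
  ref <- stats::anova(stats::lm(dev ~ g))
  expect_equal(lv$statistic, ref[1, "F value"], tolerance = 1e-12)
  expect_equal(lv$p, ref[1, "Pr(>F)"], tolerance = 1e-12)
})

test_that("Holm step-down follows the sequential rejection rule", {
  d1 <- group_compare_holm(p = c(0.01, 0.04))
  expect_true(all(d1$reject))

  d2 <- group_compare_holm(p = c(0.03, 0.04))
  expect_false(any(d2$reject))

  d3 <- group_compare_holm(p = 0.049)
  expect_true(d3$reject)

  # monotone: rejecting a p implies rejecting all smaller p
  set.seed(8)
  for (i in 1:20) {
    p <- runif(7)
    d <- group_compare_holm(p = p)
    o <- order(d$p)
    expect_true(all(diff(d$reject[o]) <= 0))
  }

  expect_error(group_compare_holm(p = c(0.5, 1.2)), "\\[0, 1\\]")

  # sample pairs route (rank-sum)
  set.seed(9)
  prs <- list(list(rnorm(30), rnorm(30, 3)), list(rnorm(30), rnorm(30)))
  d4 <- group_compare_holm(pairs = prs)
  expect_true(d4$reject[1])
})

test_that("Spearman correlation is invariant to monotone rate transforms", {
  m <- fake_metrics(c(9, 12, 20, 4, 6, 2, 1, 0.5),
                    rep(c("walk", "wake", "REM", "NREM"), 2))
  a <- state_correlation(m)
  m$total_rate_hz <- exp(m$total_rate_hz / 3)
  b <- state_correlation(m)
  expect_equal(a$rho, b$rho)
})

test_that("the firing-feature embedding is deterministic and separates regimes", {
  set.seed(4)
  wakeish <- data.frame(tonic_rate_hz = rnorm(15, 20, 1),
                        burst_spike_rate_hz = abs(rnorm(15, 0.1, 0.05)),
                        burst_event_rate_per_min = abs(rnorm(15, 0.2, 0.1)),
                        state = "wake")
  nremish <- data.frame(tonic_rate_hz = rnorm(15, 3, 0.5),
                        burst_spike_rate_hz = rnorm(15, 2, 0.3),
                        burst_event_rate_per_min = rnorm(15, 5.8, 0.8),
                        state = "NREM")
  feats <- rbind(wakeish, nremish)
  e1 <- state_space_embedding(feats, seed = 3)
  e2 <- state_space_embedding(feats, seed = 3)
  expect_identical(e1, e2)

  cw <- colMeans(e1[e1$state == "wake", 1:2])
  cn <- colMeans(e1[e1$state == "NREM", 1:2])
  between <- sqrt(sum((cw - cn)^2))
  spread <- mean(c(
    sqrt(rowSums((e1[e1$state == "wake", 1:2] - rep(cw, each = 15))^2)),
    sqrt(rowSums((e1[e1$state == "NREM", 1:2] - rep(cn, each = 15))^2))))
  expect_gt(between, spread)

  expect_error(state_space_embedding(feats[1:5, ]), "at least 10")
  feats$tonic_rate_hz[1] <- NA
  expect_error(state_space_embedding(feats), "missing")
})

test_that("the end-to-end pipeline is deterministic and KO-safe", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- default_pipeline_config(seed = 5)
  cfg$synth$n_wt <- 3; cfg$synth$n_ko <- 3
  cfg$synth$schedule_total_s <- 1200
  cfg$motion$total_s <- 2400
  cfg$motion$episode_onsets_s <- 1200
  cfg$motion$episode_durations_s <- 200
  cfg$activity$horizon_s <- 1800

  p1 <- run_pipeline(cfg, d1)
  p2 <- run_pipeline(cfg, d2)
  for (f in c("metrics.tsv", "state_metrics.tsv", "bursts.tsv",
              "stats.tsv", "embedding.tsv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  log <- readLines(file.path(d1, "run_log.txt"))
  expect_true(any(grepl("seed = 5", log)))

  # KO-only run yields an empty burst table
  cfg$synth$n_wt <- 0
  d3 <- withr::local_tempdir()
  run_pipeline(cfg, d3)
  bt <- utils::read.delim(file.path(d3, "bursts.tsv"))
  expect_equal(nrow(bt), 0L)
})
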