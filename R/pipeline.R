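#' Default end-to-end pipeline configuration
#'
#' A fully synthetic run at desk scale: a state schedule over home-cage
#' wake/sleep states plus a forced-walking segment, a small population of
#' bursting (WT-like) and non-bursting (KO-like) units, and a motion trace
#' with planted loss-of-movement episodes.
#'
#' @param seed Integer master seed; every stochastic stage derives its
#'   sub-seed from it.
#' @return Nested named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    synth = list(
      n_wt = 6, n_ko = 6,
      schedule_total_s = 3600,
      state_menu = c("wake", "NREM", "REM", "walk"),
      mean_epoch_s = 120
    ),
    motion = list(
      mode = "video",
      total_s = 4200, baseline_duration_s = 600, sample_rate_hz = 20,
      episode_onsets_s = c(1200, 2400),
      episode_durations_s = c(300, 180)
    ),
    activity = list(injection_time_s = 600, horizon_s = 3600,
                    lom_level = 0.25, nonwalk_min_s = 60, lom_min_s = 30),
    spikes = list(isi_max_ms = 10, silence_min_ms = 50, min_spikes = 2,
                  zscore_bin_s = 10, zscore_target = "NREM")
  )
}

#' Run the full synthetic-session pipeline
#'
#' Executes, in order: synthetic generation (state schedule, WT-like and
#' KO-like spike trains, motion trace), the motion-to-LOM analysis, the
#' per-unit spike analysis (burst detection, state firing metrics,
#' wake-referenced Z-scores), and the statistics layer (state rank
#' correlation per genotype, WT-vs-KO Levene variance test with Holm
#' decisions, firing-feature embedding). All tables are written as TSV
#' under `out_dir` together with a run log recording the seed, the config
#' and the package version. A single seed fixes every stochastic stage, so
#' the same config produces byte-identical numeric outputs.
#'
#' @param config A config list (see [default_pipeline_config()]) or the
#'   path to a key=value config file ([read_config()]).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- utils::modifyList(
    default_pipeline_config(), read_config(config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- list()

  ## --- synth -------------------------------------------------------------
  sy <- config$synth
  schedule <- stage("synth", gen_state_schedule(
    seed, sy$schedule_total_s, sy$state_menu, mean_epoch_s = sy$mean_epoch_s))
  genotypes <- rep(c("WT", "KO"), c(sy$n_wt, sy$n_ko))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(genotypes) + 1L)
  trains <- stage("synth", lapply(seq_along(genotypes), function(i) {
    gen_spike_train(sub_seeds[i], schedule, genotype = genotypes[i],
                    unit_id = sprintf("%s_u%02d", genotypes[i], i))
  }))
  mo <- config$motion
  mparams <- stage("synth", motion_gen_params(
    total_s = mo$total_s, baseline_duration_s = mo$baseline_duration_s,
    sample_rate_hz = mo$sample_rate_hz,
    episodes = data.frame(onset_s = mo$episode_onsets_s,
                          duration_s = mo$episode_durations_s,
                          level = rep(0.02, length(mo$episode_onsets_s)))))
  motion <- stage("synth", gen_motion_trace(sub_seeds[length(sub_seeds)],
                                            mparams, mode = mo$mode))
  paths$epochs <- write_epochs(schedule, file.path(out_dir, "epochs.tsv"))
  paths$spikes <- write_spikes(trains, file.path(out_dir, "spikes.tsv"))

  ## --- activity ----------------------------------------------------------
  ac <- config$activity
  lom <- stage("activity", activity_pipeline(
    motion, injection_time_s = ac$injection_time_s,
    horizon_s = ac$horizon_s, lom_level = ac$lom_level,
    nonwalk_min_s = ac$nonwalk_min_s, lom_min_s = ac$lom_min_s))
  paths$metrics <- write_results(lom$metrics, file.path(out_dir, "metrics.tsv"))
  paths$episodes <- write_results(lom$states$episodes,
                                  file.path(out_dir, "episodes.tsv"))

  ## --- spikes ------------------------------------------------------------
  sp <- config$spikes
  bursts <- stage("spikes", lapply(trains, detect_bursts,
                                   isi_max_ms = sp$isi_max_ms,
                                   silence_min_ms = sp$silence_min_ms,
                                   min_spikes = sp$min_spikes))
  metrics <- stage("spikes", do.call(rbind, lapply(seq_along(trains), function(i) {
    m <- state_firing_metrics(trains[[i]], bursts[[i]], schedule)
    m$genotype <- genotypes[i]
    m
  })))
  burst_tab <- do.call(rbind, lapply(seq_along(bursts), function(i) {
    b <- bursts[[i]]
    if (length(b$onsets_s) == 0L) return(NULL)
    data.frame(unit_id = b$unit_id, onset_s = b$onsets_s,
               n_spikes = b$n_spikes, stringsAsFactors = FALSE)
  }))
  if (is.null(burst_tab)) {
    burst_tab <- data.frame(unit_id = character(0), onset_s = numeric(0),
                            n_spikes = integer(0))
  }
  paths$bursts <- file.path(out_dir, "bursts.tsv")
  if (nrow(burst_tab)) write_results(burst_tab, paths$bursts) else
    writeLines("unit_id\tonset_s\tn_spikes", paths$bursts)
  paths$state_metrics <- write_results(metrics,
                                       file.path(out_dir, "state_metrics.tsv"))

  z_tab <- stage("spikes", do.call(rbind, lapply(seq_along(trains), function(i) {
    wk <- schedule[schedule$label == "wake", , drop = FALSE]
    tg <- schedule[schedule$label == sp$zscore_target, , drop = FALSE]
    if (nrow(wk) == 0L || nrow(tg) == 0L) return(NULL)
    z <- zscore_vs_wake(trains[[i]], wk, tg, bin_s = sp$zscore_bin_s)
    data.frame(unit_id = trains[[i]]$unit_id, genotype = genotypes[i],
               z = z$z, label = z$label, stringsAsFactors = FALSE)
  })))
  if (!is.null(z_tab)) {
    paths$zscores <- write_results(z_tab, file.path(out_dir, "zscores.tsv"))
  }

  ## --- stats -------------------------------------------------------------
  stats_rows <- stage("stats", {
    rows <- list()
    for (g in unique(genotypes)) {
      sc <- state_correlation(metrics[metrics$genotype == g, ])
      rows[[length(rows) + 1L]] <- data.frame(
        test = paste0("spearman_state_rate_", g),
        statistic = sc$rho, p = sc$p, n = sc$n)
    }
    wt_rate <- metrics$total_rate_hz[metrics$genotype == "WT"]
    ko_rate <- metrics$total_rate_hz[metrics$genotype == "KO"]
    if (length(wt_rate) >= 2L && length(ko_rate) >= 2L) {
      lev <- variance_homogeneity(wt_rate, ko_rate)
      rows[[length(rows) + 1L]] <- data.frame(
        test = "levene_total_rate_WT_vs_KO",
        statistic = lev$statistic, p = lev$p,
        n = length(wt_rate) + length(ko_rate))
    }
    do.call(rbind, rows)
  })
  holm <- group_compare_holm(p = stats_rows$p)
  stats_rows$p_holm <- holm$p_holm
  stats_rows$reject <- holm$reject
  paths$stats <- write_results(stats_rows, file.path(out_dir, "stats.tsv"))

  emb <- stage("stats", {
    feats <- metrics[, c("tonic_rate_hz", "burst_spike_rate_hz",
                         "burst_event_rate_per_min", "state", "genotype",
                         "unit_id")]
    ok <- stats::complete.cases(feats[, 1:3])
    feats <- feats[ok, , drop = FALSE]
    sds <- vapply(feats[, 1:3], stats::sd, numeric(1))
    feats <- feats[, c(which(sds > 0), 4:6), drop = FALSE]
    if (sum(sds > 0) >= 2L && nrow(feats) >= 10L) {
      state_space_embedding(feats, seed = seed)
    } else NULL
  })
  if (!is.null(emb)) {
    paths$embedding <- write_results(emb, file.path(out_dir, "embedding.tsv"))
  }

  ## --- log ---------------------------------------------------------------
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste0("thalamostate pipeline run, package version ",
           as.character(utils::packageVersion("thalamostate"))),
    paste0("seed = ", seed),
    paste0("R version: ", R.version.string),
    "config:",
    utils::capture.output(utils::str(config))
  ), log_path)
  paths$log <- log_path
  invisible(paths)
}
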