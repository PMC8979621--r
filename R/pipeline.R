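#' Default pipeline configuration
#'
#' All analysis constants live here rather than in the analysis code: the
#' 15 mV detection threshold, the 400 ms detection window (stimulation
#' duration + 100 ms), the 10 ms peak separation, the 4-pressure x
#' 3-duty-cycle protocol grid, and the generator settings. The configuration
#' is a plain list and serialises losslessly to JSON.
#'
#' @param seed Integer seed for the whole run.
#' @param n_cells Number of synthetic cells.
#' @return A named list (class `sonophys_config`).
#' @export
default_config <- function(seed = 1, n_cells = 12) {
  structure(list(
    seed = seed,
    generator = list(
      n_cells = n_cells,
      cell_type = "N",
      pressures_kpa = c(8, 12, 16, 20),
      duty_cycles = c(0.05, 0.5, 1),
      n_windows = 3,
      isi_s = 2,
      sampling_khz = 10,
      pre_ms = 1000,
      post_ms = 700,
      el_control = list(enabled = TRUE, current_na = 3, duration_s = 0.5)
    ),
    analysis = list(
      threshold_mv = 15,
      min_separation_ms = 10,
      detection_post_ms = 100,
      baseline_ms = 300,
      subthreshold_mv = NULL
    ),
    out_dir = NULL
  ), class = "sonophys_config")
}

#' Validate a pipeline configuration
#'
#' Schema and invariant checks; returns a character vector of human-readable
#' issues (empty when the configuration is valid). [run_full_pipeline()]
#' refuses to run on a non-empty issue list.
#'
#' @param config A configuration list as from [default_config()].
#' @return Character vector of issues.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  g <- config$generator
  a <- config$analysis
  if (is.null(config$seed) || !is.finite(config$seed)) add("seed must be a finite number")
  if (is.null(g)) { add("missing generator section"); return(issues) }
  if (is.null(a)) { add("missing analysis section"); return(issues) }
  if (is.null(g$n_cells) || g$n_cells < 1) add("generator.n_cells must be >= 1")
  if (!is.null(g$cell_type) && !g$cell_type %in% c("N", "P")) {
    add("generator.cell_type must be 'N' or 'P'")
  }
  if (any(g$pressures_kpa <= 0)) add("generator.pressures_kpa must be positive")
  if (any(g$duty_cycles <= 0 | g$duty_cycles > 1)) {
    add("generator.duty_cycles must lie in (0, 1]")
  }
  if (g$isi_s <= 0) add("generator.isi_s must be positive")
  if (g$sampling_khz < 5) add("generator.sampling_khz must be >= 5 (ms-scale AP features)")
  if (g$pre_ms < 600) add("generator.pre_ms must be >= 600")
  if (g$post_ms < 700) add("generator.post_ms must be >= 700")
  if (a$threshold_mv <= 0) add("analysis.threshold_mv must be positive")
  if (a$min_separation_ms <= 0) add("analysis.min_separation_ms must be positive")
  if (!is.null(a$subthreshold_mv) && a$subthreshold_mv >= a$threshold_mv) {
    add("analysis.subthreshold_mv must be below analysis.threshold_mv")
  }
  issues
}

#' Run the analysis pipeline over a set of traces
#'
#' Applies the windowed-median subthreshold statistics and spike
#' detection/morphometry to every stimulation window of every trace. The
#' spike-detection threshold is referenced to the median of the
#' `baseline_ms` interval immediately preceding each window onset
#' (per-stimulation, robust to slow drift).
#'
#' @param traces List of `membrane_trace` objects (each carrying its
#'   protocol).
#' @param analysis Analysis parameter list (see [default_config()]).
#' @return List of data.frames: `windows` (one row per stimulation window:
#'   identifiers, protocol fields, I_spta and bin, mean delta-V, spike count,
#'   `has_spike`), `cycles` (long per-cycle delta-V and baseline-variation
#'   rows, US only) and `spikes` (per-spike morphometry).
#' @export
analyze_experiment <- function(traces, analysis = default_config()$analysis) {
  win_rows <- list(); cyc_rows <- list(); spk_rows <- list()
  for (ti in seq_along(traces)) {
    tr <- traces[[ti]]
    p <- tr$protocol
    if (is.null(p)) stop("trace ", ti, " carries no protocol", call. = FALSE)
    us <- p$modality == "US"
    ispta_val <- if (us) ispta(p) else NA_real_
    for (k in seq_along(tr$stim_onsets_ms)) {
      onset <- tr$stim_onsets_ms[k]
      wid <- sprintf("t%03d_w%d", ti, k)
      sd_ms <- stim_window_ms(p)
      # US: stimulation duration + 100 ms post (delayed, outlasting responses);
      # EL: the pulse itself (onset-locked spikes; keeps the step-off
      # transition and undershoot out of the detrended analysis window)
      detection <- if (us) c(onset, onset + sd_ms + analysis$detection_post_ms)
                   else c(onset, onset + sd_ms)
      baseline <- c(onset - analysis$baseline_ms, onset)
      spikes <- detect_spikes(tr, detection, baseline,
                              threshold_mv = analysis$threshold_mv,
                              min_separation_ms = analysis$min_separation_ms,
                              subthreshold_mv = analysis$subthreshold_mv,
                              window_id = wid, modality = p$modality)
      if (nrow(spikes)) {
        spikes$trace <- ti
        spikes$cell_id <- tr$cell_id
        spikes$latency_ms <- spikes$peak_time_ms - onset
        spk_rows[[length(spk_rows) + 1L]] <- spikes
      }
      mean_dv <- NA_real_
      if (us) {
        sch <- build_schedule(p, onset, analysis$detection_post_ms)
        dv <- delta_v(tr, sch)
        bv <- baseline_variation(tr, sch)
        mean_dv <- mean_response(dv)
        cyc_rows[[length(cyc_rows) + 1L]] <- data.frame(
          window_id = wid, trace = ti, cell_id = tr$cell_id,
          p_rms_kpa = p$p_rms_kpa, duty_cycle = p$duty_cycle,
          cycle = seq_along(dv), dv_mv = dv,
          bvar_mv = c(bv, rep(NA_real_, length(dv) - length(bv))))
      }
      n_supra <- sum(!spikes$subthreshold)
      win_rows[[length(win_rows) + 1L]] <- data.frame(
        window_id = wid, trace = ti, cell_id = tr$cell_id,
        cell_type = tr$cell_type, modality = p$modality,
        p_rms_kpa = if (us) p$p_rms_kpa else NA_real_,
        duty_cycle = if (us) p$duty_cycle else NA_real_,
        ispta_mw_cm2 = ispta_val,
        onset_ms = onset,
        mean_dv_mv = mean_dv,
        n_spikes = n_supra,
        has_spike = n_supra > 0)
    }
  }
  windows <- do.call(rbind, win_rows)
  if (!is.null(windows) && any(windows$modality == "US")) {
    windows$bin <- NA_character_
    usr <- windows$modality == "US"
    windows$bin[usr] <- as.character(classify_intensity(windows$ispta_mw_cm2[usr]))
  }
  list(windows = windows,
       cycles = if (length(cyc_rows)) do.call(rbind, cyc_rows) else NULL,
       spikes = if (length(spk_rows)) do.call(rbind, spk_rows) else empty_spike_table())
}

#' Run the full synthetic pipeline
#'
#' End-to-end orchestration: draw a cell population, simulate the protocol
#' grid (plus EL control pulses), run the subthreshold and spike analyses,
#' and compute the summary statistics relating responses to stimulation
#' parameters. Identical configuration and seed give identical results; when
#' `config$out_dir` is set, all result tables are written there as CSV files
#' together with a JSON run manifest (package version, configuration hash,
#' seed).
#'
#' @param config Configuration list from [default_config()], possibly
#'   modified.
#' @return A list of class `sonophys_results`:
#'   \describe{
#'     \item{dosimetry}{the protocol-grid dosimetry table}
#'     \item{windows, cycles, spikes}{the [analyze_experiment()] tables}
#'     \item{success_by_bin}{per-intensity-bin success summary}
#'     \item{dv_regression}{mean delta-V per protocol regressed on I_spta}
#'     \item{success_regression}{per-bin success rate regressed on median bin
#'       intensity}
#'     \item{dv_anova}{two-way (DC x pressure) Type II ANOVA of window mean
#'       delta-V}
#'     \item{ap_comparison}{US vs EL spike-feature summary and Kruskal-Wallis
#'       p-values}
#'     \item{manifest}{version, config hash, seed}
#'   }
#' @export
run_full_pipeline <- function(config = default_config()) {
  issues <- validate_config(config)
  if (length(issues)) {
    stop("invalid configuration:\n  - ", paste(issues, collapse = "\n  - "),
         call. = FALSE)
  }
  g <- config$generator
  protocols <- protocol_grid(g$pressures_kpa, g$duty_cycles,
                             n_windows = g$n_windows, isi_s = g$isi_s)
  el <- NULL
  if (isTRUE(g$el_control$enabled)) {
    el <- stim_protocol("EL", el_current_na = g$el_control$current_na,
                        el_duration_s = g$el_control$duration_s,
                        n_windows = g$n_windows, isi_s = g$isi_s)
  }
  population <- generate_cell_population(g$n_cells, seed = derive_seed(config$seed, 0),
                                         cell_type = g$cell_type)
  experiment <- generate_experiment(protocols, population, seed = config$seed,
                                    el_control = el,
                                    sampling_khz = g$sampling_khz,
                                    pre_ms = g$pre_ms, post_ms = g$post_ms)
  tables <- analyze_experiment(experiment$traces, config$analysis)
  w <- tables$windows
  usw <- w[w$modality == "US", ]

  # mean response per protocol (over cells and windows) vs dose
  agg <- stats::aggregate(cbind(mean_dv_mv, ispta_mw_cm2) ~ p_rms_kpa + duty_cycle,
                          data = usw, FUN = mean)
  dv_reg <- linear_regression(agg$ispta_mw_cm2, agg$mean_dv_mv)

  success_by_bin <- do.call(rbind, lapply(split(usw, usw$bin), function(d) {
    data.frame(bin = d$bin[1], n_windows = nrow(d),
               n_with_spike = sum(d$has_spike),
               success_rate = mean(d$has_spike),
               median_ispta = stats::median(d$ispta_mw_cm2))
  }))
  success_by_bin <- success_by_bin[order(success_by_bin$median_ispta), ]
  rownames(success_by_bin) <- NULL
  success_reg <- if (nrow(success_by_bin) >= 3 &&
                     stats::var(success_by_bin$median_ispta) > 0) {
    linear_regression(success_by_bin$median_ispta, success_by_bin$success_rate)
  } else NULL

  dv_anova <- two_way_anova(usw$mean_dv_mv, factor(usw$duty_cycle),
                            factor(usw$p_rms_kpa))

  ap_comparison <- compare_ap_features(tables$spikes)

  manifest <- list(package = "sonophys",
                   version = as.character(utils::packageVersion("sonophys")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   n_traces = length(experiment$traces))

  res <- structure(list(dosimetry = dosimetry_table(protocols),
                        windows = tables$windows,
                        cycles = tables$cycles,
                        spikes = tables$spikes,
                        success_by_bin = success_by_bin,
                        dv_regression = dv_reg,
                        success_regression = success_reg,
                        dv_anova = dv_anova,
                        ap_comparison = ap_comparison,
                        manifest = manifest,
                        truths = experiment$truths),
                   class = "sonophys_results")
  if (!is.null(config$out_dir)) write_results(res, config$out_dir)
  res
}

# US vs EL AP-feature summary: per-set means/SDs and pairwise rank tests
compare_ap_features <- function(spikes) {
  sp <- spikes[!spikes$subthreshold & !is.na(spikes$duration_ms), ]
  if (!nrow(sp)) return(NULL)
  sets <- list(us_first = sp[sp$modality == "US" & sp$order == "first", ],
               us_following = sp[sp$modality == "US" & sp$order == "following", ],
               us_all = sp[sp$modality == "US", ],
               el = sp[sp$modality == "EL", ])
  summary <- do.call(rbind, lapply(names(sets), function(nm) {
    d <- sets[[nm]]
    data.frame(set = nm, n = nrow(d),
               amp_mean = mean(d$amplitude_mv), amp_sd = stats::sd(d$amplitude_mv),
               dur_mean = mean(d$duration_ms), dur_sd = stats::sd(d$duration_ms),
               ratio_mean = mean(d$ratio_mv_ms), ratio_sd = stats::sd(d$ratio_mv_ms))
  }))
  tests <- NULL
  if (nrow(sets$us_all) && nrow(sets$el)) {
    tests <- data.frame(
      feature = c("duration_ms", "amplitude_mv", "ratio_mv_ms"),
      p_us_vs_el = c(
        kruskal_wallis(list(sets$us_all$duration_ms, sets$el$duration_ms))$p_value,
        kruskal_wallis(list(sets$us_all$amplitude_mv, sets$el$amplitude_mv))$p_value,
        kruskal_wallis(list(sets$us_all$ratio_mv_ms, sets$el$ratio_mv_ms))$p_value))
  }
  list(summary = summary, tests = tests)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}

write_results <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(res$dosimetry, file.path(out_dir, "dosimetry.csv"), row.names = FALSE)
  utils::write.csv(res$windows, file.path(out_dir, "windows.csv"), row.names = FALSE)
  if (!is.null(res$cycles)) {
    utils::write.csv(res$cycles, file.path(out_dir, "subthreshold_cycles.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(res$spikes, file.path(out_dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(res$success_by_bin, file.path(out_dir, "success_by_bin.csv"),
                   row.names = FALSE)
  if (!is.null(res$ap_comparison)) {
    utils::write.csv(res$ap_comparison$summary,
                     file.path(out_dir, "ap_comparison.csv"), row.names = FALSE)
  }
  stat_rows <- data.frame(
    term = c("dv_vs_ispta_slope", "dv_vs_ispta_r2", "dv_vs_ispta_p",
             "anova_dc_F", "anova_dc_p", "anova_pressure_F", "anova_pressure_p",
             "anova_interaction_F", "anova_interaction_p"),
    value = c(res$dv_regression$slope, res$dv_regression$r_squared,
              res$dv_regression$p_value,
              res$dv_anova$factor_a["F"], res$dv_anova$factor_a["p"],
              res$dv_anova$factor_b["F"], res$dv_anova$factor_b["p"],
              res$dv_anova$interaction["F"], res$dv_anova$interaction["p"]))
  utils::write.csv(stat_rows, file.path(out_dir, "stats.csv"), row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.sonophys_results <- function(x, ...) {
  cat("<sonophys_results>\n")
  cat(sprintf("  %d protocols, %d stimulation windows, %d detected spikes\n",
              nrow(x$dosimetry), nrow(x$windows), nrow(x$spikes)))
  cat(sprintf("  mean dV vs I_spta: R^2 = %.3f (p = %.3g)\n",
              x$dv_regression$r_squared, x$dv_regression$p_value))
  if (!is.null(x$success_by_bin)) {
    cat("  success by bin:",
        paste(sprintf("%s %.0f%%", x$success_by_bin$bin,
                      100 * x$success_by_bin$success_rate), collapse = ", "), "\n")
  }
  invisible(x)
}
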