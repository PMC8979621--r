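#' Detect action potentials in a stimulation window
#'
#' Threshold-crossing spike detection: local maxima of the membrane voltage
#' exceeding `median(baseline) + threshold_mv` inside the detection window,
#' separated by at least `min_separation_ms`. The first supra-threshold event
#' of a window is tagged `"first"`, later ones `"following"`. Morphometry
#' (peak-to-subsequent-minimum amplitude and the half-prominence duration of
#' the early repolarization) is measured on the detrended window signal
#' (first-order polynomial removed); peak times and the baseline-referenced
#' threshold use the raw trace.
#'
#' An optional secondary pass with a lower threshold flags additional events
#' as subthreshold; these never count toward success rates.
#'
#' @param trace A `membrane_trace`.
#' @param detection Length-2 vector, the half-open detection window `[start,
#'   end)` in ms (onset + stimulation duration + 100 ms by convention).
#' @param baseline Length-2 vector, the pre-stimulus baseline interval used to
#'   reference the threshold.
#' @param threshold_mv Detection threshold above the baseline median, mV
#'   (default 15).
#' @param min_separation_ms Minimum separation between accepted peaks, ms
#'   (default 10; about four times the typical early-repolarization duration).
#' @param subthreshold_mv Optional lower threshold for the secondary pass,
#'   mV above baseline; `NULL` (default) disables it.
#' @param window_id Identifier stored with each event.
#' @param modality `"US"` or `"EL"`, stored with each event.
#' @return A data.frame with one row per event: `window_id`, `modality`,
#'   `order` ("first"/"following"), `peak_time_ms`, `peak_mv`,
#'   `trough_time_ms`, `trough_mv`, `amplitude_mv`, `duration_ms`,
#'   `ratio_mv_ms`, `latency_ms`, `subthreshold`.
#' @export
detect_spikes <- function(trace, detection, baseline,
                          threshold_mv = 15,
                          min_separation_ms = 10,
                          subthreshold_mv = NULL,
                          window_id = "w1",
                          modality = c("US", "EL")) {
  modality <- match.arg(modality)
  stopifnot(length(detection) == 2L, length(baseline) == 2L)
  v <- extract_epoch(trace, detection[1], detection[2])
  if (!length(v)) stop("empty detection window", call. = FALSE)
  b <- extract_epoch(trace, baseline[1], baseline[2])
  if (!length(b)) stop("empty baseline epoch", call. = FALSE)
  base_med <- stats::median(b)
  r <- trace$sampling_khz
  t0 <- detection[1]
  vd <- if (length(v) >= 2) detrend_window(v) else v

  main_idx <- find_peaks(v, base_med + threshold_mv, min_separation_ms * r)
  sub_idx <- integer(0)
  if (!is.null(subthreshold_mv)) {
    all_idx <- find_peaks(v, base_med + subthreshold_mv, min_separation_ms * r)
    sub_idx <- setdiff(all_idx, main_idx)
  }
  idx <- sort(c(main_idx, sub_idx))
  if (!length(idx)) return(empty_spike_table())

  rows <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    bound <- if (k < length(idx)) idx[k + 1] else length(v)
    m <- measure_ap(vd, i, bound, r)
    peak_t <- t0 + (i - 1) / r
    data.frame(window_id = window_id,
               modality = modality,
               order = NA_character_,
               peak_time_ms = peak_t,
               peak_mv = v[i],
               trough_time_ms = t0 + (m$trough_idx - 1) / r,
               trough_mv = v[m$trough_idx],
               amplitude_mv = m$amplitude,
               duration_ms = m$duration,
               ratio_mv_ms = if (is.na(m$duration) || m$duration <= 0) NA_real_
                             else m$amplitude / m$duration,
               latency_ms = peak_t - t0,
               subthreshold = i %in% sub_idx)
  })
  out <- do.call(rbind, rows)
  supra <- !out$subthreshold
  if (any(supra)) {
    out$order[supra] <- c("first", rep("following", sum(supra) - 1L))
  }
  out
}

empty_spike_table <- function() {
  data.frame(window_id = character(0), modality = character(0),
             order = character(0), peak_time_ms = numeric(0),
             peak_mv = numeric(0), trough_time_ms = numeric(0),
             trough_mv = numeric(0), amplitude_mv = numeric(0),
             duration_ms = numeric(0), ratio_mv_ms = numeric(0),
             latency_ms = numeric(0), subthreshold = logical(0))
}

# Local maxima of v above `height`, greedily thinned so that accepted peaks
# are at least `min_sep_samples` apart (taller peaks win).
find_peaks <- function(v, height, min_sep_samples) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  cand <- cand[v[cand] > height]
  if (length(cand) <= 1L) return(cand)
  cand <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_sep_samples)) kept <- c(kept, i)
  }
  sort(kept)
}

# Amplitude (peak to subsequent minimum before `bound_idx`) and the
# half-prominence duration of the declining phase, with linear interpolation
# at the crossing. Works on a (detrended) window vector.
measure_ap <- function(v, peak_idx, bound_idx, r_khz) {
  if (peak_idx >= bound_idx) {
    return(list(trough_idx = peak_idx, trough_raw = v[peak_idx],
                amplitude = NA_real_, duration = NA_real_))
  }
  seg <- v[peak_idx:bound_idx]
  trough_rel <- which.min(seg)
  trough_idx <- peak_idx + trough_rel - 1L
  amplitude <- v[peak_idx] - v[trough_idx]
  half_level <- v[peak_idx] - amplitude / 2
  fall <- v[peak_idx:trough_idx]
  below <- which(fall <= half_level)
  if (!length(below) || amplitude <= 0) {
    duration <- NA_real_
  } else {
    j <- below[1]
    if (j == 1L) {
      duration <- 0
    } else {
      # linear interpolation between samples j-1 (above) and j (at/below)
      frac <- (fall[j - 1] - half_level) / (fall[j - 1] - fall[j])
      duration <- (j - 2 + frac) / r_khz
    }
  }
  list(trough_idx = trough_idx, trough_raw = v[trough_idx],
       amplitude = amplitude, duration = duration)
}

#' Peak-to-subsequent-minimum amplitude of one action potential
#'
#' The AP amplitude is the difference between the peak voltage and the
#' subsequent minimum, searched up to `bound_ms` (by default the end of the
#' trace; pass the next peak time or the detection-window end).
#'
#' @param trace A `membrane_trace`.
#' @param peak_time_ms Time of the spike peak, ms (must map to a sample).
#' @param bound_ms Exclusive search bound, ms.
#' @return List with `amplitude_mv` and `trough_time_ms`.
#' @export
ap_amplitude <- function(trace, peak_time_ms, bound_ms = trace_end_ms(trace)) {
  i <- time_to_index(trace, peak_time_ms)
  j <- time_to_index(trace, bound_ms, clamp = TRUE)
  if (j <= i) stop("no samples after the peak to search for the trough", call. = FALSE)
  m <- measure_ap(trace$voltage_mv, i, j, trace$sampling_khz)
  list(amplitude_mv = m$amplitude,
       trough_time_ms = trace$t_start_ms + (m$trough_idx - 1) / trace$sampling_khz)
}

#' Early-repolarization duration of one action potential
#'
#' Time from the AP peak to the first crossing of the half-prominence level
#' (peak minus half the peak-to-trough amplitude) on the declining phase, with
#' linear interpolation between samples.
#'
#' @inheritParams ap_amplitude
#' @return Duration in ms (`NA` with a warning if the declining phase never
#'   reaches the half level).
#' @export
ap_duration <- function(trace, peak_time_ms, bound_ms = trace_end_ms(trace)) {
  i <- time_to_index(trace, peak_time_ms)
  j <- time_to_index(trace, bound_ms, clamp = TRUE)
  if (j <= i) stop("no samples after the peak", call. = FALSE)
  m <- measure_ap(trace$voltage_mv, i, j, trace$sampling_khz)
  if (is.na(m$duration)) {
    warning("degenerate spike: declining phase never reaches half prominence")
  }
  m$duration
}

#' Amplitude-to-duration ratio
#'
#' Proportional to the slope of the AP decay phase; a shape measure that is
#' comparable across stimulation modalities.
#'
#' @param amplitude_mv AP amplitude, mV.
#' @param duration_ms Early-repolarization duration, ms (> 0).
#' @return Ratio in mV/ms.
#' @export
ap_ratio <- function(amplitude_mv, duration_ms) {
  if (any(duration_ms <= 0, na.rm = TRUE)) {
    stop("duration must be positive", call. = FALSE)
  }
  amplitude_mv / duration_ms
}

#' Response latency
#'
#' Time from the stimulus-window onset to the AP peak.
#'
#' @param peak_time_ms Spike peak time, ms.
#' @param onset_ms Stimulus-window onset, ms.
#' @return Latency in ms (errors if negative).
#' @export
spike_latency <- function(peak_time_ms, onset_ms) {
  lat <- peak_time_ms - onset_ms
  if (any(lat < 0)) stop("negative latency: peak precedes window onset", call. = FALSE)
  lat
}

time_to_index <- function(trace, time_ms, clamp = FALSE) {
  i <- round((time_ms - trace$t_start_ms) * trace$sampling_khz) + 1
  if (clamp) i <- min(max(i, 1), length(trace$voltage_mv))
  if (i < 1 || i > length(trace$voltage_mv)) {
    stop("time outside trace extent", call. = FALSE)
  }
  as.integer(i)
}

#' Success rate over stimulation windows
#'
#' Fraction of stimulation windows whose 400 ms detection window (stimulation
#' duration + 100 ms post) contains at least one supra-threshold spike.
#'
#' @param spikes A spike table as returned by [detect_spikes()] (rows with
#'   `subthreshold = TRUE` are ignored).
#' @param window_ids Character vector of all stimulation-window identifiers
#'   that were analysed (including spike-free ones).
#' @return A list of class `success_summary`: `n_stimulations`,
#'   `n_with_spike`, `success_rate`.
#' @export
success_rate <- function(spikes, window_ids) {
  if (!length(window_ids)) stop("success_rate needs >= 1 stimulation", call. = FALSE)
  hit <- unique(spikes$window_id[!spikes$subthreshold])
  n_hit <- sum(window_ids %in% hit)
  structure(list(n_stimulations = length(window_ids),
                 n_with_spike = n_hit,
                 success_rate = n_hit / length(window_ids)),
            class = "success_summary")
}

#' @export
print.success_summary <- function(x, ...) {
  cat(sprintf("<success_summary> %d/%d windows with spikes (%.1f%%)\n",
              x$n_with_spike, x$n_stimulations, 100 * x$success_rate))
  invisible(x)
}
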