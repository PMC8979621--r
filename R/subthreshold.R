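#' Per-window epoch schedule for subthreshold analysis
#'
#' Derives, from a pulsed-ultrasound protocol and a stimulus-window onset, the
#' baseline/response epoch pairs used for the median depolarization statistic,
#' the wider off-state windows used for baseline-variation, the 400 ms spike
#' detection window (stimulation duration + 100 ms post) and the post-stimulus
#' window. All intervals are half-open `[start, end)` in ms.
#'
#' For pulsed duty cycles each response epoch is one tone burst and its
#' baseline is the equally long slice of off-state immediately preceding the
#' burst; for continuous stimulation (DC = 1) the response is the full 300 ms
#' window and the baseline the 300 ms preceding onset. Baseline-variation
#' windows span the full off-intervals (e.g. 95 ms at DC 5%); for DC = 1 they
#' are the 300 ms before onset and the 300 ms after stimulus end.
#'
#' @param protocol A US `stim_protocol`.
#' @param onset_ms Stimulus-window onset, ms.
#' @param detection_post_ms Post-stimulation extension of the spike-detection
#'   window, ms (default 100).
#' @return An object of class `window_schedule` with elements `cycles`
#'   (data.frame of baseline/response bounds), `bvar` (data.frame of
#'   baseline-variation windows), `detection` and `post` (length-2 vectors).
#' @export
build_schedule <- function(protocol, onset_ms, detection_post_ms = 100) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (protocol$modality != "US") {
    stop("build_schedule is defined for US protocols only", call. = FALSE)
  }
  sd_ms <- protocol$stim_ms
  bursts <- burst_timing(protocol)
  if (protocol$duty_cycle >= 1) {
    cycles <- data.frame(baseline_start = onset_ms - sd_ms,
                         baseline_end = onset_ms,
                         response_start = onset_ms,
                         response_end = onset_ms + sd_ms)
    bvar <- data.frame(start = c(onset_ms - sd_ms, onset_ms + sd_ms),
                       end = c(onset_ms, onset_ms + 2 * sd_ms))
  } else {
    t_on <- protocol$duty_cycle * protocol$prp_ms
    t_off <- protocol$prp_ms - t_on
    rs <- onset_ms + bursts$on_start_ms
    cycles <- data.frame(baseline_start = rs - t_on,
                         baseline_end = rs,
                         response_start = rs,
                         response_end = rs + t_on)
    # full off-state windows: one before stimulus onset, one after each burst
    bvar <- data.frame(start = c(onset_ms - t_off, onset_ms + bursts$on_end_ms),
                       end = c(onset_ms, onset_ms + bursts$on_end_ms + t_off))
  }
  structure(list(onset_ms = onset_ms,
                 cycles = cycles,
                 bvar = bvar,
                 detection = c(onset_ms, onset_ms + sd_ms + detection_post_ms),
                 post = c(onset_ms + sd_ms, onset_ms + sd_ms + detection_post_ms),
                 protocol = protocol),
            class = "window_schedule")
}

#' @export
print.window_schedule <- function(x, ...) {
  cat(sprintf("<window_schedule> onset %g ms, %d cycle(s), detection [%g, %g) ms\n",
              x$onset_ms, nrow(x$cycles), x$detection[1], x$detection[2]))
  invisible(x)
}

#' Per-cycle median depolarization
#'
#' The membrane-potential variation of each stimulation cycle: the median
#' voltage during the response epoch minus the median during its preceding
#' baseline epoch. Positive values are depolarizations.
#'
#' @param trace A `membrane_trace`.
#' @param schedule A `window_schedule` whose epochs lie within the trace.
#' @return Numeric vector of per-cycle delta-V, mV.
#' @export
delta_v <- function(trace, schedule) {
  stopifnot(inherits(schedule, "window_schedule"))
  vapply(seq_len(nrow(schedule$cycles)), function(i) {
    cy <- schedule$cycles[i, ]
    b <- extract_epoch(trace, cy$baseline_start, cy$baseline_end)
    r <- extract_epoch(trace, cy$response_start, cy$response_end)
    if (!length(b) || !length(r)) {
      stop("degenerate window: empty baseline or response epoch", call. = FALSE)
    }
    stats::median(r) - stats::median(b)
  }, numeric(1))
}

#' Baseline variation across cycles
#'
#' Differences of consecutive off-state window medians,
#' `B_i = median(window i+1) - median(window i)`, capturing depolarization
#' that outlasts each tone burst.
#'
#' @param trace A `membrane_trace`.
#' @param schedule A `window_schedule`.
#' @return Numeric vector of length `nrow(schedule$bvar) - 1` (empty when only
#'   one off-state window exists).
#' @export
baseline_variation <- function(trace, schedule) {
  stopifnot(inherits(schedule, "window_schedule"))
  w <- schedule$bvar
  if (nrow(w) < 2L) return(numeric(0))
  med <- vapply(seq_len(nrow(w)), function(i) {
    s <- extract_epoch(trace, w$start[i], w$end[i])
    if (!length(s)) stop("degenerate window: empty baseline-variation epoch",
                         call. = FALSE)
    stats::median(s)
  }, numeric(1))
  diff(med)
}

#' Mean response over cycles
#'
#' Arithmetic mean of the per-cycle median depolarizations; responses are
#' always summarised by their average over all cycles of a stimulation
#' window.
#'
#' @param dv Numeric vector of per-cycle delta-V values.
#' @return Scalar mean, mV.
#' @export
mean_response <- function(dv) {
  if (!length(dv)) stop("mean_response needs at least one cycle", call. = FALSE)
  mean(dv)
}

#' Subthreshold summary of one stimulation window
#'
#' Convenience wrapper bundling [delta_v()], [mean_response()] and
#' [baseline_variation()] with the protocol dose.
#'
#' @param trace A `membrane_trace`.
#' @param schedule A `window_schedule`.
#' @param medium A [medium()] for dosimetry.
#' @return A list of class `subthreshold_result` with `dv`, `mean_dv`, `bvar`,
#'   `ispta_mw_cm2` and the protocol.
#' @export
subthreshold_result <- function(trace, schedule, medium = water_medium()) {
  dv <- delta_v(trace, schedule)
  structure(list(dv = dv,
                 mean_dv = mean_response(dv),
                 bvar = baseline_variation(trace, schedule),
                 ispta_mw_cm2 = ispta(schedule$protocol, medium),
                 protocol = schedule$protocol),
            class = "subthreshold_result")
}

#' @export
print.subthreshold_result <- function(x, ...) {
  cat(sprintf("<subthreshold_result> mean dV = %.3f mV over %d cycle(s), I_spta = %.3g mW/cm^2\n",
              x$mean_dv, length(x$dv), x$ispta_mw_cm2))
  invisible(x)
}
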