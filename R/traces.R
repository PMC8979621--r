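#' Membrane-voltage trace
#'
#' A uniformly sampled intracellular voltage recording with stimulus markers.
#' Sample `i` (1-based) covers time `t_start_ms + (i - 1) / rate` ms; all
#' epoch arithmetic uses half-open `[start, end)` intervals in ms.
#'
#' @param voltage_mv Numeric vector of membrane voltage, mV.
#' @param sampling_khz Sampling rate, kHz (samples per ms).
#' @param t_start_ms Time of the first sample, ms.
#' @param cell_id Cell identifier string.
#' @param cell_type `"N"` (nociceptive) or `"P"` (pressure) mechanosensory cell.
#' @param stim_onsets_ms Onset time of each stimulation window, ms.
#' @param protocol The `stim_protocol` shared by the stimulation windows.
#' @return An object of class `membrane_trace`.
#' @export
membrane_trace <- function(voltage_mv,
                           sampling_khz = 10,
                           t_start_ms = 0,
                           cell_id = "cell1",
                           cell_type = c("N", "P"),
                           stim_onsets_ms = numeric(0),
                           protocol = NULL) {
  cell_type <- match.arg(cell_type)
  tr <- structure(list(voltage_mv = as.numeric(voltage_mv),
                       sampling_khz = sampling_khz,
                       t_start_ms = t_start_ms,
                       cell_id = as.character(cell_id),
                       cell_type = cell_type,
                       stim_onsets_ms = as.numeric(stim_onsets_ms),
                       protocol = protocol),
                  class = "membrane_trace")
  validate_trace(tr)
  tr
}

validate_trace <- function(tr) {
  stopifnot(inherits(tr, "membrane_trace"))
  if (!is.finite(tr$sampling_khz) || tr$sampling_khz <= 0) {
    stop("sampling_khz must be positive", call. = FALSE)
  }
  if (length(tr$voltage_mv) < 1L) stop("trace has no samples", call. = FALSE)
  if (anyNA(tr$voltage_mv)) stop("trace contains missing samples", call. = FALSE)
  if (length(tr$stim_onsets_ms)) {
    if (is.unsorted(tr$stim_onsets_ms, strictly = TRUE)) {
      stop("stimulus onsets must be strictly increasing", call. = FALSE)
    }
    if (!is.null(tr$protocol)) {
      sd_ms <- stim_window_ms(tr$protocol)
      ends <- tr$stim_onsets_ms + sd_ms + 100
      if (any(tr$stim_onsets_ms < tr$t_start_ms) || any(ends > trace_end_ms(tr))) {
        stop("stimulation window (onset to onset + duration + 100 ms) outside trace extent",
             call. = FALSE)
      }
      if (length(tr$stim_onsets_ms) > 1L) {
        gaps_s <- diff(tr$stim_onsets_ms) / 1000
        if (any(gaps_s < tr$protocol$isi_s - 1e-9)) {
          stop("stimulus onsets closer than the protocol inter-stimulation interval",
               call. = FALSE)
        }
      }
    }
  }
  invisible(tr)
}

# stimulus duration of a protocol in ms (EL pulses are specified in s)
stim_window_ms <- function(protocol) {
  if (protocol$modality == "US") protocol$stim_ms else protocol$el_duration_s * 1000
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf(
    "<membrane_trace> cell %s (%s), %d samples @ %g kHz, t = [%g, %g) ms, %d stim window(s)\n",
    x$cell_id, x$cell_type, length(x$voltage_mv), x$sampling_khz,
    x$t_start_ms, trace_end_ms(x), length(x$stim_onsets_ms)))
  invisible(x)
}

#' Trace end time (ms, exclusive)
#' @param trace A `membrane_trace`.
#' @export
trace_end_ms <- function(trace) {
  trace$t_start_ms + length(trace$voltage_mv) / trace$sampling_khz
}

#' Sample times of a trace (ms)
#' @param trace A `membrane_trace`.
#' @export
trace_times_ms <- function(trace) {
  trace$t_start_ms + (seq_along(trace$voltage_mv) - 1) / trace$sampling_khz
}

#' Extract the samples of an epoch
#'
#' Returns the voltage samples whose times fall in the half-open interval
#' `[start_ms, end_ms)`.
#'
#' @param trace A `membrane_trace`.
#' @param start_ms,end_ms Interval bounds in ms; `end_ms >= start_ms`.
#' @return Numeric vector of mV samples (empty for a degenerate interval).
#' @export
extract_epoch <- function(trace, start_ms, end_ms) {
  stopifnot(inherits(trace, "membrane_trace"))
  if (end_ms < start_ms) stop("end_ms must be >= start_ms", call. = FALSE)
  if (start_ms < trace$t_start_ms - 1e-9 || end_ms > trace_end_ms(trace) + 1e-9) {
    stop("epoch outside trace extent", call. = FALSE)
  }
  if (end_ms == start_ms) return(numeric(0))
  r <- trace$sampling_khz
  # first sample index with t >= start, last with t < end (1-based)
  i0 <- ceiling((start_ms - trace$t_start_ms) * r - 1e-9) + 1
  i1 <- ceiling((end_ms - trace$t_start_ms) * r - 1e-9)
  if (i1 < i0) return(numeric(0))
  trace$voltage_mv[i0:i1]
}

#' Remove a linear trend from a signal window
#'
#' Subtracts the least-squares first-order polynomial fit, as applied to each
#' analysis window before peak measurements. Residuals have zero mean and zero
#' least-squares slope.
#'
#' @param samples Numeric vector, length >= 2.
#' @return Detrended samples.
#' @export
detrend_window <- function(samples) {
  n <- length(samples)
  if (n < 2L) stop("degenerate window: detrending needs >= 2 samples", call. = FALSE)
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), samples)
  as.numeric(fit$residuals)
}

#' Write a trace to CSV + JSON sidecar
#'
#' The interchange format is a CSV with header `time_ms,voltage_mV` and a JSON
#' sidecar (same path with extension `.json`) carrying `sampling_khz`,
#' `t_start_ms`, `cell_id`, `cell_type`, `stim_onsets_ms` and the protocol
#' fields.
#'
#' @param trace A `membrane_trace`.
#' @param path Path of the CSV file to create.
#' @return Invisibly, the two file paths.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "membrane_trace"))
  # %.17g keeps doubles value-exact through the text round-trip
  lines <- c("time_ms,voltage_mV",
             sprintf("%.17g,%.17g", trace_times_ms(trace), trace$voltage_mv))
  writeLines(lines, path)
  meta <- list(sampling_khz = trace$sampling_khz,
               t_start_ms = trace$t_start_ms,
               cell_id = trace$cell_id,
               cell_type = trace$cell_type,
               stim_onsets_ms = as.numeric(trace$stim_onsets_ms),
               protocol = protocol_to_list(trace$protocol))
  sidecar <- sidecar_path(path)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv = path, json = sidecar))
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

protocol_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  unclass(p)
}

protocol_from_list <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NULL)
  do.call(stim_protocol, x[!vapply(x, is.null, logical(1))])
}

#' Read a trace from CSV + JSON sidecar
#'
#' Inverse of [write_trace()]. Validates sampling uniformity against the
#' sidecar rate and all trace invariants.
#'
#' @param path Path of the CSV file.
#' @return A `membrane_trace`.
#' @export
read_trace <- function(path) {
  sidecar <- sidecar_path(path)
  if (!file.exists(sidecar)) {
    stop("metadata error: missing JSON sidecar ", sidecar, call. = FALSE)
  }
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "voltage_mV") %in% names(df))) {
    stop("format error: CSV must have columns time_ms, voltage_mV", call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dt <- diff(df$time_ms)
  if (nrow(df) > 1) {
    expected_dt <- 1 / meta$sampling_khz
    if (any(abs(dt - expected_dt) > 1e-6 * max(1, expected_dt))) {
      stop("format error: non-uniform sampling in ", path, call. = FALSE)
    }
  }
  membrane_trace(voltage_mv = df$voltage_mV,
                 sampling_khz = meta$sampling_khz,
                 t_start_ms = meta$t_start_ms,
                 cell_id = meta$cell_id,
                 cell_type = meta$cell_type,
                 stim_onsets_ms = meta$stim_onsets_ms %||% numeric(0),
                 protocol = protocol_from_list(meta$protocol))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
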