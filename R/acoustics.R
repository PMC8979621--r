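#' Acoustic medium
#'
#' Density and speed of sound of the coupling medium used to convert acoustic
#' pressure into intensity. Defaults are water at 20 degrees C, the
#' approximation used when dosing unfocused low-intensity stimulation delivered
#' through a water tank.
#'
#' @param density_kg_m3 Density rho in kg/m^3.
#' @param speed_m_s Speed of sound c in m/s.
#' @return An object of class `medium`.
#' @examples
#' water_medium()
#' @export
medium <- function(density_kg_m3 = 1000, speed_m_s = 1482) {
  if (!is.numeric(density_kg_m3) || length(density_kg_m3) != 1L ||
      !is.finite(density_kg_m3) || density_kg_m3 <= 0) {
    stop("invalid medium: density must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(speed_m_s) || length(speed_m_s) != 1L ||
      !is.finite(speed_m_s) || speed_m_s <= 0) {
    stop("invalid medium: speed of sound must be a single positive number", call. = FALSE)
  }
  structure(list(density_kg_m3 = density_kg_m3, speed_m_s = speed_m_s),
            class = "medium")
}

#' @rdname medium
#' @export
water_medium <- function() medium()

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> rho = %g kg/m^3, c = %g m/s\n",
              x$density_kg_m3, x$speed_m_s))
  invisible(x)
}

#' Stimulation protocol
#'
#' One stimulation setting: modality (ultrasound `"US"` or intracellular
#' electrical pulse `"EL"`), acoustic pressure, pulse timing and repetition
#' structure. For pulsed ultrasound the tone burst lasts
#' `duty_cycle * prp_ms` (T-on) of every pulse repetition period; continuous
#' stimulation is `duty_cycle = 1`.
#'
#' @param modality `"US"` or `"EL"`.
#' @param carrier_khz Carrier frequency in kHz (US only; default 490).
#' @param p_rms_kpa Root-mean-square acoustic pressure at the target, kPa.
#' @param duty_cycle On-time fraction of the pulse repetition period, in (0, 1].
#' @param prp_ms Pulse repetition period, ms.
#' @param stim_ms Stimulation duration per window, ms.
#' @param n_windows Number of repeated stimulation windows per recording.
#' @param isi_s Inter-stimulation interval between windows, s.
#' @param el_current_na Injected current, nA (EL only).
#' @param el_duration_s Pulse duration, s (EL only).
#' @return An object of class `stim_protocol`.
#' @examples
#' stim_protocol("US", p_rms_kpa = 20, duty_cycle = 0.05)
#' @export
stim_protocol <- function(modality = c("US", "EL"),
                          carrier_khz = 490,
                          p_rms_kpa = NULL,
                          duty_cycle = NULL,
                          prp_ms = 100,
                          stim_ms = 300,
                          n_windows = 3,
                          isi_s = 20,
                          el_current_na = NULL,
                          el_duration_s = NULL) {
  modality <- match.arg(modality)
  p <- structure(list(modality = modality,
                      carrier_khz = carrier_khz,
                      p_rms_kpa = p_rms_kpa,
                      duty_cycle = duty_cycle,
                      prp_ms = prp_ms,
                      stim_ms = stim_ms,
                      n_windows = as.integer(n_windows),
                      isi_s = isi_s,
                      el_current_na = el_current_na,
                      el_duration_s = el_duration_s),
                 class = "stim_protocol")
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "stim_protocol"))
  if (p$modality == "US") {
    if (is.null(p$p_rms_kpa) || !is.finite(p$p_rms_kpa) || p$p_rms_kpa < 0) {
      stop("US protocol requires p_rms_kpa >= 0", call. = FALSE)
    }
    if (is.null(p$duty_cycle) || !is.finite(p$duty_cycle) ||
        p$duty_cycle <= 0 || p$duty_cycle > 1) {
      stop("duty_cycle must lie in (0, 1]", call. = FALSE)
    }
    if (!is.finite(p$prp_ms) || p$prp_ms <= 0) {
      stop("prp_ms must be positive", call. = FALSE)
    }
    if (p$duty_cycle < 1) {
      n_cyc <- p$stim_ms / p$prp_ms
      if (abs(n_cyc - round(n_cyc)) > 1e-9) {
        stop("stim_ms must be an integer multiple of prp_ms for pulsed protocols",
             call. = FALSE)
      }
    }
  } else {
    if (is.null(p$el_current_na) || is.null(p$el_duration_s)) {
      stop("EL protocol requires el_current_na and el_duration_s", call. = FALSE)
    }
    if (p$el_duration_s <= 0) stop("el_duration_s must be positive", call. = FALSE)
  }
  if (!is.finite(p$stim_ms) && p$modality == "US") {
    stop("stim_ms must be finite", call. = FALSE)
  }
  if (p$n_windows < 1L) stop("n_windows must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.stim_protocol <- function(x, ...) {
  if (x$modality == "US") {
    cat(sprintf(
      "<stim_protocol US> %g kPa, DC %g%%, PRP %g ms, SD %g ms, %d window(s), ISI %g s\n",
      x$p_rms_kpa, 100 * x$duty_cycle, x$prp_ms, x$stim_ms, x$n_windows, x$isi_s))
  } else {
    cat(sprintf("<stim_protocol EL> %g nA for %g s, %d window(s), ISI %g s\n",
                x$el_current_na, x$el_duration_s, x$n_windows, x$isi_s))
  }
  invisible(x)
}

# W/m^2 -> mW/cm^2 (1 W/m^2 = 1000 mW / 1e4 cm^2)
W_M2_TO_MW_CM2 <- 0.1

#' Spatial-peak pulse-average intensity
#'
#' Converts root-mean-square acoustic pressure into the plane-wave pulse-average
#' intensity I_sppa = P_rms^2 / (rho c), reported in mW/cm^2.
#'
#' @param p_rms_kpa RMS pressure in kPa (scalar or vector).
#' @param medium A [medium()]; defaults to water.
#' @return Intensity in mW/cm^2.
#' @examples
#' isppa(20) # about 27 mW/cm^2 in water
#' @export
isppa <- function(p_rms_kpa, medium = water_medium()) {
  if (!inherits(medium, "medium")) {
    stop("invalid medium: supply a medium() object", call. = FALSE)
  }
  if (any(!is.finite(p_rms_kpa)) || any(p_rms_kpa < 0)) {
    stop("p_rms_kpa must be non-negative and finite", call. = FALSE)
  }
  p_pa <- p_rms_kpa * 1000
  w_m2 <- p_pa^2 / (medium$density_kg_m3 * medium$speed_m_s)
  w_m2 * W_M2_TO_MW_CM2
}

#' Spatial-peak temporal-average intensity
#'
#' Time-averaged acoustic dose of a pulsed protocol:
#' I_spta = I_sppa * DC = P_rms^2 / (rho c) * DC, in mW/cm^2. This is the
#' exposure metric that summarises pressure and duty cycle jointly.
#'
#' @param protocol A `stim_protocol` with `modality = "US"`.
#' @param medium A [medium()]; defaults to water.
#' @return Intensity in mW/cm^2.
#' @examples
#' ispta(stim_protocol("US", p_rms_kpa = 8, duty_cycle = 0.05)) # ~0.22
#' @export
ispta <- function(protocol, medium = water_medium()) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (protocol$modality != "US") {
    stop("ispta is defined for US protocols only", call. = FALSE)
  }
  isppa(protocol$p_rms_kpa, medium) * protocol$duty_cycle
}

#' Intensity bin boundaries (mW/cm^2)
#'
#' Upper bounds of the very-low/low/medium/high bins; intensities above the
#' last bound are "very_high". Bounds are inclusive on the upper side.
#' @export
intensity_bin_bounds <- c(very_low = 0.5, low = 2.5, medium = 5, high = 10)

#' Bin a temporal-average intensity
#'
#' Assigns I_spta values to the five exposure classes
#' (`very_low <= 0.5 < low <= 2.5 < medium <= 5 < high <= 10 < very_high`,
#' all in mW/cm^2), with inclusive upper bounds.
#'
#' @param ispta_mw_cm2 Intensity value(s) in mW/cm^2, non-negative.
#' @return An ordered factor with levels very_low < low < medium < high <
#'   very_high.
#' @examples
#' classify_intensity(c(0.216, 0.5, 3, 27))
#' @export
classify_intensity <- function(ispta_mw_cm2) {
  if (any(!is.finite(ispta_mw_cm2)) || any(ispta_mw_cm2 < 0)) {
    stop("ispta must be non-negative and finite", call. = FALSE)
  }
  cut(ispta_mw_cm2,
      breaks = c(-Inf, intensity_bin_bounds, Inf),
      labels = c("very_low", "low", "medium", "high", "very_high"),
      right = TRUE, ordered_result = TRUE)
}

#' Tone-burst on-intervals of a stimulation window
#'
#' Returns the on-state (tone burst) intervals of one stimulation window as
#' half-open `[start, end)` intervals in ms relative to window onset. Pulsed
#' protocols emit `stim_ms / prp_ms` bursts of length `duty_cycle * prp_ms`;
#' continuous stimulation is a single burst spanning the window.
#'
#' @param protocol A US `stim_protocol`.
#' @return A data.frame with columns `on_start_ms`, `on_end_ms`, one row per
#'   burst.
#' @examples
#' burst_timing(stim_protocol("US", p_rms_kpa = 8, duty_cycle = 0.05))
#' @export
burst_timing <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (protocol$modality != "US") {
    stop("burst_timing is defined for US protocols only", call. = FALSE)
  }
  if (protocol$duty_cycle >= 1) {
    return(data.frame(on_start_ms = 0, on_end_ms = protocol$stim_ms))
  }
  n <- as.integer(round(protocol$stim_ms / protocol$prp_ms))
  t_on <- protocol$duty_cycle * protocol$prp_ms
  starts <- (seq_len(n) - 1L) * protocol$prp_ms
  data.frame(on_start_ms = starts, on_end_ms = starts + t_on)
}

#' The standard 4-pressure x 3-duty-cycle protocol grid
#'
#' Builds the full factorial grid of ultrasound settings used throughout the
#' package: P_rms in {8, 12, 16, 20} kPa crossed with duty cycles
#' {5, 50, 100}%, 490 kHz carrier, 100 ms pulse repetition period, 300 ms
#' stimulation windows.
#'
#' @param p_rms_kpa Pressures, kPa.
#' @param duty_cycles Duty-cycle fractions in (0, 1].
#' @param ... Passed to [stim_protocol()] (e.g. `n_windows`, `isi_s`).
#' @return A list of `stim_protocol` objects, ordered pressure-major.
#' @export
protocol_grid <- function(p_rms_kpa = c(8, 12, 16, 20),
                          duty_cycles = c(0.05, 0.5, 1),
                          ...) {
  grid <- expand.grid(dc = duty_cycles, p = p_rms_kpa)
  lapply(seq_len(nrow(grid)), function(i) {
    stim_protocol("US", p_rms_kpa = grid$p[i], duty_cycle = grid$dc[i], ...)
  })
}

#' Dosimetry table for a set of protocols
#'
#' @param protocols List of US `stim_protocol` objects.
#' @param medium A [medium()].
#' @return data.frame with p_rms_kpa, duty_cycle, isppa, ispta (mW/cm^2) and
#'   intensity bin.
#' @export
dosimetry_table <- function(protocols = protocol_grid(), medium = water_medium()) {
  rows <- lapply(protocols, function(p) {
    data.frame(p_rms_kpa = p$p_rms_kpa,
               duty_cycle = p$duty_cycle,
               isppa_mw_cm2 = isppa(p$p_rms_kpa, medium),
               ispta_mw_cm2 = ispta(p, medium))
  })
  out <- do.call(rbind, rows)
  out$bin <- classify_intensity(out$ispta_mw_cm2)
  out
}
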