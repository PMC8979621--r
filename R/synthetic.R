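#' Synthetic cell parameters
#'
#' Parameters of one simulated mechanosensory neuron. The ultrasound response
#' model is a saturating leaky integrator: during the tone-burst on-state the
#' slow depolarization `u` grows as `du/dt = g * I_sppa * (1 - u/u_max)` and
#' during the off-state it decays with time constant `tau_slow`, so the effect
#' accumulates over bursts and outlasts the stimulation. A spike is emitted
#' whenever `u` plus the instantaneous recording noise exceeds the cell's
#' threshold outside the refractory period; the slow depolarization persists
#' across spikes (residual depolarization). Spike-frequency adaptation raises
#' the effective threshold by `adaptation_mv` after every spike of a
#' stimulation window (fatigue), keeping firing sparse as in recordings;
#' adaptation recovers fully between windows. Electrical pulses instead drive a fast step
#' depolarization (membrane time constant `el_tau_ms`) with a single
#' accommodated spike per pulse and a post-pulse undershoot.
#'
#' @param v_rest_mv Resting potential, mV.
#' @param noise_sigma_mv Gaussian recording-noise SD, mV.
#' @param threshold_mv Spiking threshold above rest, mV.
#' @param us_gain Ultrasound gain `g`, mV per (mW/cm^2 * s) of on-state
#'   I_sppa.
#' @param tau_slow_ms Decay time constant of the accumulated depolarization,
#'   ms.
#' @param u_max_mv Saturation ceiling of the accumulated depolarization, mV.
#' @param refractory_ms Minimum interval between spikes, ms.
#' @param adaptation_mv Per-spike increment of the effective threshold within
#'   a stimulation window, mV (0 disables adaptation).
#' @param cell_type `"N"` or `"P"`.
#' @param p_attenuation Gain attenuation applied to P cells (their high-pass
#'   filtering makes them nearly insensitive to the slow US depolarization).
#' @param el_gain_mv_na EL steady-state depolarization per nA, mV.
#' @param el_tau_ms Fast membrane time constant for EL steps, ms.
#' @param el_undershoot_mv Post-pulse undershoot depth, mV.
#' @param el_undershoot_tau_ms Undershoot recovery time constant, ms.
#' @param cell_id Identifier.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(v_rest_mv = -40,
                        noise_sigma_mv = 0.4,
                        threshold_mv = 9.5,
                        us_gain = 2.3,
                        tau_slow_ms = 300,
                        u_max_mv = 13,
                        refractory_ms = 100,
                        adaptation_mv = 3,
                        cell_type = c("N", "P"),
                        p_attenuation = 0.25,
                        el_gain_mv_na = 4,
                        el_tau_ms = 8,
                        el_undershoot_mv = 2,
                        el_undershoot_tau_ms = 50,
                        cell_id = "cell1") {
  cell_type <- match.arg(cell_type)
  stopifnot(tau_slow_ms > 0, u_max_mv > 0, noise_sigma_mv >= 0,
            p_attenuation >= 0, p_attenuation <= 1, refractory_ms > 0,
            adaptation_mv >= 0)
  if (!all(is.finite(c(v_rest_mv, threshold_mv, us_gain)))) {
    stop("non-finite cell parameters", call. = FALSE)
  }
  structure(as.list(environment()), class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(
    "<cell_params %s (%s)> v_rest %g mV, theta %g mV, g %g, tau_slow %g ms, sigma %g mV\n",
    x$cell_id, x$cell_type, x$v_rest_mv, x$threshold_mv, x$us_gain,
    x$tau_slow_ms, x$noise_sigma_mv))
  invisible(x)
}

#' Action-potential template parameters
#'
#' Nominal waveform distributions for spliced APs, per stimulation modality.
#' Amplitude (peak to trough) and early-repolarization half-width are drawn
#' log-normally with the requested distribution mean and SD (moment-matched,
#' not log-scale moments), so sample means of measured features are directly
#' comparable to the nominal means. The template rises linearly for
#' `rise_ms`, falls linearly from the peak to the afterhyperpolarization
#' trough over twice the drawn half-width (which places the half-prominence
#' crossing exactly one half-width after the peak), then relaxes back
#' exponentially.
#'
#' Defaults: US spikes 64 +/- 45 mV and 2.35 +/- 0.45 ms; EL spikes
#' 79 +/- 15 mV and 2.87 +/- 0.7 ms.
#'
#' @param modality `"US"` or `"EL"`.
#' @param amp_mean_mv,amp_sd_mv Amplitude distribution mean and SD, mV.
#' @param dur_mean_ms,dur_sd_ms Half-width distribution mean and SD, ms.
#' @param rise_ms Rise time, ms.
#' @param ahp_mv Afterhyperpolarization depth below the local membrane level,
#'   mV.
#' @param ahp_tau_ms AHP recovery time constant, ms.
#' @return An object of class `ap_template_params`.
#' @export
ap_template_params <- function(modality = c("US", "EL"),
                               amp_mean_mv = NULL, amp_sd_mv = NULL,
                               dur_mean_ms = NULL, dur_sd_ms = NULL,
                               rise_ms = 1, ahp_mv = 5, ahp_tau_ms = 15) {
  modality <- match.arg(modality)
  defaults <- if (modality == "US") c(64, 45, 2.35, 0.45) else c(79, 15, 2.87, 0.7)
  amp_mean_mv <- amp_mean_mv %||% defaults[1]
  amp_sd_mv <- amp_sd_mv %||% defaults[2]
  dur_mean_ms <- dur_mean_ms %||% defaults[3]
  dur_sd_ms <- dur_sd_ms %||% defaults[4]
  stopifnot(amp_mean_mv > 0, dur_mean_ms > 0, rise_ms > 0, ahp_tau_ms > 0,
            amp_sd_mv >= 0, dur_sd_ms >= 0)
  structure(list(modality = modality,
                 amp_mean_mv = amp_mean_mv, amp_sd_mv = amp_sd_mv,
                 dur_mean_ms = dur_mean_ms, dur_sd_ms = dur_sd_ms,
                 rise_ms = rise_ms, ahp_mv = ahp_mv, ahp_tau_ms = ahp_tau_ms),
            class = "ap_template_params")
}

# moment-matched log-normal draw: E = mean, SD = sd
rlnorm_moments <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Derive a per-trace seed from a global seed
#'
#' Counter-based expansion so that any trace of a seeded experiment can be
#' regenerated independently of the others.
#'
#' @param seed Global integer seed.
#' @param index Trace counter (>= 1).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647
  as.integer(((as.numeric(seed) %% m) * 48271 + as.numeric(index) * 16807) %% m + 1) %% m
}

# ---- internal: segment machinery -------------------------------------------

# Build the on/off segment table (sample index ranges) of a whole trace.
# type: "off" (decay), "on" (US accumulation), "el_on" (step), "el_off"
# (undershoot recovery).
build_segments <- function(protocol, onsets_ms, n, r) {
  segs <- list()
  pos <- 1L
  for (o in onsets_ms) {
    if (protocol$modality == "US") {
      bt <- burst_timing(protocol)
      for (k in seq_len(nrow(bt))) {
        s <- ms_to_index(o + bt$on_start_ms[k], r)
        e <- ms_to_index(o + bt$on_end_ms[k], r) - 1L
        if (s > pos) segs[[length(segs) + 1L]] <- list(start = pos, end = s - 1L, type = "off")
        segs[[length(segs) + 1L]] <- list(start = s, end = e, type = "on")
        pos <- e + 1L
      }
    } else {
      s <- ms_to_index(o, r)
      e <- ms_to_index(o + protocol$el_duration_s * 1000, r) - 1L
      if (s > pos) segs[[length(segs) + 1L]] <- list(start = pos, end = s - 1L, type = "off")
      segs[[length(segs) + 1L]] <- list(start = s, end = e, type = "el_on")
      segs[[length(segs) + 1L]] <- list(start = e + 1L, end = n, type = "el_off")
      pos <- n + 1L
      # el_off runs to trace end or is truncated by the next window below
    }
  }
  if (pos <= n) segs[[length(segs) + 1L]] <- list(start = pos, end = n, type = "off")
  # truncate overlapping el_off segments at the next segment start
  if (length(segs) > 1L) {
    for (i in seq_len(length(segs) - 1L)) {
      if (segs[[i]]$end >= segs[[i + 1L]]$start) {
        segs[[i]]$end <- segs[[i + 1L]]$start - 1L
      }
    }
  }
  segs[vapply(segs, function(s) s$end >= s$start, logical(1))]
}

ms_to_index <- function(t_ms, r) as.integer(round(t_ms * r)) + 1L

# Evaluate the slow depolarization u from sample `from` to the end, starting
# at value u0, given the segment table. Vectorized per segment.
compute_u <- function(segs, from, u0, n, r, cell, protocol) {
  u <- numeric(n - from + 1L)
  cur <- u0
  dt <- 1 / r  # ms per sample
  el_state <- list(u_end = 0)
  for (sg in segs) {
    if (sg$end < from) {
      # still need to track EL pulse end value for undershoot segments
      next
    }
    s <- max(sg$start, from)
    len <- sg$end - s + 1L
    k <- seq_len(len)
    # offset of the first evaluated sample from the segment start, in samples
    off0 <- s - sg$start
    if (sg$type == "off") {
      # `cur` is the value at the sample preceding `s`, so plain first-order
      # decay applies whether we enter at the segment start or resume mid-way
      vals <- cur * exp(-(k * dt) / cell$tau_slow_ms)
      cur <- vals[len]
    } else if (sg$type == "on") {
      isppa_val <- isppa(protocol$p_rms_kpa)
      g_eff <- cell$us_gain * if (cell$cell_type == "P") cell$p_attenuation else 1
      kk <- g_eff * isppa_val / (1000 * cell$u_max_mv)  # 1/ms
      vals <- cell$u_max_mv + (cur - cell$u_max_mv) * exp(-kk * k * dt)
      cur <- vals[len]
    } else if (sg$type == "el_on") {
      a_el <- cell$el_gain_mv_na * protocol$el_current_na
      vals <- a_el + (cur - a_el) * exp(-(k * dt) / cell$el_tau_ms)
      cur <- vals[len]
      el_state$u_end <- cur
    } else { # el_off: fast decay plus transient undershoot
      u_end <- el_state$u_end
      tt <- (off0 + k) * dt
      vals <- (u_end + cell$el_undershoot_mv) * exp(-tt / cell$el_tau_ms) -
        cell$el_undershoot_mv * exp(-tt / cell$el_undershoot_tau_ms)
      cur <- vals[len]
    }
    u[(s - from + 1L):(sg$end - from + 1L)] <- vals
  }
  u
}

# Spliced AP waveform evaluated at sample offsets; crossing index c is the
# threshold crossing, the peak sits rise_ms later. Values are relative to the
# local membrane level.
ap_waveform <- function(amp, width, tpl, r) {
  p <- max(amp - tpl$ahp_mv, 0.5)     # peak height above local level
  d <- p + tpl$ahp_mv                 # total drop over the fall = amplitude
  rise_s <- max(1L, as.integer(round(tpl$rise_ms * r)))
  fall_ms <- 2 * width
  rec_ms <- 6 * tpl$ahp_tau_ms
  total_s <- rise_s + as.integer(ceiling((fall_ms + rec_ms) * r))
  t <- (0:total_s) / r                # ms from waveform start
  t_peak <- rise_s / r
  w <- numeric(length(t))
  rising <- t <= t_peak
  w[rising] <- p * t[rising] / t_peak
  falling <- t > t_peak & t <= t_peak + fall_ms
  w[falling] <- p - d * (t[falling] - t_peak) / fall_ms
  after <- t > t_peak + fall_ms
  w[after] <- -tpl$ahp_mv * exp(-(t[after] - t_peak - fall_ms) / tpl$ahp_tau_ms)
  list(values = w, peak_offset = rise_s)
}

#' Simulate one stimulus-annotated membrane-voltage trace
#'
#' Generates an intracellular voltage trace for a cell under one stimulation
#' protocol, together with the ground truth needed to validate the analysis
#' pipeline: the noiseless slow-depolarization trajectory, the true spike
#' times and drawn waveform features, and the true per-cycle median
#' depolarizations.
#'
#' The trace is `V(t) = v_rest + u(t) + AP waveforms + Gaussian noise`; see
#' [cell_params()] for the dynamics of `u`. Identical `seed` yields a
#' bit-identical trace.
#'
#' @param protocol A `stim_protocol` (US or EL).
#' @param cell A [cell_params()] object.
#' @param seed Integer seed for this trace.
#' @param sampling_khz Sampling rate, kHz.
#' @param pre_ms Pre-stimulus margin before the first window, ms (>= 600 so
#'   that all baseline windows exist).
#' @param post_ms Margin after the last stimulation window, ms (>= 700 so the
#'   continuous-stimulation post window exists).
#' @param template Optional [ap_template_params()]; defaults to the modality's
#'   standard template.
#' @return A list with elements `trace` (a `membrane_trace`) and `truth`
#'   (class `synthetic_ground_truth`): `spike_times_ms`, `spike_window`,
#'   `spike_amp_mv`, `spike_width_ms`, `u` (noiseless trajectory), `dv_true`
#'   (list of per-cycle delta-V per window, US only), `responder`.
#' @export
simulate_membrane <- function(protocol, cell, seed = 1,
                              sampling_khz = 10,
                              pre_ms = 1000,
                              post_ms = 700,
                              template = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"), inherits(cell, "cell_params"))
  if (pre_ms < 600 || post_ms < 700) {
    stop("pre_ms must be >= 600 and post_ms >= 700 to cover all analysis windows",
         call. = FALSE)
  }
  tpl <- template %||% ap_template_params(protocol$modality)
  r <- sampling_khz
  sd_ms <- stim_window_ms(protocol)
  onsets <- pre_ms + (seq_len(protocol$n_windows) - 1) * protocol$isi_s * 1000
  total_ms <- onsets[length(onsets)] + sd_ms + post_ms
  n <- as.integer(round(total_ms * r))
  set.seed(seed)
  noise <- if (cell$noise_sigma_mv > 0) stats::rnorm(n, 0, cell$noise_sigma_mv) else numeric(n)

  segs <- build_segments(protocol, onsets, n, r)
  u <- compute_u(segs, 1L, 0, n, r, cell, protocol)

  refr_s <- as.integer(round(cell$refractory_ms * r))
  theta <- cell$threshold_mv
  onset_idx <- ms_to_index(onsets, r)
  spike_wave <- numeric(n)
  spk_t <- numeric(0); spk_amp <- numeric(0); spk_w <- numeric(0)
  # adaptation resets at every window onset: process the trace as the
  # intervals [1, onset_1), [onset_1, onset_2), ..., [onset_K, n]
  bounds <- unique(c(1L, onset_idx[onset_idx <= n], n + 1L))
  last_spike <- -refr_s
  for (b in seq_len(length(bounds) - 1L)) {
    iv_start <- bounds[b]
    iv_end <- bounds[b + 1L] - 1L
    adapt_count <- 0L
    pos <- max(iv_start, last_spike + refr_s)
    repeat {
      if (pos > iv_end) break
      theta_eff <- theta + cell$adaptation_mv * adapt_count
      rel <- which(u[pos:iv_end] + noise[pos:iv_end] >= theta_eff)
      if (!length(rel)) break
      cidx <- pos + rel[1] - 1L
      adapt_count <- adapt_count + 1L
      last_spike <- cidx
      amp <- rlnorm_moments(1, tpl$amp_mean_mv, tpl$amp_sd_mv)
      wid <- rlnorm_moments(1, tpl$dur_mean_ms, tpl$dur_sd_ms)
      wf <- ap_waveform(amp, wid, tpl, r)
      i0 <- cidx
      i1 <- min(n, cidx + length(wf$values) - 1L)
      spike_wave[i0:i1] <- spike_wave[i0:i1] + wf$values[seq_len(i1 - i0 + 1L)]
      peak_idx <- cidx + wf$peak_offset
      spk_t <- c(spk_t, (peak_idx - 1L) / r)
      spk_amp <- c(spk_amp, amp)
      spk_w <- c(spk_w, wid)
      if (protocol$modality == "US") {
        pos <- cidx + refr_s
      } else {
        # accommodation: one spike per electrical pulse, lasting until the
        # membrane has recovered (next pulse onset)
        pos <- iv_end + 1L
      }
    }
  }

  voltage <- cell$v_rest_mv + u + spike_wave + noise
  trace <- membrane_trace(voltage, sampling_khz = r, t_start_ms = 0,
                          cell_id = cell$cell_id, cell_type = cell$cell_type,
                          stim_onsets_ms = onsets, protocol = protocol)

  # assign spikes to stimulation windows via their detection windows
  win_of <- rep(NA_integer_, length(spk_t))
  for (k in seq_along(onsets)) {
    det_end <- onsets[k] + sd_ms + 100
    win_of[spk_t >= onsets[k] & spk_t < det_end] <- k
  }

  dv_true <- NULL
  if (protocol$modality == "US") {
    u_trace <- membrane_trace(u, sampling_khz = r, t_start_ms = 0,
                              cell_id = "truth", cell_type = cell$cell_type)
    dv_true <- lapply(onsets, function(o) {
      sch <- build_schedule(protocol, o)
      delta_v(u_trace, sch)
    })
  }

  truth <- structure(list(spike_times_ms = spk_t,
                          spike_window = win_of,
                          spike_amp_mv = spk_amp,
                          spike_width_ms = spk_w,
                          u = u,
                          dv_true = dv_true,
                          responder = length(spk_t) > 0),
                     class = "synthetic_ground_truth")
  list(trace = trace, truth = truth)
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat(sprintf("<synthetic_ground_truth> %d true spike(s), responder = %s\n",
              length(x$spike_times_ms), x$responder))
  invisible(x)
}

#' Draw a population of synthetic cells
#'
#' Per-cell thresholds are drawn from a truncated normal and ultrasound gains
#' from a moment-matched log-normal, reproducing the large inter-cell
#' variability of recorded neurons: whether a cell responds emerges from its
#' threshold versus the depolarization attainable at the strongest protocol.
#' P cells additionally attenuate their gain (`p_attenuation`) and halve
#' `tau_slow`, reflecting their high-pass membrane filtering.
#'
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed.
#' @param cell_type `"N"` or `"P"`.
#' @param threshold_mean_mv,threshold_sd_mv Threshold distribution, mV above
#'   rest (truncated below at 3 mV).
#' @param gain_mean,gain_sd Ultrasound gain distribution, mV per
#'   (mW/cm^2 * s).
#' @param ... Further arguments passed to [cell_params()] for every cell.
#' @return List of `cell_params`.
#' @export
generate_cell_population <- function(n_cells, seed = 1,
                                     cell_type = c("N", "P"),
                                     threshold_mean_mv = 9.5,
                                     threshold_sd_mv = 2.5,
                                     gain_mean = 3,
                                     gain_sd = 2.5,
                                     ...) {
  cell_type <- match.arg(cell_type)
  stopifnot(n_cells >= 1)
  set.seed(seed)
  theta <- pmax(3, stats::rnorm(n_cells, threshold_mean_mv, threshold_sd_mv))
  g <- rlnorm_moments(n_cells, gain_mean, gain_sd)
  lapply(seq_len(n_cells), function(i) {
    cell_params(threshold_mv = theta[i],
                us_gain = g[i],
                cell_type = cell_type,
                tau_slow_ms = if (cell_type == "P") 150 else 300,
                cell_id = sprintf("%s%02d", tolower(cell_type), i),
                ...)
  })
}

#' Generate a full synthetic experiment
#'
#' One trace per cell x protocol, each with the protocol's stimulation
#' windows, plus (optionally) one EL control trace per cell. Per-trace seeds
#' are derived from the global seed with [derive_seed()], so any trace can be
#' regenerated independently. When `out_dir` is given every trace is written
#' as a CSV/JSON pair and a manifest CSV is produced.
#'
#' @param protocols List of `stim_protocol` objects (e.g. [protocol_grid()]).
#' @param population List of `cell_params` (e.g.
#'   [generate_cell_population()]).
#' @param seed Global integer seed.
#' @param el_control Optional EL `stim_protocol` to record per cell as a
#'   control.
#' @param sampling_khz,pre_ms,post_ms Passed to [simulate_membrane()].
#' @param out_dir Optional output directory for CSV/JSON trace files and
#'   `manifest.csv`.
#' @return List with `traces` (list of `membrane_trace`), `truths` (matching
#'   `synthetic_ground_truth` list) and `manifest` (data.frame: trace index,
#'   cell, modality, protocol fields, per-trace seed, file path when
#'   written).
#' @export
generate_experiment <- function(protocols, population, seed = 1,
                                el_control = NULL,
                                sampling_khz = 10,
                                pre_ms = 1000, post_ms = 700,
                                out_dir = NULL) {
  if (!length(protocols)) stop("empty protocol grid", call. = FALSE)
  if (!length(population)) stop("empty cell population", call. = FALSE)
  jobs <- list()
  for (cell in population) {
    for (p in protocols) jobs[[length(jobs) + 1L]] <- list(cell = cell, protocol = p)
    if (!is.null(el_control)) {
      jobs[[length(jobs) + 1L]] <- list(cell = cell, protocol = el_control)
    }
  }
  traces <- vector("list", length(jobs))
  truths <- vector("list", length(jobs))
  rows <- vector("list", length(jobs))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (i in seq_along(jobs)) {
    jb <- jobs[[i]]
    s_i <- derive_seed(seed, i)
    sim <- simulate_membrane(jb$protocol, jb$cell, seed = s_i,
                             sampling_khz = sampling_khz,
                             pre_ms = pre_ms, post_ms = post_ms)
    traces[[i]] <- sim$trace
    truths[[i]] <- sim$truth
    path <- NA_character_
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, sprintf("trace_%03d.csv", i))
      write_trace(sim$trace, path)
    }
    rows[[i]] <- data.frame(
      trace = i,
      cell_id = jb$cell$cell_id,
      cell_type = jb$cell$cell_type,
      modality = jb$protocol$modality,
      p_rms_kpa = jb$protocol$p_rms_kpa %||% NA_real_,
      duty_cycle = jb$protocol$duty_cycle %||% NA_real_,
      n_windows = jb$protocol$n_windows,
      seed = s_i,
      path = path)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(traces = traces, truths = truths, manifest = manifest)
}
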