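# Spike detection and AP morphometry.

test_that("noise alone never crosses the 15 mV detection threshold", {
  tr <- flat_trace(6000, level = -40, sigma = 0.5, seed = 3)
  sp <- detect_spikes(tr, detection = c(100, 500), baseline = c(0, 100))
  expect_equal(nrow(sp), 0)
})

test_that("threshold-crossing peaks are detected and ordered first/following", {
  v <- rep(-40, 6000)
  v <- add_linear_ap(v, 10, at_ms = 200, rise_mv = 30, fall_to_mv = -5)
  tr <- membrane_trace(v, sampling_khz = 10)
  sp <- detect_spikes(tr, c(100, 500), c(0, 100))
  expect_equal(nrow(sp), 1)
  expect_equal(sp$order, "first")
  expect_equal(sp$peak_time_ms, 201)  # rise takes 1 ms
  expect_equal(sp$latency_ms, 101)

  v2 <- add_linear_ap(v, 10, at_ms = 250, rise_mv = 40, fall_to_mv = -8)
  tr2 <- membrane_trace(v2, sampling_khz = 10)
  sp2 <- detect_spikes(tr2, c(100, 500), c(0, 100))
  expect_equal(sp2$order, c("first", "following"))
  expect_equal(sp2$peak_time_ms, c(201, 251))
})

test_that("amplitude is peak minus subsequent minimum", {
  # explicit: peak +20 absolute, subsequent minimum -50 absolute
  v <- rep(-40, 4000)
  v <- add_linear_ap(v, 10, at_ms = 100, rise_mv = 60, fall_to_mv = -10)
  tr <- membrane_trace(v, sampling_khz = 10)
  a <- ap_amplitude(tr, peak_time_ms = 101, bound_ms = 200)
  expect_equal(a$amplitude_mv, 70)
  # monotone decay to a plateau: amplitude measured at plateau start
  v2 <- rep(-40, 2000)
  i <- 501:530
  v2[i] <- seq(10, -40, length.out = 30)
  tr2 <- membrane_trace(v2, sampling_khz = 10)
  a2 <- ap_amplitude(tr2, peak_time_ms = 50, bound_ms = 150)
  expect_equal(a2$amplitude_mv, 50)
  expect_equal(a2$trough_time_ms, 52.9)
  # symmetric biphasic: peak +10, AHP at -55
  v3 <- rep(-40, 2000)
  v3 <- add_linear_ap(v3, 10, at_ms = 50, rise_mv = 50, fall_to_mv = -15)
  tr3 <- membrane_trace(v3, sampling_khz = 10)
  expect_equal(ap_amplitude(tr3, 51, 150)$amplitude_mv, 65)
  expect_error(ap_amplitude(tr, peak_time_ms = 399.9), "after the peak")
})

test_that("early-repolarization duration interpolates the half-prominence crossing", {
  # triangular AP: rise 0 -> 40 over 1 ms, fall 40 -> -10 over 5 ms
  # amplitude 50, half level 15, crossing 2.5 ms after the peak
  v <- rep(0, 4000)
  v <- add_linear_ap(v, 10, at_ms = 100, rise_mv = 40, fall_to_mv = -10,
                     rise_ms = 1, fall_ms = 5)
  tr <- membrane_trace(v, sampling_khz = 10)
  expect_equal(ap_duration(tr, 101, 200), 2.5, tolerance = 1e-9)
  # one-sample drop: duration below one sample period
  v2 <- rep(0, 1000)
  v2[500] <- 30
  tr2 <- membrane_trace(v2, sampling_khz = 10)
  expect_lte(ap_duration(tr2, 49.9, 80), 0.1)
  # declining phase that never reaches half prominence is flagged
  v3 <- rep(0, 1000)
  v3[300:1000] <- 20  # step up, never down
  tr3 <- membrane_trace(v3, sampling_khz = 10)
  expect_warning(d <- ap_duration(tr3, 29.9, 99.9), "degenerate")
  expect_true(is.na(d))
})

test_that("amplitude-duration ratio and latency are simple quotients/differences", {
  expect_equal(ap_ratio(70, 2.5), 28)
  expect_equal(ap_ratio(50, 2), 25)
  expect_error(ap_ratio(50, 0), "positive")
  expect_equal(spike_latency(1105, 1000), 105)
  expect_error(spike_latency(990, 1000), "negative latency")
})

test_that("morphometry is invariant to offset and time shift", {
  v <- rep(-40, 4000)
  v <- add_linear_ap(v, 10, at_ms = 150, rise_mv = 45, fall_to_mv = -9)
  tr <- membrane_trace(v, sampling_khz = 10)
  sp <- detect_spikes(tr, c(100, 390), c(0, 100))
  # offset the whole trace
  tr_off <- membrane_trace(v + 37, sampling_khz = 10)
  sp_off <- detect_spikes(tr_off, c(100, 390), c(0, 100))
  expect_equal(sp_off$amplitude_mv, sp$amplitude_mv)
  expect_equal(sp_off$duration_ms, sp$duration_ms)
  expect_equal(sp_off$peak_time_ms, sp$peak_time_ms)
  # shift the time axis
  tr_sh <- membrane_trace(v, sampling_khz = 10, t_start_ms = 2000)
  sp_sh <- detect_spikes(tr_sh, c(2100, 2390), c(2000, 2100))
  expect_equal(sp_sh$amplitude_mv, sp$amplitude_mv)
  expect_equal(sp_sh$duration_ms, sp$duration_ms)
  expect_equal(sp_sh$peak_time_ms - 2000, sp$peak_time_ms)
})

test_that("detection matches generator ground truth exactly at fixed amplitude", {
  # deterministic template (64 mV, 2.35 ms) over sigma = 0.5 noise:
  # every in-window true spike detected within 1 ms, no false alarms
  tpl <- ap_template_params("US", amp_sd_mv = 0, dur_sd_ms = 0)
  p <- us_protocol(20, 1)
  hits <- 0; total <- 0; fa <- 0
  for (s in 1:4) {
    cell <- cell_params(us_gain = 20, threshold_mv = 9, noise_sigma_mv = 0.5,
                        adaptation_mv = 0, refractory_ms = 30,
                        cell_id = sprintf("o%d", s))
    sim <- simulate_membrane(p, cell, seed = 100 + s, template = tpl)
    tab <- analyze_experiment(list(sim$trace))
    det <- tab$spikes
    all_truth <- sim$truth$spike_times_ms
    for (k in seq_along(sim$trace$stim_onsets_ms)) {
      onset <- sim$trace$stim_onsets_ms[k]
      # peaks in the last ms of the detection window have no right neighbour
      # to establish a local maximum; exclude that sliver from the hit count
      truth_k <- all_truth[sim$truth$spike_window == k & !is.na(sim$truth$spike_window)]
      truth_k <- truth_k[truth_k < onset + 399]
      det_k <- det$peak_time_ms[det$window_id == sprintf("t001_w%d", k)]
      total <- total + length(truth_k)
      hits <- hits + sum(vapply(truth_k, function(t0) any(abs(det_k - t0) <= 1),
                                logical(1)))
      fa <- fa + sum(vapply(det_k, function(t0) all(abs(all_truth - t0) > 1),
                            logical(1)))
    }
  }
  expect_gt(total, 20)
  expect_equal(hits, total)   # hit rate 1
  expect_equal(fa, 0)         # no false alarms
})

test_that("success rate counts windows with at least one supra-threshold spike", {
  sp <- data.frame(window_id = c("w1", "w1", "w3"),
                   subthreshold = c(FALSE, FALSE, FALSE))
  s <- success_rate(sp, c("w1", "w2", "w3"))
  expect_equal(s$n_with_spike, 2)
  expect_equal(s$success_rate, 2 / 3)
  expect_equal(success_rate(sp[0, ], c("w1", "w2"))$success_rate, 0)
  # subthreshold events never count
  sp2 <- data.frame(window_id = "w2", subthreshold = TRUE)
  expect_equal(success_rate(sp2, c("w1", "w2"))$success_rate, 0)
  expect_error(success_rate(sp, character(0)), ">= 1 stimulation")
})

test_that("optional low-threshold pass flags subthreshold events separately", {
  v <- rep(-40, 6000)
  v <- add_linear_ap(v, 10, at_ms = 150, rise_mv = 8, fall_to_mv = -2)   # small bump
  v <- add_linear_ap(v, 10, at_ms = 300, rise_mv = 40, fall_to_mv = -8)  # real AP
  tr <- membrane_trace(v, sampling_khz = 10)
  sp <- detect_spikes(tr, c(100, 500), c(0, 100), subthreshold_mv = 5)
  expect_equal(nrow(sp), 2)
  expect_equal(sp$subthreshold, c(TRUE, FALSE))
  expect_equal(sp$order, c(NA_character_, "first"))
  expect_equal(success_rate(sp, "w1")$n_with_spike, 1)
})
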