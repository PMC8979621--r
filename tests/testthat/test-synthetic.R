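# Synthetic trace generator: determinism, closed-form agreement, population
# structure, modality-specific behaviour.

test_that("identical seeds give bit-identical traces", {
  p <- us_protocol(16, 0.5)
  cell <- cell_params(us_gain = 10, threshold_mv = 8)
  s1 <- simulate_membrane(p, cell, seed = 123)
  s2 <- simulate_membrane(p, cell, seed = 123)
  expect_identical(s1$trace$voltage_mv, s2$trace$voltage_mv)
  expect_identical(s1$truth$spike_times_ms, s2$truth$spike_times_ms)
  s3 <- simulate_membrane(p, cell, seed = 124)
  expect_false(identical(s1$trace$voltage_mv, s3$trace$voltage_mv))
})

test_that("zero gain produces pure noise around rest with no responses", {
  p <- us_protocol(20, 1)
  cell <- cell_params(us_gain = 0, noise_sigma_mv = 0.4)
  sim <- simulate_membrane(p, cell, seed = 6)
  expect_length(sim$truth$spike_times_ms, 0)
  expect_equal(mean(sim$trace$voltage_mv), cell$v_rest_mv, tolerance = 0.05)
  dv <- delta_v(sim$trace, build_schedule(p, sim$trace$stim_onsets_ms[1]))
  expect_lt(abs(mean(dv)), 0.2)
})

test_that("noise-free continuous stimulation follows the saturating ODE solution", {
  p <- us_protocol(20, 1)
  cell <- cell_params(us_gain = 3, noise_sigma_mv = 0, threshold_mv = 1e6)
  sim <- simulate_membrane(p, cell, seed = 1)
  r <- sim$trace$sampling_khz
  onset <- sim$trace$stim_onsets_ms[1]
  i_sppa <- isppa(20)
  k <- cell$us_gain * i_sppa / (1000 * cell$u_max_mv)  # 1/ms
  u_closed <- function(t_ms) cell$u_max_mv * (1 - exp(-k * t_ms))
  # trajectory agreement: the i-th response sample has accrued i on-state
  # intervals of 1/r ms
  for (t_in in c(10, 100, 299)) {
    i <- round((onset + t_in) * r) + 1
    expect_equal(sim$truth$u[i], u_closed(t_in + 1 / r), tolerance = 1e-9)
  }
  # pipeline delta-V equals the closed-form median of the monotone trajectory
  dv <- delta_v(sim$trace, build_schedule(p, onset))
  samples <- u_closed(seq_len(300 * r) / r)
  expect_equal(dv, median(samples), tolerance = 1e-9)
  # off-state decay
  i_end <- round((onset + 300) * r)
  i_later <- round((onset + 300 + 150) * r)
  expect_equal(sim$truth$u[i_later] / sim$truth$u[i_end],
               exp(-150 / cell$tau_slow_ms), tolerance = 1e-6)
})

test_that("log-normal feature draws match the requested moments", {
  set.seed(99)
  x <- sonophys:::rlnorm_moments(2e5, 64, 45)
  expect_equal(mean(x), 64, tolerance = 0.02)
  expect_equal(sd(x), 45, tolerance = 0.03)
  expect_true(all(x > 0))
  expect_identical(sonophys:::rlnorm_moments(3, 5, 0), rep(5, 3))
})

test_that("experiment generation counts traces and windows correctly", {
  prot <- protocol_grid(isi_s = 2)
  pop <- generate_cell_population(5, seed = 2)
  ex <- generate_experiment(prot, pop, seed = 3)
  expect_length(ex$traces, 60)             # 12 protocols x 5 cells
  expect_equal(nrow(ex$manifest), 60)
  expect_equal(sum(ex$manifest$n_windows), 180)
  # regeneration with the same seed is identical
  ex2 <- generate_experiment(prot, pop, seed = 3)
  expect_identical(ex$traces[[17]]$voltage_mv, ex2$traces[[17]]$voltage_mv)
  # any single trace can be rebuilt from its manifest seed
  row <- ex$manifest[41, ]
  cell <- pop[[which(vapply(pop, function(c) c$cell_id, "") == row$cell_id)]]
  proto <- prot[[(41 - 1) %% 12 + 1]]
  re <- simulate_membrane(proto, cell, seed = row$seed)
  expect_identical(re$trace$voltage_mv, ex$traces[[41]]$voltage_mv)
})

test_that("population heterogeneity yields a partial responder fraction", {
  prot <- protocol_grid(isi_s = 2)
  pop <- generate_cell_population(44, seed = 11)
  ex <- generate_experiment(prot, pop, seed = 11)
  by_cell <- split(vapply(ex$truths, function(t) t$responder, logical(1)),
                   ex$manifest$cell_id)
  frac <- mean(vapply(by_cell, any, logical(1)))
  expect_between(frac, 0.4, 0.8)
  # single-cell population
  expect_length(generate_cell_population(1, seed = 1), 1)
})

test_that("pressure cells respond weakly and rarely spike", {
  prot <- protocol_grid(isi_s = 2)
  pop_p <- generate_cell_population(10, seed = 21, cell_type = "P")
  ex <- generate_experiment(prot, pop_p, seed = 21)
  n_spikes <- sum(vapply(ex$truths, function(t) length(t$spike_times_ms), 0L))
  n_windows <- sum(ex$manifest$n_windows)
  expect_lt(n_spikes / n_windows, 0.05)
  # membrane response still scales with dose, with a small slope
  tab <- analyze_experiment(ex$traces)
  agg <- aggregate(cbind(mean_dv_mv, ispta_mw_cm2) ~ p_rms_kpa + duty_cycle,
                   data = tab$windows, FUN = mean)
  reg <- linear_regression(agg$ispta_mw_cm2, agg$mean_dv_mv)
  expect_gt(reg$slope, 0)
})

test_that("electrical pulses give one onset-locked spike and an undershoot", {
  el <- stim_protocol("EL", el_current_na = 3, el_duration_s = 0.5,
                      n_windows = 3, isi_s = 2)
  cell <- cell_params(threshold_mv = 8)
  sim <- simulate_membrane(el, cell, seed = 14)
  tr <- sim$trace
  expect_length(sim$truth$spike_times_ms, 3)  # exactly one per pulse
  lat <- sim$truth$spike_times_ms - tr$stim_onsets_ms
  expect_true(all(lat > 0 & lat < 20))
  # post-stimulus membrane sits below the pre-stimulus level
  for (onset in tr$stim_onsets_ms) {
    pre <- median(extract_epoch(tr, onset - 100, onset))
    post <- median(extract_epoch(tr, onset + 510, onset + 610))
    expect_lt(post, pre)
  }
})

test_that("depolarization outlasts the stimulation and boosts post-stimulus firing", {
  p <- us_protocol(20, 1)
  # excitable cells (the responder pool): firing, once started, continues
  # past the stimulus because u decays with tau_slow = 300 ms
  pop <- generate_cell_population(25, seed = 31, gain_mean = 25, gain_sd = 20,
                                  threshold_mean_mv = 3.5, threshold_sd_mv = 1)
  ex <- generate_experiment(list(p), pop, seed = 31)
  pre <- 0; post <- 0
  for (i in seq_along(ex$truths)) {
    t <- ex$truths[[i]]; tr <- ex$traces[[i]]
    for (onset in tr$stim_onsets_ms) {
      pre <- pre + sum(t$spike_times_ms >= onset - 100 & t$spike_times_ms < onset)
      post <- post + sum(t$spike_times_ms >= onset + 300 &
                           t$spike_times_ms < onset + 400)
    }
  }
  expect_gt(post, pre)
  expect_gt(post, 0)
})
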