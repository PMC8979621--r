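# Shared fixtures, all built in code.

# A flat trace at `level` mV with optional Gaussian noise.
flat_trace <- function(n = 10000, level = -40, sigma = 0, rate = 10, seed = 1,
                       ...) {
  set.seed(seed)
  v <- rep(level, n) + if (sigma > 0) rnorm(n, 0, sigma) else 0
  membrane_trace(v, sampling_khz = rate, ...)
}

# Splice a piecewise-linear AP into a voltage vector: linear rise over
# `rise_ms` to `peak` above the local value, linear fall over `fall_ms` to
# `trough` relative to local, then flat recovery back after `rec_ms`.
add_linear_ap <- function(v, rate, at_ms, rise_mv, fall_to_mv,
                          rise_ms = 1, fall_ms = 5, rec_ms = 20) {
  i0 <- round(at_ms * rate) + 1
  n_rise <- round(rise_ms * rate)
  n_fall <- round(fall_ms * rate)
  n_rec <- round(rec_ms * rate)
  shape <- c(seq(0, rise_mv, length.out = n_rise + 1),
             seq(rise_mv, fall_to_mv, length.out = n_fall + 1)[-1],
             seq(fall_to_mv, 0, length.out = n_rec + 1)[-1])
  idx <- i0:(i0 + length(shape) - 1)
  v[idx] <- v[idx] + shape
  v
}

# Standard US test protocols
us_protocol <- function(p = 20, dc = 1, isi_s = 2, ...) {
  stim_protocol("US", p_rms_kpa = p, duty_cycle = dc, isi_s = isi_s, ...)
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
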