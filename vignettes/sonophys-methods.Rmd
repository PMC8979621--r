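---
title: "Methods: dosimetry, windowed statistics, spike morphometry, and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetry, windowed statistics, spike morphometry, and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonophys)
```

`sonophys` analyses intracellular membrane-voltage recordings made during
low-intensity pulsed ultrasound (US) and intracellular electrical (EL)
stimulation, and ships a ground-truth generator so that every estimator can
be validated end to end. This vignette documents the models, the defaults
and why they were chosen, the numerical conventions, and what passing the
test suite does and does not demonstrate.

## Acoustic dosimetry

Acoustic pressure is converted to intensity under the plane-wave
approximation,

$$I_{sppa} = \frac{P_{rms}^2}{\rho c}, \qquad I_{spta} = I_{sppa} \cdot DC,$$

where $P_{rms}$ is the RMS pressure at the target, $DC$ the duty cycle, and
$\rho c$ the acoustic impedance of the coupling medium. Stimulation is
delivered through a water bath, so the defaults are water at 20 °C
($\rho = 1000$ kg/m³, $c = 1482$ m/s); both are configurable via
`medium()`. Pressures are entered in kPa and intensities reported in
mW/cm², the units in which such protocols are usually printed; with these
constants the experimental grid (8–20 kPa × 5–100 % DC) spans
0.2–27 mW/cm² after rounding to the printed precision. The exact
temperature (hence $c$) used when such ranges are reported is rarely
stated; the chosen constants reproduce the printed endpoints, and a ±1 %
change in $\rho c$ moves no grid protocol across a bin boundary.

Intensity bins follow the five-class chain `very_low ≤ 0.5 < low ≤ 2.5 <
medium ≤ 5 < high ≤ 10 < very_high` (mW/cm²), with upper bounds inclusive
as the chain is written.

## Epochs, ΔV, and baseline variation

All intervals are half-open `[start, end)` in milliseconds; sample $i$
(1-based) of a trace covers time $t_0 + (i-1)/f_s$. This makes epoch
concatenation exact (`[0,50) + [50,100) = [0,100)`) and window lengths
unambiguous.

For pulsed duty cycles, the response epoch of each cycle is the tone burst
itself and the baseline is the equally long slice of off-state immediately
preceding the burst; for continuous stimulation both are 300 ms, the
baseline preceding onset. The per-cycle statistic is

$$\Delta V_i = \mathrm{median}(\text{response}_i) -
\mathrm{median}(\text{baseline}_i),$$

positive for depolarization, summarised by its mean over cycles. Medians
rather than means are used throughout because spikes riding on the
depolarization would otherwise dominate the response windows. Placing the
pulsed baselines immediately before each burst is a deliberate reading of
the window geometry (the alternative — replicating a single pre-stimulus
baseline across cycles — would conflate within-burst increments with
accumulated depolarization); with pre-burst baselines, ΔV measures the
per-cycle increment, and the accumulation that outlasts bursts is captured
separately by the baseline variation

$$B_i = \mathrm{median}(W_{i+1}) - \mathrm{median}(W_i)$$

over the full off-state windows (95 ms at 5 % DC, 50 ms at 50 %). For
continuous stimulation, which has no off-state, the pre window is the
300 ms before onset and the post window the 300 ms after stimulus end, so
that $B$ captures the outlasting depolarization there too.

`ΔV` is invariant under adding any constant to the trace, which the test
suite asserts as a property.

## Spike detection and AP morphometry

Spikes are local maxima exceeding the median of the window's pre-stimulus
baseline plus 15 mV, inside a detection window of stimulation duration
plus 100 ms (400 ms for the standard 300 ms windows). The threshold is
referenced per stimulation, not globally, to be robust against slow drift.
Peaks closer than 10 ms are thinned keeping the taller peak; the default
separation is about four times the typical early-repolarization duration
of these cells (2–3 ms), preventing double counts without merging genuine
doublets, and is configurable. For EL windows the detection window is the
pulse itself: EL spikes are onset-locked, and ending the window at the
pulse edge keeps the step-off transition and the post-pulse undershoot out
of the analysis window (otherwise the undershoot can masquerade as the
"subsequent minimum" of a spike).

Each analysis window is detrended (first-order polynomial) before peak
measurements. Morphometry per spike:

* **amplitude** — peak value minus the subsequent minimum, the minimum
  searched up to the next spike peak or the window end, whichever comes
  first;
* **duration** — time from the peak to the first crossing of
  `peak − amplitude/2` on the declining phase ("early repolarization" at
  half prominence), linearly interpolated between samples; a declining
  phase that never reaches the half level is flagged degenerate (`NA`)
  rather than extrapolated;
* **ratio** — amplitude/duration, proportional to the decay slope and
  comparable across modalities;
* **latency** — stimulus-window onset to peak.

The first supra-threshold event per window is tagged `first`, later ones
`following`. An optional second pass with a configurable lower threshold
flags `subthreshold` events; they are reported but never counted in
success rates (the criterion for "subthreshold spikes" is not standardised,
so the feature is opt-in). Success rate is the fraction of stimulation
windows with at least one supra-threshold spike in their detection window.

## Statistics

The statistics layer intentionally wraps the standard machinery rather
than reimplementing it: `stats::lm` for OLS (R² and the slope F-test),
`stats::kruskal.test` for the tie-corrected Kruskal–Wallis statistic, and
`car::Anova(type = 2)` for the two-way factorial ANOVA. Type II sums of
squares are the default because trace counts differ across `DC × P_rms`
cells in realistic designs and Type II keeps main effects interpretable
under such imbalance. No multiple-testing correction is applied anywhere;
pairwise post-hoc Kruskal–Wallis comparisons report raw p-values. The test
suite validates the wrappers against hand-computed rank statistics,
closed-form OLS coefficients, explicit residual-sum-of-squares model
comparisons, and an exact permutation null at small n.

## The synthetic generator

The generator emulates the response structure that motivates the analysis:

* **Slow depolarization.** A saturating integrator,
  $du/dt = g\,I_{sppa}\,(1-u/u_{max})$ during tone bursts and
  $du/dt = -u/\tau_{slow}$ otherwise. The solution is piecewise
  exponential and is evaluated in closed form segment by segment; the
  discretization assigns each sample the accumulated on-time up to its
  timestamp, so total dose is conserved exactly (the test suite compares
  the trajectory and the pipeline ΔV against the closed form at
  $\sigma = 0$).
* **Spiking.** A spike is emitted when $u$ plus the instantaneous
  recording noise exceeds the cell's threshold, outside a refractory
  period (default 100 ms). The slow depolarization persists across spikes.
  Spike-frequency adaptation raises the effective threshold by
  `adaptation_mv` (default 3 mV) per spike within a stimulation window and
  recovers between windows. Without adaptation the model fires
  refractory-paced trains throughout every supra-threshold window —
  roughly an order of magnitude denser than real recordings of this
  preparation — which both contaminates the subthreshold medians and
  erases the duty-cycle dependence of the latency distribution; with it,
  firing settles at one to two spikes per responding window.
* **AP waveforms.** Spliced templates: linear rise (1 ms), linear fall
  from the peak to an afterhyperpolarization trough 5 mV below the local
  membrane level, then exponential relaxation (τ = 15 ms). Amplitude
  (peak-to-trough) and half-width are drawn per spike from log-normal
  distributions moment-matched to the nominal mean ± SD — 64 ± 45 mV and
  2.35 ± 0.45 ms for US, 79 ± 15 mV and 2.87 ± 0.7 ms for EL — so sample
  means of measured features are directly comparable to the nominal means
  (a truncated normal would bias the mean; the log-normal preserves it
  with positive support). The fall spans twice the drawn half-width, which
  places the half-prominence crossing exactly one half-width after the
  peak by construction.
* **EL windows.** A fast step (membrane time constant 8 ms, 4 mV/nA)
  with a single accommodated spike per pulse when the step crosses
  threshold, and a post-pulse undershoot (default 2 mV, recovering with
  τ = 50 ms) so that the post-stimulus membrane sits below the
  pre-stimulus level — the qualitative signature distinguishing EL from US
  stimulation, where the depolarization outlasts the stimulus instead.
* **Populations.** Per-cell thresholds are truncated-normal
  (9.5 ± 2.5 mV above rest, floor 3 mV) and gains log-normal
  (mean 3, SD 2.5 mV per mW/cm²·s); whether a cell responds emerges from
  its threshold versus the depolarization attainable at the strongest
  protocol. P (pressure) cells attenuate the gain to 25 % and halve
  $\tau_{slow}$, reflecting their high-pass membrane filtering, which makes
  US-evoked spiking rare in them.

### Default calibration

The defaults are calibrated once to the reported behaviour of the
preparation and then frozen. $u_{max} = 13$ mV keeps the sustained
depolarization more than five noise standard deviations below the 15 mV
detection criterion (a plateau near the criterion would turn noise maxima
into spurious detections) while minimizing saturation; saturation is what
degrades dose-response linearity, because pulsed ΔV measures per-burst
increments while continuous ΔV measures total accumulation from a
pre-stimulus baseline. $\tau_{slow} = 300$ ms makes the depolarization
outlast bursts and sustains post-stimulus firing. The threshold and gain
distributions put the responder fraction near 0.6 at the strongest
protocol and the grid-wide ΔV in the few-mV range. Recording noise is
0.4 mV RMS, typical of sharp-electrode recordings. The default sampling
rate is 10 kHz: AP features live on the millisecond scale, so ≥ 5 kHz is
required for the half-prominence interpolation to be stable.

Stimulation windows are separated by 2 s in generated experiments. Real
protocols pause 20–30 s between windows so the cell recovers; the
synthetic membrane recovers within $5\tau_{slow} \approx 1.5$ s (residual
< 0.2 %), so the shorter gap is statistically equivalent and keeps traces
small. The protocol metadata default (`isi_s = 20`) still records the
experimental convention.

### What the generator does not emulate

Electrode drift and access-resistance artifacts, line noise, biophysical
channel kinetics (the AP is a template, not a conductance model), acoustic
field inhomogeneity and standing waves, cell damage at high exposure, and
any coupling between stimulation history and waveform shape (first and
following spike features are drawn i.i.d., so first/following amplitude
differences seen in real data are not reproduced). Passing the test suite
therefore demonstrates that the estimators recover known quantities under
the stated response model — not that the model captures every property of
real recordings.

## Numerical conventions and degenerate inputs

* Half-open intervals everywhere; epoch extraction uses
  `ceiling`/`tolerance` index arithmetic so boundary samples are assigned
  uniquely.
* Half-prominence crossings are linearly interpolated; the first crossing
  after the peak is taken.
* A one-sample declining phase yields a duration below one sample period
  (interpolated), not an error; a phase that never reaches the half level
  yields `NA` with a warning.
* Empty epochs, single-sample detrending windows, constant-x regressions
  and empty ANOVA cells raise explicit errors naming the problem; an
  all-identical Kruskal–Wallis input returns H = 0, p = 1.
* A constant-y regression returns slope 0 and R² = 0.
* Trace CSVs are written with `%.17g`, so voltage values survive the text
  round-trip bit-exactly.
* Per-trace seeds are expanded from the experiment seed with a
  multiplicative-congruential map (`derive_seed`), so any trace regenerates
  independently of the rest of the experiment.

## Problem sizes in tests and the acceptance script

The acceptance computations use 20 high-gain cells (≈ 780 US spikes) and
120 EL cells (360 spikes) for morphometry recovery, and the full
12-protocol grid with 20 default cells (720 stimulation windows) for the
dose-response regression; the property checks use 2000 null simulations
for the rank-test calibration and populations of 25–100 cells elsewhere.
These sizes put Monte-Carlo error well inside the stated tolerances
(e.g. SE ≈ 0.02 ms on the US duration mean) while a full run stays in the
tens of seconds on one core.

## Known limitations

Detection near window edges is blind to peaks in the last sample of a
window (a local maximum needs a right neighbour); the latency analysis
inherits the generator's refractory/adaptation structure, so latency
*distributions* are comparable only under matched population settings; and
the two-way ANOVA requires every design cell observed — by design it
refuses rather than silently drops cells.
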