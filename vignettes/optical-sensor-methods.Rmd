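---
title: "Methods: from raw voltage streams to mosquito abundance and monitoring power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw voltage streams to mosquito abundance and monitoring power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entosense)
```

This vignette is the package's account of its science: the measurement
model, the signal-processing decisions and their rationale, the synthetic
benchmark and what it does and does not demonstrate, and the statistical
machinery behind the trap comparison and the multi-device precision
experiment.

## 1. Measurement model

A bistatic optical sensor consists of a continuous near-infrared laser
(beam diameter `d`, default 50.8 mm) pointed at a photodetector a distance
`L` away (default 36 m). With no target in the beam the detector reads the
background voltage `V0`. An insect crossing the beam removes light by
scattering, diffraction and absorption; the received voltage drops by an
amount proportional to the insect's *optical extinction cross-section*.
Three quantities summarise each transit:

* the **wingbeat frequency** `f_w`, visible as amplitude oscillations on
  the transit dip;
* the **extinction cross-sections** of wings and body. With `A = pi (d/2)^2`
  the beam area, a voltage level `V` measured during the transit converts
  to a cross-section `(V0 - V)/V0 * A`. The body level `V_B` and the wing
  level `V_w` are each defined as the average of the 10% lowest values of
  the corresponding separated trace (Section 5);
* the **wing-to-body ratio** `sigma_w / (sigma_w + sigma_B)`, low for
  mosquitoes (small transparent wings, relatively thick body), high for
  broad-winged taxa such as moths.

Abundance is quantified as **aerial density**

$$\rho_a = \frac{\sum_i \Delta t_i}{T \cdot V}, \qquad V = A \cdot L,$$

the summed transit durations per valid observation time `T` and probe
volume `V` (about 0.073 m^3 at the default geometry), in insects per cubic
meter. Unlike a raw count, this occupancy integral does not favour fast
fliers: quick insects produce many short transits, slow insects few long
ones, and at equal true density the summed occupancy is the same. The
package verifies this cancellation explicitly in its test suite.

## 2. The synthetic signal generator

No public raw streams exist for this class of instrument, so the package
carries a generator (`simulate_transit()`, `simulate_stream()`) whose
output has exact ground truth, and every downstream stage is validated
against it.

**Waveform model.** A transit is `V(t) = V0 - D_B e(t) - D_w e(t) g(t)`:

* `e(t)` is a Gaussian envelope truncated at ±3 sd, with the stated
  duration spanning 6 sd — transit dips are "somewhat Gaussian" because
  the beam profile is approximately Gaussian after expansion;
* `g(t)` is a non-negative periodic train at `f_w`: a cosine series with
  `1/k` harmonic amplitudes (default 3 harmonics), shifted and scaled to
  `[0, 1]` so each wingbeat cycle touches zero exactly once (wings folded)
  and peaks at one (wings fully extended). This guarantees non-negative
  wing extinction and a harmonic-rich line spectrum, the two properties
  the analysis depends on; the true per-cycle waveform of a real insect is
  not claimed.

**Default conditions.** The defaults are the study conditions, chosen once:

* sampling rate 30,517 Hz, baseline 3 V — the instrument's digitizer
  configuration;
* sample noise SD 5e-5 V: the order of the quantisation step of a 16-bit
  digitizer on a 3 V range (4.6e-5 V), a realistic noise floor for an
  amplified photodiode at these light levels;
* body depth ~ 6 ± 1.5 mV: a relative extinction of 0.2%, i.e. a body
  cross-section of ~4 mm^2 in the 2.03e-3 m^2 beam — mosquito-sized;
* transit durations ~ 100 ± 20 ms (a mosquito at 0.3–1 m/s crossing a
  50.8 mm beam);
* field population parameters for `mosquito_transit_sampler()`: wingbeat
  frequency N(524, 65) Hz for males, N(300, 30) Hz for females;
  wing-to-body ratio N(0.19, 0.05) and N(0.27, 0.07) respectively,
  truncated to (0, 0.95). The wing depth is derived from the drawn ratio
  as `D_w = r/(1-r) D_B`, so the generating ratio is exactly the Eq-3
  ratio of the true depths;
* overlapping transits: with probability 1/800 an event is scheduled
  inside the span of its predecessor, the empirically rare case of two
  insects in the beam at once;
* rain: droplets are short smooth dips (3–15 ms, no 10–900 Hz content).
  Light rain is a sparse 2 s^-1 Poisson process; heavy rain, 800 s^-1,
  keeps the signal essentially continuously below baseline.

**What the generator does not emulate** — and therefore what passing tests
do not demonstrate about field data: speckle and scintillation noise,
beam-pointing drift on sub-minute timescales, insects clipping the beam
edge (partial transits), velocity-correlated duration/depth joint
distributions, species-specific waveform shapes beyond a decaying harmonic
series, and wind-borne debris with oscillatory signatures. The benchmark
shows the *analysis chain is unbiased under its stated signal model*, not
that the model exhausts field phenomenology.

## 3. Event detection

Detection (`detect_events()`) finds contiguous runs where the signal drops
below `baseline - threshold`.

* **Baseline**: medians of 0.25 s chunks, smoothed by a rolling median
  spanning 10 s (ten times the longest admissible transit) and
  interpolated to the sample grid. Medians ignore transits (which occupy
  well under half a chunk) while tracking thermal/alignment drift. For
  segments shorter than the window, a known `baseline_v0` is used instead.
* **Threshold**: `k` (default 6) robust noise SDs below baseline, where
  the noise SD is the MAD of first differences over sqrt(2) (insensitive
  to the transits themselves), with an absolute floor of 1 mV so that
  essentially noise-free streams do not trigger on numerical dust.
* **Gap bridging**: sub-threshold gaps shorter than 2 ms inside a run are
  bridged, so wing oscillations that momentarily touch baseline do not
  split one transit into several.
* **Bound refinement**: each run is then expanded outward to where the dip
  sinks below a noise ceiling (3.5 noise SDs). A threshold crossing
  systematically truncates the Gaussian tails of a transit — a dip of five
  times threshold crosses it at ±1.8 sd though the transit spans ±3 sd —
  which would corrupt both the transit time entering the density integral
  and the event windows used for feature retrieval. On noise-free streams
  refinement recovers the injected bounds to within a millisecond.
* **Duration filter**: refined events shorter than 10 ms are disregarded
  (too few wing cycles to analyse); events longer than 1 s are kept but
  labeled non-insect. Overlapping simultaneous transits necessarily merge
  into one recorded event; no attempt is made to resolve the individuals.

## 4. Insect discrimination and rain

An event is accepted as an insect (`discriminate_insect()`) when its Hann
magnitude spectrum contains a line in the 10–900 Hz band exceeding five
times the *local spectral floor*, a running median across the band. Smooth
dips (droplets, debris) have smoothly decaying spectra: no narrow line,
so the ratio to the local floor stays small. This local-prominence test
was chosen over subtracting a smoothed body envelope before a band-power
test: any fixed smoother has a cutoff that interacts with the 10 Hz band
edge for short events (the body dip of a 10–100 ms transit has genuine
spectral content up to tens of Hz), whereas the running-median floor
adapts to the body spectrum's smooth decay at every frequency.

During heavy rain no individual transit can be isolated.
`flag_invalid_intervals()` marks an interval invalid when the fraction of
time the signal sits a full threshold below the interval's own upper
envelope (its 98th voltage percentile) exceeds 50%. The upper-envelope
reference matters: a continuous droplet stream drags median-based baseline
estimates down with it, which would cap any baseline-relative occupancy
measure near 50% no matter how hard it rains. Invalid time is *excluded
from `T`* in the density computation rather than zero-filled — treating
unobservable minutes as zero density would bias seasonal densities
downward. Sparse light-rain droplets leave the interval valid and are
rejected individually by the spectral test.

## 5. Feature retrieval

**Wingbeat frequency** (`wingbeat_frequency()`): the window is detrended
with a Savitzky–Golay smooth (order 3, window ≈ 25 ms, capped at a third
of the event), Hann-windowed, zero-padded to at least 8× its length, and
Fourier-transformed. Spectral peaks above five times the running-median
floor are candidates; the fundamental is the lowest candidate of
substantial magnitude that is harmonically consistent — it must either
show support at twice its frequency or have no peak at half of it, which
guards against returning the first harmonic when it dominates. Two
refinements matter in practice. First, parabolic interpolation of the
peak gives sub-bin resolution (a 100 ms transit has only 10 Hz native
resolution; interpolated error is ~0.2 Hz). Second, a *subharmonic
rescue*: the body dip elevates the spectral floor at low frequencies and
can mask a true fundamental below ~150 Hz; if half the selected frequency
still shows a line, and so does the third harmonic of that half (which a
genuine fundamental must have, while a spurious low line does not), the
estimate steps down to the subharmonic. Estimates with fewer than three
cycles in the window are returned as undefined.

**Wing/body separation** (`separate_wing_body()`): the body envelope is
interpolated through the *between-wingbeat* signal maxima — the moments of
least extinction, wings folded — located on a lightly smoothed copy of the
window with a minimum spacing of 0.8 wingbeat periods, and joined by
shape-preserving cubic (pchip) interpolation. A second envelope through
the per-beat minima gives the wings-extended level. Each raw extremum is
refined by a least-squares parabola over ±1/12 wingbeat period of *raw*
samples: a single noisy extremum is biased outward by the expected maximum
of the local noise, whereas the parabola vertex averages it away; the
window is kept to a twelfth of a period so the fit spans only the locally
quadratic part of the waveform peak. The wing component is defined as
`body - signal`, so the decomposition reconstructs the input exactly.
Windows with fewer than three resolvable cycles are flagged degenerate and
treated as wingless.

**Levels and cross-sections.** `V_B` is the average of the 10% lowest
values of the body trace. `V_w` is the average of the 10% lowest values of
the wing-contribution trace referenced to `V0`, i.e. `V0` minus the
per-beat peak wing extinction. With both levels measured by the same
decile rule on traces sharing the same envelope, their (small, ~1.5%)
decile-vs-peak attenuation cancels in the ratio. The definition of `V_w`
deserves a note: the published description of instruments of this type is
ambiguous as to whether `V_w` is read off the full signal (deepest overall
level) or the separated wing contribution. The full-signal reading forces
`sigma_w >= sigma_B` and hence ratios ≥ 0.5 for every event, which is
incompatible with the reported mosquito field values (0.19 male, 0.27
female) and with a wingless event having zero wing cross-section; the
wing-contribution reading, which matches the published decomposition
figures, is used here. Under it a wingless event has `V_w = V0` and ratio
0. Levels above `V0` (possible under noise) clamp to zero cross-section
with a warning.

## 6. Classification

Gates are rectangles in `(f_w, sigma_w/b)` space, supplied as
configuration (`cluster_gate()`), not code. The defaults place females at
[250, 400) Hz × [0.05, 0.45] and males at [425, 700] Hz × [0.05, 0.40].
The literature bands overlap in 350–400 Hz; since the field cluster means
sit far apart (≈300 vs ≈524 Hz), the default split leaves 400–425 Hz
unassigned rather than arbitrating the overlap. The female gate takes
priority if configured gates overlap, females being the epidemiologically
relevant class. Events in no gate are `other_insect`; events with
undefined frequency are `unclassified`. Under the field distributions
these gates sex more than 90% of mosquitoes correctly; the residual is
mass outside the gate rectangles, so the mosquito share of all events is
gate-dependent and is not treated as a reproduction target.

## 7. Density, traps and correlation

`aerial_density()` evaluates the occupancy integral per time bin at a
native resolution of one minute; events spanning a bin edge contribute
their overlap to each bin. Coarser series (hourly, daily, weekly) are
derived by `resample_density()`, which aggregates occupancy and valid
time — so resampling commutes with computing at the coarse resolution
directly, and bins with no valid time stay undefined rather than zero.

For comparison with trap surveillance, `trap_count_per_day()` divides each
catch by the days since that trap's previous collection and averages
across traps per date; `align_to_trap_intervals()` degrades the density
series to the traps' resolution as a valid-time-weighted mean between
consecutive collection dates; `correlate_density_traps()` reports the
Pearson correlation, its square, the regression R² and the two-sided
p-value. The correlation coefficient and the regression R² are reported
separately because published summaries of such comparisons sometimes quote
mutually inconsistent r and R² values; for simple linear regression R² is
exactly r², and the package makes both available rather than choosing.
Alignment uses full calendar intervals; a night-only windowing (traps
operate dusk to dawn) is deliberately not applied by default, since the
correct choice depends on the deployment and is easy to apply upstream by
filtering the density series.

## 8. The precision experiment

Seasonal abundance is modeled as an exponential cubic,
`mu(t) = exp(b0 + b1 t + b2 t^2)` on day-of-year `t`, fitted to trap
counts by negative-binomial regression (`fit_seasonal_nb()`, log link,
`MASS::glm.nb`, dispersion by maximum likelihood) and to aerial densities
by ordinary least squares on the log scale (`fit_seasonal_lognormal()`;
the log transform makes the errors homoscedastic, which the tests verify
on generated data). Both fitters work on a centered day axis internally
— the raw (1, t, t²) design over a 180-day season is severely
ill-conditioned — and map coefficients back exactly. Zero counts are
legitimate NB observations and are kept; zero densities carry no
information on the log scale and are dropped by default (`offset` mode
adds half the smallest positive value instead).

`precision_experiment()` then measures how precisely a network of `d`
devices detects a 5% abundance increase: draw `d` seasons from the fitted
model and `d` from the model with its curve multiplied by 1.05, sum each
arm's annual total, record the proportional difference
`(S_1.05 - S_1)/S_1`, and repeat (10,000 comparisons per device count by
default; 2,000 in the packaged benchmark). Design choices:

* the **baseline-arm denominator** makes the statistic exactly 0.05 in
  the noise-free limit (a symmetrised denominator would not); with noise
  the ratio-of-independent-sums form carries a small positive Jensen bias
  of order CV², well inside Monte-Carlo error at the default conditions;
* the **spread metric** is the interdecile range, robust to the skew of
  count noise; spreads scale as 1/sqrt(d) for independent devices, which
  the tests check;
* the default benchmark model peaks at ~100 counts/day in mid-season
  (`b = (-17.445, 0.21, -5e-4)`, peak near day 210 of a day 121–300
  season) with NB dispersion theta = 5 — moderate overdispersion typical
  of light-trap counts;
* `device_equivalence()` interpolates log spread against log device count
  (a straight line of slope −1/2 under independence) to express one
  instrument's precision as "k devices of the other"; comparisons outside
  the simulated range are reported as bounds, not extrapolated.

## 9. Benchmark problem sizes

The packaged benchmark (test suite and `scripts/acceptance.R`) uses
2,000-event populations per sex for feature recovery, 2,000 comparisons
per device count for the precision experiment, and 200 replicate seasons
of 180 days for fitter-bias checks — sizes at which the Monte-Carlo
standard errors are a few times smaller than the effects being verified,
while a full run stays in the minutes range on a single core.

## 10. Known limitations

* The wing/body separation assumes at least three clean wingbeat cycles;
  very short or very-low-frequency transits are flagged degenerate and
  excluded from frequency-based classification rather than guessed at.
* Fundamentals below ~5 cycles per window sit inside the body dip's
  spectral support; the subharmonic rescue recovers most but not all such
  cases (verified at under 1% confusion over 100–700 Hz).
* Overlapping transits are single events by design; their features mix
  two insects and their density contribution counts the pair once.
* The rain model is a stylised droplet process: the validity flag has the
  right asymptotics (sparse rain valid, saturating rain invalid) but the
  50% saturation default has not been calibrated against real storms.
* Gates are rectangles; real clusters are not, and the mosquito share of
  all detections depends on the gate geometry.
* The NB/log-normal season simulators draw days independently; serially
  correlated weather effects on abundance are not modeled, so the
  precision experiment speaks to sampling noise, not to environmental
  confounding.
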