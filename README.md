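# entosense

Signal analysis for bistatic optical insect sensors: from raw near-infrared
extinction voltage streams to mosquito aerial density and monitoring power.

## The problem

Bistatic optical sensors monitor flying insects by pointing a continuous
near-infrared laser beam at a distant photodetector. An insect crossing the
beam scatters, diffracts and absorbs part of the light, producing a
transient drop in the received voltage — a *transit signal* — whose shape
carries a surprising amount of biology: the slow, roughly Gaussian dip
reflects the body, while fast amplitude oscillations superimposed on it
reflect the wingbeat. Because such a sensor observes thousands of transits
per day, unattended, it can track insect abundance at minute resolution
over whole seasons — something physical traps, collected twice a week,
cannot do.

`entosense` implements the complete analysis chain for this class of
instrument, for users in vector surveillance and quantitative entomology:

* **Event detection** — locate signal drops below an adaptive threshold,
  discard events shorter than 10 ms, merge simultaneous transits, and
  discriminate insects from rain droplets and debris by the presence of a
  spectral line in the 10–900 Hz wingbeat band.
* **Feature retrieval** — for each insect transit, the wingbeat fundamental
  frequency `f_w` (FFT with harmonic-consistency peak selection), and the
  optical extinction cross-sections of wings and body from the voltage
  levels `V_w`, `V_B` (averages of the 10% lowest values of the separated
  wing and body traces):

  σ_w = (V0 − V_w)/V0 × A,  σ_B = (V0 − V_B)/V0 × A,
  σ_w/b = σ_w / (σ_w + σ_B),

  where `V0` is the background voltage and `A` the beam cross-section area.
* **Classification** — rectangular gates in `(f_w, σ_w/b)` space separate
  female (≈250–400 Hz) and male (≈425–700 Hz) mosquitoes, both with low
  wing-to-body ratios.
* **Aerial density** — absolute abundance as beam occupancy,

  ρ_a = Σ_i Δt_i / (T · V)  (insects per m³),

  with Δt_i the transit times, T the (valid) observation time and
  V = A · L the probe volume; this removes the bias of raw counts toward
  fast-flying insects.
* **Trap comparison** — trap counts per day, interval alignment of the
  density series to trap collection dates, and their correlation.
* **Precision simulation** — an exponential-cubic seasonal abundance model
  `exp(β0 + β1·t + β2·t²)` with negative-binomial (counts) or log-normal
  (densities) noise, used to measure how precisely networks of 1–16
  devices detect a 5% abundance change, and to express one instrument's
  precision in units of another ("device equivalence").
* **Synthetic data** — a transit-signal and season generator with exact
  ground-truth ledgers, so every stage is testable without field data.

## Worked example

Simulate one minute of stream containing 40 mosquito transits, run the full
pipeline, and look at what comes out:

```r
library(entosense)
scenario <- stream_scenario(duration = 60, n_events = 40, seed = 1)
config   <- pipeline_config(scenario = scenario, density_resolution = 60,
                            seed = 1)
res <- run_pipeline(config)

res$log$n_insect
#> [1] 40

table(res$features$cluster)
#> female_mosquito   male_mosquito
#>              17              23

head(res$features[, c("fw_hz", "sigma_w_m2", "sigma_b_m2", "ratio_wb",
                      "cluster")], 3)
#>      fw_hz   sigma_w_m2   sigma_b_m2  ratio_wb         cluster
#> 1 584.1152 1.506539e-06 3.404346e-06 0.3067754   male_mosquito
#> 2 279.0824 1.828213e-06 4.053283e-06 0.3108416 female_mosquito
#> 3 575.0808 7.212041e-07 3.087776e-06 0.1893431   male_mosquito

print(res$density$all_insects)
#> Aerial density series: 1 bins of 60 s, probe volume 0.07297 m^3
#>   mean density 0.769 /m^3 (100.0% of time valid)

res$density$female_mosquito$density_per_m3
#> [1] 0.3226075
```

All 40 injected transits are detected and labeled insects; each event gets
a wingbeat frequency (here 584 Hz and 575 Hz males, a 279 Hz female), wing
and body cross-sections of a few 10⁻⁶–10⁻⁷ m² (a mosquito body blocks a
few mm² of a 2 × 10⁻³ m² beam), and the wing-to-body ratio used together
with frequency for sexing. The one-minute aerial density, 0.77 insects/m³,
is the summed transit time divided by the valid observation time and the
0.073 m³ probe volume; the female-only series is computed the same way
from the female-gated events.

The methods vignette (`vignettes/optical-sensor-methods.Rmd`) documents the
models, parameter choices and numerical details, and the limits of what the
synthetic benchmark demonstrates.

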