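# ppginv

Detection and quantification of **photoplethysmographic (PPG) signal
inversion** — the anomaly in which reflected light intensity *rises* during
systole instead of falling, flipping the pulse waveform. Inversion matters
for anyone extracting pulse morphology or fiducial timing from reflectance
PPG near a peripheral artery: pulse wave analysis, pulse transit time,
cuffless blood pressure estimation, and signal-quality screening.

The package provides:

* a zero-phase preprocessing chain: negation, a 60 dB baseline high-pass
  (stopband 0.05 Hz, passband 0.1 Hz), and Savitzky–Golay smoothing
  (order 20, frame 999);
* a **two-layer per-pulse classifier** — a systole/diastole symmetry
  criterion on the mean absolute first derivative (±240 samples around each
  verified extremum) and a law-of-cosines **triangulation sharpness**
  criterion on z-scored geometry — with dominance verification over ±150
  samples, noise and layer-disagreement flags;
* the inversion statistics built on the per-pulse labels
  `a_i ∈ {+1 non-inverted, −1 inverted}`:

  ```
  µ   = (1/N) Σ a_i                 mean pulse label
  DOI = (1 − µ) / 2                 degree of inversion in [0, 1]
  OOI = #(DOI > 0.25) / N_rec       occurrence of inversion per
                                    (position × pressure × LED) cell
  ```

* a seeded **synthetic multi-wavelength generator** (90 s @ 800 Hz, four LED
  channels, per-beat polarity ground truth, baseline wander, noise,
  artifacts) and the full 12-participant × 11-position × 3-pressure
  measurement protocol, so the entire pipeline is testable without clinical
  recordings;
* tidyverse-native interfaces: tibbles in and out, `tidy()`/`glance()`
  methods, `autoplot()` for recordings, fits and OOI grids, and a thin
  `ppginv` command-line tool (`exec/ppginv`) with `simulate`, `analyze`,
  `aggregate` and `report` verbs.

## Worked example

Simulate one 90 s four-channel recording in which a contiguous 30 % block of
beats is inverted, then classify every pulse:

```r
library(ppginv)
library(dplyr)

rec <- simulate_recording(sim_plan(duration_s = 90, fraction_inverted = 0.3),
                          seed = 42)
rec
#> <ppg_recording> sim-42: 72000 samples x 4 LEDs @ 800 Hz (90.0 s)
#>   ground truth inverted fraction: blue 0.30, green 0.30, ir 0.30, red 0.30

est <- run_analyze(rec)
select(est, led, n_pulses, mu, doi, inverted, noise_flag)
#> # A tibble: 4 × 6
#>   led   n_pulses    mu   doi inverted noise_flag
#>   <chr>    <int> <dbl> <dbl>    <int> <lgl>
#> 1 ir          89 0.393 0.303        1 FALSE
#> 2 red         89 0.393 0.303        1 FALSE
#> 3 green       89 0.393 0.303        1 FALSE
#> 4 blue        89 0.393 0.303        1 FALSE
```

Each channel yields 89 labelled pulses; the mean label µ = 0.393 gives
DOI = (1 − 0.393)/2 = 0.303, within 0.003 of the planted 30 % inverted
fraction, and DOI > 0.25 classifies the recording as significantly inverted
(`inverted = 1`). Aggregating many recordings produces the OOI grid and its
marginals:

```r
grid <- aggregate_grid(est_many)   # estimates from a full study
tidy(grid)                         # position × pressure × LED cells
autoplot(grid, panel = "led")      # OOI vs position, one line per LED
```

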