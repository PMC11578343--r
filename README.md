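# visconps

Single-cell viscoelastic phenotyping from multi-zone node-pore-sensing (NPS)
resistance traces.

Multi-zone NPS is an all-electronic microfluidic technique for measuring the
frequency-dependent viscoelasticity of individual suspended cells at moderate
throughput (hundreds of cells per hour). A cell is driven by pressure through
a channel containing a Coulter **sizing pore** and a series of **sinusoidal
contraction zones** (width `w(x) = w0 + a·cos(2πx/L_p)`), each probing a
different strain frequency `f = v/L_p`. The cell's transit produces a cascade
of resistive pulses, one per electrode segment; the in-pulse resistance
modulation of each zone encodes the cell's oscillatory stress response at that
zone's frequency.

This package is for experimentalists and analysts working with such devices
(or with the simulated equivalent): it turns multi-channel resistance
time-series into a per-cell table of free diameter and per-frequency storage
modulus G′, loss modulus G″, pre-stress σ_p, and loss tangent η = G″/G′.

## The model in brief

- **Sizing (Coulter principle with finite-size correction):**
  `ΔR/R = D³ / (D_eff²·L) · 1/(1 − 0.8·D³/D_eff³)`, inverted exactly by
  `coulter_diameter()`; `D_eff` is calibrated empirically
  (`fit_effective_diameter()`).
- **Strain:** `ε(t) = ε_mean − ε₀·cos(ωt)` with `ε_mean = (D − w0)/D`,
  `ε₀ = a/D`, `ω = 2πv/L_p`. For the reference geometry and an 18.4 µm cell:
  ≈ 0.4 + 0.15·cos(ωt).
- **Stress:** `σ = 2·ΔP·w / (µ_f·π·D_d)` with the deformed diameter
  `D_d = sqrt(2D³/3w)` from volume conservation, and `ΔP` obtained from the
  measured blockage by a declared pressure-partition model
  `ΔP/P = ΔR/(R_base + ΔR)`.
- **Rheology:** ordinary least squares of the reconstructed stress on
  `σ(t) = σ_p + G′ε₀cos(ωt) + G″ε₀sin(ωt)`, per cell and zone.

The signal pipeline (zero-phase low-pass → moving median → robust baseline
normalization → event detection and causal cross-channel matching →
sub-millisecond pulse-timing refinement) and a ground-truthed forward
simulator are included, so the whole inverse path is testable end to end.
See the methods vignette (`vignettes/visconps-methods.Rmd`) for assumptions,
parameter defaults, and limitations.

## Worked example

Simulate five MCF-7-like cells through the reference four-zone device
(6 mm zones, L_p = 500/250/167/125 µm, 13.8 kPa, 10 kHz sampling) with 5%
relative resistance noise, then run the full inverse pipeline:

```r
library(visconps)
library(dplyr)

sim <- simulate_trace(sim_config(n_cells = 5, seed = 42, noise_sd = 0.05))
res <- nps_analyze(sim$trace, sim$config$geometry)
res
#> <nps_result> 5 cells detected, 5 fitted (0 excluded)
#> Median per-zone moduli (Pa):
#>  zone     f_Hz       Gp      Gpp
#>     1 12.95310 189.1863 16.52969
#>     2 29.91548 190.0270 16.84908
#>     3 46.83787 189.0581 17.40624
#>     4 64.74294 188.1023 16.31872

tidy(res) |> select(cell_id, zone, D_cell, f_applied, sigma_p, Gp, Gpp, eta) |> head(4)
#>   cell_id  zone D_cell f_applied sigma_p    Gp   Gpp    eta
#> 1       1     1   19.6      12.9    45.5  337.  26.0 0.0772
#> 2       1     2   19.6      29.8    45.6  337.  23.3 0.0693
#> 3       1     3   19.6      46.7    45.6  337.  24.9 0.0739
#> 4       1     4   19.6      64.6    45.6  336.  24.2 0.0720
```

Each row is one (cell, zone): `f_applied` is the strain frequency that zone
applied to that cell (Hz), `Gp`/`Gpp` are the storage and loss moduli (Pa) at
that frequency, `sigma_p` the constant pre-stress (Pa), and `eta` the loss
tangent (larger = more fluid-like). Cell 1 here is a stiff cell (G′ ≈ 337 Pa
across 13–65 Hz) with a loss tangent ≈ 0.07. `glance(res)` gives one-row
population summaries; `autoplot(res)` draws the cells-by-zones modulus
heatmap; `iqr_filter()`, `rank_sum_test()`, `kruskal_rank_test()`, and
`cross_zone_variance()` cover the population-level statistics.

A thin CLI wraps the same functions for shell use:

```sh
Rscript inst/cli/visconps run-all --config inst/extdata/demo-run.yaml
```

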