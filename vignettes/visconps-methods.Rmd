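---
title: "Methods: single-cell viscoelastic phenotyping from multi-zone NPS traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell viscoelastic phenotyping from multi-zone NPS traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(visconps)
library(dplyr)
```

## The measurement principle

A multi-zone node-pore-sensing (NPS) device is a microfluidic channel carrying
a DC current, segmented by electrodes into a Coulter **sizing pore** followed
by several **sinusoidal contraction zones** separated by wide relaxation
nodes. A cell transiting the device produces a cascade of resistive pulses,
one per segment and channel.

Two physical relations turn those pulses into a per-cell viscoelastic
phenotype.

**Sizing.** A cell in the pore displaces conducting volume; with the
finite-size correction the relative pulse height is

$$\frac{\Delta R}{R} \;=\; \frac{D_{cell}^3}{D_{e\!f\!f}^2 L}\cdot
\frac{1}{1 - 0.8\, D_{cell}^3 / D_{e\!f\!f}^3},$$

where $D_{e\!f\!f}$ is an empirically calibrated effective pore diameter and
$L$ the pore length. `coulter_diameter()` is the exact algebraic inverse of
`forward_blockage()`; `fit_effective_diameter()` performs the one-parameter
calibration against reference particles.

**Oscillatory rheology.** Each contraction zone has width
$w(x) = w_0 + a\cos(2\pi x/L_p)$, so a cell moving at velocity $v$ feels an
oscillatory compressive strain
$\varepsilon(t) = \varepsilon_{mean} - \varepsilon_0\cos(\omega t)$ with
$\varepsilon_{mean} = (D_{cell}-w_0)/D_{cell}$,
$\varepsilon_0 = a/D_{cell}$, and $\omega = 2\pi v/L_p$. The frequency is set
purely by the period length: a four-zone device with
$L_p = 500/250/167/125\ \mu m$ probes roughly 13–65 Hz in one pass at typical
velocities. For the reference geometry ($w_0 = 11.25$, $a = 2.75\ \mu m$) and
an 18.4 um cell the strain is approximately $0.4 + 0.15\cos\omega t$.

The contact stress on the strained cell follows from the pressure drop
$\Delta P$ across it:

$$\sigma \;=\; \frac{2\,\Delta P\, w}{\mu_f\, \pi\, D_d},\qquad
D_d = \sqrt{\frac{2 D_{cell}^3}{3 w}},$$

with $\mu_f$ the cell–wall friction coefficient and $D_d$ the wall-contact
(deformed) diameter from conservation of volume. The reconstructed stress
series of each zone pulse is then fitted by ordinary least squares to the
standard oscillatory-rheology relationship

$$\sigma(t) = \sigma_p + G'\varepsilon_0\cos\omega t
            + G''\varepsilon_0\sin\omega t,$$

yielding the pre-stress $\sigma_p$, the storage modulus $G'$, and the loss
modulus $G''$ per zone, hence per frequency; the loss tangent is
$\eta = G''/G'$. We read $\varepsilon_0$ as the oscillatory strain amplitude
$a/D_{cell}$; the mean compressive strain is absorbed by $\sigma_p$. This
keeps the relationship a standard oscillatory-rheology form in which the
in-phase and quadrature coefficients are moduli.

## The pressure-partition model

The one quantity the stress relation needs that the electronics do not
directly measure is $\Delta P(t)$ across the cell. We tie it to the cell's
instantaneous fractional electrical blockage:

$$\frac{\Delta P(t)}{P_{applied}} \;=\;
  s\cdot\frac{\Delta R(t)}{R_{base} + \Delta R(t)},$$

on the rationale that the electrical and hydraulic constrictions co-scale in
a series channel; $s$ (`partition_scale`, default 1) is an explicit
calibration constant. This is a modelling choice, stated as such: the
simulator and the analysis use the same map, which makes them exact inverses
and lets every downstream stage be validated end to end. A constant-
$\Delta P$ mode (`partition_mode = "constant"`) is provided for sensitivity
analysis; it is not the default because a time-constant $\Delta P$ combined
with the purely geometric $w(t)$ and $D_d(t)$ cannot produce a quadrature
(loss) component.

Two consequences deserve emphasis. First, absolute moduli carry an unknown
multiplicative calibration: $\mu_f$ (default 0.1, the order of magnitude for
lubricated PDMS–cell contact) and $s$ rescale $\sigma_p$, $G'$ and $G''$
together. Relative comparisons between cells, zones, and conditions — and
the loss tangent — are unaffected. Second, because the map is exact by
construction in the simulator, a noiseless roundtrip recovers the true
parameters to numerical precision; this is a self-consistency check of the
implementation, not evidence about a physical device.

## Signal pipeline

`nps_analyze()` runs the stages below; every tunable lives in
`nps_control()` with the defaults stated here (10 kHz sampling assumed).

1. **Zero-phase low-pass** (Butterworth order 4, cutoff 2 kHz,
   forward–backward with odd-reflection padding). Pulse content sits below
   ~130 Hz, so the cutoff leaves a 15x margin while suppressing wideband
   noise; zero phase preserves pulse timing exactly.
2. **Moving median**, window 0.3 ms (the minimal 3-sample window). The
   window is deliberately short: a running median flattens sinusoid extrema
   by $1-\cos(\omega h/2)$ (half-window $h$), and at 65 Hz a 5 ms window
   would already bias the oscillation amplitude — hence $G'$ — by several
   percent. Even a 1 ms window leaves enough waveform distortion to displace
   the pulse-timing refinement (below) by several microseconds, i.e. ~1%
   of $G''$ for stiff, weakly viscous cells; the 3-sample window makes that
   displacement vanish. The stage exists to reject isolated spikes, not to
   smooth.
3. **Baseline tracking and normalization** (`baseline_normalize()`):
   block-wise medians (0.5 s blocks) smoothed across nine blocks give a
   rough baseline; samples deviating from it by more than 4 robust SDs
   (with a relative floor of 5e-5 for near-noiseless data and 5 ms
   dilation) are masked; the final baseline passes a natural cubic spline
   through the block medians of unmasked samples, each anchored at the
   median *position* of those samples. Both details matter: during a pulse
   the unmasked samples crowd the block edges, so a centre anchor would
   bias the baseline under drift, and linear interpolation across a masked
   pulse would leave a quadratic-in-gap error under curved drift that caps
   the accuracy of the stress reconstruction. The mask is two-sided because a cell whose
   oscillatory stress amplitude exceeds its pre-stress swings the
   resistance below baseline within a pulse.
4. **Event detection** (`detect_events()`): threshold at 5x the MAD of the
   normalized channel (floor 1e-4 for noise-free traces), bridge
   sub-threshold gaps shorter than 50 ms (longer than half the slowest
   strain period, far shorter than the inter-cell spacing), and keep runs of
   at least 5 ms. Channels are matched causally — pore, then zone 1, zone 2,
   ... within 0.5 s of the previous channel. Cells with overlapping device
   occupancy are flagged `coincident`, cells missing a zone pulse
   `incomplete`; both are excluded from fitting with machine-readable
   reasons, and (cells in) = (fitted) + (excluded) holds per run.
5. **Features and fitting**: transit time, velocity $L_{zone}/T$, frequency
   $v/L_p$, and the in-pulse oscillation (least-squares sinusoid at the
   applied frequency) per zone; Coulter sizing from the pore pulse; stress
   reconstruction and the rheological fit per zone with 5 ms edge guards
   (filter transients never enter the fit).

### Pulse-timing refinement

The fit's phase reference is zone entry ($w(0) = w_0 + a$, the widest
point). A timing error $\delta t$ rotates the fitted pair:
$G'' \mapsto G''\cos\omega\delta t + G'\sin\omega\delta t$. With
$G'/G'' \approx 10$, holding $G''$ to 1% at 65 Hz needs entry timing good to
a few microseconds — far beyond threshold-crossing accuracy on a filtered
edge (~0.3 ms). `nps_analyze()` therefore refines each pulse's entry and
transit times by minimizing the rheological fit's residual RMS, which is
sharply minimized at the true timing because a misaligned geometric model
($w(x)$, $D_d(x)$) leaves harmonic artifacts the three-term basis cannot
absorb. The search runs as coordinate descent on (pulse-centre time,
transit): in (entry, transit) coordinates the two directions form a narrow
ridge, while the centre-time parameterization decouples them. Windows are
+/-2 ms (entry) and +/-4 ms (transit) around the detected edges.

## The simulator

`simulate_trace()` is the forward model: per cell a top-hat pore pulse
(height from `forward_blockage()`), then per zone a pulse whose oscillation
encodes the true $\sigma_p, G', G''$ through the stress model and partition
map, plus white Gaussian noise and a slow sinusoidal baseline drift.
`SimTruth` tables (`$cells`, `$zones`) record every generating parameter,
so recall/precision and parameter-recovery error are computable exactly.

Defaults emulate the reference experimental conditions: diameters
18.4 +/- 0.9 um (untreated MCF-7-like), applied pressure 13.8 kPa, 10 kHz
sampling, 600 cells per hour (regular arrivals with +/-15% jitter), base
velocity 6.5 +/- 0.4 mm/s with per-zone multipliers (1, 1.155, 1.208, 1.25)
reproducing the observed zone-to-zone frequency drift (about 13/30/47/65 Hz
in the four-zone, 6 mm-zone device rather than the 13/26/39/52 Hz of
strictly constant velocity). Because no absolute stress calibration is
available, the modulus scales are this package's own choice: log-normal
$G'$ (median 200 Pa), $G''$ (median 20 Pa, so the loss tangent ~0.1 sits in
the experimentally reported 0.05-0.13 range), and $\sigma_p$ (median 50 Pa),
each with realistic cell-to-cell scatter (sdlog 0.3-0.4). A power-law
frequency dependence is available (`modulus_model(type = "powerlaw")`) but
the default is frequency-flat, since no power-law scaling was observed over
the platform's sub-decade frequency range.

**Noise convention.** `noise_sd` is relative to the *nominal pulse height*
of each channel (computed from the configuration at the population mean),
not to the baseline resistance: zone pulses are ~1e-3 of baseline, so noise
scaled to baseline would be meaningless at any realistic SNR. "5% relative
resistance noise" therefore means noise with SD equal to 5% of a typical
pulse.

What the simulator does *not* emulate: 1/f electrode noise, cell rotation or
multi-cell trains within a zone, cytoskeletal recovery dynamics, and
non-spherical free-cell shapes. Passing the end-to-end tests shows the
inverse pipeline is correct and noise-robust under the declared forward
model; it cannot validate the partition model itself against a physical
device.

## Numerical choices and degenerate inputs

- Quartiles in `iqr_filter()` use linear interpolation (R type 7); the
  Tukey fences are $Q_1 - 1.5\,\mathrm{IQR}$ and $Q_3 + 1.5\,\mathrm{IQR}$,
  with pass-through (and a warning) below four values.
- Unpaired group comparisons use the Wilcoxon rank-sum test; the signed-rank
  variant is provided for paired designs only (it errors on unequal group
  sizes). k-group comparisons use Kruskal–Wallis.
- The cross-zone heterogeneity score z-scores each zone across the
  population (unit variance per zone) and reports the per-cell variance of
  those z-scores across zones; cells with fewer than two zones score `NA`.
  Other readings of "unit variance across zones" exist (e.g. scaling
  without centring); this one makes "tracks the population" score exactly
  zero.
- Negative fitted moduli are flagged (`negative_modulus`), never clipped,
  so the $G'' < 0.1$ Pa detection threshold keeps its meaning; a cell with
  any zone below that threshold is flagged `below_detection`.
- Cells not larger than the widest contraction ($D \le w_0 + a$) are
  flagged `unstrained` and excluded from rheology rather than failing the
  batch; the simulator gives them a plain volumetric pulse with no
  oscillation.
- Degenerate inputs error with classed conditions: all-zero channels
  (`nps_baseline_error`), cutoff at/above Nyquist and channel-count
  mismatches (`nps_config_error`), rank-deficient fit bases
  (`nps_fit_error`), blockage beyond the correction's validity
  (`nps_saturation_error`), stalling-cell stresses
  (`nps_unphysical_error`).

## Validation problem sizes

The shipped tests validate analytic identities exactly (forward/inverse
sizing to 1e-9; least-squares recovery to 1e-9), run a noiseless 20-cell
population through the four-zone 6 mm device requiring every recovered
$D_{cell}$, $G'$, $G''$, $\sigma_p$ within 1% of truth, and a 100-cell
population at 5% relative noise requiring perfect event recall/precision,
median modulus errors within 10% ($G'$) and 20% ($G''$), and per-zone
frequencies within 2% of $v/L_p$. Typical observed errors are far inside
these bounds (noiseless worst case ~0.5%; noisy medians ~0.2% for $G'$ and
~3% for $G''$). Unit tests use a reduced two-zone, 2 mm-zone device to stay
fast; the population sizes above were chosen so the full suite completes in
a few minutes on one core while still exercising every pipeline stage at
realistic event rates.

## Known limitations

- Absolute moduli depend on the unknown calibration pair ($\mu_f$, $s$);
  only relative comparisons and $\eta$ are calibration-free.
- The frequency range of a device is bounded by its zone count and length;
  the default geometry spans less than one decade, too narrow to constrain
  power-law rheology.
- Coincident cells are excluded, not decoded; coded-channel multiplexing is
  out of scope.
- The detection and filter defaults were chosen from first principles and
  validated on simulations, not recovered from any published analysis code.

```{r quick-example}
sim <- simulate_trace(sim_config(n_cells = 3, seed = 7, noise_sd = 0.05))
res <- nps_analyze(sim$trace, sim$config$geometry)
glance(res)
tidy(res) |> select(cell_id, zone, f_applied, Gp, Gpp, eta) |> head(6)
```
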