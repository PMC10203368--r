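---
title: "Methods: time-lapse dielectric relaxation analysis of protein hydration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-lapse dielectric relaxation analysis of protein hydration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrodr)
```

## The model

A protein solution in the 0.1–14 GHz band is treated as a sum of Debye
dispersions on top of an apparent high-frequency limit,

$$\varepsilon^*(\omega) = \varepsilon(\infty)_{\mathrm{relax}}
 + \sum_x \frac{\Delta\varepsilon_x}{1 + i\omega\tau_x},
 \qquad x \in \{\beta, \delta_1, \delta_2, \gamma_1, \gamma_2\},$$

with $\varepsilon^* = \varepsilon' - i\varepsilon''$ and the loss stored
positive.  $\beta$ is protein tumbling (~10 MHz), $\delta_1$ and
$\delta_2$ are hydration-water modes (~0.1 and ~4 GHz), $\gamma_1$ is slow
bulk water and $\gamma_2$ fast water (sub-THz).
$\varepsilon(\infty)_{\mathrm{relax}}$ lumps all vibrational strengths with
the true high-frequency limit; the static permittivity is the strength sum
plus $\varepsilon(\infty)_{\mathrm{relax}}$.  Stretched (Cole–Cole /
Cole–Davidson) exponents are deliberately out of scope: every mode is a
pure Debye term, which is what makes the Nyquist geometry exact.

Because $\gamma_1$ carries most of the strength and is well separated in
frequency, its locus in the Nyquist plane is a semicircle centred on the
real axis.  We fit that circle algebraically (Kåsa form with the centre
ordinate constrained to zero): writing $x^2+y^2 = 2ax + (r^2-a^2)$ the
problem is linear and solved in closed form — deterministic, exact on
noiseless data, no iterative refinement.  Note the circular form is
centred at $(\varepsilon_s+\varepsilon_\infty)/2$; a version centred at
$(\varepsilon_s-\varepsilon_\infty)/2$ cannot reproduce its own real-axis
intercepts, so only the former geometry is implemented.  The intercepts
$\mathrm{centre}\pm r$ are reported as
$\varepsilon_{\gamma 1}(s)$ and $\varepsilon_{\gamma 1}(\infty)$, which by
the separated-dispersion approximation equal
$\Delta\varepsilon_{\gamma1}+\Delta\varepsilon_{\gamma2}+\varepsilon(\infty)_{\mathrm{relax}}$
and $\Delta\varepsilon_{\gamma2}+\varepsilon(\infty)_{\mathrm{relax}}$.
The relaxation frequency comes from the inscribed-angle identity
$\varepsilon''/(\varepsilon'-\varepsilon_{\gamma1}(\infty)) = \omega\tau$:
each in-band point gives an estimate of $\omega\tau$, and $\tau$ is the
least-squares slope of those estimates against $\omega$.  Using all points
rather than only the vertex is a choice; it averages noise without biasing
the noiseless case.

## Calibration

Reflection data are converted to permittivity by the Open/Short/Standard
bilinear inversion

$$\varepsilon_m^* = \frac{\varepsilon_a^*(S_m-S_o)(S_s-S_a) +
 (S_m-S_a)(S_o-S_s)}{(S_m-S_s)(S_o-S_a)},$$

a cross-ratio that inverts *any* Moebius forward map exactly — the package
treats this as an algebraic identity and tests it on random bilinear maps
to $10^{-10}$.  Degenerate anchor triples (separation below $10^{-9}$ in
the S plane) are refused; points where the measurement coincides with the
Short anchor (the $\varepsilon\to\infty$ limit) are flagged `NA` rather
than returned.  Calibration is per-frequency and stateless: no smoothing
is applied at this stage.  In time-lapse mode the same specimen measured
at the reference time is the Standard, with a declared single-Debye
slow-water model as $\varepsilon_a^*$; this forces the reference spectrum
to the declared model exactly and expresses later sweeps as differential
changes, cancelling probe and geometry drift.

## The standing-wave statistic

The 1.0 mm sample layer over the container wall supports internal
reflections.  The forward model is a transmission-line slab:
$\Gamma_{in} = (\Gamma_1 + \Gamma_2 e^{-2\gamma l})/(1 + \Gamma_1\Gamma_2
e^{-2\gamma l})$ with $\gamma = i\,2\pi f\sqrt{\varepsilon^*}/c$ and
interface coefficients from wave-impedance mismatches
($\eta \propto 1/\sqrt\varepsilon$).  $\Gamma_{in}$ is converted back to
an effective homogeneous permittivity and mapped through the probe's
Moebius map, so a matched backing reduces the model exactly to the
half-space case.  The quarter-wave condition puts the resonance where
$f\sqrt{\varepsilon'} \approx c/4l$, hence the peak moves *up* in
frequency when the permittivity drops ($\lambda \propto 1/\sqrt\varepsilon$),
which is the property the detector exploits.

`delta_r` is the inward radial deviation from the fitted circle (positive
inside, invariant to the sign of the loss), and `detect_peak` reports the
band maximum minus a baseline estimated from the 1 GHz flanking windows on
each side, excluding the peak's half-height support so that shoulders do
not bias the baseline.  Ties go to the lower frequency.  A peak too close
to the data edge for its flanking windows is an error, not a guess.

## Difference spectra and NMR analysis

Late-minus-reference difference spectra carry uncertainties combined as
$\sqrt{\sigma_A^2+\sigma_B^2}$; band statistics are unweighted means over
0.3–3 GHz (low) and 3–6.5 GHz (high), and the peak height near the
resonance (windows 6.5–7.5 GHz real / 7.5–8.5 GHz imaginary) after
subtracting the 4–5 GHz mean as background.  THz-TDS loss spectra are
corrected by subtracting the solute's vibrational reference and dividing
by the water mass fraction (0.714 at 28.6 wt%), with $\sigma$ scaled
accordingly; only the imaginary part is analysed, the real part carrying
larger measurement error in this geometry.

Methyl intensities are normalised by each sample's 1H-1D integral
(12 to −3 ppm, water resonance excluded), which is proportional to
protein concentration, making every downstream statistic scale-invariant.
Pathway profiles are per-methyl ratios against the common starting state;
correlations are Pearson coefficients of the centred ratios (affine
invariance makes centring cosmetic, but "displacement from the reference"
reads better).  Responsive methyls are flagged when a ratio moves more
than one sample standard deviation (n−1 denominator) from 1; the standard
deviation is computed per pathway, not pooled.  Hen lysozyme's 129-residue
chain carries 61 AILMTV methyls (A 1, I 2, L 2, M 1, T 1, V 2); which four
resonances are overlap-excluded is configuration — the generator marks
four evenly spaced entries, leaving the conventional 57.

## Dosimetry

Closed forms with $c = 299\,792\,458$ m/s and
$\varepsilon_0 = 8.8541878128\times10^{-12}$ F/m:
$E = \sqrt{P_s/(c\varepsilon_0\sqrt{\varepsilon'})}$,
$U = P_s\sqrt{\varepsilon'}/c$, penetration depth $1/\alpha$.  With the
beam parameters used throughout (16 mW/cm² = 160 W/m², $\varepsilon' = 7.7$
at 0.1 THz, $\alpha = 83$ cm⁻¹) these give 147 V/m ≈ 0.15 kV/m,
1.48 µJ/m³ and 120 µm.  The pulse duty cycle (0.8 µs × 10 kHz) is carried
as a derived attribute but plays no role: dosimetry uses average power.

## The synthetic experiment

The generator's defaults *are* the study conditions: four conditions
(constant-temperature control GC; irradiated THz, +4 °C over the 10-min
exposure; heated control HTC, +6 °C; cooled control LTC, −4 °C, all
returning exponentially to 24 °C with a ~5 min time constant, i.e. back to
room temperature about 20 min after the perturbation), five replicate
sweeps at 18/28/40/50/60 min, 0.1–14 GHz, 9.1 wt% lysozyme dissolved two
hours before the measurement clock starts, perturbation at 20–30 min.
Pure-water Debye parameters follow the Malmberg–Maryott static
permittivity and an Arrhenius-like relaxation time (8.27 ps at 25 °C,
18.9 kJ/mol).  Solution models anchor the slow-water limits to the
measured calibration values (76.55/5.49 at 2.9 wt%, 68.59/5.28 at
9.1 wt%), interpolate them linearly in concentration, and scale
water-derived strengths and times with temperature.

Design choices that were genuinely open, and why they were fixed as they
are:

* **Slow-water relaxation time.**  A 58.8 ps time would put the slow-water
  dispersion at 2.7 GHz — but then the permittivity at 7–9 GHz is ~13 and
  a 1.0 mm aqueous layer has no quarter-wave resonance inside the measured
  band at all, contradicting both the ~20 GHz bulk-water assignment and
  the observed 7–8 GHz standing wave.  The generator therefore uses
  5.88 ps at 24 °C (dispersion at ~27 GHz), which is water-consistent and
  places the synthetic resonance near 8–9.5 GHz.  The declared Standard
  model used in the same-sample calibration keeps the same time so the
  calibration is phase-consistent; `standard_gamma1_spectrum()` retains
  the 58.8 ps figure as its documented default for reproducing the
  published calibration configuration.
* **Hydration kinetics.**  The slow reaction is a first-order transfer of
  a fixed strength budget (0.05 permittivity units — the planted effect is
  deliberately "small", below 0.1) from the fast-water mode $\gamma_2$
  into the adjacent hydration mode $\delta_2$, conserving the static
  permittivity while lowering $\varepsilon_{\gamma1}(\infty)$.  Rate
  $k = 0.0015$ min⁻¹ (time constant ~11 h, so the unirradiated reaction
  takes more than a day) and irradiation multiplier $\kappa = 127$ (a
  10-min exposure advances the reaction by ~21 h, so the irradiated sample
  at 3 h sits where the control sits at 24 h).  These two numbers encode
  the experiment's headline timescales and are not tuned per run.
* **Probe and noise.**  The synthetic probe is the Moebius map
  $S = (1-g\varepsilon)/(1+g\varepsilon)$ with $g = 1/76$, near its
  maximum sensitivity for aqueous permittivities; reflection noise is
  additive circular complex Gaussian, $10^{-3}$ per quadrature, a
  VNA-like floor.  Sweeps are 1601 points (a standard VNA sweep length),
  log-spaced — dense enough to resolve the sharp resonance.
* **Cell coupling.**  The plane-wave slab formula at full strength drives
  the effective permittivity to ~10³ at resonance, which would pin the
  reflection against the Short anchor — an artefact of treating the probe
  aperture as a plane-wave port.  `cell_geometry()` therefore scales the
  second-interface reflection by an aperture-coupling factor (default
  0.5, with 1 recovering the plain slab); at 0.5 the standing wave is a
  sharp ripple of a few permittivity units, and changes in the peak are
  clearly resolved above the five-replicate noise floor — the regime the
  measurement method is designed around.
* **Analysis defaults.**  `analyze_timelapse()` searches for the peak in
  4–12 GHz (the synthetic cell's deviation lobes straddle ~5 and
  ~10 GHz; standalone `detect_peak()` keeps the instrument's nominal
  6–10 GHz default) and smooths `delta_r` with a 101-point moving average
  (~1.5 % of the sweep, matching the GHz-scale lobe width) before peak
  detection.  The post-exposure growth statistic is
  $P_{\Delta r}(60\,\mathrm{min}) - P_{\Delta r}(28\,\mathrm{min})$.
* **Seeding.**  One integer seed expands into fixed-offset substreams per
  condition, replicate and time point, so datasets are bit-reproducible
  and adding a condition does not reshuffle the others.

The NMR generator plants the pathway geometry directly: a latent
displacement vector over the 57 analysed methyls, realised fully by the
control at 24 h, mostly (0.8×) by the irradiated sample already at 3 h,
and in the opposite direction (−0.5×) by the heated sample, with
independent extra displacements by 24 h and log-normal measurement noise;
per-sample concentration factors are folded into both the intensities and
the 1H-1D integrals so that normalisation must cancel them.

## What the synthetic tests do and do not show

Passing the end-to-end recovery (planted slow-water intercepts within 1 %,
the hydration-transfer sign detected in the 0.3–3 GHz imaginary band, and
post-exposure peak growth larger for the irradiated condition than the
heated control in ≥95 of 100 seeds; NMR correlation signs in ≥99 of 100)
shows that the *analysis chain* is correct and sensitive at the planted
effect sizes under the assumed noise model.  It does not validate the
physics of any real instrument: the slab model is a one-dimensional
caricature of the real cell (its resonance frequency is not expected to
match the instrument's 7–8 GHz quantitatively), the probe map is an
idealised bilinear reflectometer, solvent conductivity, electrode
polarisation and drift are absent, and the hydration kinetics are a
single-exponential stand-in for an unknown reaction.

## Numerical choices and degenerate inputs

Frequencies are stored in Hz everywhere and only formatted as GHz for
display.  The circle fit needs three in-band points with positive loss and
refuses collinear data; the relaxation-frequency estimator refuses bands
with no point above the high-frequency intercept; `moving_average`
requires an odd window and truncates at the edges; `band_statistics`
requires coverage of 0.3–9 GHz.  The calibration degeneracy tolerance is
$10^{-9}$ absolute in the S plane (double-precision headroom).  All
simulation sizes used by the test suite — 1601-point sweeps, 5 replicates,
100 seeds for the recovery rates, 500 replicates for the intercept-bias
Monte Carlo — were chosen so the whole suite runs on a laptop in a few
minutes.

## Known limitations

Only the imaginary part of the THz-TDS data is analysed; the solute
vibrational reference is a synthetic stand-in, not a measured spectrum.
The four overlap-excluded methyls are configuration, not an assignment.
The temperature map of the solution model scales water-derived terms only;
protein and hydration strengths are taken temperature-independent over the
20–31 °C range.  Exact strengths and times for the β/δ modes are
plausible defaults (β: 4 at 16 ns, δ₁: 3 at 1.6 ns, δ₂: 2 at 40 ps, γ₂:
1.5 at 0.265 ps, at 9.1 wt%), configurable but not fitted to data.
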