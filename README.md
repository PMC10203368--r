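# hydrodr

Analysis tools for time-lapse dielectric relaxation (DR) measurements of
protein solutions under sub-terahertz irradiation, together with the THz
time-domain (THz-TDS) difference-spectrum and NMR methyl-intensity analyses
that accompany them, and a seeded synthetic-data generator that emulates the
whole experiment so every stage can be verified end to end.

## The scientific problem

Hydration water around a globular protein relaxes on several timescales.
In the microwave band a lysozyme solution shows a sum of Debye dispersions,

    eps*(w) = eps(inf)_relax + sum_x  D_eps_x / (1 + i w tau_x),
    x in {beta (~10 MHz), delta1 (~0.1 GHz), delta2 (~4 GHz),
          gamma1 (slow bulk water), gamma2 (fast water, sub-THz)},

with the convention `eps* = eps' - i eps''` (loss positive).  Because the
slow bulk-water term dominates (~80 % of the relaxation strength), its
single-Debye semicircle in the Nyquist plane (`eps''` vs `eps'`) can be
fitted on its own: a circle centred on the real axis at
`(eps_s + eps_inf)/2` with radius `(eps_s - eps_inf)/2`, whose real-axis
intercepts give the apparent limits `eps_gamma1(s)` and `eps_gamma1(inf)`
without any multi-dispersion fit.  Measured reflection coefficients are
converted to permittivity by Open/Short/Standard calibration — a bilinear
(Moebius) inversion that is exact for any three-term reflectometer error
model — and, in time-lapse mode, the same specimen at a reference time
serves as the Standard, cancelling probe drift.

Two derived statistics carry the biology:

* `delta_r(f) = r - |(eps'(f), eps''(f)) - (centre, 0)|`, the inward radial
  deviation of each measured point from the fitted semicircle.  A thin
  (1.0 mm) sample layer supports a quarter-wave standing wave whose
  frequency scales as `1/sqrt(eps)`, so a *small* drop in permittivity
  re-tunes the resonance and produces a sharp, baseline-subtracted peak
  `P_dr` in `delta_r` — a sensitive detector of permittivity changes below
  0.1.
* Difference spectra between late and reference time points, summarised by
  low- (0.3–3 GHz) and high-band (3–6.5 GHz) means and the background-
  subtracted peak near the resonance, with errors propagated as
  `sqrt(sigma_A^2 + sigma_B^2)`.

On the NMR side, the 61 AILMTV methyl groups of hen lysozyme (57 after
overlap exclusion) act as site-specific reporters: peak intensities are
normalised by the 1H-1D integral (proportional to concentration), expressed
as ratios against the common starting state, correlated between conditions,
and flagged when a ratio moves more than one standard deviation from 1.

The synthetic generator plants all of this: temperature-driven water Debye
parameters, a first-order kinetic transfer of relaxation strength from the
fast-water mode into the slow hydration band (accelerated during
irradiation), a one-dimensional slab standing-wave model of the sample
cell, reflection noise, and an NMR table with condition-dependent
correlated displacements — then the analysis chain must recover what was
planted.

## Worked example

```r
library(hydrodr)

# Nyquist semicircle fit of a noiseless slow-water dispersion
# (2.9 wt% lysozyme calibration parameters)
f   <- freq_grid(1e8, 14e9, 201)
m   <- relaxation_model(data.frame(label = "gamma1", strength = 71.06,
                                   tau_s = 5.88e-11), eps_inf_relax = 5.49)
fit <- fit_semicircle(eval_model(m, f))
glance(fit)
#> # A tibble: 1 × 6
#>   center_real radius eps_gamma1_s eps_gamma1_inf n_points     rmse
#>         <dbl>  <dbl>        <dbl>          <dbl>    <int>    <dbl>
#> 1        41.0   35.5         76.5           5.49      201 1.31e-14

# exposure dosimetry from the printed beam parameters
dosimetry()
#> # A tibble: 1 × 3
#>   e_field_v_per_m energy_density_j_per_m3 penetration_depth_m
#>             <dbl>                   <dbl>               <dbl>
#> 1            147.              0.00000148            0.000120

# one full synthetic experiment, simulated and analysed end to end
evaluate_recovery(seed = 1)
#> # A tibble: 1 × 4
#>   intercept_rel_err l_imag_thz growth_thz growth_htc
#>               <dbl>      <dbl>      <dbl>      <dbl>
#> 1           0.00177     0.0101    -0.0523    -0.0684
```

Reading the recovery row: the fitted slow-water intercepts sit within 0.2 %
of the planted values; the imaginary-part difference spectrum of the
irradiated sample is positive in the 0.3–3 GHz hydration band (the planted
fast-to-slow transfer is detected with the right sign); and the
post-exposure change of the standing-wave peak height is less negative for
the irradiated condition than for the heated control — the irradiated
sample keeps "growing" after the heat transient reverts, which is the
method's signature of a nonthermal effect.

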