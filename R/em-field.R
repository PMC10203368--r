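#' Physical constants
#' @keywords internal
#' @name constants
NULL

C_LIGHT <- 299792458
EPS0 <- 8.8541878128e-12

#' Sample-cell geometry
#'
#' Geometry of the thin liquid layer between the probe face and the
#' container: a 1.0 mm path length backed by a PDMS wall treated as a
#' lossless, non-dispersive dielectric.
#'
#' @param thickness_l sample path length in metres (default 1.0 mm).
#' @param eps_backing backing (container) relative permittivity
#'   (complex, default 2.68 + 0i, a typical PDMS value).
#' @param z0 reference line impedance in ohm (default 50).
#' @param coupling aperture coupling of the slab mode in (0, 1] (default 0.5): the
#'   fraction of the second-interface reflection that returns coherently to
#'   the probe aperture.  An open-ended probe's fringing field couples only
#'   weakly to the plane-wave slab mode, so the standing wave appears as a
#'   sharp but small ripple on the recovered permittivity; 1 is the fully
#'   coupled plane-wave slab.
#' @return a `cell_geometry` list.
#' @export
cell_geometry <- function(thickness_l = 1.0e-3, eps_backing = 2.68 + 0i,
                          z0 = 50, coupling = 0.5) {
  stopifnot(thickness_l > 0, coupling > 0, coupling <= 1)
  structure(list(thickness_l = thickness_l,
                 eps_backing = as.complex(eps_backing), z0 = z0,
                 coupling = coupling),
            class = "cell_geometry")
}

#' One-dimensional standing-wave reflection of the sample cell
#'
#' Models the thin sample layer as a transmission-line slab: internal
#' reflections between the probe/sample and sample/backing interfaces
#' produce a quarter-wave standing-wave resonance whose frequency scales as
#' `1/sqrt(eps)`.  The slab input reflection is
#' \deqn{\Gamma_{in} = \frac{\Gamma_1 + \Gamma_2 e^{-2\gamma l}}
#'   {1 + \Gamma_1 \Gamma_2 e^{-2\gamma l}},\qquad
#'   \gamma = i \, 2\pi f \sqrt{\varepsilon^*} / c,}
#' with interface coefficients from the wave-impedance mismatches
#' (`eta` proportional to `1/sqrt(eps)`).  `Gamma_in` is then converted to
#' an effective homogeneous permittivity and passed through the probe's
#' forward Moebius map, so that when `eps_backing == eps_sample` (no second
#' interface) the result reduces exactly to [forward_reflection()].
#'
#' @param eps_sample spectrum tibble of the sample permittivity.
#' @param geom a [cell_geometry()].
#' @param cal a [calibration_set()] describing the probe.
#' @return a reflection tibble.
#' @export
layered_reflection <- function(eps_sample, geom, cal) {
  check_spectrum(eps_sample)
  stopifnot(inherits(geom, "cell_geometry"), inherits(cal, "calibration_set"))
  stop_if_grid_mismatch(cal$open_rec, eps_sample)
  eps_eff <- effective_slab_permittivity(eps_sample, geom)
  forward_reflection(cal, eps_eff)
}

#' @rdname layered_reflection
#' @details `effective_slab_permittivity()` exposes the intermediate step:
#'   the homogeneous permittivity whose half-space reflection equals the
#'   slab's `Gamma_in`.
#' @export
effective_slab_permittivity <- function(eps_sample, geom) {
  check_spectrum(eps_sample)
  stopifnot(inherits(geom, "cell_geometry"))
  eps <- spectrum_complex(eps_sample)
  f <- eps_sample$frequency_hz
  n_s <- sqrt(eps)            # principal root: Re > 0, Im <= 0 for loss
  n_b <- sqrt(geom$eps_backing)
  # eta ~ 1/sqrt(eps); reference side is the probe line (eta0)
  g1 <- (1 - n_s) / (1 + n_s)          # line -> sample
  g2 <- geom$coupling *
    (n_s - n_b) / (n_s + n_b)          # sample -> backing (aperture-coupled)
  ph <- exp(-2i * 2 * pi * f * n_s * geom$thickness_l / C_LIGHT)
  gin <- (g1 + g2 * ph) / (1 + g1 * g2 * ph)
  n_eff <- (1 - gin) / (1 + gin)
  spectrum_tbl(f, n_eff^2)
}

#' Dosimetry parameters of the sub-THz exposure
#'
#' @param p_s surface power density in W/m^2 (default 160).
#' @param eps_real_100ghz real permittivity of water at 0.1 THz
#'   (default 7.7).
#' @param alpha_cm absorption coefficient in 1/cm (default 83).
#' @param pulse_width_s pulse width in seconds (default 0.8 us).
#' @param rep_rate_hz pulse repetition rate in Hz (default 10 kHz).
#' @return a `dose_params` list; the duty cycle
#'   (`pulse_width_s * rep_rate_hz`) is carried as a derived attribute but
#'   plays no role in the average-power dosimetry.
#' @export
dose_params <- function(p_s = 160, eps_real_100ghz = 7.7, alpha_cm = 83,
                        pulse_width_s = 0.8e-6, rep_rate_hz = 1e4) {
  stopifnot(p_s >= 0, eps_real_100ghz > 0, alpha_cm > 0,
            pulse_width_s > 0, rep_rate_hz > 0)
  structure(list(p_s = p_s, eps_real_100ghz = eps_real_100ghz,
                 alpha_cm = alpha_cm, pulse_width_s = pulse_width_s,
                 rep_rate_hz = rep_rate_hz,
                 duty_cycle = pulse_width_s * rep_rate_hz),
            class = "dose_params")
}

#' Average field strength at the irradiated surface
#'
#' `E = sqrt(P_s / (c eps0 sqrt(eps')))` in V/m.
#'
#' @param d a [dose_params()].
#' @return field strength in V/m.
#' @export
field_strength <- function(d) {
  stopifnot(inherits(d, "dose_params"))
  sqrt(d$p_s / (C_LIGHT * EPS0 * sqrt(d$eps_real_100ghz)))
}

#' Energy density at the irradiated surface
#'
#' `U = P_s / v` with the propagation velocity in the sample
#' `v = c / sqrt(eps')`; in J/m^3.
#'
#' @param d a [dose_params()].
#' @return energy density in J/m^3.
#' @export
energy_density <- function(d) {
  stopifnot(inherits(d, "dose_params"))
  d$p_s / (C_LIGHT / sqrt(d$eps_real_100ghz))
}

#' Field penetration depth from an absorption coefficient
#'
#' @param alpha_cm absorption coefficient in 1/cm (> 0).
#' @return depth `1/alpha` in metres.
#' @export
penetration_depth <- function(alpha_cm) {
  if (!is.numeric(alpha_cm) || any(alpha_cm <= 0)) {
    stop("alpha must be positive", call. = FALSE)
  }
  (1 / alpha_cm) / 100
}

#' Convert a power density from mW/cm^2 to W/m^2
#'
#' @param value_mw_per_cm2 power density in mW/cm^2 (>= 0).
#' @return power density in W/m^2 (a factor of 10).
#' @export
power_density_si <- function(value_mw_per_cm2) {
  stopifnot(all(value_mw_per_cm2 >= 0))
  value_mw_per_cm2 * 10
}

#' Dosimetry report
#'
#' @param d a [dose_params()].
#' @return a one-row tibble with `e_field_v_per_m`, `energy_density_j_per_m3`
#'   and `penetration_depth_m`.
#' @export
dosimetry <- function(d = dose_params()) {
  tibble::tibble(e_field_v_per_m = field_strength(d),
                 energy_density_j_per_m3 = energy_density(d),
                 penetration_depth_m = penetration_depth(d$alpha_cm))
}
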