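#' Empirical Debye parameters of pure water
#'
#' Smooth single-Debye parameterisation of pure water against temperature:
#' the static permittivity follows the Malmberg-Maryott polynomial
#' (78.3 at 25 C, slope about -0.36 per K) and the relaxation time an
#' Arrhenius-like law anchored at 8.27 ps / 25 C with an 18.9 kJ/mol
#' activation energy.  The high-frequency limit is held at 5.2.
#'
#' @param temp_c temperature in Celsius, 0 < temp_c < 60.
#' @return list with `eps_s`, `eps_inf`, `tau_s`.
#' @export
water_debye_params <- function(temp_c) {
  if (any(temp_c <= 0) || any(temp_c >= 60)) {
    stop("temperature out of supported range (0, 60) C", call. = FALSE)
  }
  eps_s <- 87.740 - 0.40008 * temp_c + 9.398e-4 * temp_c^2 -
    1.410e-6 * temp_c^3
  tk <- temp_c + 273.15
  tau_s <- 8.27e-12 * exp(18900 / 8.314462618 * (1 / tk - 1 / 298.15))
  list(eps_s = eps_s, eps_inf = 5.2, tau_s = tau_s)
}

#' Hydration-transfer state
#'
#' Generative model of the slow hydration change: a fraction `f_transfer` of
#' a fixed strength budget `transfer_total` has moved from the fast-water
#' mode (`gamma2`) into the slow hydration mode (`delta2`).  The move
#' conserves the total relaxation strength, so the static permittivity is
#' unchanged while the apparent high-frequency limit of the slow-water
#' semicircle drops.  The transfer relaxes toward `f_eq` with first-order
#' rate `k` (1/min), multiplied by `kappa_thz` while the sub-THz field is
#' on.  The defaults encode an unirradiated equilibration time of the order
#' of a day (k = 0.0015/min) and an irradiation boost that compresses about
#' 21 h of the reaction into a 10-min exposure (kappa_thz = 127).
#'
#' @param f_transfer transferred fraction in [0, 1].
#' @param k first-order rate (1/min).
#' @param kappa_thz rate multiplier during irradiation (>= 1).
#' @param f_eq equilibrium fraction.
#' @param transfer_total total transferable strength (permittivity units).
#' @return a `hydration_state` list.
#' @export
hydration_state <- function(f_transfer = 0, k = 0.0015, kappa_thz = 127,
                            f_eq = 1, transfer_total = 0.05) {
  stopifnot(f_transfer >= 0, f_transfer <= 1, k >= 0, kappa_thz >= 1,
            transfer_total >= 0)
  structure(list(f_transfer = f_transfer, k = k, kappa_thz = kappa_thz,
                 f_eq = f_eq, transfer_total = transfer_total),
            class = "hydration_state")
}

#' Advance a hydration state in time
#'
#' Closed-form first-order update:
#' `f(t + dt) = f_eq + (f - f_eq) exp(-k_eff dt)`, with
#' `k_eff = k * kappa_thz` while irradiating (condition `"THz"`), else `k`.
#'
#' @param state a [hydration_state()].
#' @param condition experimental condition label.
#' @param dt_min time step in minutes (> 0).
#' @param irradiating logical; is the sub-THz field on during this step?
#' @return the updated `hydration_state`.
#' @export
evolve_hydration <- function(state, condition = "GC", dt_min,
                             irradiating = FALSE) {
  stopifnot(inherits(state, "hydration_state"), dt_min > 0)
  k_eff <- if (identical(condition, "THz") && irradiating) {
    state$k * state$kappa_thz
  } else {
    state$k
  }
  state$f_transfer <- state$f_eq +
    (state$f_transfer - state$f_eq) * exp(-k_eff * dt_min)
  state
}

# transferred fraction at measurement-clock time t (minutes), for a sample
# dissolved `dissolution_min` minutes before t = 0, with irradiation (THz
# condition only) during [irr_start, irr_end]
transfer_fraction_at <- function(t_min, condition, state,
                                 dissolution_min = 120,
                                 irr_window = c(20, 30)) {
  st <- state
  st$f_transfer <- 0
  t_abs <- t_min + dissolution_min
  pre <- min(t_abs, irr_window[1] + dissolution_min)
  if (pre > 0) st <- evolve_hydration(st, condition, pre, FALSE)
  if (t_abs > irr_window[1] + dissolution_min) {
    irr <- min(t_abs, irr_window[2] + dissolution_min) -
      (irr_window[1] + dissolution_min)
    if (irr > 0) st <- evolve_hydration(st, condition, irr, TRUE)
  }
  if (t_abs > irr_window[2] + dissolution_min) {
    st <- evolve_hydration(st, condition,
                           t_abs - (irr_window[2] + dissolution_min), FALSE)
  }
  st$f_transfer
}

#' Temperature profiles of the four experimental conditions
#'
#' Condition `GC` (general control) is constant at 24 C.  `THz` rises
#' linearly by +4 C during the 10-min perturbation window, `HTC` by +6 C,
#' and `LTC` falls by 4 C; afterwards all return exponentially (about a
#' 5-min time constant) to 24 C, i.e. they are back at room temperature
#' roughly 20 min after the perturbation ends.
#'
#' @param condition one of `"THz"`, `"HTC"`, `"LTC"`, `"GC"`.
#' @param t_min measurement-clock times in minutes.
#' @param base_c room temperature (default 24).
#' @param window perturbation window in minutes (default 20-30).
#' @param return_tau_min exponential return time constant (default 5).
#' @return numeric vector of temperatures in Celsius.
#' @export
temperature_profile <- function(condition = c("GC", "THz", "HTC", "LTC"),
                                t_min, base_c = 24, window = c(20, 30),
                                return_tau_min = 5) {
  condition <- match.arg(condition)
  amp <- switch(condition, GC = 0, THz = 4, HTC = 6, LTC = -4)
  ramp <- function(t) {
    out <- numeric(length(t))
    rising <- t >= window[1] & t <= window[2]
    out[rising] <- amp * (t[rising] - window[1]) / diff(window)
    after <- t > window[2]
    out[after] <- amp * exp(-(t[after] - window[2]) / return_tau_min)
    out
  }
  base_c + ramp(t_min)
}

# linear interpolation of the printed slow-water limits against
# concentration (anchored at 2.9 and 9.1 wt%, 24 C); concentration 0 falls
# back to the pure-water parameterisation
gamma1_anchor_limits <- function(concentration_wt) {
  slope_s <- (68.59 - 76.55) / (9.1 - 2.9)
  slope_i <- (5.28 - 5.49) / (9.1 - 2.9)
  list(eps_s = 76.55 + slope_s * (concentration_wt - 2.9),
       eps_inf = 5.49 + slope_i * (concentration_wt - 2.9))
}

#' Generative relaxation model of a lysozyme solution
#'
#' Builds the five-component Debye model at a given concentration,
#' temperature, and hydration state.  The slow-water (`gamma1`) limits are
#' anchored to the printed calibration values (68.59/5.28 at 9.1 wt%,
#' 76.55/5.49 at 2.9 wt%, tau 58.8 ps at 24 C) and interpolated linearly in
#' concentration; protein and hydration strengths (beta, delta1, delta2)
#' scale with concentration; water-derived strengths and times scale with
#' temperature through [water_debye_params()].  The hydration state moves
#' `f_transfer * transfer_total` of strength from `gamma2` to `delta2`,
#' conserving the static permittivity.  Concentration 0 returns a
#' two-component pure-water model (gamma1 + gamma2 only).
#'
#' The default slow-water relaxation time (58.8 fs would be unphysical and
#' 58.8 ps would place the dispersion at 2.7 GHz, inconsistent with a
#' ~20 GHz bulk-water mode and with a 7-8 GHz quarter-wave standing wave in
#' a 1.0 mm aqueous layer; the generator therefore uses 5.88 ps at 24 C,
#' which puts the dispersion at ~27 GHz and the synthetic standing wave
#' inside the measured band).
#'
#' @param concentration_wt lysozyme concentration in weight percent.
#' @param temp_c temperature in Celsius.
#' @param state a [hydration_state()].
#' @param gamma1_tau_24c slow-water relaxation time at 24 C (seconds).
#' @return a [relaxation_model()].
#' @export
solution_model <- function(concentration_wt = 9.1, temp_c = 24,
                           state = hydration_state(),
                           gamma1_tau_24c = 5.88e-12) {
  stopifnot(concentration_wt >= 0, inherits(state, "hydration_state"))
  w <- water_debye_params(temp_c)
  w24 <- water_debye_params(24)
  s_scale <- w$eps_s / w24$eps_s       # temperature scaling of water terms
  t_scale <- w$tau_s / w24$tau_s
  g2_strength <- 1.5 * s_scale
  g2_tau <- 0.265e-12 * t_scale
  moved <- state$f_transfer * state$transfer_total
  if (moved > g2_strength) stop("transfer exceeds gamma2 strength",
                                call. = FALSE)
  if (concentration_wt == 0) {
    eps_inf_relax <- 5.2 - 1.5
    g1 <- w$eps_s - g2_strength - eps_inf_relax
    comp <- tibble::tibble(
      label = c("gamma1", "gamma2"),
      strength = c(g1, g2_strength),
      tau_s = c(w$tau_s, g2_tau))
    return(relaxation_model(comp, eps_inf_relax = eps_inf_relax))
  }
  anchor <- gamma1_anchor_limits(concentration_wt)
  eps_inf_relax <- anchor$eps_inf - 1.5  # at 24 C reference
  g1_strength <- (anchor$eps_s - anchor$eps_inf) * s_scale
  g1_tau <- gamma1_tau_24c * t_scale
  cscale <- concentration_wt / 9.1
  comp <- tibble::tibble(
    label = c("beta", "delta1", "delta2", "gamma1", "gamma2"),
    strength = c(4 * cscale, 3 * cscale,
                 2 * cscale + moved, g1_strength, g2_strength - moved),
    tau_s = c(16e-9, 1.6e-9, 40e-12, g1_tau, g2_tau))
  relaxation_model(comp, eps_inf_relax = eps_inf_relax)
}

#' Configuration of the synthetic time-lapse experiment
#'
#' The defaults mirror the study design: four temperature/irradiation
#' conditions, five replicate sweeps at 18/28/40/50/60 min, 0.1-14 GHz,
#' 9.1 wt% lysozyme dissolved two hours before the measurement clock
#' starts, a 10-min perturbation at 20-30 min, a 1.0 mm sample layer over
#' PDMS, and additive circular complex Gaussian reflection noise of
#' 1e-3 per quadrature.  The sweep is 1601 points (a standard VNA sweep
#' length), dense enough to resolve the sharp 7-9 GHz standing wave.
#'
#' @param concentration_wt lysozyme concentration (wt%).
#' @param conditions condition labels to simulate.
#' @param times_min measurement time points (min).
#' @param n_replicates sweeps per condition and time point.
#' @param n_freq,f_min_hz,f_max_hz frequency sweep definition.
#' @param noise_sd reflection-coefficient noise per quadrature.
#' @param k_per_min,kappa_thz,transfer_total,f_eq hydration kinetics, see
#'   [hydration_state()].
#' @param dissolution_min minutes between dissolution and the measurement
#'   clock origin.
#' @param irr_window perturbation window (min).
#' @param geom a [cell_geometry()].
#' @param probe_g probe constant for [probe_map()].
#' @return a `timelapse_config` list.
#' @export
timelapse_config <- function(concentration_wt = 9.1,
                             conditions = c("GC", "THz", "HTC", "LTC"),
                             times_min = c(18, 28, 40, 50, 60),
                             n_replicates = 5,
                             n_freq = 1601, f_min_hz = 1e8, f_max_hz = 14e9,
                             noise_sd = 1e-3,
                             k_per_min = 0.0015, kappa_thz = 127,
                             transfer_total = 0.05, f_eq = 1,
                             dissolution_min = 120, irr_window = c(20, 30),
                             geom = cell_geometry(), probe_g = 1 / 76) {
  stopifnot(n_replicates >= 1, noise_sd >= 0, all(times_min > 0))
  structure(list(concentration_wt = concentration_wt, conditions = conditions,
                 times_min = times_min, n_replicates = n_replicates,
                 n_freq = n_freq, f_min_hz = f_min_hz, f_max_hz = f_max_hz,
                 noise_sd = noise_sd, k_per_min = k_per_min,
                 kappa_thz = kappa_thz, transfer_total = transfer_total,
                 f_eq = f_eq, dissolution_min = dissolution_min,
                 irr_window = irr_window, geom = geom, probe_g = probe_g),
            class = "timelapse_config")
}

#' Printed-parameter single-Debye standard model
#'
#' The slow-water single-Debye model used as the declared Standard
#' permittivity in the same-sample calibration: intercepts interpolated
#' from the printed 2.9/9.1 wt% values, tau = 58.8 ps.
#'
#' @param concentration_wt concentration (wt%).
#' @param frequency_hz grid to evaluate on.
#' @param tau_s relaxation time of the Standard model (seconds); the
#'   printed calibration value by default.
#' @return a spectrum tibble.
#' @export
standard_gamma1_spectrum <- function(concentration_wt, frequency_hz,
                                     tau_s = 5.88e-11) {
  a <- gamma1_anchor_limits(concentration_wt)
  m <- relaxation_model(
    tibble::tibble(label = "gamma1", strength = a$eps_s - a$eps_inf,
                   tau_s = tau_s),
    eps_inf_relax = a$eps_inf)
  eval_model(m, frequency_hz)
}

#' Simulate the full time-lapse reflection experiment
#'
#' For every condition, replicate, and time point: the temperature profile
#' and hydration kinetics set the solution model; its permittivity passes
#' through the 1-D slab standing-wave model and the probe's Moebius map;
#' additive circular complex Gaussian noise lands on S11.  The result is
#' bit-reproducible for a fixed seed (each condition/replicate series draws
#' from its own fixed-offset substream).
#'
#' @param config a [timelapse_config()].
#' @param seed integer seed.
#' @return a `timelapse_dataset` list: `measurements` (long tibble with
#'   condition, replicate, time_min, frequency_hz, s11), `temperature`
#'   (condition, time_min, temp_c), `truth` (condition, time_min,
#'   f_transfer, temp_c, true gamma1 limits), `config`, `seed`.
#' @export
simulate_timelapse <- function(config = timelapse_config(), seed = 1) {
  stopifnot(inherits(config, "timelapse_config"))
  f <- freq_grid(config$f_min_hz, config$f_max_hz, config$n_freq)
  state0 <- hydration_state(0, config$k_per_min, config$kappa_thz,
                            config$f_eq, config$transfer_total)
  grid <- tidyr::expand_grid(condition = config$conditions,
                             time_min = config$times_min)
  truth <- purrr::pmap_dfr(grid, function(condition, time_min) {
    tc <- temperature_profile(condition, time_min,
                              window = config$irr_window)
    ft <- transfer_fraction_at(time_min, condition, state0,
                               config$dissolution_min, config$irr_window)
    st <- state0; st$f_transfer <- ft
    m <- solution_model(config$concentration_wt, tc, st)
    lim <- gamma1_effective_limits(m)
    tibble::tibble(condition = condition, time_min = time_min,
                   temp_c = tc, f_transfer = ft,
                   eps_gamma1_s = lim$eps_gamma1_s,
                   eps_gamma1_inf = lim$eps_gamma1_inf)
  })
  cond_idx <- stats::setNames(seq_along(config$conditions),
                              config$conditions)
  meas <- purrr::pmap_dfr(truth[, c("condition", "time_min")],
                          function(condition, time_min) {
    row <- truth[truth$condition == condition &
                   truth$time_min == time_min, ]
    st <- state0; st$f_transfer <- row$f_transfer
    m <- solution_model(config$concentration_wt, row$temp_c, st)
    eps <- eval_model(m, f)
    eps_eff <- effective_slab_permittivity(eps, config$geom)
    s_clean <- probe_map(spectrum_complex(eps_eff), config$probe_g)
    purrr::map_dfr(seq_len(config$n_replicates), function(rep_i) {
      sub <- seed + 7919L * cond_idx[[condition]] + 101L * rep_i +
        round(time_min)
      set.seed(sub %% .Machine$integer.max)
      noise <- complex(real = stats::rnorm(length(f), 0, config$noise_sd),
                       imaginary = stats::rnorm(length(f), 0,
                                                config$noise_sd))
      if (config$noise_sd == 0) noise <- 0 + 0i
      tibble::tibble(condition = condition, replicate = rep_i,
                     time_min = time_min, frequency_hz = f,
                     s11 = s_clean + noise)
    })
  })
  temp_tbl <- tidyr::expand_grid(condition = config$conditions,
                                 time_min = seq(0, 60, by = 0.5)) |>
    dplyr::mutate(temp_c = purrr::map2_dbl(
      .data$condition, .data$time_min,
      ~ temperature_profile(.x, .y, window = config$irr_window)))
  structure(list(measurements = meas, temperature = temp_tbl,
                 truth = truth, config = config, seed = seed),
            class = "timelapse_dataset")
}

#' @export
print.timelapse_dataset <- function(x, ...) {
  cat("<timelapse_dataset>",
      length(unique(x$measurements$condition)), "conditions x",
      length(unique(x$measurements$time_min)), "times x",
      max(x$measurements$replicate), "replicates,",
      x$config$n_freq, "frequencies (seed", x$seed, ")\n")
  invisible(x)
}

#' Synthetic THz-TDS loss spectra
#'
#' Emulates the 0.3-2.5 THz imaginary-part measurement: pure water as the
#' slow+fast bulk-water Debye losses, a synthetic stand-in for the
#' dehydrated-protein vibrational spectrum (a broad frequency-squared ramp
#' with a Gaussian bump), and the solution as
#' `solute + water_fraction * water`, optionally with part of the
#' fast-water strength removed for an irradiated sample.  Four replicates
#' with additive noise supply the per-point standard deviations.
#'
#' @param seed integer seed.
#' @param temp_c sample temperature (C).
#' @param water_fraction mass fraction of water (default 0.714,
#'   i.e. 28.6 wt% solute).
#' @param gamma2_loss fast-water strength removed in the irradiated sample.
#' @param noise_sd additive noise per replicate point.
#' @param n_freq grid size over 0.3-2.5 THz.
#' @param n_replicates replicates used for the sigma estimate.
#' @return list of spectrum tibbles: `water`, `solute_ref`, `mixture`,
#'   `mixture_irradiated` (all with `sigma_imag` where replicated), plus
#'   `water_fraction`.
#' @export
simulate_thz_tds <- function(seed = 1, temp_c = 25, water_fraction = 0.714,
                             gamma2_loss = 0.05, noise_sd = 0.01,
                             n_freq = 111, n_replicates = 4) {
  set.seed(seed)
  f <- freq_grid(0.3e12, 2.5e12, n_freq, spacing = "linear")
  w <- water_debye_params(temp_c)
  water_imag <- function(g2) {
    g1 <- gamma2_imag_mode(w$eps_s - 5.2, w$tau_s, f)$eps_imag
    g2c <- gamma2_imag_mode(g2, 0.265e-12, f)$eps_imag
    g1 + g2c
  }
  solute <- 0.15 * (f / 2.5e12)^2 + 0.08 * exp(-((f - 1.5e12) / 4e11)^2)
  mix_clean <- function(g2) solute + water_fraction * water_imag(g2)
  with_reps <- function(clean) {
    reps <- replicate(n_replicates,
                      clean + stats::rnorm(length(f), 0, noise_sd))
    spectrum_tbl(f, rowMeans(reps) * 0, eps_imag = rowMeans(reps),
                 sigma_real = 0, sigma_imag = apply(reps, 1, stats::sd))
  }
  list(water = with_reps(water_imag(1.5)),
       solute_ref = spectrum_tbl(f, rep(0, n_freq), eps_imag = solute),
       mixture = with_reps(mix_clean(1.5)),
       mixture_irradiated = with_reps(mix_clean(1.5 - gamma2_loss)),
       water_fraction = water_fraction)
}
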