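test_that("the pure-water parameterisation matches accepted values", {
  w25 <- water_debye_params(25)
  expect_gt(w25$eps_s, 78); expect_lt(w25$eps_s, 79)
  expect_equal(w25$tau_s, 8.27e-12, tolerance = 1e-6)
  expect_lt(water_debye_params(30)$eps_s, water_debye_params(20)$eps_s)
  expect_lt(water_debye_params(30)$tau_s, water_debye_params(20)$tau_s)
  expect_error(water_debye_params(75), "out of supported range")
})

test_that("the solution model is anchored to the printed slow-water limits", {
  m91 <- solution_model(9.1, 24, hydration_state(0))
  lim <- gamma1_effective_limits(m91)
  expect_equal(lim$eps_gamma1_s, 68.59, tolerance = 1e-9)
  expect_equal(lim$eps_gamma1_inf, 5.28, tolerance = 1e-9)
  m29 <- solution_model(2.9, 24, hydration_state(0))
  lim29 <- gamma1_effective_limits(m29)
  expect_equal(lim29$eps_gamma1_s, 76.55, tolerance = 1e-9)
  expect_equal(lim29$eps_gamma1_inf, 5.49, tolerance = 1e-9)
  # concentration 0 is pure water, no protein or hydration terms
  m0 <- solution_model(0, 25)
  expect_true(all(m0$components$label %in% c("gamma1", "gamma2")))
  expect_equal(static_permittivity(m0), water_debye_params(25)$eps_s,
               tolerance = 1e-9)
})

test_that("hydration transfer conserves the static permittivity", {
  s0 <- static_permittivity(solution_model(9.1, 24, hydration_state(0)))
  s5 <- static_permittivity(solution_model(9.1, 24, hydration_state(0.5)))
  s1 <- static_permittivity(solution_model(9.1, 24, hydration_state(1)))
  expect_equal(s5, s0, tolerance = 1e-12)
  expect_equal(s1, s0, tolerance = 1e-12)
  # and lowers the apparent high-frequency limit by the moved strength
  l0 <- gamma1_effective_limits(solution_model(9.1, 24, hydration_state(0)))
  l1 <- gamma1_effective_limits(solution_model(9.1, 24, hydration_state(1)))
  expect_equal(l0$eps_gamma1_inf - l1$eps_gamma1_inf, 0.05,
               tolerance = 1e-12)
})

test_that("hydration kinetics follow the closed-form exponential", {
  st <- hydration_state(0, k = 0.01, kappa_thz = 20)
  # no boost: irradiated and control updates coincide
  a <- evolve_hydration(hydration_state(0, 0.01, kappa_thz = 1), "THz", 10,
                        irradiating = TRUE)
  b <- evolve_hydration(hydration_state(0, 0.01, kappa_thz = 1), "GC", 10,
                        irradiating = TRUE)
  expect_equal(a$f_transfer, b$f_transfer)
  # long-time limit reaches equilibrium
  long <- evolve_hydration(st, "GC", 1e6)
  expect_equal(long$f_transfer, 1, tolerance = 1e-9)
  # 10 irradiated minutes at kappa = 20 equal 200 unirradiated minutes
  irr10 <- evolve_hydration(st, "THz", 10, irradiating = TRUE)
  ctl200 <- evolve_hydration(st, "GC", 200)
  expect_equal(irr10$f_transfer, ctl200$f_transfer, tolerance = 1e-12)
  expect_gt(irr10$f_transfer, evolve_hydration(st, "GC", 190)$f_transfer)
})

test_that("temperature profiles match the stated experimental design", {
  t <- seq(0, 60, by = 0.5)
  expect_true(all(temperature_profile("GC", t) == 24))
  thz <- temperature_profile("THz", t)
  expect_equal(max(thz), 28, tolerance = 1e-9)           # +4 C at end of ramp
  expect_equal(t[which.max(thz)], 30)
  expect_equal(max(temperature_profile("HTC", t)), 30)   # +6 C
  expect_equal(min(temperature_profile("LTC", t)), 20)   # -4 C
  # back to room temperature about 20 min after the perturbation
  expect_lt(abs(temperature_profile("THz", 50) - 24), 0.1)
  expect_lt(abs(temperature_profile("HTC", 55) - 24), 0.05)
})

test_that("the simulator is reproducible and still under no perturbation", {
  cfg <- small_config()
  a <- simulate_timelapse(cfg, seed = 123)
  b <- simulate_timelapse(cfg, seed = 123)
  expect_identical(a$measurements$s11, b$measurements$s11)
  c2 <- simulate_timelapse(cfg, seed = 124)
  expect_false(identical(a$measurements$s11, c2$measurements$s11))
  # frozen kinetics, no noise, constant temperature: time points identical
  cfg0 <- small_config(noise_sd = 0, k_per_min = 0, kappa_thz = 1,
                       conditions = "GC")
  s0 <- simulate_timelapse(cfg0, seed = 1)
  m <- s0$measurements
  t1 <- m$s11[m$time_min == 18 & m$replicate == 1]
  t2 <- m$s11[m$time_min == 28 & m$replicate == 1]
  expect_equal(t1, t2, tolerance = 1e-14)
})

test_that("generated spectra are passive and truth is carried alongside", {
  cfg <- small_config()
  sim <- simulate_timelapse(cfg, seed = 9)
  expect_true(all(Mod(sim$measurements$s11) <= 1.05))
  expect_equal(nrow(sim$truth), 4)
  expect_true(all(c("f_transfer", "eps_gamma1_s", "eps_gamma1_inf")
                  %in% names(sim$truth)))
  # the model spectra behind the data have nonnegative loss
  st <- hydration_state(0.5)
  eps <- eval_model(solution_model(9.1, 27, st), freq_grid(1e8, 14e9, 101))
  expect_true(all(eps$eps_imag >= 0))
})

test_that("THz-TDS synthesis composes exactly and reproducibly", {
  tds0 <- simulate_thz_tds(seed = 1, noise_sd = 0)
  rec <- subtract_solute(tds0$mixture, tds0$solute_ref, tds0$water_fraction)
  expect_equal(rec$eps_imag, tds0$water$eps_imag, tolerance = 1e-9)
  # fast-water mode peak near 0.60 THz
  g2 <- gamma2_imag_mode(1.5, 0.265e-12, freq_grid(0.05e12, 2.5e12, 4001))
  expect_equal(g2$frequency_hz[which.max(g2$eps_imag)] / 1e12, 0.60,
               tolerance = 2e-3)
  # irradiated minus control loss is negative in the fast-water band
  d <- spectrum_difference(tds0$mixture_irradiated, tds0$mixture)
  expect_true(all(d$d_imag <= 1e-12))
  a <- simulate_thz_tds(seed = 7)
  b <- simulate_thz_tds(seed = 7)
  expect_identical(a$mixture$eps_imag, b$mixture$eps_imag)
})
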