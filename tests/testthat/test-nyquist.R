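test_that("the circle fit recovers the printed calibration parameters", {
  # 2.9 wt% parameters
  s29 <- debye_spectrum(76.55, 5.49, 5.88e-11, n = 50)
  fit <- fit_semicircle(s29)
  expect_equal(fit$center_real, (76.55 + 5.49) / 2, tolerance = 1e-9)
  expect_equal(fit$radius, (76.55 - 5.49) / 2, tolerance = 1e-9)
  expect_equal(fit$eps_gamma1_s, 76.55, tolerance = 1e-6)
  expect_equal(fit$eps_gamma1_inf, 5.49, tolerance = 1e-6)
  # 9.1 wt% parameters
  s91 <- debye_spectrum(68.59, 5.28, 5.88e-11, n = 50)
  fit91 <- fit_semicircle(s91)
  expect_equal(fit91$eps_gamma1_s, 68.59, tolerance = 1e-6)
  expect_equal(fit91$eps_gamma1_inf, 5.28, tolerance = 1e-6)
})

test_that("three exact points determine the circle", {
  th <- c(30, 90, 150) * pi / 180
  x <- 40 + 35 * cos(th); y <- 35 * sin(th)
  spec <- spectrum_tbl(freq_grid(1e9, 3e9, 3), x, eps_imag = y)
  fit <- fit_semicircle(spec)
  expect_equal(fit$center_real, 40, tolerance = 1e-9)
  expect_equal(fit$radius, 35, tolerance = 1e-9)
})

test_that("noiseless single-Debye recovery is exact across the model range", {
  set.seed(5)
  for (i in 1:12) {
    eps_s <- runif(1, 10, 100)
    eps_inf <- runif(1, 2, 10)
    tau <- runif(1, 10e-12, 100e-12)
    fit <- fit_semicircle(debye_spectrum(eps_s, eps_inf, tau, n = 201))
    expect_equal(fit$eps_gamma1_s, eps_s, tolerance = 1e-6)
    expect_equal(fit$eps_gamma1_inf, eps_inf, tolerance = 1e-6)
  }
})

test_that("intercept bias stays small under complex Gaussian noise", {
  set.seed(99)
  n_rep <- 500
  est <- matrix(NA_real_, n_rep, 2)
  for (i in seq_len(n_rep)) {
    s <- debye_spectrum(76.55, 5.49, 5.88e-11, n = 201)
    s$eps_real <- s$eps_real + rnorm(201, 0, 0.1)
    s$eps_imag <- s$eps_imag + rnorm(201, 0, 0.1)
    fit <- fit_semicircle(s)
    est[i, ] <- c(fit$eps_gamma1_s, fit$eps_gamma1_inf)
  }
  expect_lt(abs(mean(est[, 1]) - 76.55), 0.2)
  expect_lt(abs(mean(est[, 2]) - 5.49), 0.2)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_semicircle(spectrum_tbl(c(1e9, 2e9), c(1, 2),
                                           eps_imag = c(1, 1))),
               "insufficient points")
  flat <- spectrum_tbl(freq_grid(1e9, 5e9, 10), rep(5, 10),
                       eps_imag = rep(0, 10))
  expect_error(fit_semicircle(flat), "no positive loss")
  collinear <- spectrum_tbl(freq_grid(1e9, 5e9, 5), rep(5, 5),
                            eps_imag = 1:5)
  expect_error(fit_semicircle(collinear), "degenerate|radius")
})

test_that("the circumferential-angle tangent recovers the relaxation frequency", {
  tau <- 5.88e-11
  spec <- debye_spectrum(68.59, 5.28, tau, n = 201)
  fit <- fit_semicircle(spec)
  fc <- relaxation_frequency(spec, fit)
  expect_equal(fc, 1 / (2 * pi * tau), tolerance = 1e-6)
  expect_equal(fc / 1e9, 2.7067, tolerance = 1e-4)
  # the vertex satisfies eps'' / (eps' - eps_inf) = 1
  vertex <- eval_model(relaxation_model(
    data.frame(label = "gamma1", strength = 63.31, tau_s = tau),
    eps_inf_relax = 5.28), 1 / (2 * pi * tau))
  expect_equal(vertex$eps_imag / (vertex$eps_real - 5.28), 1,
               tolerance = 1e-12)
})

test_that("the relaxation-frequency estimator is unbiased under vertical noise", {
  set.seed(2)
  tau <- 5.88e-11
  spec <- debye_spectrum(68.59, 5.28, tau, n = 1e4)
  fit <- fit_semicircle(spec)
  noisy <- spec
  noisy$eps_imag <- noisy$eps_imag + runif(1e4, -0.2, 0.2)
  fc <- relaxation_frequency(noisy, fit)
  expect_lt(abs(fc / (1 / (2 * pi * tau)) - 1), 0.005)
})

test_that("delta-r vanishes on ideal Debye data and measures radial offsets", {
  spec <- debye_spectrum(68.59, 5.28, 5.88e-11, n = 201)
  fit <- fit_semicircle(spec)
  dr <- compute_delta_r(spec, fit)
  expect_true(all(abs(dr$delta_r) < 1e-9))
  # displace one point radially inward by 0.1
  i <- 100
  v <- c(spec$eps_real[i] - fit$center_real, spec$eps_imag[i])
  v <- v / sqrt(sum(v^2))
  spec2 <- spec
  spec2$eps_real[i] <- spec$eps_real[i] - 0.1 * v[1]
  spec2$eps_imag[i] <- spec$eps_imag[i] - 0.1 * v[2]
  dr2 <- compute_delta_r(spec2, fit)
  expect_equal(dr2$delta_r[i], 0.1, tolerance = 1e-9)
  # reflection invariance in the loss sign
  spec3 <- spec
  spec3$eps_imag <- -spec3$eps_imag
  dr3 <- compute_delta_r(spec3, fit)
  expect_equal(dr3$delta_r, dr$delta_r, tolerance = 1e-12)
})

test_that("peak detection separates a narrow bump from its baseline", {
  f <- seq(1e9, 14e9, by = 0.05e9)
  base <- 0.3
  # narrow bump: apex 2 above baseline, shoulders above half height, then
  # an immediate drop to the baseline
  bump <- numeric(length(f))
  bump[abs(f - 8e9) < 0.075e9] <- 1.2
  bump[abs(f - 8e9) < 0.025e9] <- 2
  dr <- tibble::tibble(frequency_hz = f, delta_r = base + bump)
  pk <- detect_peak(dr, search_band = c(6e9, 10e9))
  expect_equal(pk$f_peak_hz, 8e9)
  expect_equal(pk$height, 2, tolerance = 1e-9)
  expect_equal(pk$baseline, base, tolerance = 1e-9)
  # flat spectrum: zero height
  flat <- tibble::tibble(frequency_hz = f, delta_r = rep(0, length(f)))
  pk0 <- detect_peak(flat, search_band = c(6e9, 10e9))
  expect_equal(pk0$height, 0)
  # tie-break toward the lower frequency
  two <- tibble::tibble(frequency_hz = f,
                        delta_r = pmax(0, 1 - abs(f - 7e9) / 0.2e9) +
                          pmax(0, 1 - abs(f - 9e9) / 0.2e9))
  pk2 <- detect_peak(two, search_band = c(6e9, 10e9))
  expect_equal(pk2$f_peak_hz, 7e9)
  # flanking windows must fit inside the data
  expect_error(detect_peak(dr, search_band = c(0.5e9, 10e9)),
               "too close to the data edge")
})
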