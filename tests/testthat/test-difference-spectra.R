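make_spec <- function(f, re, im, sr = NULL, si = NULL) {
  spectrum_tbl(f, re, eps_imag = im, sigma_real = sr, sigma_imag = si)
}

test_that("differences are antisymmetric with symmetric error propagation", {
  f <- freq_grid(0.1e9, 14e9, 20)
  a <- make_spec(f, runif(20, 60, 70), runif(20, 0, 30), 3, 3)
  b <- make_spec(f, runif(20, 60, 70), runif(20, 0, 30), 4, 4)
  ab <- spectrum_difference(a, b)
  ba <- spectrum_difference(b, a)
  expect_equal(ab$d_real, -ba$d_real)
  expect_equal(ab$d_imag, -ba$d_imag)
  expect_equal(ab$sigma_real, ba$sigma_real)
  expect_equal(ab$sigma_real, rep(5, 20)) # 3-4-5
  same <- spectrum_difference(a, a)
  expect_true(all(same$d_real == 0))
  expect_equal(same$sigma_imag, rep(sqrt(2) * 3, 20))
})

test_that("band statistics summarise constant and localised differences", {
  f <- seq(0.2e9, 9.5e9, by = 0.01e9)
  n <- length(f)
  const <- tibble::tibble(frequency_hz = f, d_real = rep(2.5, n),
                          d_imag = rep(2.5, n))
  st <- band_statistics(const, "real")
  expect_equal(st$l_mean, 2.5)
  expect_equal(st$h_mean, 2.5)
  expect_equal(st$p_height, 0)
  zero <- tibble::tibble(frequency_hz = f, d_real = rep(0, n),
                         d_imag = rep(0, n))
  st0 <- band_statistics(zero, "imaginary")
  expect_true(all(c(st0$l_mean, st0$h_mean, st0$p_height) == 0))
  bump <- tibble::tibble(frequency_hz = f,
                         d_real = 1.7 * exp(-((f - 7e9) / 0.1e9)^2),
                         d_imag = rep(0, n))
  stb <- band_statistics(bump, "real")
  expect_equal(stb$p_height, 1.7, tolerance = 1e-6)
  # insufficient coverage is refused
  short_grid <- tibble::tibble(frequency_hz = f[f < 5e9],
                               d_real = 0, d_imag = 0)
  expect_error(band_statistics(short_grid, "real"), "0.3-9 GHz")
})

test_that("band means are linear and the peak scales with positive factors", {
  set.seed(3)
  f <- seq(0.2e9, 9.5e9, by = 0.02e9)
  n <- length(f)
  d1 <- tibble::tibble(frequency_hz = f, d_real = rnorm(n), d_imag = rnorm(n))
  d2 <- tibble::tibble(frequency_hz = f, d_real = rnorm(n), d_imag = rnorm(n))
  comb <- tibble::tibble(frequency_hz = f,
                         d_real = 2 * d1$d_real - 3 * d2$d_real,
                         d_imag = 2 * d1$d_imag - 3 * d2$d_imag)
  s1 <- band_statistics(d1, "real"); s2 <- band_statistics(d2, "real")
  sc <- band_statistics(comb, "real")
  expect_equal(sc$l_mean, 2 * s1$l_mean - 3 * s2$l_mean)
  expect_equal(sc$h_mean, 2 * s1$h_mean - 3 * s2$h_mean)
  pos <- tibble::tibble(frequency_hz = f, d_real = 4 * d1$d_real,
                        d_imag = d1$d_imag)
  expect_equal(band_statistics(pos, "real")$p_height, 4 * s1$p_height)
})

test_that("correlation reports the Pearson line and rejects degeneracies", {
  d <- data.frame(p = c(1, 2, 3, 4), l = c(2, 4, 6, 8))
  out <- correlate_bands(d, "p", "l")
  expect_equal(out$r, 1)
  expect_equal(out$slope, 0.5)
  expect_equal(out$intercept, 0)
  set.seed(8)
  big <- data.frame(p = rnorm(4000), l = rnorm(4000))
  expect_lt(abs(correlate_bands(big, "p", "l")$r), 0.05)
  expect_error(correlate_bands(data.frame(p = 1:3, l = rep(1, 3)), "p", "l"),
               "zero variance")
  expect_error(correlate_bands(data.frame(p = 1:2, l = 1:2), "p", "l"),
               "at least 3")
})

test_that("solute subtraction and renormalisation invert the mixture", {
  f <- freq_grid(0.3e12, 2.5e12, 40)
  water <- make_spec(f, rep(0, 40), runif(40, 1, 10))
  solute <- make_spec(f, rep(0, 40), runif(40, 0.1, 0.5))
  raw <- make_spec(f, rep(0, 40),
                   solute$eps_imag + 0.714 * water$eps_imag,
                   sr = 0.0714, si = 0.0714)
  out <- subtract_solute(raw, solute, 0.714)
  expect_equal(out$eps_imag, water$eps_imag, tolerance = 1e-12)
  expect_equal(out$sigma_imag, rep(0.1, 40), tolerance = 1e-12)
  ident <- subtract_solute(water, make_spec(f, rep(0, 40), rep(0, 40)), 1)
  expect_equal(ident$eps_imag, water$eps_imag)
  expect_error(subtract_solute(raw, solute, 0), "water_fraction")
  expect_error(subtract_solute(raw, solute, 1.2), "water_fraction")
})

test_that("the moving average smooths a step as computed by hand", {
  x <- c(0, 0, 0, 1, 1, 1)
  expect_equal(moving_average(x, 3), c(0, 0, 1 / 3, 2 / 3, 1, 1))
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(rep(4, 10), 5), rep(4, 10))
  expect_error(moving_average(x, 4), "odd")
})
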