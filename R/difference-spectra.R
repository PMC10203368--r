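#' Time-lapse difference spectra
#'
#' Subtracting a reference-time spectrum from a later one isolates the slow
#' spectral changes; per-point uncertainties are propagated as
#' `sqrt(sigma_A^2 + sigma_B^2)`.
#'
#' @param a,b spectrum tibbles on identical grids; the result is `a - b`.
#' @return a tibble with columns `frequency_hz`, `d_real`, `d_imag`, and
#'   `sigma_real`/`sigma_imag` when both inputs carry uncertainties.
#' @export
spectrum_difference <- function(a, b) {
  check_spectrum(a); check_spectrum(b)
  stop_if_grid_mismatch(a, b)
  out <- tibble::tibble(frequency_hz = a$frequency_hz,
                        d_real = a$eps_real - b$eps_real,
                        d_imag = a$eps_imag - b$eps_imag)
  if (all(c("sigma_real", "sigma_imag") %in% names(a)) &&
      all(c("sigma_real", "sigma_imag") %in% names(b))) {
    out$sigma_real <- sqrt(a$sigma_real^2 + b$sigma_real^2)
    out$sigma_imag <- sqrt(a$sigma_imag^2 + b$sigma_imag^2)
  }
  out
}

#' Band statistics of a difference spectrum
#'
#' Summarises a difference spectrum by the unweighted means over a low
#' (`L`, 0.3-3 GHz) and a high (`H`, 3-6.5 GHz) band, plus the
#' background-subtracted peak height `P` near the standing-wave resonance.
#' The background is the mean over 4-5 GHz; the peak is the maximum within
#' 6.5-7.5 GHz for the real part and 7.5-8.5 GHz for the imaginary part.
#' `p_bar` is the frequency-averaged background-subtracted signal over the
#' same peak window.
#'
#' @param d a difference tibble from [spectrum_difference()].
#' @param part `"real"` or `"imaginary"`.
#' @param l_band,h_band,bg_band band limits in Hz.
#' @param peak_band peak search window in Hz; defaults to 6.5-7.5 GHz
#'   (real) or 7.5-8.5 GHz (imaginary).
#' @return one-row tibble with `part`, `l_mean`, `h_mean`, `p_height`,
#'   `p_bar`.
#' @export
band_statistics <- function(d, part = c("real", "imaginary"),
                            l_band = c(0.3e9, 3e9), h_band = c(3e9, 6.5e9),
                            bg_band = c(4e9, 5e9), peak_band = NULL) {
  part <- match.arg(part)
  stopifnot(is.data.frame(d),
            all(c("frequency_hz", "d_real", "d_imag") %in% names(d)))
  f <- d$frequency_hz
  if (min(f) > l_band[1] || max(f) < 8.5e9) {
    stop("grid must cover 0.3-9 GHz for band statistics", call. = FALSE)
  }
  y <- if (part == "real") d$d_real else d$d_imag
  if (is.null(peak_band)) {
    peak_band <- if (part == "real") c(6.5e9, 7.5e9) else c(7.5e9, 8.5e9)
  }
  in_band <- function(b) y[f >= b[1] & f <= b[2]]
  bg <- mean(in_band(bg_band))
  pk <- in_band(peak_band)
  tibble::tibble(part = part,
                 l_mean = mean(in_band(l_band)),
                 h_mean = mean(in_band(h_band)),
                 p_height = max(pk) - bg,
                 p_bar = mean(pk) - bg)
}

#' Pearson correlation with a least-squares line
#'
#' Correlates a response (e.g. the frequency-averaged peak height of each
#' condition) with a predictor (e.g. the low-band mean), returning the
#' correlation coefficient and the fitted line.
#'
#' @param data a data frame.
#' @param response,predictor column names (strings) in `data`.
#' @return one-row tibble with `r`, `slope`, `intercept`, `n`.
#' @export
correlate_bands <- function(data, response, predictor) {
  stopifnot(is.data.frame(data), response %in% names(data),
            predictor %in% names(data))
  y <- data[[response]]; x <- data[[predictor]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  tibble::tibble(r = stats::cor(x, y),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(x))
}

#' Remove the solute contribution and renormalise to the water fraction
#'
#' `(raw - solute_ref) / water_fraction`, with any `sigma` columns scaled by
#' `1 / water_fraction`.  Used on THz-TDS loss spectra, where the solute's
#' underdamped vibrational spectrum is subtracted before comparing the
#' remaining water response with pure water.
#'
#' @param raw,solute_ref spectrum tibbles on a common grid.
#' @param water_fraction mass fraction of water in (0, 1].
#' @return a spectrum tibble for the water component.
#' @export
subtract_solute <- function(raw, solute_ref, water_fraction = 0.714) {
  check_spectrum(raw); check_spectrum(solute_ref)
  stop_if_grid_mismatch(raw, solute_ref)
  if (water_fraction <= 0 || water_fraction > 1) {
    stop("water_fraction must be in (0, 1]", call. = FALSE)
  }
  out <- tibble::tibble(
    frequency_hz = raw$frequency_hz,
    eps_real = (raw$eps_real - solute_ref$eps_real) / water_fraction,
    eps_imag = (raw$eps_imag - solute_ref$eps_imag) / water_fraction)
  for (s in c("sigma_real", "sigma_imag")) {
    if (s %in% names(raw)) out[[s]] <- raw[[s]] / water_fraction
  }
  out
}

#' Centred moving average with edge truncation
#'
#' @param x numeric series.
#' @param window odd window length (>= 1); near the edges the window is
#'   truncated to the available points.
#' @return smoothed series, same length as `x`.
#' @export
moving_average <- function(x, window = 11) {
  stopifnot(is.numeric(x), window >= 1)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}
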