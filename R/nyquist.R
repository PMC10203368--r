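#' Nyquist semicircle fit of the slow-water dispersion
#'
#' A single Debye dispersion traces a semicircle in the Nyquist plane
#' (`eps''` against `eps'`) centred on the real axis at
#' `(eps_s + eps_inf)/2` with radius `(eps_s - eps_inf)/2`.  Fitting that
#' circle to the measured band and extrapolating to the real axis yields the
#' apparent static and high-frequency limits of the slow bulk-water
#' relaxation, `eps_gamma1_s = center + radius` and
#' `eps_gamma1_inf = center - radius`, without any multi-dispersion fit.
#'
#' The fit is an algebraic least-squares circle (Kasa form) with the centre
#' ordinate constrained to zero: writing
#' `x^2 + y^2 = 2 a x + (r^2 - a^2)` the problem is linear in `a` and
#' `r^2 - a^2` and is solved in closed form.  It is exact on noiseless Debye
#' data and deterministic; no iterative refinement is applied.
#'
#' @param spec spectrum tibble.
#' @param band two-element numeric, the frequency interval (Hz) used for the
#'   fit.  Default 0.1-14 GHz.
#' @param min_points minimum number of in-band points (a real-axis-centred
#'   circle needs three for redundancy).
#' @return an object of class `semicircle_fit` with elements `center_real`,
#'   `radius`, `eps_gamma1_s`, `eps_gamma1_inf`, `fit_band`, `n_points`,
#'   `rmse`, and the in-band `data`.
#' @examples
#' f <- freq_grid(1e8, 14e9, 50)
#' m <- relaxation_model(data.frame(label = "gamma1", strength = 71.06,
#'                                  tau_s = 5.88e-11), eps_inf_relax = 5.49)
#' fit <- fit_semicircle(eval_model(m, f))
#' glance(fit)
#' @export
fit_semicircle <- function(spec, band = c(1e8, 14e9), min_points = 3) {
  check_spectrum(spec)
  stopifnot(length(band) == 2, band[1] < band[2])
  keep <- spec$frequency_hz >= band[1] & spec$frequency_hz <= band[2] &
    is.finite(spec$eps_real) & is.finite(spec$eps_imag)
  d <- spec[keep, , drop = FALSE]
  if (nrow(d) < min_points) {
    stop("insufficient points in fit band (", nrow(d), " < ", min_points, ")",
         call. = FALSE)
  }
  if (all(d$eps_imag <= 0)) {
    stop("no positive loss in fit band; cannot fit a semicircle",
         call. = FALSE)
  }
  x <- d$eps_real; y <- d$eps_imag
  # linear LS for (a, c) in x^2 + y^2 = 2 a x + c, with c = r^2 - a^2
  sx <- sum(x); sxx <- sum(x^2); n <- length(x)
  z <- x^2 + y^2
  det <- 4 * sxx * n - 4 * sx^2
  if (abs(det) < 1e-14 * max(1, sxx * n)) {
    stop("degenerate (collinear) data; radius solve failed", call. = FALSE)
  }
  a <- (n * 2 * sum(x * z) - 2 * sx * sum(z)) / det
  cc <- (sum(z) - 2 * a * sx) / n
  r2 <- cc + a^2
  if (!is.finite(r2) || r2 <= 0) {
    stop("degenerate data; radius solve failed", call. = FALSE)
  }
  r <- sqrt(r2)
  resid <- r - sqrt((x - a)^2 + y^2)
  structure(list(center_real = a, radius = r,
                 eps_gamma1_s = a + r, eps_gamma1_inf = a - r,
                 fit_band = as.numeric(band), n_points = n,
                 rmse = sqrt(mean(resid^2)), data = d),
            class = "semicircle_fit")
}

#' @export
print.semicircle_fit <- function(x, ...) {
  cat("<semicircle_fit>\n")
  cat(sprintf("  center %.4f, radius %.4f  (n = %d, rmse %.3g)\n",
              x$center_real, x$radius, x$n_points, x$rmse))
  cat(sprintf("  eps_gamma1(s) = %.4f, eps_gamma1(inf) = %.4f\n",
              x$eps_gamma1_s, x$eps_gamma1_inf))
  invisible(x)
}

#' @rdname fit_semicircle
#' @param x a `semicircle_fit`.
#' @param ... unused.
#' @export
tidy.semicircle_fit <- function(x, ...) {
  tibble::tibble(
    term = c("center_real", "radius", "eps_gamma1_s", "eps_gamma1_inf"),
    estimate = c(x$center_real, x$radius, x$eps_gamma1_s, x$eps_gamma1_inf))
}

#' @rdname fit_semicircle
#' @export
glance.semicircle_fit <- function(x, ...) {
  tibble::tibble(center_real = x$center_real, radius = x$radius,
                 eps_gamma1_s = x$eps_gamma1_s,
                 eps_gamma1_inf = x$eps_gamma1_inf,
                 n_points = x$n_points, rmse = x$rmse)
}

#' Nyquist plot of a semicircle fit
#'
#' @param object a `semicircle_fit`.
#' @param ... unused.
#' @return a ggplot: measured points and the fitted circle.
#' @export
autoplot.semicircle_fit <- function(object, ...) {
  th <- seq(0, pi, length.out = 181)
  circ <- tibble::tibble(eps_real = object$center_real +
                           object$radius * cos(th),
                         eps_imag = object$radius * sin(th))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$eps_real, y = .data$eps_imag)) +
    ggplot2::geom_path(data = circ, colour = "grey50", linetype = 2) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ε'", y = "ε''",
                  title = "Nyquist plot with fitted semicircle")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Relaxation frequency from the circumferential-angle tangent
#'
#' For points on a Debye semicircle the inscribed-angle identity gives
#' `eps'' / (eps' - eps_gamma1_inf) = omega tau`, so each in-band point
#' supplies an estimate of `omega tau`.  `tau` is obtained by least squares
#' of those estimates against `omega` (the slope through the origin), and
#' the relaxation frequency is `f_c = 1 / (2 pi tau)`.  At the semicircle
#' vertex the tangent equals 1.
#'
#' @param spec spectrum tibble.
#' @param fit a [fit_semicircle()] result.
#' @param band frequency interval used (defaults to the fit band).
#' @return relaxation frequency `f_c` in Hz.
#' @export
relaxation_frequency <- function(spec, fit, band = fit$fit_band) {
  check_spectrum(spec)
  stopifnot(inherits(fit, "semicircle_fit"))
  keep <- spec$frequency_hz >= band[1] & spec$frequency_hz <= band[2] &
    is.finite(spec$eps_real) & is.finite(spec$eps_imag) &
    spec$eps_real > fit$eps_gamma1_inf
  d <- spec[keep, , drop = FALSE]
  if (nrow(d) == 0) {
    stop("no points with eps' above eps_gamma1_inf; cannot estimate f_c",
         call. = FALSE)
  }
  w <- 2 * pi * d$frequency_hz
  wt_est <- d$eps_imag / (d$eps_real - fit$eps_gamma1_inf)
  tau <- sum(w * wt_est) / sum(w^2)
  if (tau <= 0) stop("nonpositive tau estimate", call. = FALSE)
  1 / (2 * pi * tau)
}

#' Deviation of a spectrum from the fitted Debye semicircle
#'
#' `delta_r(f) = r - |(eps'(f), eps''(f)) - (center, 0)|`: the radial
#' distance by which each measured point falls *inside* the fitted circle.
#' Inward deformation is positive, so a decrease in sample permittivity
#' (which pulls the standing-wave resonance across the band) produces a
#' positive excursion.
#'
#' @param spec spectrum tibble.
#' @param fit a [fit_semicircle()] result.
#' @return a tibble with columns `frequency_hz`, `delta_r`.
#' @export
compute_delta_r <- function(spec, fit) {
  check_spectrum(spec)
  stopifnot(inherits(fit, "semicircle_fit"))
  dr <- fit$radius -
    sqrt((spec$eps_real - fit$center_real)^2 + spec$eps_imag^2)
  tibble::tibble(frequency_hz = spec$frequency_hz, delta_r = dr)
}

#' Baseline-subtracted peak of a delta-r spectrum
#'
#' Finds the maximum of `delta_r` in the search band (ties broken toward the
#' lower frequency), then estimates a baseline as the mean of `delta_r` over
#' the 1-GHz flanking windows on both sides of the peak, excluding the
#' peak's half-height support so that broad shoulders do not bias the
#' baseline.  The reported height is `delta_r(f_peak) - baseline`.
#'
#' @param dr a delta-r tibble from [compute_delta_r()].
#' @param search_band two-element numeric interval (Hz), default 6-10 GHz.
#' @param flank_hz width of each flanking baseline window (default 1 GHz).
#' @return one-row tibble with `f_peak_hz`, `height`, `baseline`.
#' @export
detect_peak <- function(dr, search_band = c(6e9, 10e9), flank_hz = 1e9) {
  stopifnot(is.data.frame(dr),
            all(c("frequency_hz", "delta_r") %in% names(dr)))
  check_grid(dr$frequency_hz)
  f <- dr$frequency_hz; y <- dr$delta_r
  if (search_band[1] - flank_hz < min(f) || search_band[2] + flank_hz > max(f)) {
    stop("search band too close to the data edge for flanking windows",
         call. = FALSE)
  }
  in_band <- which(f >= search_band[1] & f <= search_band[2])
  if (!length(in_band)) stop("no points in search band", call. = FALSE)
  ipk <- in_band[which.max(y[in_band])] # which.max -> first = lowest f
  f_pk <- f[ipk]; v_pk <- y[ipk]
  flank <- which(f >= f_pk - flank_hz & f <= f_pk + flank_hz & f != f_pk)
  base0 <- mean(y[flank])
  half <- (v_pk + base0) / 2
  # contiguous half-height support around the peak (strict, so a flat
  # spectrum has an empty support beyond the peak itself)
  sup <- ipk
  i <- ipk - 1L
  while (i >= 1 && y[i] > half) { sup <- c(i, sup); i <- i - 1L }
  i <- ipk + 1L
  while (i <= length(y) && y[i] > half) { sup <- c(sup, i); i <- i + 1L }
  flank_kept <- setdiff(flank, sup)
  baseline <- if (length(flank_kept)) mean(y[flank_kept]) else base0
  tibble::tibble(f_peak_hz = f_pk, height = v_pk - baseline,
                 baseline = baseline)
}

#' Plot a delta-r spectrum with its detected peak
#'
#' @param dr delta-r tibble.
#' @param peak optional one-row tibble from [detect_peak()].
#' @return a ggplot.
#' @export
plot_delta_r <- function(dr, peak = NULL) {
  p <- ggplot2::ggplot(dr, ggplot2::aes(x = .data$frequency_hz / 1e9,
                                        y = .data$delta_r)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (GHz)", y = expression(Delta * r))
  if (!is.null(peak)) {
    p <- p + ggplot2::geom_vline(xintercept = peak$f_peak_hz / 1e9,
                                 colour = "red", linetype = 2)
  }
  p
}
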