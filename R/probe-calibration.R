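#' Open/Short/Standard probe calibration
#'
#' An open-ended coaxial probe maps sample permittivity to the measured
#' reflection coefficient through a bilinear (Moebius) transformation.  Three
#' reference measurements pin the map down: Open (air, `eps = 1`), Short
#' (`eps -> Inf`), and a Standard of known complex permittivity `eps_a*`.
#' The unknown permittivity then follows per frequency from
#' \deqn{\varepsilon_m^* = \frac{\varepsilon_a^* (S_m - S_o)(S_s - S_a) +
#'   (S_m - S_a)(S_o - S_s)}{(S_m - S_s)(S_o - S_a)}.}
#' Because the expression is a cross-ratio it inverts *any* bilinear forward
#' map exactly, whatever the physical probe details.
#'
#' In time-lapse work the Standard can be the same specimen measured at a
#' reference time point with a modelled `eps_a*`; later measurements of the
#' same sample are then referenced to that state, cancelling probe and
#' geometry drift.
#'
#' @param open_rec,short_rec,standard_rec reflection tibbles
#'   (`frequency_hz`, `s11`) on a common grid.
#' @param standard_eps spectrum tibble of the Standard's known permittivity
#'   on the same grid.
#' @param degeneracy_tol minimum pairwise separation of the three anchors in
#'   the S plane (absolute).
#' @return a `calibration_set` object.
#' @export
calibration_set <- function(open_rec, short_rec, standard_rec, standard_eps,
                            degeneracy_tol = 1e-9) {
  check_reflection(open_rec)
  check_reflection(short_rec)
  check_reflection(standard_rec)
  check_spectrum(standard_eps)
  stop_if_grid_mismatch(open_rec, short_rec)
  stop_if_grid_mismatch(open_rec, standard_rec)
  stop_if_grid_mismatch(open_rec, standard_eps)
  so <- open_rec$s11; ss <- short_rec$s11; sa <- standard_rec$s11
  sep <- pmin(Mod(so - ss), Mod(so - sa), Mod(ss - sa))
  if (any(sep <= degeneracy_tol)) {
    f_bad <- open_rec$frequency_hz[which(sep <= degeneracy_tol)[1]]
    stop(sprintf("degenerate calibration anchors at %.6g Hz", f_bad),
         call. = FALSE)
  }
  structure(list(open_rec = open_rec, short_rec = short_rec,
                 standard_rec = standard_rec, standard_eps = standard_eps,
                 degeneracy_tol = degeneracy_tol),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  f <- x$open_rec$frequency_hz
  cat("<calibration_set>", length(f), "frequencies,",
      format(min(f)), "-", format(max(f)), "Hz\n")
  invisible(x)
}

#' Convert measured reflection to complex permittivity
#'
#' Applies the Open/Short/Standard bilinear inversion per frequency.  Points
#' where the measured reflection coincides with the Short anchor (the
#' `eps -> Inf` limit) are flagged invalid (`NA`) rather than returned, with
#' a warning.
#'
#' @param cal a [calibration_set()].
#' @param measured reflection tibble on the calibration grid.
#' @param short_tol relative tolerance for flagging `S_m ~ S_s` divergences.
#' @return a spectrum tibble; diverging points carry `NA` in `eps_real`
#'   and `eps_imag`.
#' @examples
#' f <- freq_grid(1e9, 10e9, 11)
#' s_of_eps <- function(eps) (eps - 10) / (eps + 10)
#' cal <- calibration_set(
#'   reflection_tbl(f, rep(s_of_eps(1 + 0i), 11)),
#'   reflection_tbl(f, rep(1 + 0i, 11)),
#'   reflection_tbl(f, rep(s_of_eps(80 + 0i), 11)),
#'   spectrum_tbl(f, rep(80 + 0i, 11)))
#' calibrate_osm(cal, reflection_tbl(f, rep(s_of_eps(40 + 0i), 11)))
#' @export
calibrate_osm <- function(cal, measured, short_tol = 1e-12) {
  stopifnot(inherits(cal, "calibration_set"))
  check_reflection(measured)
  stop_if_grid_mismatch(cal$open_rec, measured)
  so <- cal$open_rec$s11; ss <- cal$short_rec$s11
  sa <- cal$standard_rec$s11; sm <- measured$s11
  ea <- spectrum_complex(cal$standard_eps)
  bad <- Mod(sm - ss) <= short_tol * pmax(Mod(sm), Mod(ss), 1)
  num <- ea * (sm - so) * (ss - sa) + (sm - sa) * (so - ss)
  den <- (sm - ss) * (so - sa)
  em <- num / den
  if (any(bad)) {
    warning(sum(bad), " point(s) at the Short limit flagged invalid")
    em[bad] <- NA_complex_
  }
  spectrum_tbl(measured$frequency_hz, em)
}

#' Forward reflection map of a calibrated probe
#'
#' The exact inverse of [calibrate_osm()]: evaluates the Moebius map fixed by
#' the anchors (`eps = 1 -> S_o`, `eps -> Inf -> S_s`, `eps_a -> S_a`) at a
#' given permittivity spectrum.  Used to synthesise reflection data;
#' `calibrate_osm(cal, forward_reflection(cal, eps))` is the identity.
#'
#' @param cal a [calibration_set()].
#' @param eps spectrum tibble on the calibration grid.
#' @return a reflection tibble.
#' @export
forward_reflection <- function(cal, eps) {
  stopifnot(inherits(cal, "calibration_set"))
  check_spectrum(eps)
  stop_if_grid_mismatch(cal$open_rec, eps)
  so <- cal$open_rec$s11; ss <- cal$short_rec$s11; sa <- cal$standard_rec$s11
  ea <- spectrum_complex(cal$standard_eps)
  em <- spectrum_complex(eps)
  # Solve the bilinear relation for S_m:
  #   em (S_m - S_s)(S_o - S_a) = ea (S_m - S_o)(S_s - S_a) + (S_m - S_a)(S_o - S_s)
  den <- em * (so - sa) - ea * (ss - sa) - (so - ss)
  num <- em * ss * (so - sa) - ea * so * (ss - sa) - sa * (so - ss)
  reflection_tbl(eps$frequency_hz, num / den)
}

#' Synthetic probe reflection map
#'
#' A simple physical stand-in for an open-ended probe immersed in a sample:
#' `S(eps) = (1 - g eps) / (1 + g eps)` with a real admittance-like constant
#' `g`.  For `g > 0` it maps passive permittivities (`Re eps > 0`) into the
#' unit disc.  The default `g = 1/76` puts the map near its maximum
#' sensitivity for aqueous samples.
#'
#' @param eps complex permittivity values.
#' @param g probe constant (> 0).
#' @return complex reflection coefficients.
#' @export
probe_map <- function(eps, g = 1 / 76) {
  stopifnot(g > 0)
  (1 - g * eps) / (1 + g * eps)
}

#' Build a calibration set from the synthetic probe map
#'
#' Convenience constructor for simulation work: Open/Short anchors from
#' [probe_map()] at `eps = 1` and `eps -> Inf` (`S = -1`), Standard from a
#' supplied known spectrum.
#'
#' @param standard_eps spectrum tibble of the Standard permittivity.
#' @param g probe constant passed to [probe_map()].
#' @param standard_s11 optional measured Standard reflections (same grid);
#'   when given these override the ideal `probe_map` values — the
#'   same-sample time-lapse mode, where the Standard record is the specimen's
#'   own reference-time measurement.
#' @return a [calibration_set()].
#' @export
synthetic_calibration <- function(standard_eps, g = 1 / 76,
                                  standard_s11 = NULL) {
  check_spectrum(standard_eps)
  f <- standard_eps$frequency_hz
  open_rec <- reflection_tbl(f, probe_map(rep(1 + 0i, length(f)), g))
  short_rec <- reflection_tbl(f, rep(-1 + 0i, length(f)))
  std <- if (is.null(standard_s11)) {
    reflection_tbl(f, probe_map(spectrum_complex(standard_eps), g))
  } else {
    check_reflection(standard_s11)
    standard_s11
  }
  calibration_set(open_rec, short_rec, std, standard_eps)
}
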