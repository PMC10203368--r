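#' Frequency grids and spectrum tables
#'
#' The package's central currency is a *permittivity spectrum*: a tibble with
#' columns `frequency_hz`, `eps_real`, `eps_imag` and (optionally) per-point
#' standard deviations `sigma_real`, `sigma_imag`.  The sign convention
#' throughout is `eps* = eps' - i eps''` with the loss `eps''` stored as a
#' positive number, so Nyquist plots show the loss upward.  Reflection data
#' are tibbles with columns `frequency_hz` and a complex `s11`.
#'
#' @param from,to band limits in Hz; both must be positive.
#' @param n number of points (>= 2).
#' @param spacing `"log"` (default) or `"linear"`.
#' @return `freq_grid()` returns a strictly increasing numeric vector of
#'   frequencies in Hz.
#' @examples
#' f <- freq_grid(1e8, 14e9, n = 201)
#' head(f)
#' @export
freq_grid <- function(from, to, n = 201, spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  stopifnot(is.numeric(from), is.numeric(to), from > 0, to > from, n >= 2)
  if (spacing == "log") {
    exp(seq(log(from), log(to), length.out = n))
  } else {
    seq(from, to, length.out = n)
  }
}

check_grid <- function(frequency_hz, what = "frequency grid") {
  if (!is.numeric(frequency_hz) || length(frequency_hz) < 1 ||
      any(!is.finite(frequency_hz)) || any(frequency_hz <= 0)) {
    stop(what, " must be finite and positive", call. = FALSE)
  }
  if (is.unsorted(frequency_hz, strictly = TRUE)) {
    stop(what, " must be strictly increasing", call. = FALSE)
  }
  invisible(frequency_hz)
}

#' Assemble a permittivity spectrum tibble
#'
#' @param frequency_hz strictly increasing positive frequencies (Hz).
#' @param eps complex permittivity values `eps' - i eps''`, or a real vector
#'   when `eps_imag` is given separately.
#' @param eps_imag optional positive loss values when `eps` is real.
#' @param sigma_real,sigma_imag optional per-point standard deviations.
#' @return a tibble with columns `frequency_hz`, `eps_real`, `eps_imag`
#'   (and sigma columns when supplied).
#' @export
spectrum_tbl <- function(frequency_hz, eps, eps_imag = NULL,
                         sigma_real = NULL, sigma_imag = NULL) {
  check_grid(frequency_hz)
  if (is.complex(eps)) {
    er <- Re(eps)
    ei <- -Im(eps) # eps* = eps' - i eps''
  } else {
    er <- as.numeric(eps)
    ei <- if (is.null(eps_imag)) rep(0, length(er)) else as.numeric(eps_imag)
  }
  stopifnot(length(er) == length(frequency_hz), length(ei) == length(er))
  out <- tibble::tibble(frequency_hz = as.numeric(frequency_hz),
                        eps_real = er, eps_imag = ei)
  if (!is.null(sigma_real)) out$sigma_real <- rep_len(sigma_real, nrow(out))
  if (!is.null(sigma_imag)) out$sigma_imag <- rep_len(sigma_imag, nrow(out))
  out
}

check_spectrum <- function(spec) {
  need <- c("frequency_hz", "eps_real", "eps_imag")
  if (!is.data.frame(spec) || !all(need %in% names(spec))) {
    stop("spectrum must have columns frequency_hz, eps_real, eps_imag",
         call. = FALSE)
  }
  check_grid(spec$frequency_hz)
  invisible(spec)
}

#' Extract the complex permittivity from a spectrum tibble
#'
#' @param spec a spectrum tibble (see [spectrum_tbl()]).
#' @return complex vector `eps' - i eps''`.
#' @export
spectrum_complex <- function(spec) {
  check_spectrum(spec)
  complex(real = spec$eps_real, imaginary = -spec$eps_imag)
}

#' Assemble a reflection record tibble
#'
#' @param frequency_hz strictly increasing positive frequencies (Hz).
#' @param s11 complex reflection coefficients.
#' @return a tibble with columns `frequency_hz`, `s11`.
#' @export
reflection_tbl <- function(frequency_hz, s11) {
  check_grid(frequency_hz)
  stopifnot(length(s11) == length(frequency_hz))
  tibble::tibble(frequency_hz = as.numeric(frequency_hz),
                 s11 = as.complex(s11))
}

check_reflection <- function(rec) {
  if (!is.data.frame(rec) || !all(c("frequency_hz", "s11") %in% names(rec))) {
    stop("reflection record must have columns frequency_hz, s11",
         call. = FALSE)
  }
  check_grid(rec$frequency_hz)
  invisible(rec)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$frequency_hz) == length(b$frequency_hz) &&
    all(abs(a$frequency_hz - b$frequency_hz) <=
          tol * pmax(a$frequency_hz, b$frequency_hz))
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("inputs are not on a common frequency grid",
                             call. = FALSE)
  invisible(TRUE)
}
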