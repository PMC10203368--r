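#' Multi-Debye relaxation models
#'
#' A protein solution in the MHz-GHz band is described as a sum of Debye
#' dispersions: a protein tumbling term (`beta`, ~10 MHz), two hydration-water
#' terms (`delta1` ~0.1 GHz, `delta2` ~4 GHz), and slow/fast bulk-water terms
#' (`gamma1` ~20 GHz, `gamma2` sub-THz),
#' \deqn{\varepsilon^*(\omega) = \varepsilon(\infty)_{relax} +
#'   \sum_x \frac{\Delta\varepsilon_x}{1 + i\omega\tau_x},}
#' with the convention \eqn{\varepsilon^* = \varepsilon' - i\varepsilon''}
#' and the loss stored positive.  `eps_inf_relax` is the apparent
#' high-frequency limit of the Debye part; it lumps all vibrational strengths
#' and the true high-frequency limit, `eps_inf_relax = sum(vib) + eps_inf`.
#'
#' @param components a data frame with columns `label` (one of `beta`,
#'   `delta1`, `delta2`, `gamma1`, `gamma2`), `strength` (relaxation strength,
#'   dimensionless, > 0) and `tau_s` (relaxation time, seconds, > 0).
#' @param eps_inf_relax apparent high-frequency limit (>= 1).
#' @param vib_strengths optional vector of vibrational strengths; when given,
#'   the true `eps_inf` is derived as `eps_inf_relax - sum(vib_strengths)`.
#' @return an object of class `relaxation_model`.
#' @examples
#' m <- relaxation_model(
#'   components = data.frame(label = "gamma1", strength = 63.31,
#'                           tau_s = 5.88e-11),
#'   eps_inf_relax = 5.28)
#' static_permittivity(m)
#' @export
relaxation_model <- function(components = NULL, eps_inf_relax = 1,
                             vib_strengths = NULL) {
  labels <- c("beta", "delta1", "delta2", "gamma1", "gamma2")
  if (is.null(components)) {
    components <- tibble::tibble(label = character(), strength = numeric(),
                                 tau_s = numeric())
  }
  components <- tibble::as_tibble(components)
  stopifnot(all(c("label", "strength", "tau_s") %in% names(components)))
  if (!all(components$label %in% labels)) {
    stop("component labels must be one of: ", paste(labels, collapse = ", "),
         call. = FALSE)
  }
  if (any(components$strength <= 0) || any(components$tau_s <= 0)) {
    stop("component strengths and relaxation times must be positive",
         call. = FALSE)
  }
  if (eps_inf_relax < 1) stop("eps_inf_relax must be >= 1", call. = FALSE)
  eps_inf <- if (is.null(vib_strengths)) NA_real_ else
    eps_inf_relax - sum(vib_strengths)
  structure(list(components = components,
                 eps_inf_relax = as.numeric(eps_inf_relax),
                 vib_strengths = vib_strengths,
                 eps_inf = eps_inf),
            class = "relaxation_model")
}

#' @export
print.relaxation_model <- function(x, ...) {
  cat("<relaxation_model>\n")
  cat("  eps_inf_relax:", format(x$eps_inf_relax), "\n")
  cat("  static permittivity:", format(static_permittivity(x)), "\n")
  if (nrow(x$components)) print(x$components) else cat("  (no components)\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname relaxation_model
#' @param x a `relaxation_model`.
#' @param ... unused.
#' @export
tidy.relaxation_model <- function(x, ...) {
  dplyr::mutate(x$components, f_c_hz = 1 / (2 * pi * .data$tau_s))
}

#' Evaluate a single Debye dispersion term
#'
#' Computes \eqn{\Delta\varepsilon / (1 + i\omega\tau)} per frequency and
#' reports it with the loss positive:
#' \eqn{\varepsilon' = \Delta\varepsilon/(1+\omega^2\tau^2)},
#' \eqn{\varepsilon'' = \Delta\varepsilon\,\omega\tau/(1+\omega^2\tau^2)}.
#'
#' @param strength relaxation strength (> 0).
#' @param tau_s relaxation time in seconds (> 0).
#' @param frequency_hz frequencies in Hz.
#' @return a spectrum tibble of the component's contribution.
#' @export
eval_debye_component <- function(strength, tau_s, frequency_hz) {
  stopifnot(strength > 0, tau_s > 0)
  check_grid(frequency_hz)
  wt <- 2 * pi * frequency_hz * tau_s
  d <- 1 + wt^2
  spectrum_tbl(frequency_hz, strength / d, eps_imag = strength * wt / d)
}

#' Evaluate a relaxation model on a frequency grid
#'
#' Sums all Debye components and adds `eps_inf_relax` to the real part.
#'
#' @param model a [relaxation_model()].
#' @param frequency_hz frequencies in Hz.
#' @return a spectrum tibble.
#' @export
eval_model <- function(model, frequency_hz) {
  stopifnot(inherits(model, "relaxation_model"))
  check_grid(frequency_hz)
  er <- rep(model$eps_inf_relax, length(frequency_hz))
  ei <- rep(0, length(frequency_hz))
  for (i in seq_len(nrow(model$components))) {
    wt <- 2 * pi * frequency_hz * model$components$tau_s[i]
    d <- 1 + wt^2
    er <- er + model$components$strength[i] / d
    ei <- ei + model$components$strength[i] * wt / d
  }
  spectrum_tbl(frequency_hz, er, eps_imag = ei)
}

#' Static (zero-frequency) permittivity of a model
#'
#' The zero-frequency limit: the sum of all relaxation strengths plus the
#' apparent high-frequency limit.
#'
#' @inheritParams eval_model
#' @return a single number.
#' @export
static_permittivity <- function(model) {
  stopifnot(inherits(model, "relaxation_model"))
  sum(model$components$strength) + model$eps_inf_relax
}

#' Effective frequency limits of the slow bulk-water dispersion
#'
#' Because the slow bulk-water relaxation (`gamma1`) is well separated in
#' frequency from the protein and hydration terms, its apparent static and
#' high-frequency limits are
#' `eps_gamma1_s = strength(gamma1) + strength(gamma2) + eps_inf_relax` and
#' `eps_gamma1_inf = strength(gamma2) + eps_inf_relax`.
#'
#' @inheritParams eval_model
#' @return named list with `eps_gamma1_s` and `eps_gamma1_inf`.
#' @export
gamma1_effective_limits <- function(model) {
  stopifnot(inherits(model, "relaxation_model"))
  comp <- model$components
  g1 <- comp$strength[comp$label == "gamma1"]
  g2 <- comp$strength[comp$label == "gamma2"]
  if (length(g1) != 1 || length(g2) != 1) {
    stop("model must contain exactly one gamma1 and one gamma2 component",
         call. = FALSE)
  }
  list(eps_gamma1_s = g1 + g2 + model$eps_inf_relax,
       eps_gamma1_inf = g2 + model$eps_inf_relax)
}

#' Fast-water Debye loss curve
#'
#' The imaginary-part (loss) curve of a single fast-water (`gamma2`) mode,
#' \eqn{\Delta\varepsilon\,\omega\tau/(1+\omega^2\tau^2)}, peaking at
#' `f = 1/(2 pi tau)` with peak value `strength / 2`.
#'
#' @param strength relaxation strength (>= 0).
#' @param tau_s relaxation time in seconds (> 0).
#' @param frequency_hz frequencies in Hz.
#' @return a tibble with columns `frequency_hz`, `eps_imag`.
#' @export
gamma2_imag_mode <- function(strength, tau_s, frequency_hz) {
  stopifnot(strength >= 0, tau_s > 0)
  check_grid(frequency_hz)
  wt <- 2 * pi * frequency_hz * tau_s
  tibble::tibble(frequency_hz = as.numeric(frequency_hz),
                 eps_imag = strength * wt / (1 + wt^2))
}
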