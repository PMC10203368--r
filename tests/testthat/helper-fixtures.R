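# shared fixtures built in code

# exact single-Debye spectrum on the standard measurement band
debye_spectrum <- function(eps_s, eps_inf, tau_s, n = 201,
                           band = c(1e8, 14e9)) {
  m <- relaxation_model(
    data.frame(label = "gamma1", strength = eps_s - eps_inf, tau_s = tau_s),
    eps_inf_relax = eps_inf)
  eval_model(m, freq_grid(band[1], band[2], n))
}

# oracle bilinear probe: S(eps) = (eps - p) / (eps + p); Short limit is 1
oracle_cal <- function(f, p = 10, eps_a = 80 + 0i) {
  s_of <- function(eps) (eps - p) / (eps + p)
  n <- length(f)
  calibration_set(
    open_rec = reflection_tbl(f, rep(s_of(1 + 0i), n)),
    short_rec = reflection_tbl(f, rep(1 + 0i, n)),
    standard_rec = reflection_tbl(f, rep(s_of(eps_a), n)),
    standard_eps = spectrum_tbl(f, rep(eps_a, n)))
}

# random non-degenerate Moebius map coefficients
random_moebius <- function() {
  repeat {
    m <- matrix(complex(real = stats::rnorm(4), imaginary = stats::rnorm(4)),
                2, 2)
    if (Mod(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) > 0.1) return(m)
  }
}

apply_moebius <- function(m, s) (m[1, 1] * s + m[1, 2]) / (m[2, 1] * s + m[2, 2])

# small reduced configuration for fast structural tests
small_config <- function(...) {
  defaults <- list(conditions = c("GC", "THz"), times_min = c(18, 28),
                   n_replicates = 2, n_freq = 41)
  do.call(timelapse_config, utils::modifyList(defaults, list(...)))
}
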