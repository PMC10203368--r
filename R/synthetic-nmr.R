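#' Configuration of the synthetic NMR methyl experiment
#'
#' Encodes the pathway geometry of the time-lapse HSQC comparison: from the
#' common starting state (constant-temperature control at 3 h) the methyls
#' carry a latent displacement vector `d`; by 24 h the unperturbed sample
#' realises it in full, the irradiated sample has already realised most of
#' it at 3 h (`a_thz * d`), and the heated sample has moved the opposite
#' way (`-b_htc * d`).  By 24 h the irradiated and heated samples acquire
#' independent extra displacements, decorrelating their endpoints.
#'
#' @param a_thz fraction of the displacement realised by the irradiated
#'   sample at 3 h.
#' @param b_htc opposite-direction fraction for the heated sample at 3 h.
#' @param d_sd standard deviation of the latent per-methyl displacement.
#' @param noise_sd multiplicative (log-normal) measurement noise.
#' @param decouple_sd_24h sd of the independent 24-h displacements.
#' @param conc_sd log-normal spread of per-sample concentration factors.
#' @param base_meanlog,base_sdlog log-normal base intensity distribution.
#' @param n_excluded number of overlap-excluded methyls (default 4, leaving
#'   57 of lysozyme's 61 analysed).
#' @return an `nmr_config` list.
#' @export
nmr_config <- function(a_thz = 0.8, b_htc = 0.5, d_sd = 0.15,
                       noise_sd = 0.03, decouple_sd_24h = 0.1,
                       conc_sd = 0.05, base_meanlog = 0, base_sdlog = 0.3,
                       n_excluded = 4) {
  stopifnot(a_thz >= 0, b_htc >= 0, d_sd >= 0, noise_sd >= 0,
            n_excluded >= 0)
  structure(list(a_thz = a_thz, b_htc = b_htc, d_sd = d_sd,
                 noise_sd = noise_sd, decouple_sd_24h = decouple_sd_24h,
                 conc_sd = conc_sd, base_meanlog = base_meanlog,
                 base_sdlog = base_sdlog, n_excluded = n_excluded),
            class = "nmr_config")
}

#' Simulate a methyl intensity table
#'
#' Generates the full methyl table for conditions GC/THz/HTC at 3 h and
#' 24 h over the analysed methyls of the bundled lysozyme sequence
#' (61 AILMTV methyls minus the overlap-excluded set).  Per-sample
#' concentration factors are folded into both the raw intensities and the
#' 1H-1D integrals, so they cancel under [normalize_intensities()].
#'
#' @param config an [nmr_config()].
#' @param seed integer seed.
#' @param sequence amino-acid sequence (default the bundled lysozyme).
#' @return list with `table` (a methyl table, see
#'   [normalize_intensities()]), `excluded` (the overlap-excluded methyls)
#'   and `truth` (the latent displacement vector and sample factors).
#' @export
simulate_nmr_table <- function(config = nmr_config(), seed = 1,
                               sequence = lysozyme_sequence()) {
  stopifnot(inherits(config, "nmr_config"))
  set.seed(seed)
  methyls <- enumerate_methyls(sequence)
  n_all <- nrow(methyls)
  if (config$n_excluded > 0) {
    # deterministic stand-in for the unlisted overlap-excluded resonances:
    # evenly spaced entries of the enumeration
    excl_idx <- round(seq(1, n_all, length.out = config$n_excluded + 2))
    excl_idx <- excl_idx[-c(1, length(excl_idx))]
    excl_idx <- excl_idx[seq_len(config$n_excluded)]
  } else {
    excl_idx <- integer()
  }
  excluded <- methyls[excl_idx, , drop = FALSE]
  analyzed <- if (length(excl_idx)) methyls[-excl_idx, , drop = FALSE] else
    methyls
  n <- nrow(analyzed)
  base <- stats::rlnorm(n, config$base_meanlog, config$base_sdlog)
  d <- stats::rnorm(n, 0, config$d_sd)
  u24 <- stats::rnorm(n, 0, config$decouple_sd_24h)
  v24 <- stats::rnorm(n, 0, config$decouple_sd_24h)
  samples <- tibble::tibble(
    condition = rep(c("GC", "THz", "HTC"), each = 2),
    timepoint = rep(c("3h", "24h"), times = 3))
  clean <- list(
    `GC-3h` = base,
    `GC-24h` = base * (1 + d),
    `THz-3h` = base * (1 + config$a_thz * d),
    `THz-24h` = base * (1 + d + u24),
    `HTC-3h` = base * (1 - config$b_htc * d),
    `HTC-24h` = base * (1 - config$b_htc * d + v24))
  tab <- purrr::pmap_dfr(samples, function(condition, timepoint) {
    key <- paste(condition, timepoint, sep = "-")
    conc <- stats::rlnorm(1, 0, config$conc_sd)
    noise <- if (config$noise_sd > 0) {
      stats::rlnorm(n, 0, config$noise_sd)
    } else {
      rep(1, n)
    }
    intens <- pmax(clean[[key]] * noise, 0) * conc
    tibble::tibble(residue_number = analyzed$residue_number,
                   residue_type = analyzed$residue_type,
                   methyl_id = analyzed$methyl_id,
                   condition = condition, timepoint = timepoint,
                   raw_intensity = intens,
                   oned_integral = conc * sum(base))
  })
  list(table = tab, excluded = excluded,
       truth = list(d = d, base = base, config = config, seed = seed))
}
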