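#' Read a Touchstone v1 one-port file
#'
#' Supports the RI (real/imaginary) and MA (magnitude/angle) data dialects
#' with any of the standard frequency units (Hz/kHz/MHz/GHz); frequencies
#' are normalised to Hz.  Comment lines (`!`) are ignored.
#'
#' @param path path to a `.s1p` file.
#' @return a reflection tibble (`frequency_hz`, `s11`).
#' @export
read_touchstone <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("!.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty or comment-only Touchstone file",
                           call. = FALSE)
  opt <- grep("^#", lines, value = TRUE)
  unit_mult <- 1e9; fmt <- "MA" # Touchstone defaults
  if (length(opt)) {
    tok <- toupper(strsplit(opt[1], "\\s+")[[1]][-1])
    units <- c(HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)
    u <- intersect(tok, names(units))
    if (length(u)) unit_mult <- units[[u[1]]]
    f <- intersect(tok, c("RI", "MA", "DB"))
    if (length(f)) fmt <- f[1]
    if (!"S" %in% tok && length(tok)) {
      # parameter type other than S is outside scope
      if (any(tok %in% c("Y", "Z", "G", "H"))) {
        stop("only S-parameter Touchstone files are supported",
             call. = FALSE)
      }
    }
  }
  dat <- lines[!grepl("^#", lines)]
  if (!length(dat)) stop("Touchstone file has no data rows", call. = FALSE)
  vals <- lapply(strsplit(dat, "\\s+"), as.numeric)
  if (any(lengths(vals) != 3) || any(vapply(vals, anyNA, logical(1)))) {
    stop("malformed Touchstone data row (expect: freq col1 col2)",
         call. = FALSE)
  }
  m <- do.call(rbind, vals)
  f_hz <- m[, 1] * unit_mult
  if (is.unsorted(f_hz, strictly = TRUE)) {
    stop("non-monotone frequencies in Touchstone file", call. = FALSE)
  }
  s11 <- switch(fmt,
    RI = complex(real = m[, 2], imaginary = m[, 3]),
    MA = complex(modulus = m[, 2], argument = m[, 3] * pi / 180),
    DB = complex(modulus = 10^(m[, 2] / 20), argument = m[, 3] * pi / 180))
  reflection_tbl(f_hz, s11)
}

#' Write a Touchstone v1 one-port file
#'
#' @param rec a reflection tibble.
#' @param path output path.
#' @param format `"RI"` or `"MA"`.
#' @return `path`, invisibly.
#' @export
write_touchstone <- function(rec, path, format = c("RI", "MA")) {
  format <- match.arg(format)
  check_reflection(rec)
  header <- sprintf("# Hz S %s R 50", format)
  body <- if (format == "RI") {
    sprintf("%.10e %.12e %.12e", rec$frequency_hz, Re(rec$s11), Im(rec$s11))
  } else {
    sprintf("%.10e %.12e %.12e", rec$frequency_hz, Mod(rec$s11),
            Arg(rec$s11) * 180 / pi)
  }
  writeLines(c("! one-port reflection data", header, body), path)
  invisible(path)
}

#' Read / write permittivity spectrum CSV
#'
#' The column contract is `frequency_hz, eps_real, eps_imag` with optional
#' `sigma_real, sigma_imag`; decimal points only (locale-independent).
#'
#' @param path CSV path.
#' @return `read_spectrum_csv()` returns a spectrum tibble.
#' @export
read_spectrum_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("frequency_hz", "eps_real", "eps_imag")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("spectrum CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(c(need, "sigma_real", "sigma_imag"), names(d))
  check_spectrum(d[, keep])
}

#' @rdname read_spectrum_csv
#' @param spec spectrum tibble to write.
#' @export
write_spectrum_csv <- function(spec, path) {
  check_spectrum(spec)
  readr::write_csv(spec, path, progress = FALSE)
  invisible(path)
}

#' Read a reflection CSV (`frequency_hz, s11_real, s11_imag`)
#'
#' @param path CSV path.
#' @return a reflection tibble.
#' @export
read_reflection_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("frequency_hz", "s11_real", "s11_imag")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("reflection CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  reflection_tbl(d$frequency_hz,
                 complex(real = d$s11_real, imaginary = d$s11_imag))
}

#' @rdname read_reflection_csv
#' @param rec reflection tibble to write.
#' @export
write_reflection_csv <- function(rec, path) {
  check_reflection(rec)
  readr::write_csv(tibble::tibble(frequency_hz = rec$frequency_hz,
                                  s11_real = Re(rec$s11),
                                  s11_imag = Im(rec$s11)),
                   path, progress = FALSE)
  invisible(path)
}

# first sequence of a FASTA file as a single uppercase string
read_fasta_sequence <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             seqonly = TRUE)
  if (!length(seqs)) stop("no sequences in FASTA file", call. = FALSE)
  toupper(seqs[[1]])
}

#' Command-line entry point
#'
#' A thin dispatcher over the package functions, used by the installed
#' `exec/hydrodr` script.  Subcommands: `dosimetry`, `simulate`,
#' `analyze-relaxation`, `diffspec`, `nmr`.  Logs go to standard error;
#' outputs to files or standard output.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
hydrodr_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: hydrodr <subcommand> [options]",
    "subcommands:",
    "  dosimetry [p_s_w_m2] [eps_100ghz] [alpha_cm]   print exposure report",
    "  simulate <outdir> [seed]                       write synthetic sweep",
    "  analyze-relaxation <outdir> [seed]             simulate + analyse",
    "  diffspec <outdir> [seed]                       difference band stats",
    "  nmr [seed]                                     NMR pathway summary",
    sep = "\n")
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]; rest <- args[-1]
  num <- function(i, default) {
    if (length(rest) >= i) as.numeric(rest[i]) else default
  }
  if (cmd == "dosimetry") {
    d <- dose_params(p_s = num(1, 160), eps_real_100ghz = num(2, 7.7),
                     alpha_cm = num(3, 83))
    rep <- dosimetry(d)
    cat(sprintf("E = %.4g kV/m\nU = %.4g uJ/m^3\npenetration depth = %.4g um\n",
                rep$e_field_v_per_m / 1e3,
                rep$energy_density_j_per_m3 * 1e6,
                rep$penetration_depth_m * 1e6))
    return(invisible(0L))
  }
  if (cmd %in% c("simulate", "analyze-relaxation", "diffspec")) {
    if (!length(rest)) {
      message("missing output directory\n", usage)
      return(invisible(1L))
    }
    outdir <- rest[1]
    seed <- as.integer(num(2, 1))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    message("simulating time-lapse dataset (seed ", seed, ") ...")
    sim <- simulate_timelapse(seed = seed)
    readr::write_csv(sim$truth, file.path(outdir, "ground_truth.csv"),
                     progress = FALSE)
    if (cmd == "simulate") {
      first <- sim$measurements[sim$measurements$replicate == 1, ]
      for (cond in unique(first$condition)) {
        for (tm in unique(first$time_min)) {
          d <- first[first$condition == cond & first$time_min == tm, ]
          write_touchstone(reflection_tbl(d$frequency_hz, d$s11),
                           file.path(outdir,
                                     sprintf("%s_t%02d_rep1.s1p", cond,
                                             as.integer(tm))))
        }
      }
      message("wrote ", outdir)
      return(invisible(0L))
    }
    an <- analyze_timelapse(sim)
    readr::write_csv(an$parameters, file.path(outdir, "fit_parameters.csv"),
                     progress = FALSE)
    if (cmd == "diffspec") {
      readr::write_csv(difference_bands(an),
                       file.path(outdir, "difference_bands.csv"),
                       progress = FALSE)
    }
    message("wrote ", outdir)
    return(invisible(0L))
  }
  if (cmd == "nmr") {
    seed <- as.integer(num(1, 1))
    sim <- simulate_nmr_table(seed = seed)
    prof <- pathway_profiles(sim$table)
    cors <- pathway_correlation_matrix(prof)
    cat(format(as.data.frame(cors)), sep = "\n")
    return(invisible(0L))
  }
  message("unknown subcommand: ", cmd, "\n", usage)
  invisible(1L)
}
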