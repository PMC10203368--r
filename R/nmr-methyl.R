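#' Methyl enumeration from an amino-acid sequence
#'
#' Counts the AILMTV methyl groups used as site-specific NMR reporters:
#' alanine (beta), isoleucine (gamma2, delta1), leucine (delta1, delta2),
#' methionine (epsilon), threonine (gamma2) and valine (gamma1, gamma2) —
#' multiplicities A=1, I=2, L=2, M=1, T=1, V=2.  Hen lysozyme carries 61.
#'
#' @param sequence one-letter amino-acid string.
#' @return a tibble with one row per residue: `residue_number`,
#'   `residue_type`, `n_methyls`.  Unknown letters are reported with a
#'   warning and counted as 0.  The total is `sum(out$n_methyls)`.
#' @examples
#' methyls <- count_ailmtv_methyls(lysozyme_sequence())
#' sum(methyls$n_methyls) # 61
#' @export
count_ailmtv_methyls <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  unknown <- setdiff(unique(aa), alphabet)
  if (length(unknown)) {
    warning("unknown residue letters counted as 0 methyls: ",
            paste(unknown, collapse = ", "))
  }
  mult <- c(A = 1, I = 2, L = 2, M = 1, T = 1, V = 2)
  n <- unname(mult[aa])
  n[is.na(n)] <- 0
  tibble::tibble(residue_number = seq_along(aa), residue_type = aa,
                 n_methyls = as.integer(n))
}

#' The bundled hen egg-white lysozyme sequence
#'
#' Mature 129-residue chain (UniProt P00698), read from the packaged FASTA.
#'
#' @return a single character string.
#' @export
lysozyme_sequence <- function() {
  path <- system.file("extdata", "lysozyme_P00698.fasta", package = "hydrodr")
  read_fasta_sequence(path)
}

methyl_names <- list(A = "beta", I = c("gamma2", "delta1"),
                     L = c("delta1", "delta2"), M = "epsilon",
                     T = "gamma2", V = c("gamma1", "gamma2"))

#' Enumerate individual methyl groups of a sequence
#'
#' Expands [count_ailmtv_methyls()] to one row per methyl group with its
#' conventional position name (e.g. Leu delta1/delta2, Ile gamma2/delta1).
#'
#' @inheritParams count_ailmtv_methyls
#' @return tibble with `residue_number`, `residue_type`, `methyl_id`.
#' @export
enumerate_methyls <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  rows <- purrr::imap(aa, function(a, i) {
    ids <- methyl_names[[a]]
    if (is.null(ids)) return(NULL)
    tibble::tibble(residue_number = i, residue_type = a, methyl_id = ids)
  })
  dplyr::bind_rows(rows)
}

check_methyl_table <- function(t) {
  need <- c("residue_number", "residue_type", "methyl_id", "condition",
            "timepoint", "raw_intensity", "oned_integral")
  if (!is.data.frame(t) || !all(need %in% names(t))) {
    stop("methyl table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(t$raw_intensity < 0)) stop("raw intensities must be >= 0",
                                     call. = FALSE)
  if (any(t$oned_integral <= 0)) stop("1H-1D integrals must be positive",
                                      call. = FALSE)
  invisible(t)
}

#' Concentration normalisation of methyl intensities
#'
#' Divides each peak intensity by its sample's 1H-1D integral (taken over
#' 12 to -3 ppm, water resonance excluded), which is proportional to the
#' protein concentration.  Doubling every intensity together with the
#' integral leaves the normalised values unchanged.
#'
#' @param t a methyl table: columns `residue_number`, `residue_type`,
#'   `methyl_id`, `condition`, `timepoint`, `raw_intensity`,
#'   `oned_integral` (one integral value per sample, i.e. per
#'   condition-timepoint).
#' @return the table with an added `intensity` column.
#' @export
normalize_intensities <- function(t) {
  check_methyl_table(t)
  dplyr::mutate(t, intensity = .data$raw_intensity / .data$oned_integral)
}

#' Per-methyl intensity ratios against a reference sample
#'
#' For each (condition, timepoint) sample, computes the per-methyl ratio
#' `I / I_ref` against the reference sample (default the constant-temperature
#' control at 3 h).  These "pathway profiles" describe how each methyl's
#' signal moved away from the common starting state.
#'
#' @param t a methyl table (normalised with [normalize_intensities()] if
#'   `intensity` is absent).
#' @param ref_condition,ref_timepoint the reference sample labels.
#' @return tibble with `residue_number`, `residue_type`, `methyl_id`,
#'   `condition`, `timepoint`, `ratio`.
#' @export
pathway_profiles <- function(t, ref_condition = "GC", ref_timepoint = "3h") {
  if (!"intensity" %in% names(t)) t <- normalize_intensities(t)
  ref <- dplyr::filter(t, .data$condition == ref_condition,
                       .data$timepoint == ref_timepoint)
  if (!nrow(ref)) stop("reference sample not present", call. = FALSE)
  if (any(ref$intensity == 0)) stop("zero reference intensity",
                                    call. = FALSE)
  ref <- dplyr::select(ref, "residue_number", "methyl_id",
                       ref_intensity = "intensity")
  t |>
    dplyr::inner_join(ref, by = c("residue_number", "methyl_id")) |>
    dplyr::mutate(ratio = .data$intensity / .data$ref_intensity) |>
    dplyr::select("residue_number", "residue_type", "methyl_id",
                  "condition", "timepoint", "ratio")
}

#' Correlation between two pathway profiles
#'
#' Pearson correlation of the centred ratio vectors (`ratio - 1`) over the
#' common methyl set.  (Pearson correlation is affine-invariant, so this
#' equals the correlation of the raw ratios; the centred form reads as
#' "displacement from the reference state".)
#'
#' @param a,b pathway-profile tibbles (from [pathway_profiles()]) for one
#'   sample each.
#' @return the correlation coefficient.
#' @export
pathway_correlation <- function(a, b) {
  m <- dplyr::inner_join(a, b, by = c("residue_number", "methyl_id"),
                         suffix = c("_a", "_b"))
  if (nrow(m) < 3) stop("profiles share too few methyls", call. = FALSE)
  da <- m$ratio_a - 1; db <- m$ratio_b - 1
  if (stats::sd(da) == 0 || stats::sd(db) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  stats::cor(da, db)
}

#' All pairwise pathway correlations
#'
#' @param profiles a pathway-profile tibble covering several samples.
#' @return tibble of sample pairs with their correlation `r`.
#' @export
pathway_correlation_matrix <- function(profiles) {
  profiles <- dplyr::mutate(profiles,
                            sample = paste(.data$condition, .data$timepoint,
                                           sep = "-"))
  samples <- unique(profiles$sample)
  pairs <- utils::combn(samples, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- dplyr::filter(profiles, .data$sample == pairs[1, i])
    b <- dplyr::filter(profiles, .data$sample == pairs[2, i])
    tibble::tibble(sample_a = pairs[1, i], sample_b = pairs[2, i],
                   r = pathway_correlation(a, b))
  })
}

#' Flag methyls with responses beyond one standard deviation
#'
#' Computes the sample standard deviation (n-1 denominator) of the ratios
#' across the analysed methyls of one profile, then flags a methyl as
#' increased when `ratio - 1 > SD` and decreased when `1 - ratio > SD`.
#' These are the residues mapped onto the structure.
#'
#' @param profile a pathway-profile tibble for one sample.
#' @return list with `increased` and `decreased` (tibbles of flagged
#'   methyls, each with a `direction` column) and `sd`.
#' @export
flag_responsive <- function(profile) {
  stopifnot(is.data.frame(profile), "ratio" %in% names(profile))
  if (nrow(profile) < 2) stop("need at least 2 methyls", call. = FALSE)
  s <- stats::sd(profile$ratio)
  if (s == 0) stop("degenerate profile: all ratios equal", call. = FALSE)
  up <- dplyr::filter(profile, .data$ratio - 1 > s)
  dn <- dplyr::filter(profile, 1 - .data$ratio > s)
  list(increased = dplyr::mutate(up, direction = "increased"),
       decreased = dplyr::mutate(dn, direction = "decreased"),
       sd = s)
}
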