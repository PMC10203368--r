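test_that("methyl enumeration counts the AILMTV multiplicities", {
  lys <- count_ailmtv_methyls(lysozyme_sequence())
  expect_equal(nrow(lys), 129)
  expect_equal(sum(lys$n_methyls), 61)
  expect_equal(sum(count_ailmtv_methyls("AILMTV")$n_methyls), 9)
  expect_equal(nrow(count_ailmtv_methyls("")), 0)
  expect_warning(out <- count_ailmtv_methyls("AXL"), "unknown")
  expect_equal(sum(out$n_methyls), 3)
  # the per-methyl enumeration agrees with the counts
  expect_equal(nrow(enumerate_methyls(lysozyme_sequence())), 61)
})

test_that("the default synthetic table analyses 57 methyls", {
  sim <- simulate_nmr_table(seed = 1)
  per_sample <- dplyr::count(sim$table, condition, timepoint)
  expect_true(all(per_sample$n == 57))
  expect_equal(nrow(sim$excluded), 4)
})

test_that("concentration normalisation is scale invariant", {
  sim <- simulate_nmr_table(seed = 2)
  t1 <- normalize_intensities(sim$table)
  t2 <- sim$table
  t2$raw_intensity <- t2$raw_intensity * 2
  t2$oned_integral <- t2$oned_integral * 2
  expect_equal(normalize_intensities(t2)$intensity, t1$intensity)
  t3 <- sim$table
  t3$oned_integral <- 1
  expect_equal(normalize_intensities(t3)$intensity, t3$raw_intensity)
  # flag sets are invariant under global rescaling
  prof1 <- pathway_profiles(t1)
  p_gc <- dplyr::filter(prof1, condition == "GC", timepoint == "24h")
  f1 <- flag_responsive(p_gc)
  prof2 <- pathway_profiles(normalize_intensities(t2))
  p_gc2 <- dplyr::filter(prof2, condition == "GC", timepoint == "24h")
  f2 <- flag_responsive(p_gc2)
  expect_equal(f1$increased$residue_number, f2$increased$residue_number)
  expect_equal(f1$decreased$residue_number, f2$decreased$residue_number)
})

test_that("pathway profiles are ratios against the reference sample", {
  sim <- simulate_nmr_table(nmr_config(noise_sd = 0, conc_sd = 0), seed = 3)
  prof <- pathway_profiles(sim$table)
  ref <- dplyr::filter(prof, condition == "GC", timepoint == "3h")
  expect_true(all(abs(ref$ratio - 1) < 1e-12))
  gc24 <- dplyr::filter(prof, condition == "GC", timepoint == "24h")
  expect_equal(gc24$ratio, 1 + sim$truth$d, tolerance = 1e-9)
})

test_that("pathway correlations are exact under the noiseless geometry", {
  sim <- simulate_nmr_table(nmr_config(noise_sd = 0, conc_sd = 0), seed = 4)
  prof <- pathway_profiles(sim$table)
  pick <- function(c, t) dplyr::filter(prof, condition == c, timepoint == t)
  expect_equal(pathway_correlation(pick("THz", "3h"), pick("GC", "24h")), 1)
  expect_equal(pathway_correlation(pick("THz", "3h"), pick("HTC", "3h")), -1)
  expect_equal(pathway_correlation(pick("GC", "24h"), pick("GC", "24h")), 1)
  # reflection about ratio 1 flips the sign exactly
  refl <- pick("GC", "24h")
  refl$ratio <- 2 - refl$ratio
  expect_equal(pathway_correlation(pick("GC", "24h"), refl), -1)
  # no displacement at all leaves the correlation undefined
  flat <- simulate_nmr_table(nmr_config(a_thz = 0, b_htc = 0, noise_sd = 0,
                                        d_sd = 0, decouple_sd_24h = 0,
                                        conc_sd = 0), seed = 5)
  pflat <- pathway_profiles(flat$table)
  expect_error(
    pathway_correlation(dplyr::filter(pflat, condition == "THz",
                                      timepoint == "3h"),
                        dplyr::filter(pflat, condition == "GC",
                                      timepoint == "24h")),
    "zero variance")
})

test_that("a planted correlation is recovered at the analysed sample size", {
  set.seed(10)
  hits <- 0L
  for (i in 1:500) {
    d <- rnorm(57)
    rho <- sample(c(-0.6, 0.6), 1)
    e <- rho * d + sqrt(1 - rho^2) * rnorm(57)
    a <- tibble::tibble(residue_number = 1:57, methyl_id = "x",
                        ratio = 1 + 0.1 * d)
    b <- tibble::tibble(residue_number = 1:57, methyl_id = "x",
                        ratio = 1 + 0.1 * e)
    if (sign(pathway_correlation(a, b)) == sign(rho)) hits <- hits + 1L
  }
  expect_gte(hits, 495) # >= 99%
})

test_that("responsive methyls are flagged one standard deviation out", {
  n <- 57
  d <- 0.3
  prof <- tibble::tibble(residue_number = 1:n, methyl_id = "x",
                         ratio = c(rep(1, n - 1), 1 + d))
  # hand computation: sample sd of (n-1) ones and one 1+d is d/sqrt(n)
  fl <- flag_responsive(prof)
  expect_equal(fl$sd, d / sqrt(n), tolerance = 1e-12)
  expect_equal(fl$increased$residue_number, n)
  expect_equal(nrow(fl$decreased), 0)
  # reflecting the profile about 1 swaps the direction sets
  refl <- prof
  refl$ratio <- 2 - refl$ratio
  fr <- flag_responsive(refl)
  expect_equal(fr$decreased$residue_number, n)
  expect_equal(nrow(fr$increased), 0)
  expect_error(flag_responsive(prof[1, ]), "at least 2")
  all_one <- tibble::tibble(residue_number = 1:5, methyl_id = "x",
                            ratio = rep(1, 5))
  expect_error(flag_responsive(all_one), "degenerate")
})
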