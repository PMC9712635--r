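# genotype codes: 0 = HOM_REF, 1 = HET, 2 = HOM_ALT, NA = missing

test_that("correction rules overwrite forwards from homozygous runs and backwards from het runs", {
  # later HET after two consecutive HOM_REF is overwritten
  r1 <- correct_line(c(1L, 0L, 0L, 1L, 0L))
  expect_equal(r1$corrected, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(r1$status, "kept")
  expect_equal(r1$provenance[4], "corrected")
  expect_equal(r1$provenance[1], "observed")

  # founder back-corrected to HET from a heterozygous run
  r2 <- correct_line(c(2L, 1L, 1L, 1L, 1L))
  expect_equal(r2$corrected, c(1L, 1L, 1L, 1L, 1L))
  expect_equal(r2$status, "kept")

  # contradictory rules remove the locus and leave values untouched
  r3 <- correct_line(c(0L, 0L, 1L, 1L, 1L))
  expect_equal(r3$status, "removed_uncorrectable")
  expect_equal(r3$corrected, c(0L, 0L, 1L, 1L, 1L))

  # opposite homozygous runs in order are uncorrectable
  r4 <- correct_line(c(0L, 0L, 2L, 2L))
  expect_equal(r4$status, "removed_uncorrectable")

  # missing entries are imputed when a rule covers them
  r5 <- correct_line(c(1L, 0L, 0L, NA, 0L))
  expect_equal(r5$corrected, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(r5$provenance[4], "imputed")

  # a short vector is returned unchanged
  r6 <- correct_line(c(1L))
  expect_equal(r6$status, "kept")
  expect_equal(r6$corrected, c(1L))
})

test_that("correction is idempotent and conservative on random vectors", {
  set.seed(31)
  M <- matrix(sample(c(0L, 1L, 2L, NA), 10000 * 6, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), ncol = 6)
  r1 <- selfdrift:::correct_line_matrix(M)
  r2 <- selfdrift:::correct_line_matrix(r1$corrected)
  kept <- r1$status == "kept"
  expect_equal(r2$corrected[kept, ], r1$corrected[kept, ])
  expect_true(all(r2$status[kept] == "kept"))
  # removed rows are untouched
  expect_equal(r1$corrected[!kept, ], M[!kept, ])
  # entries consistent with the outcome keep provenance "observed"
  same <- !is.na(M) & !is.na(r1$corrected) & M == r1$corrected
  expect_true(all(r1$provenance[same] == "observed"))
})

test_that("S3 imputation applies the single-possible-genotype rule", {
  # forced cases
  expect_equal(impute_s3(0L, 0L)$s3, 0L)
  expect_equal(impute_s3(2L, 2L)$s3, 2L)
  expect_equal(impute_s3(1L, 1L)$s3, 1L)
  # two possibilities -> missing
  amb <- impute_s3(1L, 0L)
  expect_true(is.na(amb$s3))
  expect_equal(amb$status, "kept")
  # impossible under selfing
  expect_equal(impute_s3(0L, 2L)$status, "removed_uncorrectable")
  expect_equal(impute_s3(0L, 1L)$status, "removed_uncorrectable")
})

test_that("panel correction recovers miscalled entries against the simulator truth", {
  cfg <- sim_config(n_lines = 28, n_generations = 5, n_loci = 2000,
                    fs_het_fraction = 1, miscall_rate = 0.01,
                    missing_rate = 0.02, seed = 17)
  sim <- simulate_selfing_panel(cfg)
  cl <- correct_panel(sim$genotypes, sim$pedigree)
  sc <- score_correction(sim, cl)
  # rule-detectable errors (entries a rule overwrote) are fixed to truth
  expect_gt(sc$n_detected, 0)
  expect_gte(sc$n_recovered / sc$n_detected, 0.95)
  # a single miscall can never fabricate a trigger, so any corruption of
  # truth-consistent entries must trace to coincident double miscalls
  expect_true(sc$corruption_confined)
  expect_lt(sc$n_corrupted / length(cl$geno), 1e-4)
})

test_that("errors that fabricate no trigger are never propagated into truth-consistent entries", {
  cfg <- sim_config(n_lines = 28, n_generations = 5, n_loci = 2000,
                    fs_het_fraction = 1, miscall_rate = 0,
                    missing_rate = 0, seed = 18)
  sim <- simulate_selfing_panel(cfg)
  set.seed(181)
  noisy <- inject_sparse_miscalls(sim, rate = 0.01)
  cl <- correct_panel(noisy$genotypes, noisy$pedigree)
  sc <- score_correction(noisy, cl)
  expect_equal(sc$n_corrupted, 0)
  expect_gt(sc$n_detected, 0)
  expect_gte(sc$n_recovered / sc$n_detected, 0.95)
})

test_that("F_UNI per-locus terms match the closed form", {
  # construct a table whose allele frequency at each locus is p = 0.5:
  # samples (0, 1, 2, 1) -> p = 0.5
  gt <- gt_from_codes(matrix(c(0L, 1L, 2L, 1L), 1))
  f <- f_uni(gt)
  # per-locus terms at p = 0.5: x=2 (ref hom, code 0) -> 1; x=1 -> -1; x=0 -> 1
  expect_equal(unname(f), c(1, -1, 1, -1))

  # x = 2, p = 0.25 -> (4 - 3 + 0.125) / 0.375 = 3
  # build p_ref = 0.25 with codes (0, 2, 2, 2): ref dosages (2, 0, 0, 0)
  gt2 <- gt_from_codes(matrix(c(0L, 2L, 2L, 2L), 1))
  f2 <- f_uni(gt2)
  expect_equal(unname(f2[1]), 3)

  # monomorphic loci are skipped; a sample with no usable loci gets NA
  gt3 <- gt_from_codes(matrix(c(0L, 0L), 1))
  expect_true(all(is.na(f_uni(gt3))))
})

test_that("expected inbreeding trajectory follows the halving recurrence", {
  expect_equal(expected_f_trajectory(0, 5),
               c(0.5, 0.75, 0.875, 0.9375, 0.96875))
  expect_equal(expected_f_trajectory(1, 4), rep(1, 4))
  # recurrence and closed form agree
  f <- 0.2
  for (t in 1:6) f <- (1 + f) / 2
  expect_equal(expected_f_trajectory(0.2, 6)[6], f)
  expect_lt(1 - expected_f_trajectory(0, 40)[40], 1e-11)
})

test_that("trajectory summary: halving expectation and sign test behaviour", {
  cfg <- sim_config(n_lines = 28, n_generations = 4, n_loci = 400,
                    fs_het_fraction = 1, miscall_rate = 0,
                    missing_rate = 0, seed = 23)
  sim <- simulate_selfing_panel(cfg)
  cl <- correct_panel(sim$genotypes, sim$pedigree)
  tr <- trajectory_summary(cl, sim$pedigree)
  # expected H at S1 is half the FS observed (all-het founders -> 0.5)
  expect_equal(tr$mean_H_exp[tr$generation == "S1"], 0.5)
  expect_true(all(tr$mean_H_obs >= 0 & tr$mean_H_obs <= 1, na.rm = TRUE))
  # FS row has no expectation
  expect_true(is.na(tr$mean_H_exp[tr$generation == "FS"]))

  # sign test: all observed below expected at 10 loci -> p = 2 * (1/2)^10
  d <- rep(-0.1, 10)
  expect_equal(stats::binom.test(sum(d > 0), length(d))$p.value,
               2 * 0.5^10, tolerance = 1e-12)
})

test_that("mean F_UNI tracks the selfing recurrence on an error-free panel", {
  cfg <- sim_config(n_lines = 28, n_generations = 4, n_loci = 3000,
                    fs_het_fraction = 0.3, miscall_rate = 0,
                    missing_rate = 0, seed = 29)
  sim <- simulate_selfing_panel(cfg)
  cl <- correct_panel(sim$genotypes, sim$pedigree)
  tr <- trajectory_summary(cl, sim$pedigree)
  # F rises toward 1 and stays within a few SE of the recurrence
  expect_true(all(diff(tr$mean_F) > 0))
  later <- tr$generation %in% c("S2", "S3", "S4")
  expect_lt(max(abs(tr$mean_F[later] - tr$exp_F[later])), 0.06)
})

test_that("mixed-mating population mean F_UNI converges to s/(2-s)", {
  set.seed(41)
  p <- runif(3000, 0.2, 0.8)
  gt <- simulate_mixed_mating_population(p, 150, selfing_rate = 0.3,
                                         seed = 41)
  f <- f_uni(gt)
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 0.3 / 1.7), 3 * se + 0.01)
})
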