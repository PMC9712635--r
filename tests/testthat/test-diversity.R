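test_that("pi matches hand counts on worked examples", {
  # 10 invariant sites, full data -> pi = 0
  inv <- gt_from_codes(matrix(0L, 10, 4), is_variant = FALSE)
  expect_equal(pi_region(inv)$pi, 0)

  # 2 samples, one fixed difference among 10 fully called sites:
  # diffs 4, comps 6 * 10 -> pi = 1/15
  codes <- matrix(0L, 10, 2)
  codes[5, ] <- c(0L, 2L)
  gt <- gt_from_codes(codes, is_variant = seq_len(10) == 5)
  r <- pi_region(gt)
  expect_equal(r$n_diffs, 4)
  expect_equal(r$n_comparisons, 60)
  expect_equal(r$pi, 4 / 60)

  # missing data shrink the denominator, not the estimate
  codes2 <- codes
  codes2[5, 2] <- NA
  gt2 <- gt_from_codes(codes2, is_variant = seq_len(10) == 5)
  r2 <- pi_region(gt2)
  expect_equal(r2$n_diffs, 0)
  expect_equal(r2$n_comparisons, 9 * 6 + 1)
  expect_error(pi_region(gt, samples = character(0)), "empty sample")
})

test_that("pi and dxy agree with brute-force allele-pair enumeration", {
  set.seed(55)
  for (i in 1:100) {
    gt <- random_gt(50, 5, p_missing = 0.15)
    got <- pi_region(gt)
    oracle <- pi_bruteforce(gt)
    expect_equal(got$n_diffs, oracle$diffs)
    expect_equal(got$n_comparisons, oracle$comps)
  }
  for (i in 1:20) {
    gt <- random_gt(40, 6, p_missing = 0.15)
    got <- dxy_region(gt, 1:3, 4:6)
    oracle <- dxy_bruteforce(gt, 1:3, 4:6)
    expect_equal(got$n_diffs, oracle$diffs)
    expect_equal(got$n_comparisons, oracle$comps)
  }
})

test_that("dropping invariant sites inflates pi (the denominator effect)", {
  set.seed(56)
  gt <- random_gt(200, 8, p_missing = 0.05, p_invariant = 0.6)
  skip_if_not(any(gt$loci$is_variant) && any(!gt$loci$is_variant))
  full <- pi_region(gt)$pi
  variant_only <- pi_region(subset_gt(gt, loci = gt$loci$is_variant))$pi
  expect_gt(variant_only, full)
})

test_that("dxy is symmetric and restricted to cross-population pairs", {
  # pop A all HOM_REF, pop B all HOM_ALT at 1 of 10 sites, one diploid
  # each: dxy = 4 / 40 = 0.1
  codes <- matrix(0L, 10, 2)
  codes[3, 2] <- 2L
  gt <- gt_from_codes(codes, is_variant = seq_len(10) == 3)
  expect_equal(dxy_region(gt, 1, 2)$dxy, 0.1)
  expect_equal(dxy_region(gt, 2, 1)$dxy, dxy_region(gt, 1, 2)$dxy)
  expect_error(dxy_region(gt, 1, 1), "disjoint")

  # identical homozygous samples: zero divergence
  same <- gt_from_codes(matrix(0L, 10, 2), is_variant = FALSE)
  expect_equal(dxy_region(same, 1, 2)$dxy, 0)

  # pop B missing at a site contributes no comparisons there
  codes_na <- codes
  codes_na[3, 2] <- NA
  gt_na <- gt_from_codes(codes_na, is_variant = seq_len(10) == 3)
  expect_equal(dxy_region(gt_na, 1, 2)$n_comparisons, 9 * 4)
})

test_that("codon degeneracy classes follow the standard genetic code", {
  # single CDS of three codons on the plus strand: GGG ATG AAA
  ref <- c(chrA = "GGGATGAAA")
  cds <- data.frame(cds_id = "g1", seqid = "chrA", start = 1, end = 9,
                    strand = "+")
  deg <- classify_degeneracy(cds, ref)
  cls <- deg$class[match(1:9, deg$pos)]
  expect_equal(cls[3], "4-fold")            # GGN glycine
  expect_equal(cls[4:6], rep("0-fold", 3))  # ATG methionine
  expect_equal(cls[9], "2-fold")            # AAA/AAG lysine
  expect_equal(cls[1:2], rep("0-fold", 2))

  # minus strand: reverse complement of TTTCATCCC is GGGATGAAA
  refm <- c(chrB = "TTTCATCCC")
  cdsm <- data.frame(cds_id = "g2", seqid = "chrB", start = 1, end = 9,
                     strand = "-")
  degm <- classify_degeneracy(cdsm, refm)
  # genomic position 7 is codon position 3 of GGG -> 4-fold
  expect_equal(degm$class[degm$pos == 7], "4-fold")

  # frame violation and internal stop are skipped with warnings
  expect_warning(classify_degeneracy(
    data.frame(cds_id = "bad", seqid = "chrA", start = 1, end = 8,
               strand = "+"), ref), "multiple of 3")
  refstop <- c(chrC = "ATGTAAAAA")
  expect_warning(classify_degeneracy(
    data.frame(cds_id = "stopper", seqid = "chrC", start = 1, end = 9,
               strand = "+"), refstop), "stop")
})

test_that("pi0/pi4 ratio is computed over the degeneracy site classes", {
  # diversity only at 4-fold sites -> ratio 0
  codes <- matrix(0L, 6, 4)
  codes[5, ] <- c(0L, 1L, 1L, 2L)
  gt <- gt_from_codes(codes, pos = 1:6,
                      is_variant = seq_len(6) == 5)
  deg <- data.frame(seqid = "s1", pos = 1:6,
                    class = rep(c("0-fold", "4-fold"), each = 3))
  r <- pi_by_degeneracy(gt, deg)
  expect_equal(r$pi_0, 0)
  expect_gt(r$pi_4, 0)
  expect_equal(r$ratio, 0)

  # equal diversity in both classes -> ratio 1
  codes2 <- matrix(rep(c(0L, 1L, 1L, 2L), each = 1), 6, 4, byrow = TRUE)
  codes2[c(1, 4), ] <- 0L
  gt2 <- gt_from_codes(codes2, pos = 1:6,
                       is_variant = !(seq_len(6) %in% c(1, 4)))
  r2 <- pi_by_degeneracy(gt2, deg)
  expect_equal(r2$ratio, 1)

  # no 4-fold diversity -> ratio absent
  r3 <- pi_by_degeneracy(gt_from_codes(matrix(0L, 6, 2),
                                       pos = 1:6, is_variant = FALSE), deg)
  expect_true(is.na(r3$ratio))
})

test_that("folded SFS tallies minor-allele counts and projects hypergeometrically", {
  # 3 diploids with codes (0, 1, 2): alt count 3 of 6 -> bin 3
  gt <- gt_from_codes(matrix(c(0L, 1L, 2L), 1))
  sfs <- folded_sfs(gt)
  expect_equal(as.numeric(sfs), c(0, 0, 0, 1))

  # all samples HET -> maximal folded bin (excess-het artifact signature)
  gt2 <- gt_from_codes(matrix(1L, 1, 4))
  sfs2 <- folded_sfs(gt2)
  expect_equal(as.numeric(sfs2[length(sfs2)]), 1)

  # complete-case: locus with missing data is dropped
  gt3 <- gt_from_codes(rbind(c(0L, 1L, 2L), c(0L, NA, 2L)))
  expect_equal(attr(folded_sfs(gt3), "n_loci_used"), 1)

  # projection: 10 called alleles, 4 minor, projected to 6 follows the
  # hypergeometric mass
  gt4 <- gt_from_codes(matrix(c(2L, 2L, 0L, 0L, 0L), 1))
  sfs4 <- folded_sfs(gt4, projection = 6)
  pr <- dhyper(0:6, 4, 6, 6)
  folded <- sapply(0:3, function(b)
    sum(pr[pmin(0:6, 6 - (0:6)) == b]))
  expect_equal(as.numeric(sfs4), folded)
  # projection larger than available alleles drops the locus
  expect_equal(attr(folded_sfs(gt4, projection = 12), "n_loci_used"), 0)
})
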