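test_that("locus QC statistics match hand counts", {
  # 4 samples all HET
  qc1 <- compute_locus_qc(gt_from_codes(matrix(1L, 1, 4)))
  expect_equal(qc1$H_O, 1)
  expect_equal(qc1$H_E, 0.5)
  expect_equal(qc1$MAF, 0.5)

  # (HOM_REF, HOM_REF, HET, MISSING): call rate 3/4, p = 5/6, H_O = 1/3
  qc2 <- compute_locus_qc(gt_from_codes(matrix(c(0L, 0L, 1L, NA), 1)))
  expect_equal(qc2$call_rate, 0.75)
  expect_equal(qc2$p_ref, 5 / 6)
  expect_equal(qc2$H_O, 1 / 3)
  expect_equal(qc2$MAC, 1)

  # pooled het reads ref=30, alt=10 -> allele balance 0.25, D = 20/sqrt(40)
  gt <- gt_from_codes(matrix(c(1L, 1L), 1))
  dp <- depth_table(matrix(c(20L, 20L), 1), matrix(c(15L, 15L), 1),
                    matrix(c(5L, 5L), 1))
  qc3 <- compute_locus_qc(gt, dp)
  expect_equal(qc3$allele_balance, 0.25)
  expect_equal(qc3$D, 20 / sqrt(40))
  expect_equal(qc3$mean_depth, 20)
})

test_that("read-ratio deviation score D follows the pooled z-score", {
  # pooled A=50, B=50 -> D = 0 (retained); A=90, B=10 -> D = 8 (removed);
  # A=30, B=20 -> D = 10/sqrt(50) (retained)
  mk <- function(a, b) {
    gt <- gt_from_codes(matrix(1L, 1, 1))
    dp <- depth_table(matrix(a + b, 1, 1), matrix(a, 1, 1), matrix(b, 1, 1))
    compute_locus_qc(gt, dp)
  }
  expect_equal(mk(50L, 50L)$D, 0)
  expect_equal(mk(90L, 10L)$D, 8)
  expect_equal(mk(30L, 20L)$D, 10 / sqrt(50), tolerance = 1e-12)
  expect_true(filter_read_ratio(mk(50L, 50L))$keep)
  expect_false(filter_read_ratio(mk(90L, 10L))$keep)
  expect_true(filter_read_ratio(mk(30L, 20L))$keep)
})

test_that("exact HWE test agrees with full enumeration on small tables", {
  cases <- list(c(1L, 2L, 1L), c(0L, 4L, 0L), c(3L, 0L, 2L),
                c(2L, 2L, 1L), c(1L, 1L, 3L), c(4L, 1L, 0L))
  for (cs in cases) {
    got <- hwe_exact(cs[1], cs[2], cs[3])
    oracle <- hwe_enum_oracle(cs[1], cs[2], cs[3])
    expect_equal(got$p_two, oracle$p_two, tolerance = 1e-9,
                 info = paste(cs, collapse = ","))
    expect_equal(got$p_excess, oracle$p_excess, tolerance = 1e-9,
                 info = paste(cs, collapse = ","))
  }
  # monomorphic locus: p = 1 by convention
  expect_equal(hwe_exact(5L, 0L, 0L)$p_two, 1)
})

test_that("het-excess filter removes the pathological configurations", {
  # (25, 50, 25): perfectly HWE, retained
  qc_ok <- compute_locus_qc(gt_from_codes(
    matrix(rep(c(0L, 1L, 2L), c(25, 50, 25)), 1)))
  expect_true(filter_het_excess(qc_ok)$keep)
  # (0, 100, 0): everything het -> excess-het p tiny, removed
  qc_bad <- compute_locus_qc(gt_from_codes(matrix(1L, 1, 100)))
  expect_lt(qc_bad$p_excess_het, 1e-10)
  expect_false(filter_het_excess(qc_bad)$keep)
  # H_O = 0.56 > 0.55 removed regardless of p-values
  qc_ho <- qc_ok
  qc_ho$H_O <- 0.56
  expect_false(filter_het_excess(qc_ho)$keep)
})

test_that("F_IS statistic and filter honour the equilibrium constant", {
  # H_O = H_E -> F_IS = F_eq = 0.17
  expect_equal(fis_statistic(0.4, 0.4), 0.17)
  # H_O = 0 -> F_IS = 1
  expect_equal(fis_statistic(0, 0.4), 1)
  # H_O/H_E = 1/0.83 -> F_IS = 0 exactly, retained (boundary)
  expect_equal(fis_statistic(1 / 0.83, 1), 0, tolerance = 1e-12)
  qc <- data.frame(H_O = c(0.4, 0, 1 / 0.83, 0.5), H_E = c(0.4, 0.4, 1, 0.4))
  expect_equal(fis_filter(qc)$keep, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(fis_statistic(0.5, 0), "inconsistent")

  # monotone in H_O/H_E: removal iff ratio exceeds 1/(1 - F_eq)
  ratios <- seq(0, 2, by = 0.05)
  keep <- fis_filter(data.frame(H_O = ratios * 0.3, H_E = 0.3))$keep
  expect_equal(keep, ratios <= 1 / 0.83 + 1e-12)
})

test_that("basic, allele-balance and MAF/MAC filters apply printed thresholds", {
  qc <- data.frame(is_variant = TRUE, qual = 50, call_rate = 1,
                   mean_depth = c(10, 35, 61, 15, 60),
                   allele_balance = NA, MAF = 0.2, MAC = 10)
  expect_equal(filter_basic(qc)$keep, c(FALSE, TRUE, FALSE, TRUE, TRUE))
  qc2 <- data.frame(is_variant = TRUE, qual = c(29, 30), call_rate = c(0.95, 0.94),
                    mean_depth = 35)
  expect_equal(filter_basic(qc2)$keep, c(FALSE, FALSE))
  expect_true(filter_basic(qc2[2, ] |> transform(call_rate = 0.95))$keep)

  ab <- data.frame(allele_balance = c(0.5, 0.15, 0.005, 0.2, 0.8, NA))
  expect_equal(filter_allele_balance(ab)$keep,
               c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))

  mm <- data.frame(is_variant = TRUE, MAF = c(0.05, 0.04, 0), MAC = c(5, 2, 0))
  expect_equal(filter_maf_mac(mm, maf = 0.05)$keep, c(TRUE, FALSE, FALSE))
  expect_equal(filter_maf_mac(mm, mac = 3)$keep, c(TRUE, FALSE, FALSE))
  expect_error(filter_maf_mac(mm), "exactly one")
  expect_error(filter_maf_mac(mm, maf = 0.05, mac = 3), "exactly one")
})

test_that("filter cascade conserves locus counts and records first reasons", {
  set.seed(42)
  gt <- random_gt(300, 40, p_missing = 0.05)
  dp <- simulate_depths(gt, mean_depth = 35, seed = 1)
  rep <- filter_cascade(gt, dp, mac = 3)
  expect_equal(rep$steps$n_in[1], n_loci(gt))
  expect_equal(rep$steps$n_in[-1], rep$steps$n_out[-nrow(rep$steps)])
  expect_equal(sum(rep$steps$n_removed) + n_loci(rep$filtered), n_loci(gt))
  expect_equal(sum(!is.na(rep$removal_reason)), sum(rep$steps$n_removed))
  expect_equal(sum(rep$keep), n_loci(rep$filtered))
})

test_that("cascade on a clean HWE panel removes little beyond nominal levels", {
  set.seed(99)
  p <- runif(4000, 0.1, 0.9)
  gt <- simulate_mixed_mating_population(p, 100, selfing_rate = 0, seed = 99)
  dp <- simulate_depths(gt, mean_depth = 35, seed = 100)
  rep <- filter_cascade(gt, dp, mac = NULL, maf = 0.05)
  hwe_removed <- rep$steps$n_removed[rep$steps$step == "het_excess_hwe"]
  # nominal level 0.05 (excess het) + 1e-5 (HWE); allow 2x
  expect_lt(hwe_removed / n_loci(gt), 2 * 0.05)
  fis_removed <- rep$steps$n_removed[rep$steps$step == "fis"]
  # outbred HWE data sit at F_IS ~ 0.17 under the equilibrium-scaled
  # statistic, so the negative-F_IS filter should fire rarely
  expect_lt(fis_removed / n_loci(gt), 0.10)
})

test_that("D filter separates paralog mimics from faithful het loci", {
  gt <- gt_from_codes(matrix(1L, 400, 50))
  dp_bad <- simulate_depths(gt, mean_depth = 40, het_ab = 0.8, seed = 21)
  dp_ok <- simulate_depths(gt, mean_depth = 40, het_ab = 0.5, seed = 22)
  rm_bad <- mean(!filter_read_ratio(compute_locus_qc(gt, dp_bad))$keep)
  rm_ok <- mean(!filter_read_ratio(compute_locus_qc(gt, dp_ok))$keep)
  expect_gte(rm_bad, 0.99)
  expect_lte(rm_ok, 0.01)
})

test_that("greedy LD pruning follows the window rule", {
  # loci 1 and 2 duplicated -> second dropped
  dup <- gt_from_codes(rbind(c(0L, 0L, 2L, 2L), c(0L, 0L, 2L, 2L)),
                       pos = c(1000L, 2000L))
  expect_equal(ld_prune(dup), c(TRUE, FALSE))

  # independent loci retained
  ind <- gt_from_codes(rbind(c(0L, 0L, 2L, 2L), c(0L, 2L, 0L, 2L)),
                       pos = c(1000L, 2000L))
  expect_equal(ld_prune(ind), c(TRUE, TRUE))

  # chain: 1-2 and 2-3 correlated, 1-3 not -> keep {1, 3}
  x1 <- c(0L, 0L, 1L, 2L, 2L, 0L, 2L, 1L)
  x2 <- c(0L, 0L, 1L, 2L, 2L, 2L, 0L, 1L)   # r2(x1,x2) high
  x3 <- c(2L, 1L, 1L, 2L, 2L, 2L, 0L, 0L)   # r2(x2,x3) high, r2(x1,x3) low
  chain <- gt_from_codes(rbind(x1, x2, x3), pos = c(1e3L, 2e3L, 3e3L))
  r12 <- pairwise_r2(chain, 1, 2); r23 <- pairwise_r2(chain, 2, 3)
  r13 <- pairwise_r2(chain, 1, 3)
  skip_if_not(r12 > 0.1 && r23 > 0.1 && r13 <= 0.1)
  expect_equal(ld_prune(chain), c(TRUE, FALSE, TRUE))

  # outside the window nothing is compared
  expect_equal(ld_prune(dup, window_bp = 500), c(TRUE, TRUE))
})

test_that("VanRaden GRM matches hand arithmetic and flags duplicates", {
  # dosages (ref scale): sample1 = (0,0), sample2 = (2,2); p = 0.5 each
  gt <- gt_from_codes(rbind(c(2L, 0L), c(2L, 0L)), pos = c(100L, 200L))
  A <- grm_vanraden(gt)
  expect_equal(unname(A[1, 2]), -2)
  expect_equal(unname(A[1, 1]), 2)

  set.seed(8)
  gtd <- gt_from_codes(cbind(m <- matrix(sample(0:2, 60, TRUE), 20), m[, 1]))
  Ad <- grm_vanraden(gtd)
  expect_equal(Ad[1, 4], Ad[1, 1])
  expect_gt(Ad[1, 4], 0.2)
  excl <- exclude_related(Ad)
  expect_true(length(excl) >= 1)
  keep <- setdiff(rownames(Ad), excl)
  off <- Ad[keep, keep]; diag(off) <- 0
  expect_true(all(off <= 0.2))

  # unrelated draws: empty exclusion list
  set.seed(9)
  gtu <- gt_from_codes(matrix(rbinom(500 * 10, 2, 0.5), 500, 10))
  expect_length(exclude_related(grm_vanraden(gtu)), 0)
  expect_error(grm_vanraden(gt_from_codes(matrix(0L, 5, 3))), "monomorphic")
})
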