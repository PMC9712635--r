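# small in-code fixtures and independent oracles shared across tests

gt_from_codes <- function(codes, chrom = "s1", pos = NULL,
                          is_variant = TRUE, qual = NA_real_) {
  codes <- as.matrix(codes)
  n <- nrow(codes)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  loci <- data.frame(chrom = rep_len(chrom, n), pos = pos, ref = "A",
                     alt = ifelse(rep_len(is_variant, n), "G", NA_character_),
                     is_variant = rep_len(is_variant, n),
                     qual = rep_len(qual, n))
  genotype_table(codes, loci, paste0("smp", seq_len(ncol(codes))))
}

random_gt <- function(n_loci, n_samples, p_missing = 0.1,
                      p_invariant = 0.3) {
  codes <- matrix(sample(c(0L, 1L, 2L), n_loci * n_samples, replace = TRUE),
                  n_loci, n_samples)
  inv <- runif(n_loci) < p_invariant
  codes[inv, ] <- 0L
  codes[runif(n_loci * n_samples) < p_missing] <- NA_integer_
  gt_from_codes(codes, is_variant = !inv)
}

# brute-force pi: double loop over all allele pairs at all sites
pi_bruteforce <- function(gt) {
  diffs <- 0; comps <- 0
  allele_map <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))
  for (i in seq_len(n_loci(gt))) {
    alleles <- integer(0)
    for (j in seq_len(n_samples(gt))) {
      gcode <- gt$geno[i, j]
      if (!is.na(gcode)) alleles <- c(alleles, allele_map[[gcode + 1L]])
    }
    m <- length(alleles)
    if (m >= 2) {
      for (a in seq_len(m - 1)) for (b in (a + 1):m) {
        comps <- comps + 1
        if (alleles[a] != alleles[b]) diffs <- diffs + 1
      }
    }
  }
  list(diffs = diffs, comps = comps,
       pi = if (comps > 0) diffs / comps else NA_real_)
}

dxy_bruteforce <- function(gt, ia, ib) {
  diffs <- 0; comps <- 0
  allele_map <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))
  pool <- function(i, idx) {
    al <- integer(0)
    for (j in idx) {
      gcode <- gt$geno[i, j]
      if (!is.na(gcode)) al <- c(al, allele_map[[gcode + 1L]])
    }
    al
  }
  for (i in seq_len(n_loci(gt))) {
    aa <- pool(i, ia); bb <- pool(i, ib)
    for (x in aa) for (y in bb) {
      comps <- comps + 1
      if (x != y) diffs <- diffs + 1
    }
  }
  list(diffs = diffs, comps = comps,
       dxy = if (comps > 0) diffs / comps else NA_real_)
}

# exact HWE oracle: enumerate every assignment of the minor alleles to the
# 2n allele slots, pair consecutive slots into individuals, tabulate the
# heterozygote-count distribution
hwe_enum_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n0 + n1
  slots <- 2 * n
  combs <- utils::combn(slots, min(nA, slots - nA))
  hcounts <- apply(combs, 2, function(ix) {
    al <- integer(slots); al[ix] <- 1L
    sum(colSums(matrix(al, nrow = 2)) == 1L)
  })
  tab <- table(hcounts) / ncol(combs)
  hs <- as.integer(names(tab)); probs <- as.numeric(tab)
  pobs <- probs[match(n1, hs)]
  list(p_two = sum(probs[probs <= pobs * (1 + 1e-9)]),
       p_excess = sum(probs[hs >= n1]))
}

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  writeLines(c(hdr, lines), path)
  path
}

# score a corrected panel against the simulator truth record
score_correction <- function(sim, cl) {
  gens <- cl$generations
  truth <- sim$truth$geno[, , gens, drop = FALSE]
  obs <- array(NA_integer_, dim(truth))
  for (gi in seq_along(gens)) {
    cols <- sim$pedigree$sample_id[sim$pedigree$generation == gens[gi]]
    obs[, , gi] <- sim$genotypes$geno[, match(cols, sim$genotypes$sample_ids)]
  }
  kept <- cl$locus_status == "kept"
  corr <- cl$geno[kept, , , drop = FALSE]
  obs_k <- obs[kept, , , drop = FALSE]
  tru_k <- truth[kept, , , drop = FALSE]

  overwritten <- !is.na(obs_k) & !is.na(corr) & obs_k != corr
  erroneous <- !is.na(obs_k) & obs_k != tru_k
  detected <- overwritten & erroneous
  consistent <- !is.na(obs_k) & obs_k == tru_k
  corrupted <- consistent & !is.na(corr) & corr != tru_k

  # line-locus rows containing a fabricated trigger: two generation-
  # adjacent cells that are both erroneous and agree with each other
  ng <- dim(obs_k)[3]
  false_trig <- matrix(FALSE, dim(obs_k)[1], dim(obs_k)[2])
  for (t in seq_len(ng - 1)) {
    a <- obs_k[, , t]; b <- obs_k[, , t + 1]
    ea <- erroneous[, , t]; eb <- erroneous[, , t + 1]
    false_trig <- false_trig |
      (!is.na(a) & !is.na(b) & a == b & ea & eb)
  }
  corrupted_rows <- apply(corrupted, c(1, 2), any)
  list(n_detected = sum(detected),
       n_recovered = sum(detected & corr == tru_k, na.rm = TRUE),
       n_corrupted = sum(corrupted),
       corruption_confined = all(!corrupted_rows | false_trig))
}

# inject miscalls into an error-free panel such that no two generation-
# adjacent cells of the same line-locus are both altered
inject_sparse_miscalls <- function(sim, rate) {
  geno <- sim$genotypes$geno
  ped <- sim$pedigree
  gens <- unique(ped$generation)
  altered <- array(FALSE, dim = c(nrow(geno), length(unique(ped$line_id)),
                                  length(gens)))
  for (gi in seq_along(gens)) {
    cols <- match(ped$sample_id[ped$generation == gens[gi]],
                  sim$genotypes$sample_ids)
    hit <- matrix(runif(nrow(geno) * length(cols)) < rate,
                  nrow(geno), length(cols))
    if (gi > 1) hit <- hit & !altered[, , gi - 1]
    altered[, , gi] <- hit
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx)) {
      cells <- cbind(idx[, 1], cols[idx[, 2]])
      v <- geno[cells]
      geno[cells] <- ifelse(v == 1L,
                            ifelse(runif(length(v)) < 0.5, 0L, 2L), 1L)
    }
  }
  out <- sim
  out$genotypes$geno <- geno
  out
}
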