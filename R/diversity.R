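#' Per-site allele tallies
#'
#' @param gt a [genotype_table()] (possibly subset).
#' @return list of per-locus vectors: `n_ref`, `n_alt` (called allele
#'   counts) and `m` (total called alleles).
#' @keywords internal
allele_tallies <- function(gt) {
  g <- gt$geno
  n0 <- rowSums(g == GENO_HOM_REF, na.rm = TRUE)
  n1 <- rowSums(g == GENO_HET, na.rm = TRUE)
  n2 <- rowSums(g == GENO_HOM_ALT, na.rm = TRUE)
  list(n_ref = 2 * n0 + n1, n_alt = 2 * n2 + n1, m = 2 * (n0 + n1 + n2))
}

#' Nucleotide diversity over a region, missing-data aware
#'
#' Pools the called alleles at every site (two per called genotype) and
#' accumulates pairwise differences and pairwise comparisons separately,
#' so missing data shrink the denominator instead of biasing the
#' estimate toward zero: `pi = sum(diffs) / sum(comparisons)` with
#' per-site `diffs = n_ref * n_alt` and `comparisons = choose(m, 2)`.
#' Invariant sites contribute comparisons only, which is why they must be
#' kept in the input table.
#'
#' @param gt a [genotype_table()] including invariant sites.
#' @param samples optional sample subset (ids or indices).
#' @param region optional `list(chrom =, start =, end =)` (1-based
#'   inclusive); `NULL` uses every locus.
#' @return data.frame (one row): `n_diffs`, `n_comparisons`,
#'   `n_sites_used`, `pi` (`NA` when no comparisons).
#' @export
pi_region <- function(gt, samples = NULL, region = NULL) {
  if (!is.null(samples) && length(samples) == 0) stop("empty sample set")
  sub <- subset_gt(gt, loci = region_index(gt, region), samples = samples)
  tl <- allele_tallies(sub)
  diffs <- as.numeric(tl$n_ref) * tl$n_alt
  comps <- choose(tl$m, 2)
  data.frame(n_diffs = sum(diffs), n_comparisons = sum(comps),
             n_sites_used = sum(tl$m >= 2),
             pi = if (sum(comps) > 0) sum(diffs) / sum(comps) else NA_real_)
}

region_index <- function(gt, region) {
  if (is.null(region)) return(NULL)
  gt$loci$chrom == region$chrom & gt$loci$pos >= region$start &
    gt$loci$pos <= region$end
}

#' Absolute divergence d_XY between two populations
#'
#' Restricts the allele comparisons to cross-population pairs:
#' per site `comparisons = m_A * m_B` and
#' `diffs = n_ref_A * n_alt_B + n_alt_A * n_ref_B`.
#'
#' @param gt a [genotype_table()] including invariant sites.
#' @param pop_a,pop_b disjoint sample id/index sets.
#' @param region optional region as in [pi_region()].
#' @return data.frame (one row): `n_diffs`, `n_comparisons`,
#'   `n_sites_used`, `dxy`.
#' @export
dxy_region <- function(gt, pop_a, pop_b, region = NULL) {
  ia <- if (is.character(pop_a)) match(pop_a, gt$sample_ids) else pop_a
  ib <- if (is.character(pop_b)) match(pop_b, gt$sample_ids) else pop_b
  if (length(intersect(ia, ib))) stop("populations must be disjoint")
  sel <- region_index(gt, region)
  ta <- allele_tallies(subset_gt(gt, loci = sel, samples = ia))
  tb <- allele_tallies(subset_gt(gt, loci = sel, samples = ib))
  diffs <- as.numeric(ta$n_ref) * tb$n_alt + as.numeric(ta$n_alt) * tb$n_ref
  comps <- as.numeric(ta$m) * tb$m
  data.frame(n_diffs = sum(diffs), n_comparisons = sum(comps),
             n_sites_used = sum(ta$m >= 1 & tb$m >= 1),
             dxy = if (sum(comps) > 0) sum(diffs) / sum(comps) else NA_real_)
}

#' Windowed nucleotide diversity
#'
#' @param gt a [genotype_table()] including invariant sites.
#' @param samples optional sample subset.
#' @param window_bp window width (non-overlapping, default 10 kb).
#' @return data.frame: chrom, start, end, n_diffs, n_comparisons,
#'   n_sites_used, pi.
#' @export
pi_windows <- function(gt, samples = NULL, window_bp = 10000) {
  sub <- if (is.null(samples)) gt else subset_gt(gt, samples = samples)
  win <- (sub$loci$pos - 1) %/% window_bp
  key <- paste(sub$loci$chrom, win)
  out <- do.call(rbind, lapply(split(seq_len(n_loci(sub)), key), function(ix) {
    r <- pi_region(subset_gt(sub, loci = ix))
    cbind(data.frame(chrom = sub$loci$chrom[ix[1]],
                     start = win[ix[1]] * window_bp + 1,
                     end = (win[ix[1]] + 1) * window_bp), r)
  }))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# codon-position degeneracy lookup, standard nuclear code
degeneracy_lookup <- function() {
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  codons <- names(gc)
  out <- matrix(NA_integer_, length(codons), 3,
                dimnames = list(codons, c("1", "2", "3")))
  for (cd in codons) {
    for (k in 1:3) {
      variants <- vapply(nts, function(nt) {
        v <- strsplit(cd, "")[[1]]
        v[k] <- nt
        paste(v, collapse = "")
      }, character(1))
      out[cd, k] <- sum(gc[variants] == gc[cd])
    }
  }
  out
}

#' Classify CDS sites by codon degeneracy
#'
#' A site is fourfold degenerate when all four nucleotides at its codon
#' position encode the same amino acid, zerofold when every change is
#' nonsynonymous; twofold and threefold otherwise (standard nuclear
#' code). Minus-strand CDS are reverse-complemented before translation.
#' CDS whose spliced length is not a multiple of three, or that contain
#' an internal stop codon, are skipped with a warning.
#'
#' @param cds data.frame of CDS segments: `cds_id`, `seqid`, `start`,
#'   `end` (1-based inclusive), `strand` ("+"/"-").
#' @param ref_seqs named character vector (or `Biostrings::DNAStringSet`)
#'   of reference sequences keyed by `seqid`.
#' @return data.frame: `seqid`, `pos`, `class` in
#'   `{"0-fold","2-fold","3-fold","4-fold"}`.
#' @export
classify_degeneracy <- function(cds, ref_seqs) {
  if (methods::is(ref_seqs, "DNAStringSet")) {
    ref_seqs <- stats::setNames(as.character(ref_seqs), names(ref_seqs))
  }
  lut <- degeneracy_lookup()
  res <- list()
  for (id in unique(cds$cds_id)) {
    seg <- cds[cds$cds_id == id, ]
    seg <- seg[order(seg$start), ]
    chrom <- seg$seqid[1]
    pos <- unlist(Map(seq, seg$start, seg$end))
    seq <- paste(substring(ref_seqs[[chrom]], seg$start, seg$end),
                 collapse = "")
    if (nchar(seq) %% 3 != 0) {
      warning("CDS ", id, " length not a multiple of 3; skipped")
      next
    }
    minus <- seg$strand[1] == "-"
    if (minus) {
      seq <- chartr("ACGTacgt", "TGCAtgca",
                    paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
      pos <- rev(pos)
    }
    seq <- toupper(seq)
    n_cod <- nchar(seq) / 3
    codons <- substring(seq, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
    aa <- Biostrings::GENETIC_CODE[codons]
    if (any(aa[-n_cod] == "*", na.rm = TRUE)) {
      warning("CDS ", id, " has an internal stop codon; skipped")
      next
    }
    is_stop <- rep(aa == "*", each = 3)
    ok <- !is.na(rep(aa, each = 3)) & !is_stop
    deg <- rep(NA_integer_, length(pos))
    cod_rep <- rep(codons, each = 3)
    cpos <- rep(1:3, n_cod)
    deg[ok] <- lut[cbind(cod_rep[ok], as.character(cpos[ok]))]
    # deg counts the nucleotides encoding the reference amino acid:
    # 1 -> every change is nonsynonymous (0-fold) ... 4 -> none is (4-fold)
    res[[id]] <- data.frame(seqid = chrom, pos = pos[ok],
                            class = c("0-fold", "2-fold", "3-fold",
                                      "4-fold")[deg[ok]])
  }
  if (!length(res)) {
    return(data.frame(seqid = character(), pos = integer(),
                      class = character()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Diversity at zerofold and fourfold degenerate sites
#'
#' Restricts [pi_region()] to the 0-fold and 4-fold site sets and
#' reports their ratio, an index of the strength of purifying selection.
#'
#' @param gt a [genotype_table()] including invariant sites.
#' @param degeneracy a [classify_degeneracy()] table covering the loci.
#' @param samples optional sample subset.
#' @return data.frame (one row): `pi_0`, `pi_4`, `ratio` (`NA` when
#'   pi_4 is 0 or undefined).
#' @export
pi_by_degeneracy <- function(gt, degeneracy, samples = NULL) {
  key <- paste(gt$loci$chrom, gt$loci$pos)
  k0 <- key %in% paste(degeneracy$seqid, degeneracy$pos)[degeneracy$class == "0-fold"]
  k4 <- key %in% paste(degeneracy$seqid, degeneracy$pos)[degeneracy$class == "4-fold"]
  p0 <- pi_region(subset_gt(gt, loci = k0), samples = samples)$pi
  p4 <- pi_region(subset_gt(gt, loci = k4), samples = samples)$pi
  data.frame(pi_0 = p0, pi_4 = p4,
             ratio = if (!is.na(p4) && p4 > 0) p0 / p4 else NA_real_)
}

#' Folded site frequency spectrum
#'
#' Histogram of per-locus minor-allele counts over biallelic variant
#' loci. The default is complete-case (loci with any missing call are
#' dropped); with `projection = m`, each locus with at least `m` called
#' alleles contributes its expected hypergeometric bin mass after
#' down-projection to `m` alleles, and loci with fewer are dropped.
#'
#' @param gt a [genotype_table()].
#' @param samples optional sample subset.
#' @param projection optional even projection size in alleles.
#' @return named numeric vector of bin masses indexed by minor-allele
#'   count 0..floor(n/2); attribute `n_loci_used` counts contributing loci.
#' @export
folded_sfs <- function(gt, samples = NULL, projection = NULL) {
  sub <- if (is.null(samples)) gt else subset_gt(gt, samples = samples)
  sub <- subset_gt(sub, loci = sub$loci$is_variant)
  tl <- allele_tallies(sub)
  if (is.null(projection)) {
    full <- tl$m == 2 * n_samples(sub)
    n_alleles <- 2 * n_samples(sub)
    bins <- numeric(n_alleles %/% 2 + 1)
    minor <- pmin(tl$n_alt[full], tl$n_ref[full])
    tab <- table(factor(minor, levels = 0:(n_alleles %/% 2)))
    bins <- as.numeric(tab)
    used <- sum(full)
  } else {
    m <- projection
    usable <- which(tl$m >= m)
    bins <- numeric(m %/% 2 + 1)
    for (i in usable) {
      pr <- stats::dhyper(0:m, tl$n_alt[i], tl$n_ref[i], m)
      fold <- pmin(0:m, m - (0:m))
      for (j in 0:m) bins[fold[j + 1] + 1] <- bins[fold[j + 1] + 1] + pr[j + 1]
    }
    used <- length(usable)
  }
  names(bins) <- seq_along(bins) - 1
  attr(bins, "n_loci_used") <- used
  bins
}
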