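#' Per-locus quality-control statistics
#'
#' Computes, over called genotypes only: call rate, mean depth, observed
#' heterozygosity H_O, expected heterozygosity H_E = 2*p*(1-p) with p the
#' plug-in reference-allele frequency, minor-allele frequency and count,
#' site-level allele balance (pooled alternate-read fraction over
#' heterozygous calls), the read-ratio deviation score
#' D = (sum(ref) - sum(alt)) / sqrt(sum(ref) + sum(alt)) over pooled
#' heterozygous-call reads, exact Hardy-Weinberg p-values (two-sided and
#' one-sided excess-heterozygosity), and the inbreeding-coefficient
#' statistic F_IS = 1 - (H_O / H_E) * (1 - F_eq).
#'
#' @param gt a [genotype_table()].
#' @param dp optional [depth_table()] aligned to `gt`; when absent,
#'   depth-dependent fields are `NA`.
#' @param f_eq equilibrium fixation index used in F_IS (default 0.17, the
#'   value implied by an outcrossing rate of 0.7).
#' @return data.frame with one row per locus (class `locus_qc`).
#' @export
compute_locus_qc <- function(gt, dp = NULL, f_eq = 0.17) {
  g <- gt$geno
  ns <- n_samples(gt)
  if (!is.null(dp) && !all(dim(dp$total) == dim(g))) {
    stop("depth table dimensions do not match the genotype table")
  }
  n0 <- rowSums(g == GENO_HOM_REF, na.rm = TRUE)
  n1 <- rowSums(g == GENO_HET, na.rm = TRUE)
  n2 <- rowSums(g == GENO_HOM_ALT, na.rm = TRUE)
  nc <- n0 + n1 + n2
  call_rate <- nc / ns
  p_ref <- ifelse(nc > 0, (2 * n0 + n1) / (2 * nc), NA_real_)
  H_O <- ifelse(nc > 0, n1 / nc, NA_real_)
  H_E <- 2 * p_ref * (1 - p_ref)
  ref_count <- 2 * n0 + n1
  alt_count <- 2 * n2 + n1
  MAC <- pmin(ref_count, alt_count)
  MAF <- ifelse(nc > 0, MAC / (2 * nc), NA_real_)

  mean_depth <- allele_balance <- D <- rep(NA_real_, nrow(g))
  if (!is.null(dp)) {
    mean_depth <- rowMeans(dp$total)
    het <- !is.na(g) & g == GENO_HET
    refm <- dp$ref; altm <- dp$alt
    refm[!het] <- 0L; altm[!het] <- 0L
    A <- rowSums(refm); B <- rowSums(altm)
    has_het <- n1 > 0 & (A + B) > 0
    allele_balance[has_het] <- B[has_het] / (A + B)[has_het]
    D[has_het] <- (A[has_het] - B[has_het]) / sqrt((A + B)[has_het])
  }

  hw <- hwe_exact(n0, n1, n2)
  F_IS <- fis_statistic(H_O, H_E, f_eq)

  out <- data.frame(chrom = gt$loci$chrom, pos = gt$loci$pos,
                    is_variant = gt$loci$is_variant,
                    qual = gt$loci$qual,
                    call_rate = call_rate, mean_depth = mean_depth,
                    p_ref = p_ref, H_O = H_O, H_E = H_E,
                    MAF = MAF, MAC = MAC,
                    allele_balance = allele_balance, D = D,
                    p_hwe = hw$p_two, p_excess_het = hw$p_excess,
                    F_IS = F_IS)
  class(out) <- c("locus_qc", "data.frame")
  out
}

#' Inbreeding-coefficient statistic for the F_IS filter
#'
#' `F_IS = 1 - (H_O / H_E) * (1 - F_eq)`: the factor `(1 - F_eq)` rescales
#' the Hardy-Weinberg expectation to the heterozygosity expected at
#' mixed-mating equilibrium, so a locus matching that equilibrium scores
#' F_IS = F_eq and a paralog-like excess-heterozygosity locus scores
#' negative.
#'
#' @param H_O,H_E observed and expected heterozygosity (vectors).
#' @param f_eq equilibrium fixation index.
#' @return numeric vector; `NA` where H_E = 0 and H_O = 0 (monomorphic).
#' @export
fis_statistic <- function(H_O, H_E, f_eq = 0.17) {
  bad <- !is.na(H_E) & H_E == 0 & !is.na(H_O) & H_O > 0
  if (any(bad)) {
    stop("inconsistent locus: H_E = 0 with H_O > 0")
  }
  ifelse(!is.na(H_E) & H_E > 0, 1 - (H_O / H_E) * (1 - f_eq), NA_real_)
}

#' Exact Hardy-Weinberg test from genotype counts
#'
#' Full enumeration of the conditional distribution of the heterozygote
#' count given the allele counts (no mid-p correction). Returns the
#' two-sided p (probability of configurations no more likely than the
#' observed one) and the one-sided excess-heterozygosity p (observed or
#' more heterozygotes).
#'
#' @param n0,n1,n2 integer vectors of HOM_REF, HET, HOM_ALT counts.
#' @return list of numeric vectors `p_two` and `p_excess` (1 for
#'   monomorphic or empty loci).
#' @export
hwe_exact <- function(n0, n1, n2) {
  m <- length(n0)
  p_two <- p_excess <- rep(1, m)
  for (i in seq_len(m)) {
    n <- n0[i] + n1[i] + n2[i]
    nA <- 2L * n0[i] + n1[i]
    nB <- 2L * n2[i] + n1[i]
    if (n == 0 || nA == 0 || nB == 0) next
    rare <- min(nA, nB)
    hs <- seq.int(rare %% 2L, rare, by = 2L)
    lw <- hs * log(2) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
      lfactorial((nB - hs) / 2)
    w <- exp(lw - max(lw))
    pr <- w / sum(w)
    obs <- match(n1[i], hs)
    p_two[i] <- sum(pr[pr <= pr[obs] * (1 + 1e-12)])
    p_excess[i] <- sum(pr[hs >= n1[i]])
  }
  list(p_two = pmin(p_two, 1), p_excess = pmin(p_excess, 1))
}

filter_step <- function(name, params, keep) {
  list(name = name, params = params, keep = keep)
}

#' Basic site filters (missingness, quality, mean depth)
#'
#' Retains loci with call rate >= `max_missing`, site quality >= `minQ`
#' (skipped where quality is absent, and not applied to invariant sites),
#' and mean depth within \[`min_meanDP`, `max_meanDP`\]. All boundaries
#' are inclusive.
#'
#' @param qc a [compute_locus_qc()] table.
#' @param max_missing minimum call rate.
#' @param minQ minimum site quality (variant sites only).
#' @param min_meanDP,max_meanDP mean-depth bounds.
#' @return a filter step (name, params, logical `keep`).
#' @export
filter_basic <- function(qc, max_missing = 0.95, minQ = 30,
                         min_meanDP = 15, max_meanDP = 60) {
  keep <- qc$call_rate >= max_missing &
    (!qc$is_variant | is.na(qc$qual) | qc$qual >= minQ) &
    (is.na(qc$mean_depth) |
       (qc$mean_depth >= min_meanDP & qc$mean_depth <= max_meanDP))
  filter_step("basic", list(max_missing = max_missing, minQ = minQ,
                            min_meanDP = min_meanDP, max_meanDP = max_meanDP),
              keep)
}

#' Allele-balance filter
#'
#' Retains loci whose pooled heterozygous-call allele balance lies
#' strictly inside (`lo`, `hi`) or below `ref_only` (the near-zero branch
#' retains sites whose few alternate reads are presumably errors). Loci
#' with no heterozygous calls pass vacuously.
#'
#' @param qc a [compute_locus_qc()] table.
#' @param lo,hi open-interval bounds for the balanced branch.
#' @param ref_only upper bound of the near-zero branch.
#' @return a filter step.
#' @export
filter_allele_balance <- function(qc, lo = 0.2, hi = 0.8, ref_only = 0.01) {
  ab <- qc$allele_balance
  keep <- is.na(ab) | (ab > lo & ab < hi) | ab < ref_only
  filter_step("allele_balance", list(lo = lo, hi = hi, ref_only = ref_only),
              keep)
}

#' Read-ratio deviation filter
#'
#' Removes loci whose pooled heterozygous-call read counts deviate from
#' the balanced expectation: |D| > `max_abs_d` with
#' D = (sum(ref) - sum(alt)) / sqrt(sum(ref) + sum(alt)). Loci with no
#' heterozygous calls pass.
#'
#' @param qc a [compute_locus_qc()] table.
#' @param max_abs_d removal threshold on |D|.
#' @return a filter step.
#' @export
filter_read_ratio <- function(qc, max_abs_d = 5) {
  keep <- is.na(qc$D) | abs(qc$D) <= max_abs_d
  filter_step("read_ratio_D", list(max_abs_d = max_abs_d), keep)
}

#' Excess-heterozygosity and Hardy-Weinberg filters
#'
#' Removes loci with observed heterozygosity > `max_het`, one-sided
#' excess-heterozygosity exact p < `p_excess`, or two-sided exact HWE
#' p < `p_hwe` (computed on the designated reference population).
#'
#' @param qc a [compute_locus_qc()] table for the reference population.
#' @param max_het maximum observed heterozygosity.
#' @param p_excess one-sided excess-het p cutoff.
#' @param p_hwe two-sided HWE p cutoff.
#' @return a filter step.
#' @export
filter_het_excess <- function(qc, max_het = 0.55, p_excess = 0.05,
                              p_hwe = 1e-5) {
  keep <- (is.na(qc$H_O) | qc$H_O <= max_het) &
    (is.na(qc$p_excess_het) | qc$p_excess_het >= p_excess) &
    (is.na(qc$p_hwe) | qc$p_hwe >= p_hwe)
  filter_step("het_excess_hwe", list(max_het = max_het, p_excess = p_excess,
                                     p_hwe = p_hwe), keep)
}

#' Negative-F_IS filter
#'
#' Removes loci with strictly negative `F_IS = 1 - (H_O/H_E)*(1 - f_eq)`;
#' the boundary F_IS = 0 is retained. Monomorphic loci (H_E = 0) pass.
#'
#' @param qc a [compute_locus_qc()] table.
#' @param f_eq equilibrium fixation index (default 0.17).
#' @return a filter step.
#' @export
fis_filter <- function(qc, f_eq = 0.17) {
  fis <- fis_statistic(qc$H_O, qc$H_E, f_eq)
  keep <- is.na(fis) | fis >= 0
  filter_step("fis", list(f_eq = f_eq), keep)
}

#' Minor-allele frequency or count filter
#'
#' Exactly one of `maf` or `mac` must be given; loci at or above the
#' threshold are retained. Invariant sites are not subject to this filter.
#'
#' @param qc a [compute_locus_qc()] table.
#' @param maf minor-allele frequency threshold, or `NULL`.
#' @param mac minor-allele count threshold, or `NULL`.
#' @return a filter step.
#' @export
filter_maf_mac <- function(qc, maf = NULL, mac = NULL) {
  if (is.null(maf) == is.null(mac)) {
    stop("give exactly one of 'maf' or 'mac'")
  }
  if (!is.null(maf)) {
    keep <- !qc$is_variant | (!is.na(qc$MAF) & qc$MAF >= maf)
    filter_step("maf", list(maf = maf), keep)
  } else {
    keep <- !qc$is_variant | (!is.na(qc$MAC) & qc$MAC >= mac)
    filter_step("mac", list(mac = mac), keep)
  }
}

#' Greedy LD pruning
#'
#' Scans each scaffold in position order and drops a locus whose squared
#' dosage correlation with any already-retained locus within `window_bp`
#' exceeds `r2_max`. Deterministic given the input order. Monomorphic or
#' invariant loci are never dropped (their r-squared is undefined).
#'
#' @param gt a [genotype_table()].
#' @param r2_max maximum allowed r-squared.
#' @param window_bp window width in bp.
#' @param samples optional sample subset used for the correlations.
#' @return logical vector over loci: `TRUE` = retained.
#' @export
ld_prune <- function(gt, r2_max = 0.1, window_bp = 2.17e6, samples = NULL) {
  if (!is.null(samples)) gt <- subset_gt(gt, samples = samples)
  keep <- rep(TRUE, n_loci(gt))
  dos <- gt$geno
  for (sc in unique(gt$loci$chrom)) {
    ix <- which(gt$loci$chrom == sc)
    kept <- integer(0)
    for (i in ix) {
      near <- kept[gt$loci$pos[i] - gt$loci$pos[kept] <= window_bp]
      drop <- FALSE
      for (j in near) {
        r2 <- pairwise_r2_vec(dos[j, ], dos[i, ])
        if (!is.na(r2) && r2 > r2_max) { drop <- TRUE; break }
      }
      if (drop) keep[i] <- FALSE else kept <- c(kept, i)
    }
  }
  keep
}

#' Run the SNP filter cascade
#'
#' Applies the filter steps in order to the variant loci of a table and
#' the basic (missingness and depth, no quality) step to invariant loci,
#' recording per-step bookkeeping and the first filter that removed each
#' locus. The default order follows the methods narrative: basic ->
#' allele balance -> read-ratio D -> excess het / HWE -> F_IS -> MAF or
#' MAC -> optional LD pruning.
#'
#' @param gt a [genotype_table()].
#' @param dp optional [depth_table()].
#' @param qc_population optional [genotype_table()] whose genotypes supply
#'   the heterozygosity/HWE/F_IS statistics (the reference population);
#'   defaults to `gt` itself. Must share loci with `gt`.
#' @param max_missing,minQ,min_meanDP,max_meanDP see [filter_basic()].
#' @param ab_lo,ab_hi,ab_ref_only see [filter_allele_balance()].
#' @param max_abs_d see [filter_read_ratio()].
#' @param max_het,p_excess,p_hwe see [filter_het_excess()].
#' @param f_eq see [fis_filter()].
#' @param maf,mac see [filter_maf_mac()].
#' @param ld list(r2_max =, window_bp =) to enable LD pruning, or `NULL`.
#' @return list of class `filter_report`: `steps` (data.frame: step,
#'   n_in, n_removed, n_out), `keep` (logical over loci),
#'   `removal_reason` (character, `NA` for retained loci), and
#'   `filtered` (the retained [genotype_table()]).
#' @export
filter_cascade <- function(gt, dp = NULL, qc_population = NULL,
                           max_missing = 0.95, minQ = 30,
                           min_meanDP = 15, max_meanDP = 60,
                           ab_lo = 0.2, ab_hi = 0.8, ab_ref_only = 0.01,
                           max_abs_d = 5,
                           max_het = 0.55, p_excess = 0.05, p_hwe = 1e-5,
                           f_eq = 0.17, maf = NULL, mac = 3, ld = NULL) {
  qc <- compute_locus_qc(gt, dp, f_eq = f_eq)
  if (!is.null(qc_population)) {
    qc_pop <- compute_locus_qc(qc_population, NULL, f_eq = f_eq)
    if (nrow(qc_pop) != nrow(qc)) stop("qc_population loci do not match")
    pop_cols <- c("H_O", "H_E", "p_hwe", "p_excess_het", "F_IS")
    qc[pop_cols] <- qc_pop[pop_cols]
  }
  steps <- list(
    function(q) filter_basic(q, max_missing, minQ, min_meanDP, max_meanDP),
    function(q) filter_allele_balance(q, ab_lo, ab_hi, ab_ref_only),
    function(q) filter_read_ratio(q, max_abs_d),
    function(q) filter_het_excess(q, max_het, p_excess, p_hwe),
    function(q) fis_filter(q, f_eq),
    function(q) filter_maf_mac(q, maf = maf, mac = mac)
  )
  nl <- n_loci(gt)
  alive <- rep(TRUE, nl)
  reason <- rep(NA_character_, nl)
  book <- data.frame(step = character(), n_in = integer(),
                     n_removed = integer(), n_out = integer())
  variant <- gt$loci$is_variant
  for (f in steps) {
    st <- f(qc)
    # invariant sites only face the basic step (without minQ, which
    # filter_basic already skips for them)
    drop <- alive & !st$keep & (variant | st$name == "basic")
    reason[drop] <- st$name
    book <- rbind(book, data.frame(step = st$name, n_in = sum(alive),
                                   n_removed = sum(drop),
                                   n_out = sum(alive) - sum(drop)))
    alive <- alive & !drop
  }
  if (!is.null(ld)) {
    sub <- subset_gt(gt, loci = alive)
    keep_ld <- ld_prune(sub, r2_max = ld$r2_max, window_bp = ld$window_bp)
    idx <- which(alive)
    drop <- idx[!keep_ld]
    reason[drop] <- "ld_prune"
    book <- rbind(book, data.frame(step = "ld_prune", n_in = length(idx),
                                   n_removed = length(drop),
                                   n_out = length(idx) - length(drop)))
    alive[drop] <- FALSE
  }
  structure(list(steps = book, keep = alive, removal_reason = reason,
                 filtered = subset_gt(gt, loci = alive)),
            class = "filter_report")
}

#' @exportS3Method base::print
print.filter_report <- function(x, ...) {
  cat("SNP filter cascade:\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' VanRaden genomic relationship matrix
#'
#' `A = Z %*% t(Z) / (2 * sum(p * (1 - p)))` where Z is the
#' reference-allele dosage matrix centered by `2 * p` (missing dosages
#' imputed to the center, i.e. contribute 0). Monomorphic loci are
#' dropped; an all-monomorphic table is an error.
#'
#' @param gt a [genotype_table()].
#' @return symmetric samples x samples matrix.
#' @export
grm_vanraden <- function(gt) {
  if (n_samples(gt) < 2) stop("need at least 2 samples")
  g <- gt$geno
  dos <- 2 - g  # reference-allele dosage
  n0 <- rowSums(g == GENO_HOM_REF, na.rm = TRUE)
  n1 <- rowSums(g == GENO_HET, na.rm = TRUE)
  nc <- rowSums(!is.na(g))
  p <- ifelse(nc > 0, (2 * n0 + n1) / (2 * nc), NA_real_)
  poly <- !is.na(p) & p > 0 & p < 1 & gt$loci$is_variant
  if (!any(poly)) stop("all loci monomorphic: relationship matrix undefined")
  Z <- dos[poly, , drop = FALSE] - 2 * p[poly]
  Z[is.na(Z)] <- 0
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  A <- crossprod(Z) / denom
  dimnames(A) <- list(gt$sample_ids, gt$sample_ids)
  A
}

#' Exclude samples until no pair exceeds a relatedness threshold
#'
#' Greedy minimum-set heuristic: repeatedly drop the sample involved in
#' the most violating pairs (off-diagonal relatedness > `max_rel`),
#' breaking ties by higher mean relatedness, then input order.
#'
#' @param A relationship matrix from [grm_vanraden()].
#' @param max_rel maximum tolerated pairwise relatedness.
#' @return character vector of excluded sample ids (possibly empty).
#' @export
exclude_related <- function(A, max_rel = 0.2) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  ids <- rownames(A)
  excluded <- character(0)
  active <- rep(TRUE, nrow(A))
  repeat {
    B <- A[active, active, drop = FALSE]
    viol <- B > max_rel
    diag(viol) <- FALSE
    if (!any(viol)) break
    counts <- rowSums(viol)
    cand <- which(counts == max(counts))
    if (length(cand) > 1) {
      meanrel <- rowSums(B[cand, , drop = FALSE]) - diag(B)[cand]
      cand <- cand[which.max(meanrel)]
    }
    worst <- rownames(B)[cand[1]]
    excluded <- c(excluded, worst)
    active[match(worst, ids)] <- FALSE
  }
  excluded
}
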