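#' Expected fixation proportions under neutral selfing drift
#'
#' From a heterozygous founder, heterozygosity halves every selfed
#' generation, and each generation's lost heterozygosity splits equally
#' between the two homozygotes: at generation t,
#' `p_het = (1/2)^t` and `p_hom_ref = p_hom_alt = (1 - (1/2)^t) / 2`.
#' At t = 4 this gives the familiar 6.25% / 46.875% / 46.875%.
#'
#' @param t generation index (integer >= 0; t = 0 is the founder).
#' @return named numeric vector `(p_het, p_hom_ref, p_hom_alt)`.
#' @export
expected_fixation_proportions <- function(t) {
  if (t < 0 || t != round(t)) stop("t must be a non-negative integer")
  p_het <- 0.5^t
  c(p_het = p_het, p_hom_ref = (1 - p_het) / 2, p_hom_alt = (1 - p_het) / 2)
}

#' Tabulate fixation outcomes of founder-heterozygous loci
#'
#' For each kept locus, counts the selfing lines whose founder (FS) is
#' heterozygous and whose genotype at the target generation is
#' non-missing, split into fixed-for-reference, fixed-for-alternate and
#' still-heterozygous. Loci informative in fewer than `min_lines` lines
#' are excluded from testing. S5 is deliberately not substituted when S4
#' is absent.
#'
#' @param cl a [correct_panel()] result.
#' @param generation target generation label (default "S4").
#' @param min_lines minimum informative lines (default 3).
#' @return data.frame: `locus` (row index into `cl$loci`), `chrom`,
#'   `pos`, `k`, `n_hom_ref`, `n_hom_alt`, `n_het`.
#' @export
tabulate_fixation <- function(cl, generation = "S4", min_lines = 3) {
  gi <- match(generation, cl$generations)
  if (is.na(gi)) stop("generation ", generation, " absent from panel")
  fs <- cl$geno[, , match("FS", cl$generations), drop = FALSE][, , 1]
  gg <- cl$geno[, , gi, drop = FALSE][, , 1]
  if (is.null(dim(fs))) { fs <- matrix(fs, ncol = 1); gg <- matrix(gg, ncol = 1) }
  informative <- !is.na(fs) & fs == GENO_HET & !is.na(gg)
  use <- cl$locus_status == "kept"
  gg[!informative] <- NA_integer_
  n0 <- rowSums(gg == GENO_HOM_REF, na.rm = TRUE)
  n1 <- rowSums(gg == GENO_HET, na.rm = TRUE)
  n2 <- rowSums(gg == GENO_HOM_ALT, na.rm = TRUE)
  k <- n0 + n1 + n2
  sel <- use & k >= min_lines
  data.frame(locus = which(sel), chrom = cl$loci$chrom[sel],
             pos = cl$loci$pos[sel], k = k[sel],
             n_hom_ref = n0[sel], n_hom_alt = n2[sel], n_het = n1[sel])
}

#' Chi-square test against neutral-drift fixation expectations
#'
#' Per locus, `chi2 = sum((obs - exp)^2 / exp)` over the three fixation
#' categories with expected counts `k * expected_fixation_proportions(t)`;
#' df = 2, no continuity correction, upper-tail asymptotic p-values
#' (used even at small k, matching the study procedure). Benjamini-
#' Hochberg q-values are appended across all tested loci, with
#' significance at `fdr`, and each significant locus is flagged by the
#' categories observed in excess of expectation.
#'
#' @param counts a [tabulate_fixation()] table.
#' @param t generation index for the expectations (default 4).
#' @param fdr false-discovery-rate threshold (default 0.05).
#' @return `counts` with columns added: `exp_hom_ref`, `exp_hom_alt`,
#'   `exp_het`, `chi2`, `p`, `q`, `significant`, `excess_fix_ref`,
#'   `excess_fix_alt`, `excess_het`.
#' @export
chi2_drift_test <- function(counts, t = 4, fdr = 0.05) {
  pr <- expected_fixation_proportions(t)
  if (nrow(counts) == 0) {
    counts[c("exp_hom_ref", "exp_hom_alt", "exp_het", "chi2", "p", "q")] <-
      numeric(0)
    counts[c("significant", "excess_fix_ref", "excess_fix_alt",
             "excess_het")] <- logical(0)
    return(counts)
  }
  if (any(counts$k == 0)) stop("k = 0 locus in fixation counts")
  eref <- counts$k * pr[["p_hom_ref"]]
  ealt <- counts$k * pr[["p_hom_alt"]]
  ehet <- counts$k * pr[["p_het"]]
  chi2 <- (counts$n_hom_ref - eref)^2 / eref +
    (counts$n_hom_alt - ealt)^2 / ealt +
    (counts$n_het - ehet)^2 / ehet
  p <- stats::pchisq(chi2, df = 2, lower.tail = FALSE)
  q <- bh_fdr(p)
  counts$exp_hom_ref <- eref
  counts$exp_hom_alt <- ealt
  counts$exp_het <- ehet
  counts$chi2 <- chi2
  counts$p <- p
  counts$q <- q
  counts$significant <- q <= fdr
  counts$excess_fix_ref <- counts$n_hom_ref > eref
  counts$excess_fix_alt <- counts$n_hom_alt > ealt
  counts$excess_het <- counts$n_het > ehet
  counts
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up procedure (`p.adjust(method = "BH")`); q-values are
#' monotone non-decreasing in p rank and rejection at level `q` is
#' `q_value <= q`.
#'
#' @param p vector of p-values in (0, 1].
#' @return numeric vector of q-values (empty for empty input).
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Fisher's exact enrichment of annotation categories among outliers
#'
#' For each category, builds the 2x2 table (in category x significant)
#' over tested loci and applies the two-sided hypergeometric exact test;
#' the direction of enrichment is read off the odds ratio.
#'
#' @param categories character vector of per-locus category labels.
#' @param significant logical vector aligned with `categories`.
#' @return data.frame per category: counts `a` (significant, in),
#'   `b` (significant, out), `c` (not significant, in), `d` (not
#'   significant, out), `odds_ratio`, `p`.
#' @export
fisher_enrichment <- function(categories, significant) {
  stopifnot(length(categories) == length(significant))
  ok <- !is.na(categories)
  categories <- categories[ok]; significant <- significant[ok]
  cats <- sort(unique(categories))
  out <- do.call(rbind, lapply(cats, function(cat) {
    inc <- categories == cat
    a <- sum(inc & significant); b <- sum(!inc & significant)
    cc <- sum(inc & !significant); d <- sum(!inc & !significant)
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))
    data.frame(category = cat, a = a, b = b, c = cc, d = d,
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  }))
  rownames(out) <- NULL
  out
}
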