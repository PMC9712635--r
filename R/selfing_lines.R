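#' Correct one selfing-line genotype vector across generations
#'
#' Applies two rules justified by single-seed descent: (1) two
#' consecutive identical homozygous calls force that homozygote for every
#' later generation (a homozygote breeds true, so any later heterozygous
#' or opposite-homozygous call must be a genotyping error); (2) two
#' consecutive heterozygous calls force heterozygosity for every earlier
#' generation including the founder (a heterozygous offspring requires a
#' heterozygous parent). Rule triggers are evaluated on the observed
#' calls only, in a single pass, so correction is idempotent. Missing
#' entries never trigger a rule but are overwritten (imputed) when a rule
#' covers their slot. If the rules imply contradictory values - two
#' consecutive homozygous calls for different alleles in order, or a
#' heterozygous trigger inside a region forced homozygous (and vice
#' versa) - the locus cannot be corrected and is flagged for removal.
#'
#' @param v integer genotype-code vector ordered founder to last
#'   generation (codes 0/1/2, `NA` missing).
#' @return list: `corrected` (vector), `status` (`"kept"` or
#'   `"removed_uncorrectable"`), `provenance` (per entry: `observed`,
#'   `corrected`, `imputed`, or `missing`).
#' @export
correct_line <- function(v) {
  res <- correct_line_matrix(matrix(v, nrow = 1))
  list(corrected = as.vector(res$corrected), status = res$status,
       provenance = as.vector(res$provenance))
}

#' Vectorized genotype correction over loci
#'
#' Same rules as [correct_line()], applied to every row of a loci x
#' generations matrix at once.
#'
#' @param M integer matrix, loci in rows, ordered generations in columns.
#' @return list: `corrected` matrix, `status` per row, `provenance`
#'   character matrix.
#' @keywords internal
correct_line_matrix <- function(M) {
  L <- nrow(M); g <- ncol(M)
  status <- rep("kept", L)
  out <- M
  if (g >= 2) {
    eq <- function(a, b) !is.na(a) & !is.na(b) & a == b
    # trigger pair starting at column j
    ref_pair <- het_pair <- alt_pair <- matrix(FALSE, L, g - 1)
    for (j in seq_len(g - 1)) {
      ref_pair[, j] <- eq(M[, j], 0L) & eq(M[, j + 1], 0L)
      alt_pair[, j] <- eq(M[, j], 2L) & eq(M[, j + 1], 2L)
      het_pair[, j] <- eq(M[, j], 1L) & eq(M[, j + 1], 1L)
    }
    any_ref <- rowSums(ref_pair) > 0
    any_alt <- rowSums(alt_pair) > 0
    hom_pair <- ref_pair | alt_pair
    any_hom <- any_ref | any_alt
    any_het <- rowSums(het_pair) > 0
    first_idx <- function(mat) {
      # index of first TRUE per row, NA when none
      idx <- max.col(mat, ties.method = "first")
      idx[rowSums(mat) == 0] <- NA_integer_
      idx
    }
    last_idx <- function(mat) {
      idx <- (g - 1) + 1 - max.col(mat[, (g - 1):1, drop = FALSE],
                                   ties.method = "first")
      idx[rowSums(mat) == 0] <- NA_integer_
      idx
    }
    fh <- first_idx(hom_pair)   # earliest homozygous trigger start
    lh <- last_idx(het_pair)    # latest heterozygous trigger start

    # contradictions: opposite homozygous triggers in one vector, or a
    # heterozygous trigger slot inside the region forced homozygous
    # (equivalently a homozygous trigger inside the region forced
    # heterozygous) - both reduce to lh >= fh + 1
    conflict <- (any_ref & any_alt) |
      (any_hom & any_het & !is.na(fh) & !is.na(lh) & lh >= fh + 1)

    hom_rows <- which(!conflict & !is.na(fh))
    if (length(hom_rows)) {
      allele <- ifelse(ref_pair[cbind(hom_rows, fh[hom_rows])], 0L, 2L)
      for (k in seq_len(g)) {
        sel <- fh[hom_rows] + 2 <= k
        out[hom_rows[sel], k] <- allele[sel]
      }
    }
    het_rows <- which(!conflict & !is.na(lh) & lh >= 2)
    if (length(het_rows)) {
      for (k in seq_len(g - 1)) {
        out[het_rows[lh[het_rows] - 1 >= k], k] <- 1L
      }
    }
    status[conflict] <- "removed_uncorrectable"
  }
  prov <- matrix("missing", L, g)
  prov[!is.na(M) & !is.na(out) & M == out] <- "observed"
  prov[!is.na(M) & !is.na(out) & M != out] <- "corrected"
  prov[is.na(M) & !is.na(out)] <- "imputed"
  list(corrected = out, status = status, provenance = prov)
}

#' Impute the S3 generation from its selfing neighbours
#'
#' For lines lacking an S3 sample, the S3 genotype is forced by the
#' selfing constraints whenever only one genotype is possible:
#' identical homozygous S2 and S4 force that homozygote (homozygotes
#' breed true); a heterozygous S4 forces a heterozygous S3 (a
#' heterozygous offspring needs a heterozygous parent). A heterozygous
#' S2 with homozygous S4 leaves two possibilities and stays missing.
#' Opposite homozygotes, or homozygous S2 with heterozygous S4, are
#' impossible under selfing and flag the locus as uncorrectable.
#'
#' @param s2,s4 integer genotype-code vectors (possibly corrected).
#' @return list: `s3` (imputed codes, `NA` where ambiguous) and `status`
#'   (`"kept"` or `"removed_uncorrectable"` per locus).
#' @export
impute_s3 <- function(s2, s4) {
  stopifnot(length(s2) == length(s4))
  s3 <- rep(NA_integer_, length(s2))
  status <- rep("kept", length(s2))
  known <- !is.na(s2) & !is.na(s4)
  het4 <- !is.na(s4) & s4 == GENO_HET
  hom2 <- !is.na(s2) & s2 != GENO_HET
  # a homozygous S2 breeds true through S3; a heterozygous S4 needs a
  # heterozygous S3 parent
  s3[hom2] <- s2[hom2]
  s3[het4 & !hom2] <- GENO_HET
  impossible <- (known & s2 != GENO_HET & s4 != GENO_HET & s2 != s4) |
    (het4 & hom2)
  s3[impossible] <- NA_integer_
  status[impossible] <- "removed_uncorrectable"
  # heterozygous S2 with homozygous S4: two genotypes possible -> missing
  list(s3 = s3, status = status)
}

#' Correct a whole selfing-line panel
#'
#' Runs [correct_line()] over every (line, locus) generation vector and
#' imputes absent S3 samples from their S2/S4 neighbours. A locus flagged
#' uncorrectable in any line is removed globally (the default), matching
#' a per-SNP removal policy; set `per_line = TRUE` to drop only the
#' offending line-locus vectors instead.
#'
#' @param gt a [genotype_table()] of observed selfing-line calls.
#' @param ped a [pedigree_table()] mapping lines to samples.
#' @param per_line drop only conflicted line-locus cells instead of the
#'   whole locus.
#' @return list of class `corrected_lines`: `geno` (array loci x lines x
#'   generations), `provenance` (same shape), `locus_status`
#'   (`"kept"`/`"removed_uncorrectable"` per locus), `line_ids`,
#'   `generations`, `loci` (the locus table).
#' @export
correct_panel <- function(gt, ped, per_line = FALSE) {
  lines <- unique(ped$line_id)
  gens_present <- GENERATION_LEVELS[GENERATION_LEVELS %in% ped$generation]
  L <- n_loci(gt); nl <- length(lines); ng <- length(gens_present)
  geno <- array(NA_integer_, c(L, nl, ng),
                dimnames = list(NULL, lines, gens_present))
  prov <- array("missing", c(L, nl, ng),
                dimnames = list(NULL, lines, gens_present))
  removed <- rep(FALSE, L)
  for (li in seq_along(lines)) {
    smp <- line_samples(ped, lines[li])[gens_present]
    M <- matrix(NA_integer_, L, ng)
    have <- !is.na(smp)
    M[, have] <- gt$geno[, match(smp[have], gt$sample_ids), drop = FALSE]
    res <- correct_line_matrix(M)
    # impute a structurally absent S3 sample from corrected S2/S4
    if ("S3" %in% gens_present && is.na(smp["S3"]) &&
        all(c("S2", "S4") %in% gens_present)) {
      i2 <- match("S2", gens_present); i3 <- match("S3", gens_present)
      i4 <- match("S4", gens_present)
      ok <- res$status == "kept"
      imp <- impute_s3(res$corrected[ok, i2], res$corrected[ok, i4])
      res$corrected[ok, i3] <- imp$s3
      res$provenance[ok, i3][!is.na(imp$s3)] <- "imputed"
      res$status[ok][imp$status == "removed_uncorrectable"] <-
        "removed_uncorrectable"
    }
    bad <- res$status == "removed_uncorrectable"
    if (per_line) {
      res$corrected[bad, ] <- NA_integer_
      res$provenance[bad, ] <- "missing"
    } else {
      removed <- removed | bad
    }
    geno[, li, ] <- res$corrected
    prov[, li, ] <- res$provenance
  }
  if (!per_line) {
    geno[removed, , ] <- NA_integer_
    prov[removed, , ] <- "missing"
  }
  structure(list(geno = geno, provenance = prov,
                 locus_status = ifelse(removed & !per_line,
                                       "removed_uncorrectable", "kept"),
                 line_ids = lines, generations = gens_present,
                 loci = gt$loci),
            class = "corrected_lines")
}

#' Corrected panel back to a genotype table
#'
#' @param cl a [correct_panel()] result.
#' @param ped the pedigree used for correction (defines which samples
#'   exist; imputed S3 slots without a physical sample are omitted).
#' @return a [genotype_table()] of corrected calls for pedigree samples.
#' @export
corrected_to_gt <- function(cl, ped) {
  cols <- lapply(seq_len(nrow(ped)), function(i) {
    li <- match(ped$line_id[i], cl$line_ids)
    gi <- match(ped$generation[i], cl$generations)
    cl$geno[, li, gi]
  })
  genotype_table(do.call(cbind, cols), cl$loci, ped$sample_id)
}

#' Per-sample inbreeding coefficient from the correlation of uniting gametes
#'
#' For reference-allele dosage x and population reference-allele
#' frequency p, the per-locus term is
#' `(x^2 - (1 + 2p) x + 2 p^2) / (2 p (1 - p))`; a sample's F is the mean
#' over its non-missing, polymorphic loci.
#'
#' @param gt a [genotype_table()].
#' @param samples optional sample subset to report (frequencies are still
#'   computed from `freq_from`).
#' @param loci optional logical/integer locus subset (e.g. the LD-pruned,
#'   MAC-filtered panel).
#' @param freq_from optional [genotype_table()] supplying the population
#'   allele frequencies; defaults to `gt`.
#' @return named numeric vector of per-sample F (NA when a sample has no
#'   usable loci).
#' @export
f_uni <- function(gt, samples = NULL, loci = NULL, freq_from = NULL) {
  if (is.null(freq_from)) freq_from <- gt
  if (!is.null(loci)) {
    gt <- subset_gt(gt, loci = loci)
    freq_from <- subset_gt(freq_from, loci = loci)
  }
  g <- freq_from$geno
  n0 <- rowSums(g == GENO_HOM_REF, na.rm = TRUE)
  n1 <- rowSums(g == GENO_HET, na.rm = TRUE)
  nc <- rowSums(!is.na(g))
  p <- ifelse(nc > 0, (2 * n0 + n1) / (2 * nc), NA_real_)
  use <- !is.na(p) & p > 0 & p < 1
  x <- 2 - gt$geno[use, , drop = FALSE]  # reference dosage
  pl <- p[use]
  term <- (x^2 - (1 + 2 * pl) * x + 2 * pl^2) / (2 * pl * (1 - pl))
  f <- colMeans(term, na.rm = TRUE)
  f[colSums(!is.na(term)) == 0] <- NA_real_
  names(f) <- gt$sample_ids
  if (!is.null(samples)) f <- f[samples]
  f
}

#' Expected inbreeding trajectory under complete selfing
#'
#' Iterates `F_{t+1} = (1 + F_t) / 2` (closed form
#' `1 - (1 - F0) / 2^t`).
#'
#' @param F0 founder inbreeding coefficient in \[-1, 1\].
#' @param n_generations number of selfed generations.
#' @return numeric vector of expected F at generations 1..n.
#' @export
expected_f_trajectory <- function(F0, n_generations) {
  stopifnot(F0 >= -1, F0 <= 1, n_generations >= 0)
  if (n_generations == 0) return(numeric(0))
  1 - (1 - F0) / 2^seq_len(n_generations)
}

#' Heterozygosity and inbreeding trajectories across generations
#'
#' Per generation and locus, observed heterozygosity is the fraction of
#' heterozygous lines among non-missing calls; the expected value at
#' generation g is half the observed value at g-1 (per locus, then
#' averaged). An exact two-sided sign test (ties dropped) compares
#' per-locus observed vs expected, and a one-sample t-test compares the
#' per-sample inbreeding coefficients against the selfing recurrence
#' `F_{t+1} = (1 + F_t)/2` seeded with the mean founder F.
#'
#' @param cl a [correct_panel()] result.
#' @param ped the pedigree used for correction.
#' @param f_loci optional locus subset (logical/integer) for the
#'   inbreeding coefficients, e.g. the LD-pruned MAC >= 3 panel.
#' @return data.frame, one row per generation: mean/median observed and
#'   expected H, sign-test p, mean F, expected F, t-test p.
#' @export
trajectory_summary <- function(cl, ped, f_loci = NULL) {
  gens <- cl$generations
  keep <- cl$locus_status == "kept"
  G <- cl$geno[keep, , , drop = FALSE]
  H <- sapply(seq_along(gens), function(gi) {
    m <- G[, , gi, drop = FALSE][, , 1]
    rowMeans(m == GENO_HET, na.rm = TRUE)
  })  # loci x generations (NaN when no calls)
  H[is.nan(H)] <- NA

  gt_corr <- corrected_to_gt(cl, ped)
  fvals <- f_uni(gt_corr, loci = if (is.null(f_loci)) NULL else {
    if (is.logical(f_loci)) f_loci else seq_len(n_loci(gt_corr)) %in% f_loci
  })
  f_by_gen <- lapply(gens, function(g)
    fvals[ped$sample_id[ped$generation == g]])
  meanF <- vapply(f_by_gen, function(x) mean(x, na.rm = TRUE), numeric(1))
  f0 <- meanF[match("FS", gens)]
  expF <- c(NA, expected_f_trajectory(f0, length(gens) - 1))

  out <- data.frame(generation = gens,
                    n_lines = vapply(seq_along(gens), function(gi)
                      sum(colSums(!is.na(G[, , gi, drop = FALSE][, , 1])) > 0),
                      numeric(1)),
                    mean_H_obs = colMeans(H, na.rm = TRUE),
                    median_H_obs = apply(H, 2, stats::median, na.rm = TRUE),
                    mean_H_exp = NA_real_, median_H_exp = NA_real_,
                    sign_p = NA_real_,
                    mean_F = meanF, exp_F = expF, t_p = NA_real_)
  for (gi in seq_along(gens)[-1]) {
    exp_h <- H[, gi - 1] / 2
    obs_h <- H[, gi]
    ok <- !is.na(exp_h) & !is.na(obs_h)
    out$mean_H_exp[gi] <- mean(exp_h[ok])
    out$median_H_exp[gi] <- stats::median(exp_h[ok])
    d <- obs_h[ok] - exp_h[ok]
    d <- d[d != 0]
    if (length(d) > 0) {
      out$sign_p[gi] <- stats::binom.test(sum(d > 0), length(d))$p.value
    } else {
      out$sign_p[gi] <- 1
    }
    fv <- f_by_gen[[gi]]
    fv <- fv[!is.na(fv)]
    if (length(fv) > 1 && stats::sd(fv) > 0 && !is.na(expF[gi])) {
      out$t_p[gi] <- stats::t.test(fv, mu = expF[gi])$p.value
    }
  }
  rownames(out) <- NULL
  out
}
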