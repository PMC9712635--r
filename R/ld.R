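# squared Pearson correlation of two dosage vectors over complete pairs
pairwise_r2_vec <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Pairwise linkage disequilibrium (r-squared) between two loci
#'
#' Composite LD: the squared Pearson correlation of unphased genotype
#' dosages over samples called at both loci. Deterministic and robust to
#' missing data; may differ slightly from EM-haplotype r-squared.
#'
#' @param gt a [genotype_table()].
#' @param i,j locus indices.
#' @param samples optional sample subset.
#' @return r-squared, or `NA` when either locus has zero variance or
#'   fewer than two complete pairs remain.
#' @export
pairwise_r2 <- function(gt, i, j, samples = NULL) {
  if (!is.null(samples)) gt <- subset_gt(gt, samples = samples)
  pairwise_r2_vec(gt$geno[i, ], gt$geno[j, ])
}

#' All within-scaffold LD pairs
#'
#' Computes r-squared for every pair of biallelic variant loci on the
#' same scaffold passing the MAF threshold, with no distance cap.
#' Zero-variance pairs are skipped.
#'
#' @param gt a [genotype_table()].
#' @param maf minor-allele-frequency threshold (default 0.05).
#' @param samples optional sample subset.
#' @return data.frame: `chrom`, `pos1`, `pos2`, `dist` (bp), `r2`.
#' @export
all_pairs_within_scaffold <- function(gt, maf = 0.05, samples = NULL) {
  if (!is.null(samples)) gt <- subset_gt(gt, samples = samples)
  tl <- allele_tallies(gt)
  mafv <- ifelse(tl$m > 0, pmin(tl$n_ref, tl$n_alt) / tl$m, 0)
  use <- gt$loci$is_variant & mafv >= maf
  sub <- subset_gt(gt, loci = use)
  out <- list()
  for (sc in unique(sub$loci$chrom)) {
    ix <- which(sub$loci$chrom == sc)
    if (length(ix) < 2) next
    dos <- t(sub$geno[ix, , drop = FALSE])
    r <- suppressWarnings(stats::cor(dos, use = "pairwise.complete.obs"))^2
    pr <- which(upper.tri(r), arr.ind = TRUE)
    out[[sc]] <- data.frame(
      chrom = sc,
      pos1 = sub$loci$pos[ix[pr[, 1]]],
      pos2 = sub$loci$pos[ix[pr[, 2]]],
      dist = abs(sub$loci$pos[ix[pr[, 2]]] - sub$loci$pos[ix[pr[, 1]]]),
      r2 = r[pr])
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos1 = integer(),
                      pos2 = integer(), dist = integer(), r2 = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[!is.na(res$r2), ]
  rownames(res) <- NULL
  res
}

#' Expected r-squared under drift-recombination equilibrium
#'
#' With `C = rho * d` (rho = 4 * Ne * r per bp, d the distance in bp),
#' the unadjusted expectation is `1 / (1 + C)`. The default adjusts for
#' sample size n and low mutation:
#' `E(r2) = ((10 + C) / ((2 + C) * (11 + C))) *
#'   (1 + ((3 + C) * (12 + 12 C + C^2)) / (n (2 + C) (11 + C)))`,
#' which tends to `1/n` as C grows.
#'
#' @param C non-negative recombination-scale parameter (vectorized).
#' @param n sample size (>= 2).
#' @param adjusted use the sample-size-adjusted form (default `TRUE`).
#' @return numeric vector of expected r-squared.
#' @export
ld_expectation <- function(C, n, adjusted = TRUE) {
  stopifnot(all(C >= 0))
  if (n < 2) stop("sample size n must be >= 2")
  if (!adjusted) return(1 / (1 + C))
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the LD-decay curve
#'
#' Nonlinear least squares of `r2 ~ ld_expectation(C_hat * dist, n)` over
#' observed pairs, estimating the per-bp recombination-scale parameter
#' `C_hat >= 0`. Fitting uses `nls` (port algorithm, lower bound 0) with
#' a log-grid multi-start over starting values; if every start fails,
#' a golden-section search on the profile SSE is used. Derived distances
#' are solved on the fitted curve by bisection: the distances where the
#' curve crosses r2 = 0.2 and 0.1, and the "half-decay" distance where
#' it falls to half the 90th percentile of the observed r2 values.
#'
#' @param pairs data.frame with columns `dist` (> 0) and `r2`.
#' @param n sample size entering the expectation.
#' @param adjusted use the sample-size-adjusted expectation.
#' @return object of class `ld_decay_fit`: `C_per_bp`, `n`, `rss`,
#'   `n_pairs`, `r2_q90`, `half_decay_bp`, `d_r2_0.2`, `d_r2_0.1`
#'   (`NA` when the curve never attains a threshold).
#' @export
fit_ld_decay <- function(pairs, n, adjusted = TRUE) {
  pairs <- pairs[!is.na(pairs$r2) & pairs$dist > 0, ]
  if (nrow(pairs) < 50) stop("need at least 50 pairs with positive distance")
  sse <- function(cb) sum((pairs$r2 - ld_expectation(cb * pairs$dist, n,
                                                     adjusted))^2)
  best <- NULL
  for (start in 10^seq(-8, -4, by = 1)) {
    fit <- tryCatch(
      stats::nls(r2 ~ ld_expectation(cb * dist, n, adjusted),
                 data = pairs, start = list(cb = start),
                 algorithm = "port", lower = 0,
                 control = stats::nls.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      cb <- stats::coef(fit)[["cb"]]
      if (is.null(best) || sse(cb) < sse(best)) best <- cb
    }
  }
  if (is.null(best)) {
    opt <- stats::optimize(function(lc) sse(10^lc), c(-12, -2))
    best <- 10^opt$minimum
  }
  r2_q90 <- as.numeric(stats::quantile(pairs$r2, 0.9))
  solve_d <- function(target) {
    if (is.na(target) || target <= 0) return(NA_real_)
    f <- function(d) ld_expectation(best * d, n, adjusted) - target
    if (f(1e-9) < 0) return(NA_real_)  # threshold above the curve maximum
    hi <- 1
    while (f(hi) > 0 && hi < 1e15) hi <- hi * 10
    if (f(hi) > 0) return(NA_real_)    # curve never drops to the threshold
    stats::uniroot(f, c(1e-9, hi), tol = 1e-6)$root
  }
  structure(list(C_per_bp = best, n = n, rss = sse(best),
                 n_pairs = nrow(pairs), r2_q90 = r2_q90,
                 half_decay_bp = solve_d(r2_q90 / 2),
                 d_r2_0.2 = solve_d(0.2), d_r2_0.1 = solve_d(0.1)),
            class = "ld_decay_fit")
}

#' @exportS3Method base::print
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf(paste0("LD decay fit: C = %.4g per bp (n = %d, %d pairs, ",
                     "RSS %.4g)\n  half-decay %.0f bp; r2=0.2 at %.0f bp; ",
                     "r2=0.1 at %.0f bp\n"),
              x$C_per_bp, x$n, x$n_pairs, x$rss,
              x$half_decay_bp, x$d_r2_0.2, x$d_r2_0.1))
  invisible(x)
}
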