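#' Genotype codes
#'
#' Genotypes are stored as integer codes in a loci x samples matrix:
#' `0` = homozygous reference, `1` = heterozygous, `2` = homozygous
#' alternate, `NA` = missing. The alternate-allele dosage equals the code;
#' the reference-allele dosage is `2 - code`.
#'
#' @name genotype-codes
#' @keywords internal
NULL

GENO_HOM_REF <- 0L
GENO_HET <- 1L
GENO_HOM_ALT <- 2L

GENERATION_LEVELS <- c("FS", "S1", "S2", "S3", "S4", "S5")

#' Construct a genotype table
#'
#' The common currency of the pipeline: a matrix of diploid genotype codes
#' (loci in rows, samples in columns) together with per-locus metadata.
#' Invariant sites (no alternate allele) are carried in the same table with
#' `is_variant = FALSE`, so diversity denominators can include them.
#'
#' @param geno integer matrix of genotype codes (see [genotype-codes]),
#'   loci x samples. `NA` marks missing calls.
#' @param loci data.frame with columns `chrom` (character), `pos` (1-based
#'   integer), `ref`, `alt` (single-character nucleotides; `alt` is `NA` at
#'   invariant sites), `is_variant` (logical) and optionally `qual`
#'   (non-negative site quality, `NA` when absent).
#' @param sample_ids character vector of unique sample identifiers.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(geno, loci, sample_ids) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(loci), nrow(loci) == nrow(geno),
            length(sample_ids) == ncol(geno))
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (is.null(loci$qual)) loci$qual <- NA_real_
  if (is.null(loci$is_variant)) loci$is_variant <- !is.na(loci$alt)
  key <- paste(loci$chrom, loci$pos)
  if (anyDuplicated(key)) stop("duplicate (scaffold, position) pairs")
  if (is.unsorted(order(loci$chrom, loci$pos))) {
    o <- order(loci$chrom, loci$pos)
    loci <- loci[o, , drop = FALSE]
    geno <- geno[o, , drop = FALSE]
  }
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  inv <- !loci$is_variant
  if (any(inv) && any(geno[inv, , drop = FALSE] %in% c(1L, 2L))) {
    stop("invariant loci may only carry HOM_REF or MISSING codes")
  }
  rownames(geno) <- key
  colnames(geno) <- sample_ids
  rownames(loci) <- NULL
  structure(list(geno = geno, loci = loci, sample_ids = sample_ids),
            class = "genotype_table")
}

#' @exportS3Method base::print
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d loci (%d variant) x %d samples, %.1f%% missing\n",
              nrow(x$geno), sum(x$loci$is_variant), ncol(x$geno),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$geno)

#' Number of loci / samples in a genotype table
#' @param gt a [genotype_table()].
#' @return integer count.
#' @export
n_loci <- function(gt) nrow(gt$geno)

#' @rdname n_loci
#' @export
n_samples <- function(gt) ncol(gt$geno)

#' Subset a genotype table
#'
#' @param gt a [genotype_table()].
#' @param loci logical/integer index over loci, or `NULL` to keep all.
#' @param samples logical/integer/character index over samples, or `NULL`.
#' @return a new `genotype_table`.
#' @export
subset_gt <- function(gt, loci = NULL, samples = NULL) {
  if (is.null(loci)) loci <- seq_len(n_loci(gt))
  if (is.null(samples)) samples <- seq_len(n_samples(gt))
  if (is.character(samples)) samples <- match(samples, gt$sample_ids)
  genotype_table(gt$geno[loci, samples, drop = FALSE],
                 gt$loci[loci, , drop = FALSE],
                 gt$sample_ids[samples])
}

#' Construct a read-depth table aligned to a genotype table
#'
#' @param total,ref,alt integer matrices (loci x samples) of total,
#'   reference-supporting and alternate-supporting read counts.
#' @return An object of class `depth_table`.
#' @export
depth_table <- function(total, ref, alt) {
  total <- as.matrix(total); ref <- as.matrix(ref); alt <- as.matrix(alt)
  stopifnot(all(dim(total) == dim(ref)), all(dim(total) == dim(alt)))
  if (any(ref + alt > total, na.rm = TRUE)) {
    stop("ref_depth + alt_depth must not exceed total_depth")
  }
  if (any(total < 0, na.rm = TRUE)) stop("depths must be non-negative")
  structure(list(total = total, ref = ref, alt = alt), class = "depth_table")
}

#' @exportS3Method base::print
print.depth_table <- function(x, ...) {
  cat(sprintf("depth_table: %d x %d, mean depth %.1f\n",
              nrow(x$total), ncol(x$total), mean(x$total, na.rm = TRUE)))
  invisible(x)
}

#' Construct a selfing-line pedigree table
#'
#' Maps each selfing line to the sample genotyped at each generation.
#' Generations follow the fixed order FS (outcrossed full-sib founder)
#' then S1..S5 (successive generations of selfing, single-seed descent).
#'
#' @param df data.frame with columns `line_id`, `generation` (one of
#'   FS, S1..S5) and `sample_id`.
#' @return An object of class `pedigree_table` (a validated data.frame).
#' @export
pedigree_table <- function(df) {
  stopifnot(all(c("line_id", "generation", "sample_id") %in% names(df)))
  df$generation <- as.character(df$generation)
  bad <- setdiff(unique(df$generation), GENERATION_LEVELS)
  if (length(bad)) {
    stop("unknown generation label(s): ", paste(bad, collapse = ", "))
  }
  slot <- paste(df$line_id, df$generation)
  if (anyDuplicated(slot)) {
    stop("duplicate (line, generation) slot: ", slot[duplicated(slot)][1])
  }
  if (anyDuplicated(df$sample_id)) {
    stop("sample assigned to more than one pedigree slot: ",
         df$sample_id[duplicated(df$sample_id)][1])
  }
  df <- df[order(df$line_id, match(df$generation, GENERATION_LEVELS)), ]
  rownames(df) <- NULL
  class(df) <- c("pedigree_table", "data.frame")
  df
}

#' Samples of one line ordered by generation
#'
#' @param ped a [pedigree_table()].
#' @param line a line id present in the pedigree.
#' @return named character vector over `GENERATION_LEVELS` (NA where no
#'   sample exists for that generation).
#' @export
line_samples <- function(ped, line) {
  sub <- ped[ped$line_id == line, ]
  out <- stats::setNames(rep(NA_character_, length(GENERATION_LEVELS)),
                         GENERATION_LEVELS)
  out[sub$generation] <- sub$sample_id
  out
}
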