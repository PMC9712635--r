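#' Read a VCF into a genotype table
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into a [genotype_table()] and,
#' when the AD format field is present, a [depth_table()]. Records with no
#' alternate allele (ALT "." or empty) are kept as invariant sites.
#' Multi-allelic records are skipped with a warning (or rejected) because
#' every downstream analysis assumes biallelic SNPs. Phase is ignored
#' (`0|1` is read as `0/1`) and half-calls such as `./0` are treated as
#' missing.
#'
#' @param path path to an uncompressed or gzipped VCF file.
#' @param region optional `list(chrom =, start =, end =)` filter applied
#'   after parsing (1-based inclusive).
#' @param multiallelic `"skip"` (default) drops multi-allelic records and
#'   reports the count in attribute `n_skipped`; `"error"` aborts.
#' @return list with elements `genotypes` ([genotype_table()]), `depths`
#'   ([depth_table()] or `NULL`), and `n_skipped` (multi-allelic records
#'   dropped).
#' @export
read_vcf <- function(path, region = NULL, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    gt <- genotype_table(matrix(integer(), 0, ncol(vcf@gt) - 1L),
                         data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character(),
                                    is_variant = logical(), qual = numeric()),
                         colnames(vcf@gt)[-1])
    return(list(genotypes = gt, depths = NULL, n_skipped = 0L))
  }
  alt <- fix[, "ALT"]
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  if (any(multi) && multiallelic == "error") {
    stop(sum(multi), " multi-allelic record(s); rerun with multiallelic = 'skip'")
  }
  if (any(multi)) {
    warning("skipped ", sum(multi), " multi-allelic record(s)")
  }
  keep <- !multi
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field")
  gt_raw <- gt_raw[keep, , drop = FALSE]

  # normalize phase, then map to codes; anything with '.' is missing
  g <- gsub("|", "/", gt_raw, fixed = TRUE)
  ploidy_bad <- !is.na(g) & !grepl("^[0-9.]+/[0-9.]+$", g)
  if (any(ploidy_bad)) {
    stop("unsupported ploidy in GT field (expected diploid): e.g. '",
         g[ploidy_bad][1], "'")
  }
  codes <- matrix(NA_integer_, nrow(g), ncol(g))
  codes[!is.na(g) & g == "0/0"] <- GENO_HOM_REF
  codes[!is.na(g) & (g == "0/1" | g == "1/0")] <- GENO_HET
  codes[!is.na(g) & g == "1/1"] <- GENO_HOM_ALT

  alt_k <- alt[keep]
  is_variant <- !is.na(alt_k) & alt_k != "." & alt_k != ""
  qual <- suppressWarnings(as.numeric(fix[keep, "QUAL"]))
  loci <- data.frame(chrom = fix[keep, "CHROM"],
                     pos = as.integer(fix[keep, "POS"]),
                     ref = fix[keep, "REF"],
                     alt = ifelse(is_variant, alt_k, NA_character_),
                     is_variant = is_variant,
                     qual = qual,
                     stringsAsFactors = FALSE)
  # an invariant record cannot carry alt calls; treat them as missing
  if (any(!is_variant)) {
    inv <- which(!is_variant)
    codes[inv, ][codes[inv, , drop = FALSE] %in% c(1L, 2L)] <- NA_integer_
  }
  samples <- colnames(vcf@gt)[-1]
  gt <- genotype_table(codes, loci, samples)

  dp <- NULL
  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("AD" %in% fmt) {
    ad <- vcfR::extract.gt(vcf, element = "AD")[keep, , drop = FALSE]
    sp <- strsplit(ad, ",", fixed = TRUE)
    ref_d <- matrix(vapply(sp, function(x)
      if (length(x) >= 1) suppressWarnings(as.integer(x[1])) else NA_integer_,
      integer(1)), nrow(codes), ncol(codes))
    alt_d <- matrix(vapply(sp, function(x)
      if (length(x) >= 2) suppressWarnings(as.integer(x[2])) else 0L,
      integer(1)), nrow(codes), ncol(codes))
    ref_d[is.na(ref_d)] <- 0L
    alt_d[is.na(alt_d)] <- 0L
    tot <- ref_d + alt_d
    if ("DP" %in% fmt) {
      dpm <- suppressWarnings(
        matrix(as.integer(vcfR::extract.gt(vcf, element = "DP")[keep, , drop = FALSE]),
               nrow(codes), ncol(codes)))
      tot <- pmax(tot, dpm, na.rm = TRUE)
    }
    dp <- depth_table(tot, ref_d, alt_d)
  }

  out <- list(genotypes = gt, depths = dp, n_skipped = sum(multi))
  if (!is.null(region)) {
    sel <- gt$loci$chrom == region$chrom &
      gt$loci$pos >= region$start & gt$loci$pos <= region$end
    out$genotypes <- subset_gt(gt, loci = sel)
    if (!is.null(dp)) {
      out$depths <- depth_table(dp$total[sel, , drop = FALSE],
                                dp$ref[sel, , drop = FALSE],
                                dp$alt[sel, , drop = FALSE])
    }
  }
  out
}

#' Write a genotype table to a VCF file
#'
#' Emits a minimal VCF 4.2 file that round-trips through [read_vcf()]
#' with identical genotype codes, positions and alleles. Invariant sites
#' are written with ALT ".".
#'
#' @param gt a [genotype_table()].
#' @param path output path.
#' @param dp optional [depth_table()]; when given, AD and DP are written.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path, dp = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  if (!is.null(dp)) {
    writeLines(c("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
                 "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"),
               con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gt$sample_ids), collapse = "\t"), con)
  if (n_loci(gt) == 0) return(invisible(path))
  code_str <- c("0/0", "0/1", "1/1")
  gstr <- matrix("./.", n_loci(gt), n_samples(gt))
  ok <- !is.na(gt$geno)
  gstr[ok] <- code_str[gt$geno[ok] + 1L]
  fmt <- "GT"
  if (!is.null(dp)) {
    fmt <- "GT:AD:DP"
    gstr[] <- sprintf("%s:%d,%d:%d", gstr, dp$ref, dp$alt, dp$total)
  }
  lines <- paste(gt$loci$chrom, gt$loci$pos, ".", gt$loci$ref,
                 ifelse(gt$loci$is_variant, gt$loci$alt, "."),
                 ifelse(is.na(gt$loci$qual), ".",
                        format(gt$loci$qual, trim = TRUE)),
                 "PASS", ".", fmt,
                 apply(gstr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a selfing-line pedigree from TSV
#'
#' Expects tab-separated columns `line_id`, `generation`, `sample_id`.
#'
#' @param path path to the TSV file.
#' @return a [pedigree_table()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  pedigree_table(df)
}

#' Write a pedigree table to TSV
#' @param ped a [pedigree_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-locus effect-annotation table from TSV
#'
#' Expects columns `chrom`, `pos`, `consequence`, optionally `gene` and
#' `go` (comma-separated GO ids). The table is the consumed output of an
#' external variant-effect predictor (one consequence per SNP, most
#' severe retained).
#'
#' @param path path to the TSV file.
#' @param vocabulary optional character vector of allowed consequence
#'   categories; unknown categories are an error when supplied.
#' @return data.frame with class `annotation_table`.
#' @export
read_annotation <- function(path, vocabulary = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "consequence") %in% names(df)))
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(df$consequence), vocabulary)
    if (length(bad)) stop("unknown consequence categories: ",
                          paste(bad, collapse = ", "))
  }
  class(df) <- c("annotation_table", "data.frame")
  df
}
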