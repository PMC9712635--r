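Package: selfdrift
Title: Selfing-Line Population Genomics: Drift Expectations, Genotype
    Correction, Diversity and Linkage Disequilibrium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for panels of selfing lines propagated by
    single-seed descent, as used in conifer inbreeding studies. Provides a
    SNP quality-control filter cascade (depth, allele balance, read-ratio
    deviation, excess heterozygosity, Hardy-Weinberg exact tests, an
    inbreeding-coefficient filter calibrated to a mixed-mating equilibrium,
    minor-allele thresholds, LD pruning and relatedness exclusion),
    pedigree-aware genotype correction and imputation for selfing lines,
    heterozygosity and inbreeding-coefficient trajectories under complete
    selfing, a chi-square test for loci deviating from neutral-drift
    fixation expectations with Benjamini-Hochberg FDR control,
    missing-data-aware nucleotide diversity (pi, dxy, pi0/pi4, folded site
    frequency spectra), and linkage-disequilibrium decay fitting under the
    sample-size-adjusted drift-recombination expectation. A synthetic
    selfing-pedigree simulator generates genotypes, read depths and LD
    pair data so the whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    vcfR,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
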