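#!/usr/bin/env Rscript
# Stage 2 - SNP quality control.
#
# Applies the filter cascade to the simulated panel: missingness >= 0.95,
# site quality >= 30, mean depth 15-60x, allele balance in (0.2, 0.8) or
# < 0.01, read-ratio deviation |D| <= 5, observed heterozygosity <= 0.55,
# excess-het exact p >= 0.05, HWE exact p >= 1e-5, F_IS >= 0 at
# F_eq = 0.17, MAC >= 3. Heterozygosity-based statistics are taken from
# the range-wide population, the panel the thresholds were designed for.
# Also illustrates relatedness exclusion (>0.2) on the RWP.

suppressPackageStartupMessages(library(selfdrift))

sl <- read_vcf("results/sl_panel.vcf")
rwp <- read_vcf("results/rwp.vcf")

report <- filter_cascade(sl$genotypes, sl$depths,
                         qc_population = rwp$genotypes, mac = 3)
print(report)
write.table(report$steps, "results/filter_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_vcf(report$filtered, "results/sl_panel.filtered.vcf")

reasons <- table(report$removal_reason, useNA = "no")
cat("removal reasons:\n")
print(reasons)

A <- grm_vanraden(rwp$genotypes)
excl <- exclude_related(A, max_rel = 0.2)
cat(sprintf("RWP relatedness exclusion (>0.2): %d of %d samples dropped\n",
            length(excl), nrow(A)))
cat(sprintf("filtered panel: %d -> %d loci\n",
            n_loci(sl$genotypes), n_loci(report$filtered)))
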