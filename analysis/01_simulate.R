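#!/usr/bin/env Rscript
# Stage 1 - generate the synthetic study panel.
#
# Emulates the study design: full-sib founder lines selfed for five
# generations by single-seed descent (one sampled tree per line and
# generation), founder heterozygosity ~0.3, Capture-Seq-like read depths
# (~35x), plus a mixed-mating range-wide population (selfing rate 0.3,
# n = 112) used by the QC and LD stages. Writes VCF + pedigree under
# results/.

suppressPackageStartupMessages(library(selfdrift))

out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- sim_config(n_lines = 28, n_generations = 5, n_loci = 5000,
                  fs_het_fraction = 0.3, miscall_rate = 0.005,
                  missing_rate = 0.02, mean_depth = 35, seed = 20260925)
sim <- simulate_selfing_panel(cfg)
write_vcf(sim$genotypes, file.path(out, "sl_panel.vcf"), sim$depths)
write_pedigree(sim$pedigree, file.path(out, "sl_panel.ped.tsv"))

set.seed(20260925)
p <- runif(5000, 0.05, 0.95)
rwp <- simulate_mixed_mating_population(p, n_samples = 112,
                                        selfing_rate = 0.3, seed = 20260926)
write_vcf(rwp, file.path(out, "rwp.vcf"),
          simulate_depths(rwp, mean_depth = 35, seed = 20260927))

# all-sites companion table: the 5,000 variant loci embedded in a
# backdrop of invariant sequenced sites (with realistic missingness), so
# the diversity stage can use the full denominator
set.seed(20260928)
n_inv <- 45000
inv_codes <- matrix(0L, n_inv, 112)
inv_codes[runif(n_inv * 112) < 0.02] <- NA_integer_
inv <- genotype_table(inv_codes,
                      data.frame(chrom = "scaffold_01",
                                 pos = seq_len(n_inv) * 100L + 50L,
                                 ref = "A", alt = NA_character_,
                                 is_variant = FALSE, qual = NA_real_),
                      rwp$sample_ids)
allsites <- genotype_table(rbind(rwp$geno, inv$geno),
                           rbind(rwp$loci, inv$loci), rwp$sample_ids)
write_vcf(allsites, file.path(out, "rwp.allsites.vcf"))

cat(sprintf("selfing panel: %d loci x %d samples (%d lines x 6 generations)\n",
            n_loci(sim$genotypes), n_samples(sim$genotypes), cfg$n_lines))
cat(sprintf("range-wide population: %d loci x %d samples, F_eq = %.3f\n",
            n_loci(rwp), n_samples(rwp), equilibrium_fixation_index(0.3)))
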