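---
title: "Methods: drift expectations, genotype correction and diversity in selfing-line panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drift expectations, genotype correction and diversity in selfing-line panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfdrift)
```

`selfdrift` analyses panels of selfing lines propagated by single-seed
descent: a founder (FS) produced by outcrossing, then one selfed
offspring sampled per line per generation (S1..S5), each genotyped once,
alongside a range-wide population (RWP) sample at mixed-mating
equilibrium. This vignette is the package's account of the models it
implements, the defaults it ships, and what its simulation-based tests
do and do not demonstrate.

## The drift model for complete selfing

A diploid locus under selfing follows a Markov chain on
{HOM_REF, HET, HOM_ALT}. Homozygotes breed true; a heterozygous parent's
selfed offspring is Mendelian (¼, ½, ¼), optionally reweighted by
viability fitnesses (w_RR, w_RA, w_AA) and renormalized
(`selfing_kernel()`). Two consequences anchor the whole analysis:

* heterozygosity halves each generation: P(HET at t) = (½)^t from a
  heterozygous founder, with the loss split evenly between homozygotes —
  at S4, (6.25%, 46.875%, 46.875%) (`expected_fixation_proportions()`);
* inbreeding follows F_{t+1} = (1 + F_t)/2, closed form
  1 − (1 − F0)/2^t (`expected_f_trajectory()`).

The drift-deviation test (`chi2_drift_test()`) treats each line as an
independent replicate: for every locus heterozygous in a line's founder
and called at S4, the (fixed-ref, fixed-alt, het) counts over k ≥ 3
lines are compared to k·(0.46875, 0.46875, 0.0625) with a df = 2
chi-square, Benjamini–Hochberg corrected across tested loci. Asymptotic
p-values are used even though the expected het count is below 5 for
k < 80; this matches the procedure the design is drawn from, and an
exact multinomial alternative was considered and rejected as a default
because the BH step dominates the error control in practice. Lines
share founders within families; no family random effect is modelled.
The direction flags (`excess_het` etc.) are descriptive
(observed > expected per category), not a secondary test.

## Genotype correction

Correction uses two rules justified by the selfing Markov chain: (1) two
consecutive identical homozygous calls force that homozygote for all
later generations; (2) two consecutive heterozygous calls force HET for
all earlier generations including the founder (a heterozygous offspring
requires a heterozygous parent, recursively). Design choices that the
rules as stated leave open:

* **Triggers are evaluated on observed calls only, in one pass.**
  Retriggering on corrected values would let overwrites cascade into
  ambiguity; the single-pass rule makes correction idempotent by
  construction (verified on 10⁴ random vectors).
* **Conflicts remove the locus globally.** Opposite homozygous runs in
  order, or a heterozygous trigger inside a region forced homozygous
  (equivalently, lh ≥ fh + 1 for the latest het trigger lh and earliest
  hom trigger fh), mark the locus uncorrectable; the removal is per SNP
  across all lines, with per-line removal available behind
  `per_line = TRUE`.
* **Missing entries neither trigger nor block a rule** and are imputed
  when a rule covers their slot — this is also the mechanism that fills
  gaps in partially genotyped lines. Lines with no S3 sample get S3
  imputed from corrected S2/S4 where only one genotype is possible
  (`impute_s3()`); HET S2 with homozygous S4 stays missing (two
  genotypes possible).
* **Corrections overwrite conflicting observed calls** (error-correction
  reading) rather than only filling gaps: the rules exist to repair
  genotyping errors, and a single miscall can never fabricate a trigger,
  so an overwrite driven by a truth-consistent trigger is always safe.
  The tests verify this exactly: with injected errors that never place
  two miscalls in adjacent generations of one line-locus, zero
  truth-consistent entries are altered; under i.i.d. miscalls at 1%,
  the rare corrupted entries all trace to triggers fabricated by two
  coincident miscalls (probability ~10⁻⁴ per adjacent pair), and
  rule-detected errors are restored to the simulator truth at ≥ 95%.

## Inbreeding and heterozygosity trajectories

Observed heterozygosity is computed per locus per generation as the
heterozygous fraction of non-missing lines; the expectation at
generation g is half the observed value at g − 1, per locus first, then
averaged (mean and median) — the alternative per-line-first averaging is
not implemented. An exact two-sided sign test (ties dropped) compares
medians; a one-sample t-test compares per-sample F_UNI against the
recurrence seeded with the mean founder F. F_UNI uses the
population-wide plug-in allele frequency of the analysed table itself,
with an optional locus subset (`f_loci`) so it can be restricted to an
LD-pruned, MAC-filtered panel, where the estimator's no-LD assumption is
closest to holding. Monomorphic loci are skipped (the denominator
2p(1 − p) vanishes).

## The SNP QC cascade

Defaults are the thresholds of the targeted-capture workflow the package
is designed around: call rate ≥ 0.95; site QUAL ≥ 30 (variant sites
only — genotype-level qualities are not consulted); mean depth 15–60×
(boundaries inclusive); pooled het-read allele balance in the open
interval (0.2, 0.8) or < 0.01; |D| ≤ 5 with
D = (ΣA − ΣB)/√(ΣA + ΣB) over pooled heterozygous-call reads (the
binomial-½ z-score; the read-ratio deviation literature's normalization
is followed at site level because thresholds are quoted once per SNP);
H_O ≤ 0.55; one-sided excess-het exact p ≥ 0.05; two-sided exact HWE
p ≥ 10⁻⁵ (full enumeration of the heterozygote count conditional on
allele counts, no mid-p); F_IS = 1 − (H_O/H_E)(1 − F_eq) ≥ 0 with
F_eq = 0.17, the mixed-mating equilibrium s/(2 − s) truncated to two
decimals at outcrossing rate 0.7; MAC ≥ 3 (or MAF ≥ 0.05 — exactly one);
greedy LD pruning at r² > 0.1 within 2.17 Mb; pairwise relatedness
≤ 0.2 on the VanRaden GRM A = ZZ′/(2Σp(1 − p)) with missing dosages
imputed to 2p. H_E is the plug-in 2p̂(1 − p̂) without small-sample
correction, since F_IS is a ratio and any correction cancels unevenly.
The unusual "< 0.01" allele-balance branch (retaining near-zero-AB
sites whose stray alternate reads are presumably errors) is implemented
as printed and surfaced in the filter report. Heterozygosity-dependent
statistics can be sourced from a designated reference population
(`qc_population`), matching designs where thresholds are calibrated on
the outbred RWP rather than the inbred lines. Invariant sites pass only
the basic step (no QUAL), and each removed locus records the first
filter that removed it; the report conserves counts at every step.

## Diversity, degeneracy and the SFS

π and d_XY accumulate pairwise allele differences and comparisons
separately per site — diffs = n_ref·n_alt, comps = C(m, 2) within a
sample (m called alleles), comps = m_A·m_B between populations — so
missing data shrink the denominator instead of deflating the estimate,
and invariant sites contribute comparisons only. This is why the
genotype table carries invariant sites inline rather than in a separate
container. Windows are 10-kb and non-overlapping by default. Codon
degeneracy uses the standard nuclear code; 2- and 3-fold sites are
classified but excluded from π0/π4; CDS with frame violations or
internal stops are skipped with a warning. The folded SFS is
complete-case by default; hypergeometric projection to m alleles is
opt-in, since projection choices belong to downstream demographic
tooling.

## Linkage disequilibrium

r² is the squared Pearson correlation of unphased genotype dosages over
samples called at both loci (composite LD) — deterministic and
well-defined under missingness, though it can differ slightly from
EM-haplotype r². Decay fitting minimises unweighted least squares of
r² against the sample-size-adjusted drift-recombination expectation
E(r²)(C, n), C = ρ·d per bp, using `nls` (port, lower bound 0) with a
log-grid multi-start over starting values 10⁻⁸..10⁻⁴ and a
golden-section fallback on the profile SSE. Derived distances are
solved on the fitted curve by bisection; the half-decay reference level
is half the 90th percentile of all observed r² (not distance-binned —
the percentile's scope is genuinely ambiguous and the global choice is
the more conservative, larger reference). Thresholds above the curve
maximum, or below its 1/n asymptote, return NA rather than an
extrapolated distance.

## The synthetic-data generator

`simulate_selfing_panel()` emulates the study design the analyses
assume: 15 lines by default (28 where the drift test's complete-line
subset is the target), up to five selfed generations with exactly one
sampled offspring per line-generation, founder heterozygosity 0.3
(matching a founder H of ~0.3 in the motivating system), symmetric
genotyping miscalls at 0.005 and missingness at 0.02 (plausible
Capture-Seq placeholders — the platform's true error rates are not
published), Poisson read depths at mean 35× with binomial allele
balance at het calls (0.5 faithful, skewed to mimic collapsed
paralogs), and a mixed-mating RWP with selfing rate 0.3, i.e.
F_eq ≈ 0.176 before truncation. Selection is viability selection on the
offspring genotype distribution — the minimal mechanism producing
heterozygote excess. What the generator does **not** emulate: linkage
between panel loci (loci are independent, so LD-decay fitting is
exercised on pairs generated from the decay model itself),
family structure among founders, reference bias, allele-specific
dropout, or locus-specific error rates. Passing tests therefore show
the estimators and tests are correct under the stated model, not that
real Capture-Seq data meet that model.

## Problem sizes and reproducibility

The test suite runs panels of 28 lines × 2,000–10,000 loci, 10⁵
single-locus selfing replicates for the (½)^t law, 100 random 50 × 5
tables for the π oracle, and 20 seeds × 5,000 pairs for LD parameter
recovery — sizes at which binomial standard errors make the assertions
sharp while the whole suite completes in about a minute. All
randomness flows through explicit seeds; `run_pipeline()` derives one
stream per stage from the global seed and a stage-name offset so
toggling one stage never perturbs another's draws, and hashes the
seed-and-parameter configuration (not the output directory) into its
manifest.

## Known limitations

* The drift test conditions on the corrected founder call; founder
  miscalls that survive correction bias k downward but not the test's
  null.
* BH control is across tested loci (FS-het, k ≥ 3) only.
* The GRM exclusion is a greedy heuristic for the minimum vertex cover;
  it is deterministic (ties by mean relatedness, then input order) but
  not guaranteed minimal.
* d_XY between highly diverged populations with no invariant-site data
  inherits the same variant-only inflation as π; supply all-sites
  tables for both statistics.
* Half-calls (e.g. `./0`) are read as missing; phase is ignored.
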