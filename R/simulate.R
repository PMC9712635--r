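#' Simulation configuration for selfing-line panels
#'
#' Bundles the parameters of the synthetic selfing-pedigree generator.
#' Defaults mirror the study design the analyses target: 15 full-sib
#' founder lines selfed for up to five generations by single-seed descent,
#' a founder heterozygosity around 0.3, mean read depth around 35x, and a
#' mixed-mating range-wide population with selfing rate 0.3 (outcrossing
#' rate 0.7, equilibrium fixation index s/(2-s) ~ 0.17).
#'
#' @param n_lines number of independent selfing lines.
#' @param n_generations number of selfed generations (1..5; generations
#'   are labelled S1..S5 after the FS founder).
#' @param n_loci number of loci.
#' @param fs_het_fraction probability a locus is heterozygous in the FS
#'   founder; non-heterozygous founders are HOM_REF or HOM_ALT with equal
#'   probability.
#' @param fitness per-locus viability fitness of the three genotypes
#'   (HOM_REF, HET, HOM_ALT): either a length-3 vector applied to every
#'   locus or an `n_loci` x 3 matrix.
#' @param miscall_rate probability a true genotype is miscalled
#'   (HET to a random HOM; HOM to HET - symmetric).
#' @param missing_rate probability a call is dropped to missing.
#' @param mean_depth mean sequencing depth (Poisson lambda, > 0).
#' @param het_ab expected alternate-allele read fraction at heterozygous
#'   calls (0.5 for a faithful locus; skewed values mimic paralogs).
#' @param selfing_rate selfing rate s of the mixed-mating population.
#' @param n_scaffolds number of scaffolds loci are spread over.
#' @param seed integer seed; all randomness flows through it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 15, n_generations = 5, n_loci = 1000,
                       fs_het_fraction = 0.3, fitness = c(1, 1, 1),
                       miscall_rate = 0.005, missing_rate = 0.02,
                       mean_depth = 35, het_ab = 0.5,
                       selfing_rate = 0.3, n_scaffolds = 10, seed = 1) {
  stopifnot(n_generations >= 1, n_generations <= 5, n_loci >= 1,
            fs_het_fraction >= 0, fs_het_fraction <= 1,
            miscall_rate >= 0, miscall_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            mean_depth > 0, het_ab >= 0, het_ab <= 1,
            selfing_rate >= 0, selfing_rate <= 1)
  fitness <- fitness_matrix(fitness, n_loci)
  structure(as.list(environment()), class = "sim_config")
}

fitness_matrix <- function(fitness, n_loci) {
  if (is.null(dim(fitness))) {
    stopifnot(length(fitness) == 3)
    fitness <- matrix(fitness, n_loci, 3, byrow = TRUE)
  }
  stopifnot(ncol(fitness) == 3, all(fitness >= 0),
            all(rowSums(fitness) > 0))
  fitness
}

#' One generation of selfing (Mendelian kernel with viability selection)
#'
#' A homozygous parent breeds true. A heterozygous parent's selfed
#' offspring is drawn from Mendelian proportions (1/4, 1/2, 1/4) weighted
#' by the genotype fitnesses and renormalized; with neutral fitness the
#' offspring is heterozygous with probability exactly 1/2.
#'
#' @param geno integer vector of parental genotype codes (0/1/2).
#' @param fitness length-3 vector or `length(geno)` x 3 matrix of
#'   viabilities (w_RR, w_RA, w_AA).
#' @return integer vector of offspring genotype codes.
#' @export
self_one_generation <- function(geno, fitness = c(1, 1, 1)) {
  n <- length(geno)
  w <- fitness_matrix(fitness, n)
  out <- geno
  hom <- which(!is.na(geno) & geno != GENO_HET)
  if (length(hom)) {
    wh <- w[cbind(hom, geno[hom] + 1L)]
    if (any(wh == 0)) stop("inviable cross: homozygous parent with zero fitness")
  }
  het <- which(!is.na(geno) & geno == GENO_HET)
  if (length(het)) {
    pr <- cbind(w[het, 1] / 4, w[het, 2] / 2, w[het, 3] / 4)
    tot <- rowSums(pr)
    if (any(tot == 0)) stop("inviable cross: all offspring genotypes have zero fitness")
    pr <- pr / tot
    u <- stats::runif(length(het))
    out[het] <- ifelse(u < pr[, 1], GENO_HOM_REF,
                       ifelse(u < pr[, 1] + pr[, 2], GENO_HET, GENO_HOM_ALT))
  }
  out
}

#' Selfing transition kernel
#'
#' Transition matrix of genotype codes under one generation of selfing
#' with viability selection; rows index the parent genotype
#' (HOM_REF, HET, HOM_ALT), columns the offspring genotype.
#'
#' @param fitness length-3 viability vector (w_RR, w_RA, w_AA).
#' @return 3 x 3 row-stochastic matrix.
#' @export
selfing_kernel <- function(fitness = c(1, 1, 1)) {
  stopifnot(length(fitness) == 3, all(fitness >= 0))
  het <- c(fitness[1] / 4, fitness[2] / 2, fitness[3] / 4)
  if (sum(het) == 0) stop("inviable cross: all offspring genotypes have zero fitness")
  m <- rbind(c(1, 0, 0), het / sum(het), c(0, 0, 1))
  dimnames(m) <- list(c("HOM_REF", "HET", "HOM_ALT"),
                      c("HOM_REF", "HET", "HOM_ALT"))
  m
}

#' Simulate a selfing-line panel by single-seed descent
#'
#' Each line starts from an FS founder genotype, and exactly one selfed
#' offspring is sampled per generation. The error-free genotypes
#' ("truth") are recorded before genotyping error and missingness are
#' applied, so correction algorithms can be scored against them.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` ([genotype_table()] of observed calls),
#'   `depths` ([depth_table()]), `pedigree` ([pedigree_table()]) and
#'   `truth` (list: `geno` array loci x lines x generations of error-free
#'   codes, `selected` logical per locus marking non-neutral fitness).
#' @export
simulate_selfing_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci; nl <- config$n_lines; ng <- config$n_generations
  gens <- c("FS", paste0("S", seq_len(ng)))
  w <- config$fitness

  truth <- array(NA_integer_, dim = c(L, nl, ng + 1L),
                 dimnames = list(NULL, NULL, gens))
  fs <- matrix(GENO_HOM_REF, L, nl)
  is_het <- matrix(stats::runif(L * nl) < config$fs_het_fraction, L, nl)
  # homozygous founders are viable individuals: weight by homozygote fitness
  p_hom_ref <- ifelse(w[, 1] + w[, 3] > 0, w[, 1] / (w[, 1] + w[, 3]), 0.5)
  hom_idx <- which(!is_het, arr.ind = TRUE)
  fs[!is_het] <- ifelse(stats::runif(nrow(hom_idx)) < p_hom_ref[hom_idx[, 1]],
                        GENO_HOM_REF, GENO_HOM_ALT)
  fs[is_het] <- GENO_HET
  truth[, , 1] <- fs
  for (g in seq_len(ng)) {
    prev <- truth[, , g]
    truth[, , g + 1] <- matrix(
      self_one_generation(as.vector(prev), w[rep(seq_len(L), nl), ]),
      L, nl)
  }

  obs <- truth
  n_cells <- length(obs)
  mis <- stats::runif(n_cells) < config$miscall_rate
  if (any(mis)) {
    v <- obs[mis]
    flip_hom <- stats::runif(length(v)) < 0.5
    obs[mis] <- ifelse(v == GENO_HET,
                       ifelse(flip_hom, GENO_HOM_REF, GENO_HOM_ALT),
                       GENO_HET)
  }
  obs[stats::runif(n_cells) < config$missing_rate] <- NA_integer_

  sample_ids <- as.vector(outer(sprintf("L%02d", seq_len(nl)), gens,
                                function(l, g) paste(l, g, sep = "_")))
  geno <- matrix(NA_integer_, L, nl * (ng + 1L))
  k <- 0L
  for (g in seq_len(ng + 1L)) for (j in seq_len(nl)) {
    geno[, (g - 1L) * nl + j] <- obs[, j, g]
  }
  # outer() above enumerates lines fastest, matching this fill order
  scaf <- sort(rep_len(seq_len(config$n_scaffolds), L))
  pos <- unlist(lapply(split(seq_len(L), scaf), function(ix)
    sort(sample.int(1e7, length(ix)))), use.names = FALSE)
  loci <- data.frame(chrom = sprintf("scaffold_%02d", scaf), pos = pos,
                     ref = "A", alt = "G", is_variant = TRUE,
                     qual = NA_real_)
  gt <- genotype_table(geno, loci, sample_ids)
  dp <- simulate_depths(gt, mean_depth = config$mean_depth,
                        het_ab = config$het_ab)
  ped <- pedigree_table(data.frame(
    line_id = rep(sprintf("L%02d", seq_len(nl)), ng + 1L),
    generation = rep(gens, each = nl),
    sample_id = sample_ids))
  selected <- apply(w, 1, function(x) !all(x == x[1]))
  list(genotypes = gt, depths = dp, pedigree = ped,
       truth = list(geno = truth, selected = selected))
}

#' Simulate a mixed-mating population at inbreeding equilibrium
#'
#' Genotypes are drawn with frequencies `p^2 + p*q*F`, `2*p*q*(1 - F)`,
#' `q^2 + p*q*F` where `F = s/(2 - s)` is the equilibrium fixation index
#' under partial selfing at rate `s`.
#'
#' @param p reference-allele frequency, scalar or per-locus vector in (0,1).
#' @param n_samples number of diploid individuals.
#' @param selfing_rate selfing rate s in \[0, 1\].
#' @param n_loci number of loci (defaults to `length(p)`).
#' @param seed optional integer seed.
#' @return a [genotype_table()].
#' @export
simulate_mixed_mating_population <- function(p, n_samples,
                                             selfing_rate = 0.3,
                                             n_loci = length(p),
                                             seed = NULL) {
  if (any(p <= 0 | p >= 1)) stop("allele frequency p must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p <- rep_len(p, n_loci)
  Feq <- equilibrium_fixation_index(selfing_rate)
  q <- 1 - p
  pRR <- p^2 + p * q * Feq
  pRA <- 2 * p * q * (1 - Feq)
  u <- matrix(stats::runif(n_loci * n_samples), n_loci, n_samples)
  geno <- ifelse(u < pRR, GENO_HOM_REF,
                 ifelse(u < pRR + pRA, GENO_HET, GENO_HOM_ALT))
  loci <- data.frame(chrom = "scaffold_01",
                     pos = seq_len(n_loci) * 1000L,
                     ref = "A", alt = "G", is_variant = TRUE,
                     qual = NA_real_)
  genotype_table(geno, loci, sprintf("RWP%04d", seq_len(n_samples)))
}

#' Equilibrium fixation index under partial selfing
#'
#' At a constant selfing rate s the population inbreeding coefficient
#' equilibrates at `F = s/(2 - s)`, equivalently `(1 - t)/(1 + t)` with
#' outcrossing rate `t = 1 - s`.
#'
#' @param s selfing rate in \[0, 1\].
#' @param truncate round the result down to two decimals (the convention
#'   used when calibrating the inbreeding-coefficient SNP filter).
#' @return numeric fixation index.
#' @export
equilibrium_fixation_index <- function(s, truncate = FALSE) {
  stopifnot(s >= 0, s <= 1)
  f <- s / (2 - s)
  if (truncate) f <- floor(f * 100) / 100
  f
}

#' Simulate read depths for a genotype table
#'
#' Total depth is Poisson; at heterozygous calls the alternate-read count
#' is binomial with success probability `het_ab` (0.5 for a faithful
#' site; a skewed value mimics a collapsed paralog and should be caught
#' by the read-ratio deviation filter). Homozygous calls carry reads for
#' the called allele only, apart from `base_error` miscalled reads.
#'
#' @param gt a [genotype_table()].
#' @param mean_depth Poisson mean of the total depth (> 0).
#' @param het_ab alternate-allele read fraction at heterozygous calls.
#' @param base_error per-read error rate at homozygous calls.
#' @param seed optional integer seed.
#' @return a [depth_table()].
#' @export
simulate_depths <- function(gt, mean_depth = 35, het_ab = 0.5,
                            base_error = 0, seed = NULL) {
  stopifnot(mean_depth > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_loci(gt) * n_samples(gt)
  tot <- matrix(stats::rpois(n, mean_depth), n_loci(gt), n_samples(gt))
  alt <- matrix(0L, n_loci(gt), n_samples(gt))
  g <- gt$geno
  het <- !is.na(g) & g == GENO_HET
  alt[het] <- stats::rbinom(sum(het), tot[het], het_ab)
  hr <- !is.na(g) & g == GENO_HOM_REF
  if (base_error > 0) alt[hr] <- stats::rbinom(sum(hr), tot[hr], base_error)
  ha <- !is.na(g) & g == GENO_HOM_ALT
  alt[ha] <- if (base_error > 0) {
    tot[ha] - stats::rbinom(sum(ha), tot[ha], base_error)
  } else tot[ha]
  miss <- is.na(g)
  tot[miss] <- 0L
  alt[miss] <- 0L
  depth_table(tot, tot - alt, alt)
}

#' Simulate LD pairs from the decay expectation
#'
#' Generates (distance, r-squared) pairs lying on the sample-size-adjusted
#' decay curve [ld_expectation()] with optional Gaussian noise clamped to
#' \[0, 1\], for parameter-recovery checks of [fit_ld_decay()].
#'
#' @param C_per_bp recombination-scale parameter per bp (C = rho * d).
#' @param n sample size entering the expectation.
#' @param n_pairs number of pairs.
#' @param max_dist maximum distance in bp (distances uniform on (0, max]).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed optional integer seed.
#' @return data.frame with columns `dist` and `r2`.
#' @export
simulate_ld_pairs <- function(C_per_bp, n, n_pairs = 5000,
                              max_dist = 5e6, noise_sd = 0.05,
                              seed = NULL) {
  stopifnot(C_per_bp >= 0, n >= 2, n_pairs >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- stats::runif(n_pairs, 0, max_dist)
  d[d == 0] <- max_dist / n_pairs
  r2 <- ld_expectation(C_per_bp * d, n)
  if (noise_sd > 0) {
    r2 <- pmin(1, pmax(0, r2 + stats::rnorm(n_pairs, 0, noise_sd)))
  }
  data.frame(dist = d, r2 = r2)
}
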