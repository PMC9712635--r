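#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed global integer seed; each stage derives its own stream
#'   from it and the stage name, so toggling one stage does not perturb
#'   another's randomness.
#' @param sim a [sim_config()] to simulate inputs, or `NULL` to read
#'   `vcf` / `ped` paths.
#' @param vcf,ped input paths used when `sim` is `NULL`.
#' @param filter list of [filter_cascade()] arguments, or `FALSE` to skip.
#' @param trajectory,drift,diversity,ld_fit logical stage toggles.
#' @param ld_n sample size used in the LD-decay expectation (defaults to
#'   the number of samples in the LD input).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = "selfdrift_run", seed = 1, sim = sim_config(),
                       vcf = NULL, ped = NULL, filter = list(),
                       trajectory = TRUE, drift = TRUE, diversity = TRUE,
                       ld_fit = FALSE, ld_n = NULL) {
  structure(list(out_dir = out_dir, seed = seed, sim = sim, vcf = vcf,
                 ped = ped, filter = filter, trajectory = trajectory,
                 drift = drift, diversity = diversity, ld_fit = ld_fit,
                 ld_n = ld_n),
            class = "run_config")
}

stage_seed <- function(seed, stage) {
  (seed + sum(utf8ToInt(stage)) * 1009L) %% .Machine$integer.max
}

#' Run the pipeline end to end
#'
#' Executes simulate -> filter -> correct -> trajectory -> drift test ->
#' diversity / LD per the configuration toggles, writing stage outputs
#' under `out_dir` and returning a manifest with per-stage input/output
#' locus counts and a config hash. Identical configuration and seed
#' reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @return list of class `run_manifest`: `config_hash`, `seed`, `stages`
#'   (named list of per-stage summaries), plus the in-memory stage
#'   results in `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_file <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_file)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   seed = config$seed, stages = list())
  results <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(config$sim)) {
    run_stage("simulate", function() {
      sim_cfg <- config$sim
      sim_cfg$seed <- stage_seed(config$seed, "simulate")
      sim <- simulate_selfing_panel(sim_cfg)
      write_vcf(sim$genotypes, file.path(config$out_dir, "input.vcf"),
                sim$depths)
      write_pedigree(sim$pedigree, file.path(config$out_dir, "input.ped.tsv"))
      results$sim <<- sim
      manifest$stages$simulate <<- list(status = "ok",
                                        n_loci = n_loci(sim$genotypes),
                                        n_samples = n_samples(sim$genotypes))
    })
    gt <- results$sim$genotypes
    dp <- results$sim$depths
    ped <- results$sim$pedigree
  } else {
    run_stage("read", function() {
      inp <- read_vcf(config$vcf)
      results$input <<- inp
      results$ped <<- read_pedigree(config$ped)
      manifest$stages$read <<- list(status = "ok",
                                    n_loci = n_loci(inp$genotypes),
                                    n_skipped = inp$n_skipped)
    })
    gt <- results$input$genotypes
    dp <- results$input$depths
    ped <- results$ped
  }

  if (!isFALSE(config$filter)) {
    run_stage("filter", function() {
      rep <- do.call(filter_cascade, c(list(gt = gt, dp = dp), config$filter))
      utils::write.table(rep$steps,
                         file.path(config$out_dir, "filter_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$filter <<- rep
      manifest$stages$filter <<- list(status = "ok", n_in = n_loci(gt),
                                      n_out = n_loci(rep$filtered))
    })
    gt <- results$filter$filtered
  } else {
    manifest$stages$filter <- list(status = "skipped")
  }

  run_stage("correct", function() {
    cl <- correct_panel(gt, ped)
    results$corrected <<- cl
    manifest$stages$correct <<- list(
      status = "ok", n_loci = n_loci(gt),
      n_removed = sum(cl$locus_status != "kept"))
  })

  if (config$trajectory) run_stage("trajectory", function() {
    traj <- trajectory_summary(results$corrected, ped)
    utils::write.table(traj, file.path(config$out_dir, "trajectory.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$trajectory <<- traj
    manifest$stages$trajectory <<- list(status = "ok",
                                        generations = nrow(traj))
  }) else manifest$stages$trajectory <- list(status = "skipped")

  if (config$drift) run_stage("drift_test", function() {
    counts <- tabulate_fixation(results$corrected)
    res <- chi2_drift_test(counts)
    utils::write.table(res, file.path(config$out_dir, "drift_outliers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$drift <<- res
    manifest$stages$drift_test <<- list(status = "ok",
                                        n_tested = nrow(res),
                                        n_significant = sum(res$significant))
  }) else manifest$stages$drift_test <- list(status = "skipped")

  if (config$diversity) run_stage("diversity", function() {
    pw <- pi_windows(gt)
    utils::write.table(pw, file.path(config$out_dir, "pi_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$diversity <<- pw
    manifest$stages$diversity <<- list(status = "ok", n_windows = nrow(pw))
  }) else manifest$stages$diversity <- list(status = "skipped")

  if (config$ld_fit) run_stage("ld_fit", function() {
    prs <- all_pairs_within_scaffold(gt)
    n_eff <- if (is.null(config$ld_n)) n_samples(gt) else config$ld_n
    fit <- fit_ld_decay(prs, n = n_eff)
    results$ld_fit <<- fit
    manifest$stages$ld_fit <<- list(status = "ok", n_pairs = fit$n_pairs,
                                    C_per_bp = fit$C_per_bp)
  }) else manifest$stages$ld_fit <- list(status = "skipped")

  manifest$results <- results
  class(manifest) <- "run_manifest"
  manifest
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  # the hash must identify the analysis, not where it is written
  cfg$out_dir <- NULL
  if (!is.null(cfg$sim)) {
    cfg$sim <- lapply(unclass(cfg$sim), function(x)
      if (is.matrix(x)) as.vector(x) else x)
  }
  cfg
}

#' @exportS3Method base::print
print.run_manifest <- function(x, ...) {
  cat("pipeline run", x$config_hash, "seed", x$seed, "\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-12s %s\n", nm,
                paste(names(st), unlist(st), sep = "=", collapse = " ")))
  }
  invisible(x)
}
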