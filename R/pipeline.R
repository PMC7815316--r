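## End-to-end synthetic pipeline: simulate -> sequence -> call -> validate.

#' Pipeline configuration
#'
#' Collects the thresholds of every stage with their standard defaults
#' (minimum alternate reads 5, linkage window 25 bp, Fisher alpha 0.01,
#' presence/diploid-fixation/haploid-fixation frequencies 0.1/0.4/0.9,
#' minimum coverage 5x, 500-bp windows, 0.25 relative-depth mask, 4-window
#' CNV minimum, 6-population multi-hit threshold, 1000/10000 null
#' replicates, 0.1 enrichment pseudocount), plus the simulation settings and
#' the seed.
#'
#' @param n_populations Number of synthetic populations to simulate.
#' @param sim Base [sim_config()] for the populations (per-population seeds
#'   are derived from `seed`).
#' @param stages Character vector of stages to run, from
#'   `c("simulate", "call_mutations", "call_cnvs")`.
#' @param seed Master seed.
#' @param output_dir Where outputs are written (NULL: nothing written).
#' @param min_alt_reads,link_window,link_alpha,min_cov Mutation-calling
#'   thresholds.
#' @param cnv_noise_sd,cnv_n_windows,cnv_segments CNV-stage synthetic-track
#'   settings.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_populations = 10L, sim = sim_config(),
                            stages = c("simulate", "call_mutations",
                                       "call_cnvs"),
                            seed = 1L, output_dir = NULL,
                            min_alt_reads = 5L, link_window = 25L,
                            link_alpha = 0.01, min_cov = 5L,
                            cnv_noise_sd = 0.15,
                            cnv_n_windows = c(chr1 = 200L, chr2 = 200L),
                            cnv_segments = NULL) {
  if (!length(stages)) stop("config selects no stages")
  stages <- match.arg(stages, c("simulate", "call_mutations", "call_cnvs"),
                      several.ok = TRUE)
  structure(list(n_populations = as.integer(n_populations), sim = sim,
                 stages = stages, seed = as.integer(seed),
                 output_dir = output_dir, min_alt_reads = min_alt_reads,
                 link_window = link_window, link_alpha = link_alpha,
                 min_cov = min_cov, cnv_noise_sd = cnv_noise_sd,
                 cnv_n_windows = cnv_n_windows, cnv_segments = cnv_segments),
            class = "pipeline_config")
}

#' Run the synthetic end-to-end pipeline
#'
#' Simulates populations with planted truth, samples sequencing reads, runs
#' the mutation-calling (and optionally CNV-calling) stages, and scores the
#' calls against the truth. When `output_dir` is set, writes the allele
#' counts, per-population call tables and a machine-readable JSON summary,
#' each stamped with the configuration hash and seed.
#'
#' @param config A [pipeline_config()].
#' @return List with `summary` (including fixed-call `sensitivity` and
#'   `false_call_rate` against planted truth), `calls`, `truths`, and (if
#'   run) `cnv_calls`; plus `config_hash` and `seed`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("need a pipeline_config")
  if (!length(config$stages)) stop("config selects no stages")
  hash <- config_hash(unclass(config))
  out <- list(config_hash = hash, seed = config$seed)
  log_lines <- c(sprintf("config_hash\t%s", hash),
                 sprintf("seed\t%d", config$seed))

  if ("simulate" %in% config$stages) {
    truths <- list(); tables <- list()
    for (i in seq_len(config$n_populations)) {
      cfg <- config$sim
      cfg$seed <- config$seed * 1000L + i
      truths[[i]] <- simulate_wf_population(cfg)
      tables[[i]] <- sample_allele_counts(truths[[i]],
                                          population = sprintf("pop%02d", i),
                                          seed = cfg$seed + 1L)
    }
    table <- do.call(rbind, tables)
    out$truths <- truths
    out$table <- table
    log_lines <- c(log_lines, sprintf("simulate\t%d populations",
                                      config$n_populations))
  } else stop("stage 'simulate' is required for the synthetic pipeline")

  if ("call_mutations" %in% config$stages) {
    res <- score_calls_against_truth(out$table, out$truths,
                                     ploidy = config$sim$ploidy,
                                     min_alt_reads = config$min_alt_reads,
                                     window = config$link_window,
                                     alpha = config$link_alpha,
                                     min_cov = config$min_cov)
    out$calls <- res$calls
    out$summary <- res$summary
    log_lines <- c(log_lines,
                   sprintf("call_mutations\tsensitivity %.4f false_call_rate %.4f",
                           res$summary$sensitivity,
                           res$summary$false_call_rate))
  }

  if ("call_cnvs" %in% config$stages) {
    segs <- config$cnv_segments
    planted <- plant_cnv_track(config$cnv_n_windows, segs,
                               n_timepoints = length(config$sim$sequencing_timepoints),
                               noise_sd = config$cnv_noise_sd,
                               seed = config$seed + 7L)
    variance <- config$cnv_noise_sd^2
    out$cnv_calls <- call_cnvs(planted$tracks, variance,
                               n_windows = config$cnv_n_windows)
    out$cnv_truth <- planted$truth
    log_lines <- c(log_lines, sprintf("call_cnvs\t%d calls",
                                      nrow(out$cnv_calls)))
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_allele_counts(out$table,
                        file.path(config$output_dir, "allele_counts.tsv"))
    if (!is.null(out$summary))
      jsonlite::write_json(c(list(config_hash = hash, seed = config$seed),
                             out$summary),
                           file.path(config$output_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(config$output_dir, "run_log.tsv"))
  }
  out
}

## Run per-population mutation calling on a synthetic table and score the
## fixed calls at the final timepoint against the planted truth.
score_calls_against_truth <- function(table, truths, ploidy, ...) {
  pops <- sort(unique(table$population))
  stopifnot(length(pops) == length(truths))
  tp_final <- max(table$timepoint)
  n_true_fixed <- 0L; n_recovered <- 0L
  n_calls_total <- 0L; n_false <- 0L
  calls <- list()
  for (i in seq_along(pops)) {
    cl <- call_population(table, pops[i], ploidy = ploidy, ...)
    calls[[i]] <- cl
    truth <- truths[[i]]
    fin <- truth$frequency[, ncol(truth$frequency)]
    true_fixed <- truth$mutations[fin >= 1, , drop = FALSE]
    n_true_fixed <- n_true_fixed + nrow(true_fixed)
    if (!nrow(cl$groups)) next
    fixed_final <- vapply(cl$timelines, function(tl)
      tl$fixed[tl$timepoint == tp_final], TRUE)
    n_calls_total <- n_calls_total + nrow(cl$groups)
    ## match called groups to truth via their member variant positions
    fixed_members <- cl$members[cl$members$group %in%
                                cl$groups$group[fixed_final], , drop = FALSE]
    true_fixed_key <- paste(true_fixed$chrom, true_fixed$pos)
    n_recovered <- n_recovered +
      sum(true_fixed_key %in% paste(fixed_members$chrom, fixed_members$pos))
    ever_present <- truth$mutations[apply(truth$frequency, 1, max) > 0, ,
                                    drop = FALSE]
    ever_key <- paste(ever_present$chrom, ever_present$pos)
    false_group <- tapply(paste(cl$members$chrom, cl$members$pos) %in%
                          ever_key, cl$members$group, function(z) !any(z))
    n_false <- n_false + sum(false_group)
  }
  list(calls = calls,
       summary = list(
         n_true_fixed = n_true_fixed, n_recovered = n_recovered,
         sensitivity = if (n_true_fixed > 0) n_recovered / n_true_fixed
                       else NA_real_,
         n_calls = n_calls_total, n_false = n_false,
         false_call_rate = if (n_calls_total > 0) n_false / n_calls_total
                           else 0))
}
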