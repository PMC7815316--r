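# Shared builders for synthetic fixtures (all generated in code).

# Population metadata in the 3-strain x 3-environment design, n_per cell.
make_metadata <- function(n_per = 4L) {
  strains <- c("MATa", "MATalpha", "diploid")
  envs <- c("YPD30", "SC30", "SC37")
  md <- expand.grid(rep = seq_len(n_per), strain = strains,
                    environment = envs, stringsAsFactors = FALSE)
  md$population <- sprintf("%s_%s_%d", md$environment, md$strain, md$rep)
  md[, c("population", "strain", "environment")]
}

# Metadata matching the sequenced-population design: per environment,
# 12 MATa, 12 diploid and 6 MATalpha populations (90 in total).
make_study_metadata <- function() {
  rows <- lapply(c("YPD30", "SC30", "SC37"), function(env) {
    strain <- rep(c("MATa", "diploid", "MATalpha"), c(12, 12, 6))
    data.frame(population = sprintf("%s_%s_%d", env, strain,
                                    c(1:12, 1:12, 1:6)),
               strain = strain, environment = env,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Random gene-by-population indicator matrix.
make_hits <- function(n_genes, metadata, p = 0.3, seed = 1L) {
  set.seed(seed)
  matrix(rbinom(n_genes * nrow(metadata), 1L, p), n_genes,
         dimnames = list(paste0("g", seq_len(n_genes)), metadata$population))
}

# Minimal planted_truth object with given frequency matrix (one timepoint
# per column), for exercising sample_allele_counts in isolation.
make_truth <- function(freq, seed = 1L) {
  nm <- nrow(freq)
  set.seed(seed)
  structure(list(
    mutations = data.frame(
      id = seq_len(nm), lineage = seq_len(nm), origin_generation = 1L,
      s = 0, chrom = "chr1", pos = seq_len(nm) * 100L,
      ref = "A", alt = "T", annotation = "missense",
      stringsAsFactors = FALSE),
    frequency = freq,
    het_fraction = freq * 0,
    carriers = as.list(seq_len(nm)),
    timepoints = seq_len(ncol(freq)),
    config = sim_config(population_size = 100L, generations_total = 10L,
                        sequencing_timepoints = seq_len(ncol(freq)))),
    class = "planted_truth")
}

# Small Wright-Fisher config for fast end-to-end runs.
small_wf_config <- function(seed = 1L, ploidy = "haploid") {
  sim_config(population_size = 1000L, generations_total = 600L,
             sequencing_timepoints = c(70L, 176L, 282L, 388L, 494L, 600L),
             ploidy = ploidy, beneficial_rate = 2e-4, effect_mean = 0.08,
             neutral_rate = 1e-3, coverage_mean = 40, seed = seed)
}

# Allele-count rows for one variant in one population.
variant_rows <- function(population, pos, alt_reads, ref_reads,
                         chrom = "chr1", ref = "A", alt = "T") {
  data.frame(population = population, chrom = chrom, pos = pos, ref = ref,
             alt = alt, timepoint = seq_along(alt_reads),
             ref_reads = ref_reads, alt_reads = alt_reads,
             stringsAsFactors = FALSE)
}
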