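#' Simulation configuration for a whole-population evolution experiment
#'
#' Bundles and validates the parameters of the lineage-structured
#' Wright-Fisher simulator. Defaults emulate a long-term batch-culture yeast
#' experiment: an effective population size of ~1e4, 10,000 generations, six
#' sequenced timepoints starting at the first weekly archive (generation 70),
#' and per-genome mutation rates at the scale measured for budding yeast.
#'
#' @param population_size Integer, number of (effective) individuals at the
#'   bottleneck.
#' @param generations_total Integer, total generations simulated.
#' @param sequencing_timepoints Increasing integer vector of generations at
#'   which the population is "sequenced"; defaults to the first archive plus
#'   five evenly spaced later timepoints (six in total).
#' @param ploidy `"haploid"` or `"diploid"`.
#' @param beneficial_rate Per-genome per-generation probability of a new
#'   beneficial mutation.
#' @param effect_mean Mean selection coefficient; effects are exponential.
#' @param neutral_rate Per-genome per-generation probability of a new neutral
#'   mutation (hitchhiker substrate).
#' @param dominance Dominance coefficient h in `[0, 1]` applied to
#'   heterozygous mutations in diploids.
#' @param loh_rate Per-heterozygous-mutation per-generation probability of
#'   conversion to homozygosity (mitotic recombination / homozygosis).
#' @param coverage_mean Mean sequencing fold-coverage used by
#'   [sample_allele_counts()].
#' @param n_chromosomes,chromosome_length Abstract genome used to place
#'   mutations; no attempt is made to mimic real chromosome structure.
#' @param seed Integer seed recorded in the config (used by the simulator).
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(population_size = 10000L,
                       generations_total = 10000L,
                       sequencing_timepoints = NULL,
                       ploidy = c("haploid", "diploid"),
                       beneficial_rate = 1e-5,
                       effect_mean = 0.03,
                       neutral_rate = 4e-3,
                       dominance = 0.5,
                       loh_rate = 1e-4,
                       coverage_mean = 40,
                       n_chromosomes = 16L,
                       chromosome_length = 750000L,
                       seed = 1L) {
  ploidy <- match.arg(ploidy)
  if (is.null(sequencing_timepoints)) {
    first <- min(70L, generations_total)
    sequencing_timepoints <- unique(round(seq(first, generations_total,
                                              length.out = 6L)))
  }
  cfg <- list(population_size = as.integer(population_size),
              generations_total = as.integer(generations_total),
              sequencing_timepoints = as.integer(sequencing_timepoints),
              ploidy = ploidy,
              beneficial_rate = beneficial_rate,
              effect_mean = effect_mean,
              neutral_rate = neutral_rate,
              dominance = dominance,
              loh_rate = loh_rate,
              coverage_mean = coverage_mean,
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$beneficial_rate, cfg$neutral_rate, cfg$loh_rate,
             cfg$effect_mean, cfg$coverage_mean)
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (cfg$population_size < 1) stop("population_size must be >= 1")
  if (cfg$dominance < 0 || cfg$dominance > 1) stop("dominance must be in [0, 1]")
  tp <- cfg$sequencing_timepoints
  if (length(tp) < 1 || any(diff(tp) <= 0))
    stop("sequencing_timepoints must be strictly increasing")
  if (max(tp) > cfg$generations_total)
    stop("sequencing_timepoints must not exceed generations_total")
  invisible(cfg)
}

#' Simulate a Wright-Fisher population with lineage-structured mutations
#'
#' Runs a discrete-generation Wright-Fisher simulation in which every new
#' mutation founds a new lineage. Mutations within a lineage are perfectly
#' linked, so cohorts of mutations share frequency trajectories -- the clonal
#' interference regime in which groups of mutations rise together and crash
#' when outcompeted. In diploids, mutations arise heterozygous (fitness
#' `1 + h*s`), may convert to homozygosity (`1 + s`) at `loh_rate` per carrier
#' per generation, and the recorded allele frequency counts heterozygotes at
#' half weight.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `"planted_truth"`: a list with elements
#'   `mutations` (data.frame: id, origin lineage, origin generation, selection
#'   coefficient, chrom, pos, ref, alt, annotation), `frequency` (mutations x
#'   timepoints matrix of true allele frequencies), `het_fraction` (same shape;
#'   fraction of the population carrying the mutation heterozygously, all zero
#'   for haploids), `carriers` (carrier lineage ids at the final generation),
#'   `cohort_keys` (mutations x timepoints carrier-set keys: mutations with
#'   identical keys at every timepoint form a cohort and share a frequency
#'   trajectory), `timepoints`, and `config`.
#' @export
simulate_wf_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  N <- config$population_size
  G <- config$generations_total
  tps <- config$sequencing_timepoints
  diploid <- identical(config$ploidy, "diploid")
  h <- config$dominance

  ## lineage state (parallel vectors/lists); lineage 1 is the ancestor
  counts <- N
  muts <- list(integer(0))       # mutation ids per lineage
  zygs <- list(integer(0))       # 1 = het, 2 = hom (haploid: always 2)
  fit <- 1

  mut_s <- numeric(0)            # per-mutation selection coefficient
  mut_origin <- integer(0)       # origin generation
  mut_lineage <- integer(0)      # lineage id in which the mutation arose

  n_tp <- length(tps)
  freq_rec <- list()
  het_rec <- list()
  key_rec <- list()

  lineage_fitness <- function(m, z) {
    if (!length(m)) return(1)
    s <- mut_s[m]
    if (diploid) prod(ifelse(z == 2L, 1 + s, 1 + h * s)) else prod(1 + s)
  }

  record <- function() {
    nm <- length(mut_s)
    f <- numeric(nm); het <- numeric(nm)
    carr <- vector("list", nm)
    if (nm > 0) {
      for (l in seq_along(counts)) {
        if (counts[l] == 0 || !length(muts[[l]])) next
        m <- muts[[l]]; z <- zygs[[l]]
        w <- if (diploid) ifelse(z == 2L, 1, 0.5) else rep(1, length(m))
        f[m] <- f[m] + counts[l] * w
        if (diploid) het[m] <- het[m] + counts[l] * (z == 1L)
        for (mm in m) carr[[mm]] <- c(carr[[mm]], l)
      }
      f <- f / N
      het <- het / N
    }
    keys <- vapply(carr, function(cc)
      if (is.null(cc)) "" else paste(cc, collapse = ","), "")
    list(f = f, het = het, keys = keys)
  }

  tp_idx <- 1L
  for (gen in seq_len(G)) {
    ## selection + drift
    w <- counts * fit
    counts <- as.vector(stats::rmultinom(1, N, w))

    ## prune extinct lineages occasionally to bound state size
    if (length(counts) > 256L && gen %% 50L == 0L) {
      keep <- counts > 0L
      keep[1L] <- TRUE
      counts <- counts[keep]; muts <- muts[keep]; zygs <- zygs[keep]
      fit <- fit[keep]
    }

    ## new mutations
    nb <- stats::rpois(1, N * config$beneficial_rate)
    nn <- stats::rpois(1, N * config$neutral_rate)
    if (nb + nn > 0) {
      s_new <- c(stats::rexp(nb, rate = 1 / config$effect_mean), rep(0, nn))
      for (s in s_new) {
        parent <- sample.int(length(counts), 1, prob = counts)
        if (counts[parent] == 0) next
        mid <- length(mut_s) + 1L
        mut_s[mid] <- s
        mut_origin[mid] <- gen
        lin <- length(counts) + 1L
        mut_lineage[mid] <- lin
        counts[parent] <- counts[parent] - 1L
        counts[lin] <- 1L
        muts[[lin]] <- c(muts[[parent]], mid)
        zygs[[lin]] <- c(zygs[[parent]], if (diploid) 1L else 2L)
        fit[lin] <- lineage_fitness(muts[[lin]], zygs[[lin]])
      }
    }

    ## loss of heterozygosity: instantaneous het -> hom conversion
    if (diploid && config$loh_rate > 0) {
      for (l in seq_along(counts)) {
        if (counts[l] == 0) next
        hets <- which(zygs[[l]] == 1L)
        for (j in hets) {
          k <- stats::rbinom(1, counts[l], config$loh_rate)
          if (k == 0) next
          lin <- length(counts) + 1L
          counts[l] <- counts[l] - k
          counts[lin] <- k
          muts[[lin]] <- muts[[l]]
          z <- zygs[[l]]; z[j] <- 2L
          zygs[[lin]] <- z
          fit[lin] <- lineage_fitness(muts[[lin]], z)
        }
      }
    }

    if (tp_idx <= n_tp && gen == tps[tp_idx]) {
      rec <- record()
      freq_rec[[tp_idx]] <- rec$f
      het_rec[[tp_idx]] <- rec$het
      key_rec[[tp_idx]] <- rec$keys
      tp_idx <- tp_idx + 1L
    }
  }

  nm <- length(mut_s)
  fmat <- matrix(0, nrow = nm, ncol = n_tp,
                 dimnames = list(NULL, paste0("t", tps)))
  hmat <- fmat
  kmat <- matrix("", nrow = nm, ncol = n_tp,
                 dimnames = dimnames(fmat))
  for (k in seq_len(n_tp)) {
    fk <- freq_rec[[k]]; hk <- het_rec[[k]]
    if (length(fk)) {
      fmat[seq_along(fk), k] <- fk
      hmat[seq_along(hk), k] <- hk
      kmat[seq_along(fk), k] <- key_rec[[k]]
    }
  }

  bases <- c("A", "C", "G", "T")
  ref <- if (nm) sample(bases, nm, replace = TRUE) else character(0)
  alt <- if (nm) vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
         else character(0)
  ann_levels <- c("missense", "synonymous", "noncoding", "nonsense", "indel")
  ann_probs <- c(0.45, 0.30, 0.12, 0.05, 0.08)
  mutations <- data.frame(
    id = seq_len(nm),
    lineage = mut_lineage,
    origin_generation = mut_origin,
    s = mut_s,
    chrom = if (nm) paste0("chr", sample.int(config$n_chromosomes, nm,
                                             replace = TRUE)) else character(0),
    pos = if (nm) sample.int(config$chromosome_length, nm, replace = TRUE)
          else integer(0),
    ref = ref, alt = alt,
    annotation = if (nm) sample(ann_levels, nm, replace = TRUE,
                                prob = ann_probs) else character(0),
    stringsAsFactors = FALSE)

  ## carrier sets at the final timepoint: mutations are cohort-linked when
  ## they are carried by exactly the same surviving lineages
  carriers <- vector("list", nm)
  for (l in seq_along(counts)) {
    if (counts[l] == 0) next
    for (m in muts[[l]]) carriers[[m]] <- c(carriers[[m]], l)
  }

  structure(list(mutations = mutations, frequency = fmat,
                 het_fraction = hmat, carriers = carriers,
                 cohort_keys = kmat, timepoints = tps, config = config),
            class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("Planted truth:", nrow(x$mutations), "mutations,",
      length(x$timepoints), "sequenced timepoints,",
      x$config$ploidy, "population of", x$config$population_size, "\n")
  fin <- x$frequency[, ncol(x$frequency)]
  cat("  final-timepoint frequencies >= 0.9:", sum(fin >= 0.9), "\n")
  invisible(x)
}

#' Single-locus Wright-Fisher replicates
#'
#' Fast binomial-sampling simulator for one mutation segregating in a haploid
#' population, used to validate the lineage simulator against classical
#' results (neutral fixation probability 1/N; deterministic logistic sweep
#' times for N*s >> 1).
#'
#' @param N Population size.
#' @param s Selection coefficient.
#' @param p0 Initial frequency (default a single copy, `1/N`).
#' @param n_rep Number of replicate populations.
#' @param max_gen Generation cap.
#' @return A list with `fixed` (logical per replicate), `t10`/`t90` (first
#'   generation at which frequency reached 0.1 / 0.9; NA if never).
#' @export
wf_single_locus <- function(N, s, p0 = 1 / N, n_rep = 1000L,
                            max_gen = 100L * N) {
  p <- rep(p0, n_rep)
  active <- rep(TRUE, n_rep)
  t10 <- rep(NA_real_, n_rep); t90 <- rep(NA_real_, n_rep)
  gen <- 0L
  while (any(active) && gen < max_gen) {
    gen <- gen + 1L
    idx <- which(active)
    ps <- p[idx] * (1 + s) / (p[idx] * (1 + s) + (1 - p[idx]))
    p[idx] <- stats::rbinom(length(idx), N, ps) / N
    hit10 <- idx[p[idx] >= 0.1 & is.na(t10[idx])]
    t10[hit10] <- gen
    hit90 <- idx[p[idx] >= 0.9 & is.na(t90[idx])]
    t90[hit90] <- gen
    active[idx[p[idx] %in% c(0, 1)]] <- FALSE
  }
  list(fixed = p == 1, t10 = t10, t90 = t90)
}
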