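#' Sample sequencing allele counts from planted truth
#'
#' Emulates whole-population short-read sequencing of a simulated population:
#' at each sequenced timepoint the total depth at a variant is Poisson around
#' `coverage_mean` and the alternate-read count is binomial in the true allele
#' frequency.
#'
#' @param truth A `"planted_truth"` object from [simulate_wf_population()].
#' @param coverage_mean Mean fold-coverage; defaults to the config value.
#' @param population Population id to stamp on the rows.
#' @param seed Integer seed.
#' @return An allele-count table: data.frame with columns `population`,
#'   `chrom`, `pos`, `ref`, `alt`, `timepoint`, `ref_reads`, `alt_reads`.
#'   Timepoints are the 1-based indices of the sequenced generations.
#' @export
sample_allele_counts <- function(truth, coverage_mean = NULL,
                                 population = "pop1", seed = 1L) {
  if (is.null(coverage_mean)) coverage_mean <- truth$config$coverage_mean
  if (coverage_mean < 0) stop("coverage_mean must be >= 0")
  set.seed(seed)
  mu <- truth$mutations
  n_tp <- ncol(truth$frequency)
  nm <- nrow(mu)
  if (nm == 0) {
    return(data.frame(population = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), timepoint = integer(0),
                      ref_reads = integer(0), alt_reads = integer(0)))
  }
  out <- vector("list", n_tp)
  for (k in seq_len(n_tp)) {
    depth <- stats::rpois(nm, coverage_mean)
    altr <- stats::rbinom(nm, depth, truth$frequency[, k])
    out[[k]] <- data.frame(population = population, chrom = mu$chrom,
                           pos = mu$pos, ref = mu$ref, alt = mu$alt,
                           timepoint = k, ref_reads = depth - altr,
                           alt_reads = altr, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Plant copy-number segments on a standardized-depth track
#'
#' Builds a synthetic standardized-depth track (expectation 1 everywhere)
#' with planted copy-number segments and Gaussian noise whose standard
#' deviation scales as `noise_sd * sqrt(state)` (state 0: `sqrt(0.5)`),
#' matching the state-proportional variance model of the CNV HMM.
#'
#' @param n_windows Named integer vector: windows per chromosome.
#' @param segments data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive window indices), `state` (from the HMM state set) and
#'   optionally `timepoints` (list-column or comma string of timepoints the
#'   segment is present in; default all).
#' @param n_timepoints Number of timepoints to generate tracks for.
#' @param noise_sd Baseline noise standard deviation at state 1.
#' @param seed Integer seed.
#' @return List with `tracks` (list over timepoints of named lists of
#'   per-chromosome standardized-depth vectors) and `truth` (the segment
#'   table, normalized).
#' @export
plant_cnv_track <- function(n_windows, segments = NULL, n_timepoints = 2L,
                            noise_sd = 0.15, seed = 1L) {
  states <- cnv_hmm_states()
  set.seed(seed)
  if (is.null(names(n_windows)))
    names(n_windows) <- paste0("chr", seq_along(n_windows))
  if (is.null(segments))
    segments <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), state = numeric(0))
  if (nrow(segments)) {
    if (!all(segments$state %in% states))
      stop("segment states must be in the HMM state set: ",
           paste(states, collapse = ", "))
    if (!all(segments$chrom %in% names(n_windows)))
      stop("segment chromosome not in n_windows")
    if (any(segments$start < 1) ||
        any(segments$end > n_windows[segments$chrom]))
      stop("segments out of bounds")
    if (is.null(segments$timepoints))
      segments$timepoints <- I(rep(list(seq_len(n_timepoints)), nrow(segments)))
  }
  ## reject overlapping segments with conflicting states on a chromosome
  if (nrow(segments) > 1) {
    for (i in seq_len(nrow(segments) - 1)) for (j in (i + 1):nrow(segments)) {
      if (segments$chrom[i] != segments$chrom[j]) next
      if (segments$start[j] <= segments$end[i] &&
          segments$start[i] <= segments$end[j] &&
          length(intersect(segments$timepoints[[i]],
                           segments$timepoints[[j]])) &&
          segments$state[i] != segments$state[j])
        stop("overlapping segments with conflicting states")
    }
  }
  tracks <- vector("list", n_timepoints)
  for (tp in seq_len(n_timepoints)) {
    chroms <- lapply(names(n_windows), function(ch) {
      mean_level <- rep(1, n_windows[[ch]])
      if (nrow(segments)) {
        seg <- segments[segments$chrom == ch, , drop = FALSE]
        for (r in seq_len(nrow(seg))) {
          if (!(tp %in% seg$timepoints[[r]])) next
          mean_level[seg$start[r]:seg$end[r]] <- seg$state[r]
        }
      }
      sdv <- noise_sd * sqrt(ifelse(mean_level == 0, 0.5, mean_level))
      mean_level + stats::rnorm(length(mean_level), 0, sdv)
    })
    names(chroms) <- names(n_windows)
    tracks[[tp]] <- chroms
  }
  list(tracks = tracks, truth = segments)
}

#' Simulate a gene-by-population hit matrix from per-gene hit probabilities
#'
#' Draws independent Bernoulli indicators `h_gi` for each gene in each
#' population, the generating process of the null enrichment models.
#'
#' @param prob Matrix of per-gene (rows) per-population (columns) hit
#'   probabilities, or a vector recycled across populations.
#' @param n_populations Number of populations when `prob` is a vector.
#' @param seed Integer seed.
#' @return Integer 0/1 matrix, genes x populations.
#' @export
simulate_hit_matrix <- function(prob, n_populations = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(dim(prob))) {
    if (is.null(n_populations)) stop("n_populations required for vector prob")
    prob <- matrix(prob, nrow = length(prob), ncol = n_populations)
  }
  if (any(prob < 0 | prob > 1)) stop("probabilities must be in [0, 1]")
  h <- matrix(stats::rbinom(length(prob), 1L, prob), nrow = nrow(prob),
              dimnames = dimnames(prob))
  h
}

#' Simulate Luria-Delbruck fluctuation cultures
#'
#' Generates per-culture mutant colony counts under the Luria-Delbruck
#' process: the number of mutation events per culture is Poisson with mean
#' `m`, each event occurs at a time uniform on the log-growth of the culture
#' (so a clone's final size `u` has survival function 1/u), and the clone
#' grows deterministically to plating. Integer clone sizes therefore follow
#' P(size = s) = 1/(s(s+1)), the model underlying the Ma-Sandri-Sarkar
#' likelihood.
#'
#' @param m Expected mutation events per culture.
#' @param N_t Final cells per culture (caps clone size).
#' @param n_cultures Number of parallel cultures (default 88).
#' @param seed Integer seed.
#' @return Object of class `"fluctuation_experiment"`: list with `counts`
#'   (integer vector), `N_t`, and `m_true`.
#' @export
simulate_luria_delbruck <- function(m, N_t, n_cultures = 88L, seed = 1L) {
  if (m < 0) stop("m must be >= 0")
  if (N_t < 1) stop("N_t must be >= 1")
  set.seed(seed)
  n_mut <- stats::rpois(n_cultures, m)
  counts <- integer(n_cultures)
  pos <- which(n_mut > 0)
  for (i in pos) {
    u <- 1 / stats::runif(n_mut[i])         # P(U >= u) = 1/u, u >= 1
    counts[i] <- sum(pmin(floor(u), N_t))
  }
  structure(list(counts = counts, N_t = N_t, m_true = m),
            class = "fluctuation_experiment")
}

#' Simulate a competitive fitness assay against a fluorescent reference
#'
#' The test:reference ratio grows as `exp(fitness * generations)`; at each
#' transfer, flow-cytometry events are drawn multinomially between
#' fluorescent (reference) and nonfluorescent cells, with a fraction of
#' reference cells failing to fluoresce and therefore counted as test cells.
#'
#' @param true_fitness Per-generation selection coefficient of the test
#'   population relative to the reference.
#' @param generations_per_cycle Generations elapsed per daily growth cycle.
#' @param n_cycles Number of growth cycles after mixing (default 3).
#' @param initial_ratio Test:reference ratio at mixing (default 1).
#' @param events_per_read Cytometry events counted per measurement.
#' @param nonfluorescent_fraction Fraction of reference cells that do not
#'   fluoresce.
#' @param seed Integer seed.
#' @return data.frame with one row per timepoint (0..n_cycles): `timepoint`,
#'   `generations` (cumulative), `fluorescent`, `nonfluorescent` event counts
#'   and the latent `true_ref_freq`.
#' @export
simulate_fitness_assay <- function(true_fitness, generations_per_cycle = 10,
                                   n_cycles = 3L, initial_ratio = 1,
                                   events_per_read = 20000L,
                                   nonfluorescent_fraction = 0.05,
                                   seed = 1L) {
  if (generations_per_cycle < 0 || events_per_read < 0 ||
      nonfluorescent_fraction < 0 || initial_ratio < 0)
    stop("parameters must be >= 0")
  set.seed(seed)
  tp <- 0:n_cycles
  gens <- tp * generations_per_cycle
  ratio <- initial_ratio * exp(true_fitness * gens)
  ref_freq <- 1 / (1 + ratio)
  p_fluor <- ref_freq * (1 - nonfluorescent_fraction)
  if (is.finite(events_per_read) && events_per_read > 0) {
    fl <- stats::rbinom(length(tp), events_per_read, p_fluor)
    nf <- events_per_read - fl
  } else {
    fl <- round(p_fluor * 1e9); nf <- 1e9 - fl
  }
  data.frame(timepoint = tp, generations = gens, fluorescent = fl,
             nonfluorescent = nf, true_ref_freq = ref_freq)
}
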