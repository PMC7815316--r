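## Competitive fitness estimation from fluorescent-reference competitions.

#' Correct the observed fluorescent fraction for nonfluorescent reference cells
#'
#' A small fraction `f` of reference cells do not fluoresce and are counted
#' with the test population; the corrected reference frequency is
#' `observed / (1 - f)`, capped at 1 (reference-only control wells reach the
#' cap exactly).
#'
#' @param observed Observed fluorescent fraction(s) in `[0, 1]`.
#' @param f Nonfluorescent fraction of the reference, `0 <= f < 1`; typically
#'   estimated from reference-only control wells.
#' @return Corrected reference frequency, same length as `observed`.
#' @export
correct_reference_frequency <- function(observed, f) {
  if (f < 0 || f >= 1) stop("nonfluorescent fraction must satisfy 0 <= f < 1")
  if (any(observed < 0 | observed > 1, na.rm = TRUE))
    stop("observed fractions must be in [0, 1]")
  pmin(observed / (1 - f), 1)
}

#' Estimate the nonfluorescent fraction from reference-only control wells
#'
#' @param fluorescent,nonfluorescent Event counts in wells containing only
#'   the reference strain.
#' @return Estimated fraction of reference cells that do not fluoresce.
#' @export
estimate_nonfluorescent_fraction <- function(fluorescent, nonfluorescent) {
  tot <- sum(fluorescent) + sum(nonfluorescent)
  if (tot == 0) stop("no events in reference-only wells")
  sum(nonfluorescent) / tot
}

#' Estimate competitive fitness from a reference-frequency series
#'
#' Fitness is the least-squares slope of `ln((1 - x) / x)` against cumulative
#' generations, where `x` is the (corrected) reference frequency -- i.e. the
#' per-generation log-ratio advantage of the test population over the
#' reference. Timepoints with reference frequency below 5% or above 95% are
#' excluded before fitting.
#'
#' @param ref_freq Corrected reference frequency per transfer timepoint.
#' @param generations Cumulative generations elapsed at each timepoint
#'   (same length as `ref_freq`), or a single number of generations per
#'   transfer.
#' @return Object of class `"fitness_fit"`: list with `fitness`
#'   (per-generation slope; NA if fewer than two usable timepoints),
#'   `n_used`, `excluded` (indices), `missing` flag.
#' @export
estimate_fitness <- function(ref_freq, generations) {
  if (length(generations) == 1L)
    generations <- (seq_along(ref_freq) - 1L) * generations
  stopifnot(length(generations) == length(ref_freq))
  usable <- !is.na(ref_freq) & ref_freq >= 0.05 & ref_freq <= 0.95
  out <- list(fitness = NA_real_, n_used = sum(usable),
              excluded = which(!usable), missing = TRUE)
  if (sum(usable) >= 2) {
    y <- log((1 - ref_freq[usable]) / ref_freq[usable])
    g <- generations[usable]
    out$fitness <- sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)
    out$missing <- FALSE
  }
  class(out) <- "fitness_fit"
  out
}

#' @export
print.fitness_fit <- function(x, ...) {
  if (x$missing) cat("Fitness: missing (<2 usable timepoints)\n")
  else cat(sprintf("Fitness: %.4f per generation (%d timepoints used)\n",
                   x$fitness, x$n_used))
  invisible(x)
}

#' @export
coef.fitness_fit <- function(object, ...) c(fitness = object$fitness)

#' Estimate fitness directly from cytometry event counts
#'
#' @param fluorescent,nonfluorescent Event counts per transfer timepoint.
#' @param generations As in [estimate_fitness()].
#' @param nonfluorescent_fraction Correction factor `f` (see
#'   [correct_reference_frequency()]).
#' @return A `"fitness_fit"` object.
#' @export
fitness_from_counts <- function(fluorescent, nonfluorescent, generations,
                                nonfluorescent_fraction = 0) {
  tot <- fluorescent + nonfluorescent
  obs <- ifelse(tot > 0, fluorescent / tot, NA_real_)
  x <- correct_reference_frequency(obs, nonfluorescent_fraction)
  estimate_fitness(x, generations)
}

#' Batch-correct fitness estimates
#'
#' Subtracts, from each well's (replicate-averaged) fitness, the mean fitness
#' measured for an unlabeled copy of the reference strain in the same assay
#' batch, removing per-batch systematic offsets.
#'
#' @param fitness Numeric vector of fitness values.
#' @param batch Batch id per fitness value.
#' @param reference_fitness Numeric vector of unlabeled-reference fitness
#'   values.
#' @param reference_batch Batch id per reference value.
#' @return Corrected fitness vector.
#' @export
batch_correct <- function(fitness, batch, reference_fitness, reference_batch) {
  stopifnot(length(fitness) == length(batch),
            length(reference_fitness) == length(reference_batch))
  means <- tapply(reference_fitness, reference_batch, mean)
  miss <- setdiff(unique(batch), names(means))
  if (length(miss))
    stop("no unlabeled-reference wells in batch(es): ",
         paste(miss, collapse = ", "))
  fitness - as.numeric(means[as.character(batch)])
}

#' Define ancestral fitness from mutation-free populations
#'
#' Ancestral fitness for a strain/environment is the median first-timepoint
#' fitness among populations with no nonsynonymous mutations detected at
#' that timepoint. If no population qualifies, a stated fallback value (the
#' first-timepoint fitness of a designated population) is used.
#'
#' @param fitness First-timepoint fitness per population.
#' @param mutation_free Logical flag per population.
#' @param fallback Optional fallback fitness when no population is flagged.
#' @return Ancestral fitness (scalar).
#' @export
ancestral_fitness <- function(fitness, mutation_free, fallback = NULL) {
  stopifnot(length(fitness) == length(mutation_free))
  if (any(mutation_free)) return(stats::median(fitness[mutation_free]))
  if (!is.null(fallback)) return(fallback)
  stop("no mutation-free populations and no fallback value provided")
}
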