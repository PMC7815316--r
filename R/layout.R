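#' Serial-dilution design arithmetic for the three evolution environments
#'
#' Derives, from the culture parameters of a daily batch-transfer design,
#' the number of generations (doublings) per day and per weekly archive and
#' the bottleneck population size: a 1:2^k dilution permits k doublings per
#' day, and the bottleneck is the culture volume times the saturation cell
#' density divided by the dilution factor.
#'
#' @param environments data.frame with columns `environment`,
#'   `dilution_factor`, `volume_ml`, `density_per_ml`, `days_per_archive`.
#'   The default describes rich medium at 30C (1:2^10, saturation ~6e7
#'   cells/ml), synthetic complete at 30C (1:2^10, ~1.6e7 cells/ml) and
#'   synthetic complete at 37C (1:2^8, ~1.6e7 cells/ml), 128 ul cultures,
#'   weekly archives.
#' @return The input with added `generations_per_day`,
#'   `generations_per_archive` and `bottleneck` columns.
#' @export
environment_design <- function(environments = data.frame(
    environment = c("YPD30", "SC30", "SC37"),
    dilution_factor = c(2^10, 2^10, 2^8),
    volume_ml = 0.128,
    density_per_ml = c(6e7, 1.6e7, 1.6e7),
    days_per_archive = 7)) {
  environments$generations_per_day <- log2(environments$dilution_factor)
  environments$generations_per_archive <-
    environments$generations_per_day * environments$days_per_archive
  environments$bottleneck <- environments$volume_ml *
    environments$density_per_ml / environments$dilution_factor
  environments
}

#' Generate an experiment layout table
#'
#' Builds the population-metadata table for a multi-environment evolution
#' experiment: one row per independent population, carrying a unique id, the
#' environment it evolves in, its founding strain type and its ploidy.
#'
#' @param design Named integer vector of founding counts per strain type,
#'   e.g. `c(MATa = 45, MATalpha = 8, diploid = 37)`. Strain types named
#'   `"diploid"` are diploid; all others are haploid.
#' @param environments Character vector of environment names; the design is
#'   replicated in each environment.
#' @param lost Optional character vector of population ids flagged as lost
#'   (contamination, evaporation, pipetting failure). Lost populations are
#'   retained in the table with `active = FALSE`.
#'
#' @return A data.frame with columns `population`, `environment`, `strain`,
#'   `ploidy` and `active`.
#' @examples
#' lay <- generate_experiment_layout(
#'   c(MATa = 45, MATalpha = 8, diploid = 37),
#'   c("YPD30", "SC30", "SC37"))
#' nrow(lay)  # 270
#' @export
generate_experiment_layout <- function(design, environments, lost = character()) {
  if (length(design) == 0L || length(environments) == 0L)
    stop("empty design: need at least one strain count and one environment")
  if (is.null(names(design)) || any(!nzchar(names(design))))
    stop("design must be a named vector of strain counts")
  if (any(design < 0))
    stop("strain counts must be non-negative")
  rows <- list()
  for (env in environments) {
    for (strain in names(design)) {
      n <- design[[strain]]
      if (n == 0) next
      ids <- sprintf("%s_%s_%02d", env, strain, seq_len(n))
      rows[[length(rows) + 1L]] <- data.frame(
        population = ids,
        environment = env,
        strain = strain,
        ploidy = if (identical(strain, "diploid")) "diploid" else "haploid",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("empty design: all strain counts are zero")
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$population))
  unknown <- setdiff(lost, out$population)
  if (length(unknown))
    stop("lost ids not in layout: ", paste(unknown, collapse = ", "))
  out$active <- !(out$population %in% lost)
  out
}
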