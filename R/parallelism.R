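## Gene- and codon-level parallelism of fixed nonsynonymous mutations.
##
## The substrate is a hit table (one row per fixed nonsynonymous mutation:
## gene, population, optionally amino-acid position) or its genes x
## populations count matrix, plus a gene-model table giving each gene's
## nonsynonymous target size.

#' Build a genes x populations hit-count matrix from a hit table
#'
#' @param hits data.frame with columns `gene` and `population` (one row per
#'   hit; repeated rows count multiply).
#' @param genes Optional gene universe (rows of the matrix); defaults to the
#'   genes observed.
#' @param populations Optional population universe (columns).
#' @return Integer matrix of hit counts, genes x populations.
#' @export
hit_matrix <- function(hits, genes = NULL, populations = NULL) {
  if (is.null(genes)) genes <- sort(unique(hits$gene))
  if (is.null(populations)) populations <- sort(unique(hits$population))
  m <- table(factor(hits$gene, levels = genes),
             factor(hits$population, levels = populations))
  matrix(as.integer(m), nrow = length(genes),
         dimnames = list(genes, populations))
}

#' Gene multiplicity
#'
#' The multiplicity of a gene is its number of hits across all sequenced
#' populations divided by its relative target size: `m_i = n_i /
#' (L_i / Lbar)`, where `L_i` is the number of possible nonsynonymous
#' mutations in gene i and `Lbar` the mean target size across the whole gene
#' set. A gene hit proportionally to its target size has multiplicity equal
#' to its raw hit count at `L_i = Lbar`.
#'
#' @param hits Hit-count matrix (genes x populations) or named vector of
#'   per-gene total hits.
#' @param gene_models data.frame with columns `gene` and `target_size`
#'   covering at least all hit genes; `Lbar` is computed over all rows (the
#'   full annotated gene set).
#' @return Named numeric vector of multiplicities for the genes in `hits`.
#' @export
gene_multiplicity <- function(hits, gene_models) {
  n_i <- if (is.matrix(hits)) rowSums(hits) else hits
  idx <- match(names(n_i), gene_models$gene)
  if (anyNA(idx))
    stop("missing gene model for: ",
         paste(names(n_i)[is.na(idx)], collapse = ", "))
  lbar <- mean(gene_models$target_size)
  n_i / (gene_models$target_size[idx] / lbar)
}

#' Simulate null hit matrices by random assignment to genes
#'
#' Under the null, each population's observed number of hits is redistributed
#' across the full gene set multinomially with probabilities proportional to
#' per-gene nonsynonymous target size.
#'
#' @param hits_per_population Integer vector `M_g` of hits per population.
#' @param gene_models data.frame with `gene` and `target_size` (the full
#'   gene set used as assignment targets).
#' @param n_reps Number of null replicates (default 1000).
#' @param seed Integer seed.
#' @return List of `n_reps` hit-count matrices (genes x populations).
#' @export
simulate_null_hits <- function(hits_per_population, gene_models,
                               n_reps = 1000L, seed = 1L) {
  if (any(gene_models$target_size <= 0)) stop("target sizes must be > 0")
  set.seed(seed)
  w <- gene_models$target_size / sum(gene_models$target_size)
  G <- nrow(gene_models); P <- length(hits_per_population)
  pops <- names(hits_per_population)
  if (is.null(pops)) pops <- paste0("pop", seq_len(P))
  lapply(seq_len(n_reps), function(r) {
    m <- matrix(vapply(hits_per_population, function(mg)
      as.integer(stats::rmultinom(1, mg, w)), integer(G)), nrow = G)
    dimnames(m) <- list(gene_models$gene, pops)
    m
  })
}

## Survival curve of a statistic: fraction of items with value >= grid point.
survival_curve <- function(values, grid) {
  vapply(grid, function(g) mean(values >= g), 0)
}

#' Observed and null parallelism survival curves
#'
#' Computes three survival curves comparing the data to the
#' random-assignment null: (a) the fraction of genes with multiplicity at
#' least m; (b) the fraction of genes with hits in at least PH populations;
#' (c) the fraction of amino-acid sites with hits in at least PH
#' populations, whose null randomizes each fixed mutation's position within
#' its own gene (10 replicates). The null envelope is the pointwise 2.5% and
#' 97.5% quantile band of the replicate curves.
#'
#' @param hits Hit-count matrix (genes x populations).
#' @param gene_models data.frame with `gene`, `target_size`, and `aa_length`
#'   (amino-acid length; needed for the site-level curve).
#' @param site_hits Optional data.frame (`gene`, `population`, `aa_pos`) of
#'   per-hit amino-acid positions; if NULL the site-level curve is skipped.
#' @param null_matrices Optional pre-computed null ensemble (from
#'   [simulate_null_hits()]); generated if NULL.
#' @param n_reps Null replicates when generating (default 1000).
#' @param n_site_reps Position-randomization replicates (default 10).
#' @param seed Integer seed.
#' @return List of data.frames `multiplicity`, `populations_hit` and
#'   (optionally) `sites`, each with columns `grid`, `observed`, `null_lo`,
#'   `null_hi`, `null_mean`.
#' @export
parallelism_survival <- function(hits, gene_models, site_hits = NULL,
                                 null_matrices = NULL, n_reps = 1000L,
                                 n_site_reps = 10L, seed = 1L) {
  mg <- colSums(hits)
  if (is.null(null_matrices))
    null_matrices <- simulate_null_hits(mg, gene_models, n_reps, seed)
  genes_all <- gene_models$gene

  expand <- function(h) {       # hits over the full gene universe
    out <- matrix(0L, length(genes_all), ncol(h),
                  dimnames = list(genes_all, colnames(h)))
    out[rownames(h), ] <- h
    out
  }
  obs_full <- expand(hits)

  band <- function(obs_vals, null_vals_list, grid) {
    nullc <- vapply(null_vals_list, survival_curve, numeric(length(grid)),
                    grid = grid)
    data.frame(grid = grid, observed = survival_curve(obs_vals, grid),
               null_lo = apply(nullc, 1, stats::quantile, 0.025),
               null_hi = apply(nullc, 1, stats::quantile, 0.975),
               null_mean = rowMeans(nullc))
  }

  mult_obs <- gene_multiplicity(rowSums(obs_full), gene_models)
  mult_null <- lapply(null_matrices, function(h)
    gene_multiplicity(rowSums(h), gene_models))
  mgrid <- seq(0, max(c(mult_obs, unlist(mult_null))) + 1, length.out = 50)

  ph_obs <- rowSums(obs_full > 0)
  ph_null <- lapply(null_matrices, function(h) rowSums(h > 0))
  pgrid <- 0:max(c(ph_obs, unlist(ph_null)))

  out <- list(multiplicity = band(mult_obs, mult_null, mgrid),
              populations_hit = band(ph_obs, ph_null, pgrid))

  if (!is.null(site_hits)) {
    set.seed(seed + 1L)
    len <- stats::setNames(gene_models$aa_length, gene_models$gene)
    site_counts <- function(df) {
      key <- paste(df$gene, df$aa_pos)
      pops_per_site <- tapply(df$population, key,
                              function(p) length(unique(p)))
      total_sites <- sum(len[unique(df$gene)])
      ## sites never hit contribute zeros to the fraction
      c(as.numeric(pops_per_site),
        rep(0, max(0, total_sites - length(pops_per_site))))
    }
    obs_sites <- site_counts(site_hits)
    null_sites <- lapply(seq_len(n_site_reps), function(r) {
      df <- site_hits
      df$aa_pos <- vapply(df$gene, function(g)
        sample.int(len[[g]], 1L), 1L)
      site_counts(df)
    })
    sgrid <- 1:max(c(obs_sites, unlist(null_sites)))
    out$sites <- band(obs_sites, null_sites, sgrid)
  }
  out
}

#' Multi-hit genes
#'
#' Genes with fixed nonsynonymous hits in at least `population_threshold`
#' distinct populations. Multiple hits within one population count once.
#'
#' @param hits Hit-count matrix (genes x populations).
#' @param population_threshold Minimum number of distinct populations
#'   (default 6).
#' @return Character vector of multi-hit gene names.
#' @export
multi_hit_genes <- function(hits, population_threshold = 6L) {
  rownames(hits)[rowSums(hits > 0) >= population_threshold]
}
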