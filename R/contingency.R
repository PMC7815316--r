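## Strain/environment contingency statistics over a gene hit matrix.
##
## Throughout, the data are a genes x populations matrix of fixed
## nonsynonymous hits plus population metadata (strain background and
## evolution environment). Probability models treat within-population double
## hits as single hits (indicators h_gi).

#' Probability a gene is hit in a population under the shared-pool model
#'
#' Each of a population's `M_g` gene hits lands in gene i with probability
#' `Ntilde_i / M`, where `Ntilde_i` is the number of populations with a
#' fixed mutation in gene i plus a 0.1 pseudocount and `M` is the total
#' number of gene hits across populations in the set. The probability that
#' gene i is hit at least once is therefore
#' `1 - (1 - Ntilde_i / M)^M_g`.
#'
#' @param n_tilde Pseudocounted population-hit count(s) `Ntilde_i` (> 0).
#' @param M Total gene hits in the population set.
#' @param M_g Number of gene hits in the focal population (>= 0).
#' @return Hit probability in `[0, 1]`.
#' @export
hit_probability <- function(n_tilde, M, M_g) {
  if (any(n_tilde > M)) stop("n_tilde must not exceed M")
  if (any(M_g < 0)) stop("M_g must be >= 0")
  1 - (1 - n_tilde / M)^M_g
}

## Partition factors over populations for the four enrichment models.
enrichment_partitions <- function(metadata) {
  list(all = factor(rep("all", nrow(metadata))),
       S = factor(metadata$strain),
       E = factor(metadata$environment),
       SxE = interaction(metadata$strain, metadata$environment, drop = TRUE))
}

## Per-gene Bernoulli log-likelihood under one partition, parameters
## re-estimated from the data itself. h: 0/1 genes x pops matrix.
partition_loglik <- function(h, part, pseudo = 0.1) {
  G <- nrow(h)
  ll <- numeric(G)
  for (cell in levels(part)) {
    cols <- which(part == cell)
    hc <- h[, cols, drop = FALSE]
    M <- sum(hc)
    Mg <- colSums(hc)
    if (M == 0) next                       # no hits: P = 0, h = 0, ll += 0
    n_tilde <- rowSums(hc) + pseudo
    base <- pmax(1 - n_tilde / M, 0)       # clamp: pseudocount can push past M
    P <- 1 - outer(base, Mg, `^`)
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    ll <- ll + rowSums(hc * log(P) + (1 - hc) * log(1 - P))
  }
  ll
}

## G x 4 log-likelihood matrix (models: all, S, E, SxE).
enrichment_logliks <- function(h, partitions, pseudo = 0.1) {
  vapply(partitions, partition_loglik, numeric(nrow(h)), h = h,
         pseudo = pseudo)
}

## Null log-likelihood-ratio ensembles under model 1, vectorized across
## datasets. Returns a list with G x n_null LLR matrices for S, E, SxE.
## Parameters (Ntilde, M, M_g) are re-estimated from each simulated dataset.
enrichment_null_llrs <- function(P1, parts, n_null, pseudo = 0.1) {
  G <- nrow(P1); P <- ncol(P1)
  hs <- array(stats::rbinom(G * P * n_null, 1L, rep(as.vector(P1), n_null)),
              dim = c(G, P, n_null))
  Mg_all <- colSums(hs)                    # P x n_null
  ll <- lapply(parts, function(part) {
    out <- matrix(0, G, n_null)
    for (cell in levels(part)) {
      cols <- which(part == cell)
      hc <- hs[, cols, , drop = FALSE]     # G x |c| x n
      Mgc <- Mg_all[cols, , drop = FALSE]  # |c| x n
      Mcell <- colSums(Mgc)                # n
      ntil <- colSums(aperm(hc, c(2, 1, 3))) + pseudo   # G x n
      base <- 1 - sweep(ntil, 2, pmax(Mcell, 1e-12), `/`)
      lb <- log(pmax(base, 0))             # -Inf where pseudocount overshoots
      for (p in seq_along(cols)) {
        Pm <- 1 - exp(sweep(lb, 2, Mgc[p, ], `*`))
        Pm[!is.finite(Pm)] <- 0            # M_g = 0 cells: hit impossible
        Pm <- pmin(pmax(Pm, 1e-12), 1 - 1e-12)
        hcp <- matrix(hc[, p, ], G, n_null)
        out <- out + hcp * log(Pm) + (1 - hcp) * log(1 - Pm)
      }
    }
    out
  })
  list(S = ll$S - ll$all, E = ll$E - ll$all, SxE = ll$SxE - ll$all)
}

#' Test multi-hit genes for strain and/or environment enrichment
#'
#' Compares four Bernoulli models of where a gene's hits fall: a single
#' shared hit probability (model 1), separate probabilities per strain
#' background (S), per environment (E), or per strain-environment
#' combination (SxE). For each gene, log-likelihood ratios of models S/E/SxE
#' against the shared model are compared to their empirical null
#' distributions from datasets simulated under model 1 (parameters re-fit to
#' each simulated dataset); p-values use the (r+1)/(n+1) convention and are
#' Benjamini-Hochberg corrected jointly across genes and the three model
#' comparisons. Among models significant at `alpha`, the lowest AIC
#' (2k - 2logL, k = number of partition cells) decides the gene's label.
#'
#' @param hits Hit-count matrix (genes x populations); counts are collapsed
#'   to 0/1 indicators. `M` and `M_g` are computed from this matrix, so it
#'   should contain the full hit complement of the populations analysed.
#' @param metadata data.frame with one row per population (in column order
#'   of `hits`): `population`, `strain`, `environment`.
#' @param genes Genes to test (default all rows with at least one hit).
#' @param n_null Number of model-1 null datasets (default 10000).
#' @param alpha Significance level after correction (default 0.05).
#' @param seed Integer seed.
#' @return data.frame with one row per tested gene: `gene`, observed LLRs,
#'   raw and BH-adjusted p-values for S/E/SxE, and the final `effect` label
#'   (`none`, `S`, `E` or `SxE`).
#' @export
enrichment_test <- function(hits, metadata, genes = NULL, n_null = 10000L,
                            alpha = 0.05, seed = 1L) {
  stopifnot(ncol(hits) == nrow(metadata))
  if (length(unique(metadata$strain)) < 2 ||
      length(unique(metadata$environment)) < 2)
    stop("need at least two strains and two environments")
  set.seed(seed)
  h <- (hits > 0) * 1L
  if (is.null(genes)) genes <- rownames(h)[rowSums(h) > 0]
  parts <- enrichment_partitions(metadata)
  gi <- match(genes, rownames(h))

  ll_obs <- enrichment_logliks(h, parts)[gi, , drop = FALSE]
  llr_obs <- ll_obs[, c("S", "E", "SxE"), drop = FALSE] - ll_obs[, "all"]

  ## model-1 probabilities from the observed data, per gene x population
  M1 <- sum(h); Mg1 <- colSums(h)
  base1 <- pmax(1 - (rowSums(h) + 0.1) / M1, 0)
  P1 <- 1 - outer(base1, Mg1, `^`)

  nll <- enrichment_null_llrs(P1, parts, n_null)   # list of G x n_null
  exceed <- vapply(c("S", "E", "SxE"), function(mod)
    rowSums(nll[[mod]][gi, , drop = FALSE] >= llr_obs[, mod]), numeric(length(gi)))
  if (length(gi) == 1L) exceed <- matrix(exceed, nrow = 1)
  dimnames(exceed) <- list(genes, c("S", "E", "SxE"))
  pval <- (exceed + 1) / (n_null + 1)
  padj <- matrix(stats::p.adjust(pval, method = "BH"), nrow = nrow(pval),
                 dimnames = dimnames(pval))

  k_cells <- vapply(parts, nlevels, 1L)    # AIC parameter counts
  aic <- sweep(-2 * ll_obs, 2, 2 * k_cells, `+`)
  effect <- vapply(seq_along(genes), function(i) {
    sig <- colnames(padj)[padj[i, ] < alpha]
    if (!length(sig)) return("none")
    sig[which.min(aic[i, sig])]
  }, "")

  data.frame(gene = genes,
             llr_S = llr_obs[, "S"], llr_E = llr_obs[, "E"],
             llr_SxE = llr_obs[, "SxE"],
             p_S = pval[, "S"], p_E = pval[, "E"], p_SxE = pval[, "SxE"],
             padj_S = padj[, "S"], padj_E = padj[, "E"],
             padj_SxE = padj[, "SxE"],
             effect = effect, stringsAsFactors = FALSE, row.names = NULL)
}

## Pseudocounted marginal hit probability per gene in one combo:
## P(h_i = 1 | e) = (n_i + N_e * eps) / (N_e * (1 + eps)).
mi_marginal <- function(n_i, N_e, eps) (n_i + N_e * eps) / (N_e * (1 + eps))

## MI matrix (bits) between gene indicator columns within one combo.
## Joint cells use the same pseudocount mass, placed on the (1,1) cell so
## joints remain consistent with the padded marginals.
combo_mi <- function(hc, eps) {
  G <- nrow(hc); Ne <- ncol(hc)
  n <- rowSums(hc)
  denom <- Ne * (1 + eps)
  C11 <- hc %*% t(hc)
  P11 <- (C11 + Ne * eps) / denom
  P10 <- (matrix(n, G, G) - C11) / denom   # rows: n_i - c11
  P01 <- t(P10)
  P00 <- (Ne - outer(n, n, `+`) + C11) / denom
  p1 <- mi_marginal(n, Ne, eps)
  p0 <- 1 - p1
  term <- function(P, pr, pc) {
    t <- P * log2(P / outer(pr, pc))
    t[!is.finite(t) | P <= 0] <- 0
    t
  }
  mi <- term(P11, p1, p1) + term(P10, p1, p0) + term(P01, p0, p1) +
        term(P00, p0, p0)
  zero <- n == 0                           # zero rule: unhit gene in combo
  mi[zero, ] <- 0; mi[, zero] <- 0
  diag(mi) <- 0
  pmax(mi, 0)
}

#' Pairwise mutual information between multi-hit genes
#'
#' For each environment-strain combination, computes the mutual information
#' (in bits) between every pair of gene hit indicators, using
#' pseudocount-padded probabilities: the marginal
#' `P(h_i|e) = C_M * sum_g (M_gi + eps)` with `C_M = 1/(N_e (1 + eps))` and
#' `eps = scale / M`, and joints from co-occurrence counts padded and
#' normalized the same way. The MI of a pair is set to zero in any
#' combination where either gene has no hits, and pairs are summed across
#' combinations.
#'
#' @param hits Hit-count matrix (genes x populations; collapsed to 0/1).
#' @param metadata Population metadata (`strain`, `environment`), rows in
#'   column order of `hits`.
#' @param genes Genes to include (default all rows).
#' @param pseudocount_scale The product `eps * M` (default 1).
#' @return Symmetric MI matrix (bits), genes x genes, summed over combos.
#' @export
pairwise_mi <- function(hits, metadata, genes = NULL, pseudocount_scale = 1) {
  stopifnot(ncol(hits) == nrow(metadata))
  h <- (hits > 0) * 1L
  if (!is.null(genes)) h <- h[genes, , drop = FALSE]
  combos <- interaction(metadata$strain, metadata$environment, drop = TRUE)
  mi <- matrix(0, nrow(h), nrow(h), dimnames = list(rownames(h), rownames(h)))
  for (cb in levels(combos)) {
    hc <- h[, combos == cb, drop = FALSE]
    M <- sum(hc)
    if (M == 0) next
    eps <- pseudocount_scale / M
    mi <- mi + combo_mi(hc, eps)
  }
  mi
}

mi_summaries <- function(mi) {
  ut <- mi[upper.tri(mi)]
  c(MI_tot = sum(ut), MI_max = if (length(ut)) max(ut) else 0)
}

#' Null-simulation test of total and maximum mutual information
#'
#' Simulates `n_null` datasets in which every gene's hit indicator is drawn
#' independently from its combo-specific marginal `P(h_i|e)` (no gene-gene
#' dependence), recomputes `MI_tot` (sum over gene pairs) and `MI_max`, and
#' reports empirical upper-tail p-values with the (r+1)/(n+1) convention.
#'
#' @inheritParams pairwise_mi
#' @param n_null Number of null datasets (default 10000).
#' @param seed Integer seed.
#' @return List with `MI_tot`, `MI_max`, `p_tot`, `p_max`, and the null
#'   vectors `null_tot`, `null_max`.
#' @export
mi_null_test <- function(hits, metadata, genes = NULL, n_null = 10000L,
                         pseudocount_scale = 1, seed = 1L) {
  set.seed(seed)
  h <- (hits > 0) * 1L
  if (!is.null(genes)) h <- h[genes, , drop = FALSE]
  combos <- interaction(metadata$strain, metadata$environment, drop = TRUE)
  obs <- mi_summaries(pairwise_mi(h, metadata,
                                  pseudocount_scale = pseudocount_scale))
  ## combo-wise marginals from the observed data
  combo_idx <- lapply(levels(combos), function(cb) which(combos == cb))
  probs <- lapply(combo_idx, function(cols) {
    hc <- h[, cols, drop = FALSE]
    M <- sum(hc)
    if (M == 0) return(rep(0, nrow(h)))
    eps <- pseudocount_scale / M
    ## guard rounding: a gene hit in every population gives exactly 1
    pmin(pmax(mi_marginal(rowSums(hc), length(cols), eps), 0), 1)
  })
  null_tot <- numeric(n_null); null_max <- numeric(n_null)
  G <- nrow(h)
  ut <- upper.tri(matrix(0, G, G))
  for (r in seq_len(n_null)) {
    mi <- matrix(0, G, G)
    for (k in seq_along(combo_idx)) {
      ne <- length(combo_idx[[k]])
      hc <- matrix(stats::rbinom(G * ne, 1L, probs[[k]]), G, ne)
      M <- sum(hc)
      if (M == 0) next
      mi <- mi + combo_mi(hc, pseudocount_scale / M)
    }
    vals <- mi[ut]
    null_tot[r] <- sum(vals)
    null_max[r] <- if (length(vals)) max(vals) else 0
  }
  list(MI_tot = unname(obs["MI_tot"]), MI_max = unname(obs["MI_max"]),
       p_tot = (sum(null_tot >= obs["MI_tot"]) + 1) / (n_null + 1),
       p_max = (sum(null_max >= obs["MI_max"]) + 1) / (n_null + 1),
       null_tot = null_tot, null_max = null_max)
}

#' Robustness sweep of the MI test over the pseudocount
#'
#' Re-runs [mi_null_test()] for several values of the pseudocount product
#' `eps * M`.
#'
#' @inheritParams mi_null_test
#' @param scales Values of `eps * M` to test (default 0.1 to 2).
#' @return data.frame with `scale`, `MI_tot`, `p_tot`, `MI_max`, `p_max`.
#' @export
mi_pseudocount_sweep <- function(hits, metadata, genes = NULL,
                                 scales = c(0.1, 0.5, 1, 2),
                                 n_null = 1000L, seed = 1L) {
  rows <- lapply(seq_along(scales), function(i) {
    r <- mi_null_test(hits, metadata, genes = genes, n_null = n_null,
                      pseudocount_scale = scales[i], seed = seed + i)
    data.frame(scale = scales[i], MI_tot = r$MI_tot, p_tot = r$p_tot,
               MI_max = r$MI_max, p_max = r$p_max)
  })
  do.call(rbind, rows)
}

#' Over-/under-dispersion of hits across populations
#'
#' For one set of populations (typically an environment-strain combination),
#' compares how each gene's hits are spread across populations to multinomial
#' redistribution weighted by each population's total hits. For every
#' observed per-gene hit count n, the simulated distribution of the number
#' of distinct populations hit is built from `n_sims` draws; the \emph{excess
#' probability} is the observed minus simulated probability of each (n,
#' populations-hit) cell. The \emph{missed opportunities} statistic is
#' `sum_genes (hits - distinct populations hit)`; its null distribution is
#' built by redistributing every gene's hits, and the one-sided p-value asks
#' whether the data show fewer missed opportunities (over-dispersion) than
#' the null.
#'
#' @param counts Hit-count matrix (genes x populations) for one population
#'   set; true counts, not indicators.
#' @param n_sims Simulations per hit count (default 10000).
#' @param seed Integer seed.
#' @return List with `table` (data.frame: `n_hits`, `populations_hit`,
#'   `observed`, `simulated`, `excess`), `missed_obs`, `missed_null`
#'   (vector), `p_missed`.
#' @export
dispersion_analysis <- function(counts, n_sims = 10000L, seed = 1L) {
  set.seed(seed)
  gene_hits <- rowSums(counts)
  keep <- gene_hits > 0
  if (!any(keep)) stop("need at least one gene with at least one hit")
  counts <- counts[keep, , drop = FALSE]
  gene_hits <- gene_hits[keep]
  P <- ncol(counts)
  w <- colSums(counts)
  if (sum(w) == 0) stop("no hits")
  w <- w / sum(w)

  max_n <- max(gene_hits)
  sim_pops <- vector("list", max_n)        # distinct-populations draws per n
  for (n in seq_len(max_n)) {
    draws <- stats::rmultinom(n_sims, n, w)
    sim_pops[[n]] <- colSums(draws > 0)
  }

  rows <- list()
  for (n in sort(unique(gene_hits))) {
    obs_p <- rowSums(counts[gene_hits == n, , drop = FALSE] > 0)
    for (p in seq_len(min(n, P))) {
      rows[[length(rows) + 1]] <- data.frame(
        n_hits = n, populations_hit = p,
        observed = mean(obs_p == p),
        simulated = mean(sim_pops[[n]] == p))
    }
  }
  tab <- do.call(rbind, rows)
  tab$excess <- tab$observed - tab$simulated

  obs_pops <- rowSums(counts > 0)
  missed_obs <- sum(gene_hits - obs_pops)
  missed_null <- rep(0, n_sims)
  for (g in seq_along(gene_hits)) {
    n <- gene_hits[g]
    missed_null <- missed_null + (n - sample(sim_pops[[n]], n_sims,
                                             replace = TRUE))
  }
  p_missed <- (sum(missed_null <= missed_obs) + 1) / (n_sims + 1)
  list(table = tab, missed_obs = missed_obs, missed_null = missed_null,
       p_missed = p_missed)
}
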