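## Mutation calling from time-series allele counts.
##
## The substrate is an allele-count table: one row per
## (population, variant, timepoint) with reference and alternate read
## counts, as extracted from per-sample allele depths upstream.

variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

check_count_table <- function(table) {
  need <- c("population", "chrom", "pos", "ref", "alt", "timepoint",
            "ref_reads", "alt_reads")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("allele-count table missing columns: ", paste(miss, collapse = ", "))
  if (any(table$ref_reads < 0) || any(table$alt_reads < 0))
    stop("read counts must be non-negative")
  invisible(table)
}

#' Filter credible variants for one population
#'
#' Screens sequencing/alignment errors out of a population's variant list
#' using read support across timepoints and across populations. A variant is
#' kept iff its total alternate reads across all timepoints in the focal
#' population is at least `min_alt_reads`, AND it passes at least one of:
#' \itemize{
#'   \item the focal population's all-timepoint alternate total exceeds 90%
#'     of the alternate total across \emph{all} populations and all
#'     timepoints (the variant is essentially unique to this population); or
#'   \item at least two timepoints have >= `min_alt_reads` alternate reads in
#'     the focal population AND the focal all-timepoint alternate total
#'     exceeds 90% of the alternate total across all populations at the
#'     first sequenced timepoint only (a more lenient criterion that leaves
#'     room for nucleotide-level parallelism between populations).
#' }
#'
#' @param table Allele-count table covering all sequenced populations.
#' @param population Focal population id.
#' @param min_alt_reads Minimum alternate-read support (default 5).
#' @param frac Cross-population dominance fraction (default 0.9).
#' @return data.frame of kept variants (`chrom`, `pos`, `ref`, `alt`),
#'   sorted by chromosome and position.
#' @export
filter_population_variants <- function(table, population, min_alt_reads = 5L,
                                       frac = 0.9) {
  check_count_table(table)
  if (!population %in% table$population)
    stop("unknown population: ", population)
  key_all <- variant_key(table)
  first_tp <- min(table$timepoint)

  tot_all <- tapply(table$alt_reads, key_all, sum)            # all pops, all tps
  t1 <- table[table$timepoint == first_tp, , drop = FALSE]
  tot_t1 <- tapply(t1$alt_reads, variant_key(t1), sum)        # all pops, first tp

  foc <- table[table$population == population, , drop = FALSE]
  key_foc <- variant_key(foc)
  foc_tot <- tapply(foc$alt_reads, key_foc, sum)
  foc_ntp_ge <- tapply(foc$alt_reads >= min_alt_reads, key_foc, sum)

  keys <- names(foc_tot)
  tot_all_k <- as.numeric(tot_all[keys])
  tot_t1_k <- as.numeric(tot_t1[keys]); tot_t1_k[is.na(tot_t1_k)] <- 0
  c0 <- as.numeric(foc_tot) >= min_alt_reads
  c1 <- as.numeric(foc_tot) > frac * tot_all_k
  c2 <- as.numeric(foc_ntp_ge) >= 2 & as.numeric(foc_tot) > frac * tot_t1_k
  keep <- keys[c0 & (c1 | c2)]

  vars <- unique(foc[key_foc %in% keep,
                     c("chrom", "pos", "ref", "alt"), drop = FALSE])
  vars <- vars[order(vars$chrom, vars$pos, vars$ref, vars$alt), , drop = FALSE]
  rownames(vars) <- NULL
  vars
}

#' Group linked variants into mutation groups
#'
#' Nearby variants that arose as a single mutational event have
#' indistinguishable allele-count trajectories. For every pair of variants on
#' the same chromosome within `window` bp, Fisher's exact test is applied to
#' the 2x2 table of (alt, ref) counts at each timepoint; the pair is linked
#' iff no timepoint rejects at `alpha`. Groups are the transitive closure of
#' linked pairs and are counted as one mutation downstream.
#'
#' @param table Allele-count table (any populations; only the focal one is
#'   used).
#' @param population Focal population id.
#' @param variants data.frame of variants to group (e.g. from
#'   [filter_population_variants()]); default all variants of the population.
#' @param window Maximum pairing distance in bp (default 25).
#' @param alpha Per-timepoint Fisher significance threshold (default 0.01).
#' @return `variants` with an added integer `group` column; groups are
#'   numbered in chromosome/position order.
#' @export
group_linked_variants <- function(table, population, variants = NULL,
                                  window = 25L, alpha = 0.01) {
  check_count_table(table)
  foc <- table[table$population == population, , drop = FALSE]
  if (is.null(variants))
    variants <- unique(foc[, c("chrom", "pos", "ref", "alt"), drop = FALSE])
  variants <- variants[order(variants$chrom, variants$pos, variants$ref,
                             variants$alt), , drop = FALSE]
  rownames(variants) <- NULL
  n <- nrow(variants)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  vkey <- variant_key(variants)
  tps <- sort(unique(foc$timepoint))
  foc_key <- variant_key(foc)
  counts_of <- function(key) {
    rows <- foc[foc_key == key, , drop = FALSE]
    alt <- rep(0L, length(tps)); ref <- rep(0L, length(tps))
    idx <- match(rows$timepoint, tps)
    alt[idx] <- rows$alt_reads; ref[idx] <- rows$ref_reads
    cbind(alt = alt, ref = ref)
  }
  if (n > 1) {
    ## only variants with a candidate partner need count vectors
    cache <- vector("list", n)
    for (i in seq_len(n - 1)) {
      j <- i + 1
      while (j <= n && variants$chrom[j] == variants$chrom[i] &&
             variants$pos[j] - variants$pos[i] <= window) {
        if (is.null(cache[[i]])) cache[[i]] <- counts_of(vkey[i])
        if (is.null(cache[[j]])) cache[[j]] <- counts_of(vkey[j])
        j <- j + 1
      }
    }
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (variants$chrom[j] != variants$chrom[i]) break
        if (variants$pos[j] - variants$pos[i] > window) break
        ci <- cache[[i]]; cj <- cache[[j]]
        linked <- TRUE
        for (k in seq_along(tps)) {
          tab <- matrix(c(ci[k, "alt"], ci[k, "ref"],
                          cj[k, "alt"], cj[k, "ref"]), nrow = 2)
          if (sum(tab) == 0) next
          p <- stats::fisher.test(tab)$p.value
          if (p < alpha) { linked <- FALSE; break }
        }
        if (linked) union_(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  variants$group <- match(roots, sort(unique(roots)))
  variants
}

#' Call presence, fixation and loss of heterozygosity over time
#'
#' Applies the frequency-threshold rules for whole-population time series.
#' A mutation is \emph{present} at a timepoint if coverage is at least
#' `min_cov` and frequency at least 0.1. It is \emph{fixed} at a timepoint if
#' coverage is at least `min_cov`, frequency is at least the ploidy threshold
#' (0.9 haploid, 0.4 diploid), and the frequency does not drop below the
#' threshold at any later timepoint that has `min_cov` coverage. Once fixed,
#' a mutation stays fixed at all later timepoints regardless of coverage.
#' In diploids, loss of heterozygosity is called with the same rules at the
#' 0.9 threshold, so an LOH call always implies fixation.
#'
#' @param counts data.frame with columns `timepoint`, `ref_reads`,
#'   `alt_reads` for one mutation group (members already summed).
#' @param ploidy `"haploid"` or `"diploid"`.
#' @param min_cov Minimum coverage for a usable timepoint (default 5).
#' @return data.frame of class `"call_timeline"`: `timepoint`, `coverage`,
#'   `frequency` (NA where coverage is 0), `present`, `fixed`, `loh`.
#' @export
call_timeline <- function(counts, ploidy = c("haploid", "diploid"),
                          min_cov = 5L) {
  ploidy <- match.arg(ploidy)
  counts <- counts[order(counts$timepoint), , drop = FALSE]
  cov <- counts$ref_reads + counts$alt_reads
  freq <- ifelse(cov > 0, counts$alt_reads / cov, NA_real_)
  usable <- cov >= min_cov & !is.na(freq)
  theta <- if (ploidy == "haploid") 0.9 else 0.4
  fix_from <- function(th) {
    n <- length(freq)
    raw <- logical(n)
    for (t in seq_len(n)) {
      if (!usable[t] || freq[t] < th) next
      later <- which(usable & seq_len(n) > t)
      raw[t] <- all(freq[later] >= th)
    }
    cummax(raw) == 1          # sticky: once fixed, always fixed
  }
  fixed <- fix_from(theta)
  loh <- if (ploidy == "diploid") fix_from(0.9) else rep(FALSE, length(freq))
  out <- data.frame(timepoint = counts$timepoint, coverage = cov,
                    frequency = freq,
                    present = usable & !is.na(freq) & freq >= 0.1,
                    fixed = fixed, loh = loh)
  class(out) <- c("call_timeline", "data.frame")
  out
}

#' Classify a mutation's effect from its annotations
#'
#' Collapses one or more effect annotations to a single mutation type using
#' the fixed precedence order (decreasing putative effect): indel, nonsense,
#' missense, synonymous, noncoding.
#'
#' @param annotations Character vector of effect labels.
#' @return The single highest-precedence type present.
#' @export
classify_mutation_type <- function(annotations) {
  precedence <- c("indel", "nonsense", "missense", "synonymous", "noncoding")
  if (!length(annotations)) stop("need at least one annotation")
  bad <- setdiff(annotations, precedence)
  if (length(bad))
    stop("unrecognized annotation label(s): ", paste(bad, collapse = ", "))
  precedence[min(match(annotations, precedence))]
}

#' Remove calls in excluded regions
#'
#' Drops calls whose position falls in a masked interval (e.g. telomeres or
#' an unstable extrachromosomal element). Masks are half-open
#' `[start, end)` in the same coordinate system as the call positions, so a
#' call at `pos == end` is retained.
#'
#' @param calls data.frame with `chrom` and `pos` columns.
#' @param mask data.frame with `chrom`, `start`, `end` columns (may be empty
#'   or NULL).
#' @return `calls` with masked rows removed.
#' @export
apply_region_exclusions <- function(calls, mask = NULL) {
  if (is.null(mask) || nrow(mask) == 0) return(calls)
  drop <- rep(FALSE, nrow(calls))
  for (r in seq_len(nrow(mask))) {
    drop <- drop | (calls$chrom == mask$chrom[r] &
                    calls$pos >= mask$start[r] & calls$pos < mask$end[r])
  }
  calls[!drop, , drop = FALSE]
}

#' Call all mutations in one population
#'
#' Convenience wrapper running the full per-population calling path:
#' variant filtering, linkage grouping, region exclusion and timeline
#' calling. Member variants of a group are summed per timepoint before
#' frequencies are computed.
#'
#' @inheritParams filter_population_variants
#' @inheritParams call_timeline
#' @param mask Optional exclusion mask (see [apply_region_exclusions()]).
#' @param annotations Optional data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `annotation`) used to assign each group a mutation type by precedence.
#' @param window,alpha Linkage-grouping parameters.
#' @return List with `groups` (data.frame: group, chrom, pos = representative
#'   position, n_members, type), `members` (the grouped variant table with
#'   its `group` column) and `timelines` (list of [call_timeline()] frames
#'   indexed by group).
#' @export
call_population <- function(table, population,
                            ploidy = c("haploid", "diploid"),
                            mask = NULL, annotations = NULL,
                            min_alt_reads = 5L, window = 25L, alpha = 0.01,
                            min_cov = 5L) {
  ploidy <- match.arg(ploidy)
  vars <- filter_population_variants(table, population,
                                     min_alt_reads = min_alt_reads)
  vars <- apply_region_exclusions(vars, mask)
  if (nrow(vars) == 0)
    return(list(groups = data.frame(group = integer(0), chrom = character(0),
                                    pos = integer(0), n_members = integer(0),
                                    type = character(0)),
                members = vars, timelines = list()))
  grouped <- group_linked_variants(table, population, vars,
                                   window = window, alpha = alpha)
  foc <- table[table$population == population, , drop = FALSE]
  foc_key <- variant_key(foc)
  tps <- sort(unique(foc$timepoint))
  ann_key <- if (!is.null(annotations)) variant_key(annotations) else NULL

  ## aggregate member counts per (group, timepoint) in one pass
  mem_key <- variant_key(grouped)
  row_group <- grouped$group[match(foc_key, mem_key)]
  sub <- foc[!is.na(row_group), , drop = FALSE]
  rg <- row_group[!is.na(row_group)]
  gids <- sort(unique(grouped$group))
  gf <- factor(rg, levels = gids)
  tf <- factor(sub$timepoint, levels = tps)
  alt_m <- tapply(sub$alt_reads, list(gf, tf), sum)
  ref_m <- tapply(sub$ref_reads, list(gf, tf), sum)
  alt_m[is.na(alt_m)] <- 0; ref_m[is.na(ref_m)] <- 0

  timelines <- vector("list", length(gids))
  ginfo <- vector("list", length(gids))
  for (gi in seq_along(gids)) {
    members <- grouped[grouped$group == gids[gi], , drop = FALSE]
    cts <- data.frame(timepoint = tps, ref_reads = as.integer(ref_m[gi, ]),
                      alt_reads = as.integer(alt_m[gi, ]))
    timelines[[gi]] <- call_timeline(cts, ploidy, min_cov = min_cov)
    type <- NA_character_
    if (!is.null(annotations)) {
      ann <- annotations$annotation[ann_key %in% variant_key(members)]
      if (length(ann)) type <- classify_mutation_type(ann)
    }
    ginfo[[gi]] <- data.frame(group = gi, chrom = members$chrom[1],
                              pos = members$pos[1],
                              n_members = nrow(members), type = type,
                              stringsAsFactors = FALSE)
  }
  list(groups = do.call(rbind, ginfo), members = grouped,
       timelines = timelines)
}

#' Count fixed mutations over time with low-coverage masking
#'
#' @param timelines List of [call_timeline()] frames (one per mutation
#'   group).
#' @param mean_coverage Numeric vector of average sample coverage per
#'   timepoint.
#' @param ploidy `"haploid"` or `"diploid"`; timepoints with average coverage
#'   below 10 (haploid) or 20 (diploid) are flagged `masked`.
#' @return data.frame: `timepoint`, `n_fixed` (cumulative count of groups
#'   fixed by that timepoint), `masked`.
#' @export
count_fixed_trajectory <- function(timelines, mean_coverage,
                                   ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  floor_cov <- if (ploidy == "haploid") 10 else 20
  if (!length(timelines)) {
    tps <- seq_along(mean_coverage)
    return(data.frame(timepoint = tps, n_fixed = 0L,
                      masked = mean_coverage < floor_cov))
  }
  tps <- timelines[[1]]$timepoint
  n_fixed <- rowSums(vapply(timelines, function(tl) tl$fixed,
                            logical(length(tps))))
  data.frame(timepoint = tps, n_fixed = as.integer(n_fixed),
             masked = mean_coverage < floor_cov)
}

#' Scaled dN/dS for fixed mutations
#'
#' Ratio of nonsynonymous (missense + nonsense) to synonymous fixations by
#' the final timepoint, scaled by the genome-wide ratio of possible
#' nonsynonymous to synonymous mutations, so that purely opportunity-driven
#' fixation gives a value of 1.
#'
#' @param types Character vector of mutation types of fixed mutations
#'   (indel/nonsense/missense/synonymous/noncoding); indels and noncoding
#'   changes do not enter the ratio.
#' @param opportunity_ratio Possible nonsynonymous / possible synonymous
#'   mutations genome-wide (> 0).
#' @return List with `dnds` (NA when undefined), `n_fixed`, `s_fixed`,
#'   `undefined` flag.
#' @export
compute_dnds <- function(types, opportunity_ratio) {
  if (opportunity_ratio <= 0) stop("opportunity_ratio must be > 0")
  n_fixed <- sum(types %in% c("missense", "nonsense"))
  s_fixed <- sum(types == "synonymous")
  if (s_fixed == 0)
    return(list(dnds = NA_real_, n_fixed = n_fixed, s_fixed = 0L,
                undefined = TRUE))
  list(dnds = (n_fixed / s_fixed) / opportunity_ratio,
       n_fixed = n_fixed, s_fixed = s_fixed, undefined = FALSE)
}
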