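test_that("variant filtering applies the read-support criteria", {
  ## 4 total alt reads: excluded outright
  t1 <- variant_rows("popA", 100L, alt_reads = c(2L, 2L, 0L),
                     ref_reads = c(20L, 20L, 20L))
  expect_equal(nrow(filter_population_variants(t1, "popA")), 0)

  ## all 20 alt reads in one population: unique, kept via criterion 1
  t2 <- rbind(variant_rows("popA", 100L, c(10L, 10L, 0L), c(10L, 10L, 20L)),
              variant_rows("popB", 100L, c(0L, 0L, 0L), c(20L, 20L, 20L)))
  expect_equal(nrow(filter_population_variants(t2, "popA")), 1)

  ## split 30/30 between two populations: fails criterion 1 (30 <= 0.9*60)
  ## but passes criterion 2 (two timepoints >= 5 alt; first-timepoint
  ## all-population total is 10, and 30 > 0.9*10)
  t3 <- rbind(variant_rows("popA", 100L, c(5L, 25L), c(20L, 0L)),
              variant_rows("popB", 100L, c(5L, 25L), c(20L, 0L)))
  expect_equal(nrow(filter_population_variants(t3, "popA")), 1)

  ## same split but only one timepoint with >= 5 alt reads: excluded
  t4 <- rbind(variant_rows("popA", 100L, c(4L, 26L), c(20L, 0L)),
              variant_rows("popB", 100L, c(4L, 26L), c(20L, 0L)))
  expect_equal(nrow(filter_population_variants(t4, "popA")), 0)

  expect_error(filter_population_variants(t1, "nope"), "unknown population")
})

test_that("linkage grouping joins indistinguishable nearby variants", {
  base <- function(pos, alt, ref, alt2 = "T") {
    variant_rows("p", pos, alt, ref, alt = alt2)
  }
  ## identical counts 10 bp apart: all Fisher p = 1, grouped
  tab <- rbind(base(100L, c(10L, 12L), c(10L, 8L)),
               base(110L, c(10L, 12L), c(10L, 8L), alt2 = "G"))
  g <- group_linked_variants(tab, "p")
  expect_equal(length(unique(g$group)), 1)

  ## 30 bp apart: never tested, never grouped
  tab2 <- rbind(base(100L, c(10L, 12L), c(10L, 8L)),
                base(130L, c(10L, 12L), c(10L, 8L), alt2 = "G"))
  g2 <- group_linked_variants(tab2, "p")
  expect_equal(length(unique(g2$group)), 2)

  ## opposite counts at one timepoint: Fisher p ~ 7.3e-12 < 0.01, split
  expect_lt(fisher.test(matrix(c(20L, 0L, 0L, 20L), 2))$p.value, 0.01)
  tab3 <- rbind(base(100L, c(20L, 10L), c(0L, 10L)),
                base(110L, c(0L, 10L), c(20L, 10L), alt2 = "G"))
  g3 <- group_linked_variants(tab3, "p")
  expect_equal(length(unique(g3$group)), 2)
})

test_that("grouping is transitive and order-invariant", {
  mk <- function(pos, alt2) variant_rows("p", pos, c(8L, 9L), c(12L, 11L),
                                         alt = alt2)
  tab <- rbind(mk(100L, "T"), mk(120L, "G"), mk(140L, "C"))
  ## A-B and B-C within 25 bp, A-C not; equivalence class merges all three
  g <- group_linked_variants(tab, "p")
  expect_equal(length(unique(g$group)), 1)

  vars <- unique(tab[, c("chrom", "pos", "ref", "alt")])
  g_fwd <- group_linked_variants(tab, "p", vars)
  g_rev <- group_linked_variants(tab, "p", vars[rev(seq_len(nrow(vars))), ])
  expect_equal(g_fwd[order(g_fwd$pos), "group"],
               g_rev[order(g_rev$pos), "group"])
})

test_that("fixation calls follow the threshold-and-later-timepoints rule", {
  mk_counts <- function(freq, cov) {
    data.frame(timepoint = seq_along(freq),
               ref_reads = as.integer(round(cov * (1 - freq))),
               alt_reads = as.integer(round(cov * freq)))
  }
  ## haploid: crosses 0.9 at t3 and stays
  tl <- call_timeline(mk_counts(c(0, 0.5, 0.95, 1), 20), "haploid")
  expect_equal(tl$fixed, c(FALSE, FALSE, TRUE, TRUE))

  ## diploid heterozygous fixation at 40%, never LOH
  tl2 <- call_timeline(mk_counts(c(0.45, 0.5, 0.55), 40), "diploid")
  expect_equal(tl2$fixed, c(TRUE, TRUE, TRUE))
  expect_equal(tl2$loh, c(FALSE, FALSE, FALSE))

  ## haploid with an intermediate drop: not fixed until the drop is past
  tl3 <- call_timeline(mk_counts(c(0.95, 0.30, 0.92), 20), "haploid")
  expect_equal(tl3$fixed, c(FALSE, FALSE, TRUE))

  ## once fixed, fixed at later low-coverage timepoints too
  cts <- mk_counts(c(0.95, 0.96, 0), c(20, 20, 0))
  cts$ref_reads[3] <- 0L; cts$alt_reads[3] <- 0L
  tl4 <- call_timeline(cts, "haploid")
  expect_equal(tl4$fixed, c(TRUE, TRUE, TRUE))
  expect_true(is.na(tl4$frequency[3]))     # 0/0 treated as missing

  expect_error(call_timeline(mk_counts(0.5, 20), "triploid"))
})

test_that("fixed flags are monotone and LOH implies fixation", {
  set.seed(33)
  for (i in 1:200) {
    n_tp <- sample(3:6, 1)
    cov <- sample(0:40, n_tp, replace = TRUE)
    alt <- vapply(cov, function(cc) if (cc == 0) 0L
                  else as.integer(rbinom(1, cc, runif(1))), 1L)
    cts <- data.frame(timepoint = seq_len(n_tp), ref_reads = cov - alt,
                      alt_reads = alt)
    for (pl in c("haploid", "diploid")) {
      tl <- call_timeline(cts, pl)
      expect_true(all(diff(tl$fixed) >= 0))
      expect_true(all(diff(tl$loh) >= 0))
      expect_true(all(!tl$loh | tl$fixed))
    }
  }
})

test_that("mutation types collapse by decreasing putative effect", {
  expect_equal(classify_mutation_type(c("missense", "synonymous")),
               "missense")
  expect_equal(classify_mutation_type("noncoding"), "noncoding")
  expect_equal(classify_mutation_type(c("indel", "nonsense", "missense")),
               "indel")
  expect_error(classify_mutation_type(character(0)), "at least one")
  expect_error(classify_mutation_type("frameshifty"), "unrecognized")
})

test_that("region exclusion masks are half-open on position", {
  calls <- data.frame(chrom = "chr1", pos = c(50L, 100L, 150L, 200L))
  expect_equal(apply_region_exclusions(calls, NULL), calls)
  mask <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  kept <- apply_region_exclusions(calls, mask)
  expect_equal(kept$pos, c(50L, 200L))     # pos == end retained (half-open)
})

test_that("fixed-count trajectories accumulate and mask low coverage", {
  empty <- count_fixed_trajectory(list(), mean_coverage = rep(30, 4),
                                  ploidy = "haploid")
  expect_equal(empty$n_fixed, rep(0L, 4))

  mk_tl <- function(fix_from, n_tp = 6) {
    data.frame(timepoint = 1:n_tp, coverage = 30, frequency = 1,
               present = TRUE, fixed = seq_len(n_tp) >= fix_from,
               loh = FALSE)
  }
  tls <- c(replicate(3, mk_tl(3), simplify = FALSE), list(mk_tl(5)))
  tr <- count_fixed_trajectory(tls, mean_coverage = c(30, 30, 30, 30, 9, 30),
                               ploidy = "haploid")
  expect_equal(tr$n_fixed, c(0L, 0L, 3L, 3L, 4L, 4L))
  expect_equal(tr$masked, c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  tr_d <- count_fixed_trajectory(tls, mean_coverage = rep(19, 6),
                                 ploidy = "diploid")
  expect_true(all(tr_d$masked))
})

test_that("dN/dS is opportunity-scaled and guards division by zero", {
  expect_equal(compute_dnds(c(rep("missense", 10), rep("synonymous", 10)),
                            1)$dnds, 1)
  und <- compute_dnds(rep("missense", 5), 2)
  expect_true(und$undefined)
  expect_true(is.na(und$dnds))

  ## fixations sampled proportional to opportunity recover dN/dS = 1
  set.seed(44)
  opp <- 3.2
  types <- sample(c("missense", "synonymous"), 10000, replace = TRUE,
                  prob = c(opp, 1))
  d <- compute_dnds(types, opp)
  p <- opp / (1 + opp)
  se_ratio <- (1 / opp) * (1 / (1 - p)^2) * sqrt(p * (1 - p) / 10000)
  expect_lt(abs(d$dnds - 1), 3 * se_ratio)
})

test_that("synthetic haploid populations are called with high fidelity", {
  cfg <- small_wf_config(seed = 61L)
  tr <- simulate_wf_population(cfg)
  tab <- sample_allele_counts(tr, population = "pop1", seed = 62L)
  res <- evopop:::score_calls_against_truth(tab, list(tr),
                                            ploidy = "haploid")
  if (res$summary$n_true_fixed > 0)
    expect_gte(res$summary$sensitivity, 0.99)
  expect_lte(res$summary$false_call_rate, 0.01)
})
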