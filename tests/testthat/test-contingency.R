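test_that("hit probability follows the shared-pool formula", {
  expect_equal(hit_probability(2.1, 10, 0), 0)
  expect_equal(hit_probability(10, 10, 3), 1)
  expect_equal(hit_probability(2.1, 10, 3), 1 - 0.79^3)
  expect_equal(hit_probability(2.1, 10, 3), 0.506961)
  expect_error(hit_probability(11, 10, 1), "exceed")
})

test_that("enrichment labelling is calibrated under the shared model", {
  md <- make_metadata(2L)                  # 18 populations
  set.seed(81)
  n_none <- 0; n_genes <- 0
  for (rep in 1:20) {
    h <- make_hits(8, md, p = 0.35, seed = 800 + rep)
    h <- h[rowSums(h) > 0, , drop = FALSE]
    et <- enrichment_test(h, md, n_null = 500L, seed = 900 + rep)
    n_none <- n_none + sum(et$effect == "none")
    n_genes <- n_genes + nrow(et)
  }
  expect_lte(1 - n_none / n_genes, 0.10)
})

test_that("a perfect strain effect is labelled S", {
  md <- make_metadata(4L)                  # 12 populations per strain
  set.seed(82)
  wins <- 0
  for (rep in 1:10) {
    h <- make_hits(8, md, p = 0.3, seed = 820 + rep)
    h <- rbind(h, planted = as.integer(md$strain == "MATa"))
    et <- enrichment_test(h, md, n_null = 1000L, seed = 840 + rep)
    wins <- wins + (et$effect[et$gene == "planted"] == "S")
  }
  expect_gte(wins, 8)
})

test_that("degenerate partitions are rejected", {
  md <- data.frame(population = c("a", "b"), strain = "MATa",
                   environment = "YPD30")
  h <- matrix(1L, 1, 2, dimnames = list("g1", md$population))
  expect_error(enrichment_test(h, md), "two strains")
})

test_that("mutual information obeys the zero rule and the 2x2 closed form", {
  md <- data.frame(population = paste0("p", 1:4), strain = "MATa",
                   environment = "YPD30")
  ## identical indicator columns over 4 populations, eps -> 0: MI -> 1 bit
  h <- rbind(g1 = c(1, 1, 0, 0), g2 = c(1, 1, 0, 0))
  colnames(h) <- md$population
  mi <- pairwise_mi(h, md, pseudocount_scale = 1e-8)
  expect_equal(mi["g1", "g2"], 1, tolerance = 1e-5)

  ## a gene with no hits in the combo zeroes all its pairs
  h0 <- rbind(g1 = c(1, 1, 0, 0), g2 = c(0, 0, 0, 0))
  colnames(h0) <- md$population
  mi0 <- pairwise_mi(h0, md)
  expect_equal(mi0["g1", "g2"], 0)

  ## independent columns, large N_e: MI near zero
  set.seed(83)
  md_big <- data.frame(population = paste0("p", 1:400), strain = "MATa",
                       environment = "YPD30")
  hb <- matrix(rbinom(2 * 400, 1, 0.4), 2,
               dimnames = list(c("g1", "g2"), md_big$population))
  mib <- pairwise_mi(hb, md_big, pseudocount_scale = 1e-8)
  expect_lt(mib["g1", "g2"], 0.02)
})

test_that("MI is symmetric, non-negative, and order-invariant", {
  md <- make_metadata(3L)
  h <- make_hits(6, md, p = 0.4, seed = 84)
  mi <- pairwise_mi(h, md)
  expect_true(all(mi >= 0))
  expect_equal(mi, t(mi))
  perm <- sample(ncol(h))
  mi_p <- pairwise_mi(h[, perm], md[perm, ])
  expect_equal(mi, mi_p)
})

test_that("planted perfect co-occurrence is detected by the MI null test", {
  md <- make_metadata(4L)
  set.seed(85)
  h <- make_hits(6, md, p = 0.3, seed = 86)
  shared <- rbinom(ncol(h), 1, 0.5)
  h <- rbind(h, ga = shared, gb = shared)
  r <- mi_null_test(h, md, n_null = 1000L, seed = 87)
  expect_lte(r$p_tot, 0.02)
  ## sweep over the pseudocount keeps the qualitative call (larger
  ## pseudocounts shrink MI toward the null, so the check covers the
  ## default and below)
  sw <- mi_pseudocount_sweep(h, md, scales = c(0.1, 0.5, 1, 2),
                             n_null = 300L, seed = 88)
  expect_equal(nrow(sw), 4)
  expect_true(all(sw$p_tot[sw$scale <= 1] < 0.05))
})

test_that("MI of a single population is degenerate zero", {
  md <- data.frame(population = "p1", strain = "MATa",
                   environment = "YPD30")
  h <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("g1", "g2"), "p1"))
  r <- mi_null_test(h, md, n_null = 50L, seed = 1L)
  expect_equal(r$MI_tot, 0, tolerance = 1e-9)
})

test_that("dispersion matches the equal-weight combinatorial closed form", {
  ## single-hit filler genes arranged so every population carries exactly
  ## two hits (equal weights); the pair gene's 2 hits then land in the same
  ## population with probability sum(w^2) = 1/12
  pops <- paste0("p", 1:12)
  filler_pops <- c(1, 2, rep(3:12, each = 2))
  cm <- matrix(0L, 23, 12, dimnames = list(c(paste0("s", 1:22), "pair"),
                                           pops))
  cm[cbind(1:22, filler_pops)] <- 1L
  cm["pair", 1:2] <- 1L
  stopifnot(all(colSums(cm) == 2))
  d <- dispersion_analysis(cm, n_sims = 20000L, seed = 91)
  sim_same <- d$table$simulated[d$table$n_hits == 2 &
                                d$table$populations_hit == 1]
  expect_lt(abs(sim_same - 1 / 12), 4 * sqrt((1 / 12) / 20000))

  ## single-hit genes always occupy one population with zero excess
  ones <- d$table[d$table$n_hits == 1, ]
  expect_equal(ones$observed, 1)
  expect_equal(ones$excess, 0, tolerance = 1e-12)
})

test_that("dispersion is calibrated on multinomial-generated data", {
  set.seed(92)
  P <- 12; G <- 3000
  w <- rep(1 / P, P)
  n_g <- sample(1:3, G, replace = TRUE)
  cm <- t(vapply(n_g, function(n) as.integer(rmultinom(1, n, w)),
                 integer(P)))
  dimnames(cm) <- list(paste0("g", 1:G), paste0("p", 1:P))
  d <- dispersion_analysis(cm, n_sims = 10000L, seed = 93)
  expect_lt(mean(abs(d$table$excess)), 0.01)
  expect_gt(d$p_missed, 0.01)             # no over-dispersion signal
})

test_that("missed opportunities detect planted over-dispersion", {
  ## every gene spreads its hits maximally: fewer missed opportunities
  ## than multinomial redistribution
  pops <- paste0("p", 1:12)
  cm <- matrix(0L, 40, 12, dimnames = list(paste0("g", 1:40), pops))
  for (g in 1:40) cm[g, sample(12, 3)] <- 1L
  d <- dispersion_analysis(cm, n_sims = 5000L, seed = 94)
  expect_equal(d$missed_obs, 0)
  expect_lt(d$p_missed, 0.05)
})
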