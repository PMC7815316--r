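test_that("experiment layout reproduces the three-environment design", {
  lay <- generate_experiment_layout(c(MATa = 45, MATalpha = 8, diploid = 37),
                                    c("YPD30", "SC30", "SC37"))
  expect_equal(nrow(lay), 270)
  expect_equal(sum(lay$ploidy == "diploid"), 3 * 37)
  expect_false(anyDuplicated(lay$population) > 0)

  one <- generate_experiment_layout(c(MATa = 1), "YPD30")
  expect_equal(nrow(one), 1)

  lost <- lay$population[1:65]
  lay2 <- generate_experiment_layout(c(MATa = 45, MATalpha = 8, diploid = 37),
                                     c("YPD30", "SC30", "SC37"), lost = lost)
  expect_equal(sum(lay2$active), 205)

  expect_error(generate_experiment_layout(integer(0), "YPD30"), "empty")
  expect_error(generate_experiment_layout(c(MATa = -1), "YPD30"))
})

test_that("Wright-Fisher simulator respects the no-mutation limit and bounds", {
  cfg <- sim_config(population_size = 100L, generations_total = 50L,
                    sequencing_timepoints = c(10L, 50L),
                    beneficial_rate = 0, neutral_rate = 0, seed = 3L)
  tr <- simulate_wf_population(cfg)
  expect_equal(nrow(tr$mutations), 0)

  cfg2 <- small_wf_config(seed = 5L)
  tr2 <- simulate_wf_population(cfg2)
  expect_true(all(tr2$frequency >= 0 & tr2$frequency <= 1))
  expect_true(all(tr2$het_fraction >= 0 & tr2$het_fraction <= 1))
})

test_that("seeded simulations are bit-reproducible", {
  cfg <- small_wf_config(seed = 9L)
  t1 <- simulate_wf_population(cfg)
  t2 <- simulate_wf_population(cfg)
  expect_identical(t1$frequency, t2$frequency)
  expect_identical(t1$mutations, t2$mutations)
  a1 <- sample_allele_counts(t1, seed = 4L)
  a2 <- sample_allele_counts(t2, seed = 4L)
  expect_identical(a1, a2)
})

test_that("mutations sharing a lineage share frequency trajectories", {
  tr <- simulate_wf_population(small_wf_config(seed = 21L))
  ## cohort = identical carrier set at every sequenced timepoint
  keys <- apply(tr$cohort_keys, 1, paste, collapse = "|")
  alive <- which(apply(tr$frequency, 1, max) > 0)
  dup <- split(alive, keys[alive])
  dup <- dup[lengths(dup) > 1]
  expect_gt(length(dup), 0)
  for (grp in dup) {
    ref <- tr$frequency[grp[1], ]
    for (m in grp[-1]) expect_equal(unname(tr$frequency[m, ]), unname(ref))
  }
})

test_that("neutral fixation probability is approximately 1/N", {
  set.seed(101)
  N <- 30L
  res <- wf_single_locus(N, s = 0, p0 = 1 / N, n_rep = 12000L)
  p_hat <- mean(res$fixed)
  se <- sqrt((1 / N) * (1 - 1 / N) / 12000)
  expect_lt(abs(p_hat - 1 / N), 3 * se)
})

test_that("established beneficial mutations sweep at the logistic rate", {
  set.seed(102)
  s <- 0.05
  res <- wf_single_locus(1e5, s = s, p0 = 0.01, n_rep = 60L)
  est <- res$fixed & !is.na(res$t10) & !is.na(res$t90)
  rise <- mean((res$t90 - res$t10)[est])
  expected <- (2 / s) * log(9)      # deterministic logistic 10% -> 90%
  expect_lt(abs(rise - expected) / expected, 0.10)
})

test_that("allele-count sampling is binomial in the true frequency", {
  tr1 <- make_truth(matrix(1, nrow = 5, ncol = 3))
  ac <- sample_allele_counts(tr1, coverage_mean = 30, seed = 2L)
  expect_true(all(ac$ref_reads == 0))      # frequency 1: alt = depth

  ac0 <- sample_allele_counts(tr1, coverage_mean = 0, seed = 2L)
  expect_true(all(ac0$ref_reads + ac0$alt_reads == 0))

  tr <- make_truth(matrix(0.5, nrow = 10000, ncol = 1))
  ach <- sample_allele_counts(tr, coverage_mean = 40, seed = 3L)
  depth <- ach$ref_reads + ach$alt_reads
  frac <- ach$alt_reads[depth > 0] / depth[depth > 0]
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.5), 3 * se)
})

test_that("planted CNV tracks have the stated mean structure", {
  flat <- plant_cnv_track(c(chr1 = 50L), NULL, n_timepoints = 1,
                          noise_sd = 0, seed = 1L)
  expect_equal(flat$tracks[[1]]$chr1, rep(1, 50))

  seg <- data.frame(chrom = "chr1", start = 11L, end = 30L, state = 2)
  noiseless <- plant_cnv_track(c(chr1 = 50L), seg, n_timepoints = 1,
                               noise_sd = 0, seed = 1L)
  expect_equal(noiseless$tracks[[1]]$chr1[11:30], rep(2, 20))
  expect_equal(noiseless$tracks[[1]]$chr1[1:10], rep(1, 10))

  seg2 <- data.frame(chrom = "chr1", start = 1L, end = 400L, state = 0.5)
  noisy <- plant_cnv_track(c(chr1 = 400L), seg2, n_timepoints = 1,
                           noise_sd = 0.1, seed = 2L)
  v <- noisy$tracks[[1]]$chr1
  se <- 0.1 * sqrt(0.5) / sqrt(400)
  expect_lt(abs(mean(v) - 0.5), 3 * se)

  bad <- data.frame(chrom = c("chr1", "chr1"), start = c(1L, 5L),
                    end = c(10L, 15L), state = c(2, 3))
  expect_error(plant_cnv_track(c(chr1 = 50L), bad), "conflicting")
  expect_error(plant_cnv_track(c(chr1 = 50L),
                               data.frame(chrom = "chr1", start = 1L,
                                          end = 10L, state = 2.5)),
               "state set")
})

test_that("hit-matrix simulation draws independent Bernoulli indicators", {
  z <- simulate_hit_matrix(rep(0, 5), n_populations = 4, seed = 1L)
  expect_true(all(z == 0))
  o <- simulate_hit_matrix(rep(1, 5), n_populations = 4, seed = 1L)
  expect_true(all(o == 1))
  h <- simulate_hit_matrix(rep(0.3, 10), n_populations = 10000, seed = 2L)
  se <- sqrt(0.3 * 0.7 / length(h))
  expect_lt(abs(mean(h) - 0.3), 3 * se)
  expect_error(simulate_hit_matrix(c(0.5, 1.2), n_populations = 2), "0, 1")
})

test_that("fluctuation cultures follow the Luria-Delbruck distribution", {
  ex0 <- simulate_luria_delbruck(0, 1e7, 100L, seed = 1L)
  expect_true(all(ex0$counts == 0))

  ex1 <- simulate_luria_delbruck(1, 1e7, 20000L, seed = 2L)
  p0_hat <- mean(ex1$counts == 0)
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 20000)
  expect_lt(abs(p0_hat - exp(-1)), 3 * se)

  ## class-by-class match to the MSS recursion at m = 0.5
  n <- 1e5
  ex <- simulate_luria_delbruck(0.5, 1e9, n, seed = 3L)
  p <- msr_pmf(0.5, 10)
  cls <- pmin(ex$counts, 11L)
  for (k in 0:10) {
    obs <- mean(cls == k)
    se_k <- sqrt(p[k + 1] * (1 - p[k + 1]) / n)
    expect_lt(abs(obs - p[k + 1]), 3 * se_k + 1e-12)
  }
})

test_that("fitness-assay simulation is noiseless-consistent", {
  flat <- simulate_fitness_assay(0, 10, events_per_read = Inf, seed = 1L)
  expect_equal(var(flat$true_ref_freq), 0)

  a <- simulate_fitness_assay(0.05, 10, events_per_read = Inf,
                              nonfluorescent_fraction = 0, seed = 1L)
  fit <- fitness_from_counts(a$fluorescent, a$nonfluorescent, a$generations,
                             nonfluorescent_fraction = 0)
  expect_equal(fit$fitness, 0.05, tolerance = 1e-4)
})
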