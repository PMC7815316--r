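test_that("HMM parameters are proper distributions", {
  p <- cnv_hmm_params(0.0225)
  expect_equal(sum(p$init), 1)
  expect_true(all(abs(rowSums(p$trans) - 1) < 1e-12))
  expect_equal(p$variances[p$states == 0], 0.5 * 0.0225)
  expect_equal(p$variances[p$states == 3], 3 * 0.0225)
})

test_that("windowing and standardization normalize scale and ancestry", {
  depth <- data.frame(chrom = "chr1", pos = 1:5000, depth = 30)
  w <- window_depth(depth)
  expect_equal(length(w$chr1), 10)
  expect_equal(w$chr1, rep(30, 10))

  tracks <- list(list(chr1 = rep(30, 40)), list(chr1 = rep(60, 40)))
  md <- data.frame(sample = c("s1", "s2"), population = "p",
                   timepoint = c(1, 2), strain = "MATa")
  sd_ <- standardize_depth(tracks, md)
  expect_equal(sd_$std[[1]]$chr1, rep(1, 40))
  expect_equal(sd_$std[[2]]$chr1, rep(1, 40))   # depth scale removed

  ## ancestral CNV: first-timepoint mean 2 normalizes later 2x to 1
  tr2 <- list(list(chr1 = c(rep(30, 30), rep(60, 10))),
              list(chr1 = c(rep(30, 30), rep(60, 10))))
  sd2 <- standardize_depth(tr2, md)
  expect_equal(sd2$std[[2]]$chr1[31:40], rep(1, 10))

  ## low first-timepoint relative depth is masked
  tr3 <- list(list(chr1 = c(rep(30, 38), 3, 30)),
              list(chr1 = rep(30, 40)))
  sd3 <- standardize_depth(tr3, md)
  expect_true(is.na(sd3$std[[2]]$chr1[39]))

  expect_error(standardize_depth(list(list(chr1 = rep(0, 10))),
                                 md[1, ]), "all-zero")
})

test_that("decoding recovers exact noiseless segment boundaries", {
  x <- rep(1, 100); x[41:80] <- 1.5
  st <- decode_states(list(chr1 = x), variance = 1e-4)$chr1
  expect_equal(st, c(rep(1, 40), rep(1.5, 40), rep(1, 20)))

  flat <- decode_states(list(chr1 = rep(1, 60)), variance = 1e-4)$chr1
  expect_equal(flat, rep(1, 60))
})

test_that("a single-window excursion is bridged when the transition cost wins", {
  ## two-path comparison at sd 0.15: flipping one window to state 2 costs
  ## two transitions (2 * ln(1e-4/0.9994) ~ -18.4 nats); at x = 1.8 the
  ## emission gain is ~13.4 nats, so the all-1 path wins
  v <- 0.15^2
  x <- rep(1, 50); x[25] <- 1.8
  gain <- dnorm(1.8, 2, sqrt(2 * v), log = TRUE) -
          dnorm(1.8, 1, sqrt(v), log = TRUE)
  penalty <- 2 * (log(1e-4) - log(1 - 6e-4))
  expect_lt(gain, -penalty)
  st <- decode_states(list(chr1 = x), variance = v)$chr1
  expect_equal(st[25], 1)
  expect_true(all(st == 1))
})

test_that("Viterbi equals the exhaustive-search maximum on short tracks", {
  set.seed(501)
  params <- cnv_hmm_params(0.15^2)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    x <- rnorm(n, 1, 0.15)
    if (runif(1) < 0.7) {
      s <- sample(cnv_hmm_states()[-3], 1)
      a <- sample.int(n, 1)
      b <- if (a < n) a + sample.int(n - a + 1, 1) - 1 else n
      x[a:b] <- rnorm(b - a + 1, s, 0.15 * sqrt(max(s, 0.5)))
    }
    v <- evopop:::viterbi_path(x, params)
    o <- exhaustive_best_path(x, params)
    expect_equal(hmm_path_loglik(x, v, params), o$loglik, tolerance = 1e-9)
  }
})

test_that("merging and filtering apply the timepoint/length/mask rules", {
  n_win <- c(chr1 = 100L)
  seg_path <- function(lo, hi, state, n = 100) {
    p <- rep(1, n); p[lo:hi] <- state; list(chr1 = p)
  }
  ## present at one timepoint only: excluded
  one_tp <- merge_and_filter(list(seg_path(41, 60, 2), seg_path(1, 1, 1)),
                             n_windows = n_win)
  expect_equal(nrow(one_tp), 0)

  ## three windows: too short
  short <- merge_and_filter(list(seg_path(41, 43, 2), seg_path(41, 43, 2)),
                            n_windows = n_win)
  expect_equal(nrow(short), 0)

  ## 10-window state-2 tract at timepoints 3-6 of 6
  paths <- c(replicate(2, list(chr1 = rep(1, 100)), simplify = FALSE),
             replicate(4, seg_path(41, 50, 2), simplify = FALSE))
  calls <- merge_and_filter(paths, n_windows = n_win)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$timepoints, "3,4,5,6")
  expect_equal(c(calls$start, calls$end, calls$state), c(41, 50, 2))

  ## telomeric tract: masked (default 20 terminal windows)
  telo <- merge_and_filter(list(seg_path(5, 15, 2), seg_path(5, 15, 2)),
                           n_windows = n_win)
  expect_equal(nrow(telo), 0)
})

test_that("CNV calls are invariant to uniform depth scaling", {
  set.seed(502)
  seg <- data.frame(chrom = "chr1", start = 101L, end = 120L, state = 2)
  pl <- plant_cnv_track(c(chr1 = 200L), seg, n_timepoints = 2,
                        noise_sd = 0.1, seed = 9L)
  ## convert standardized tracks back to raw depths at two scales
  md <- data.frame(sample = c("a", "t"), population = "p",
                   timepoint = c(1, 2), strain = "s")
  calls_at_scale <- function(scale) {
    raw_t0 <- list(chr1 = rep(30, 200) * scale)
    raw_t1 <- list(chr1 = pmax(pl$tracks[[2]]$chr1, 0) * 30 * scale)
    sd_ <- standardize_depth(list(raw_t0, raw_t1), md)
    paths <- decode_states(sd_$std[[2]], sd_$variance[2])
    merge_and_filter(list(paths, paths), n_windows = c(chr1 = 200L))
  }
  expect_identical(calls_at_scale(1), calls_at_scale(7.5))
})

test_that("planted segments are recovered with tight boundaries", {
  set.seed(503)
  n_rec <- 0; n_seg <- 30
  for (i in 1:n_seg) {
    start <- sample(30:150, 1)
    len <- sample(5:20, 1)
    state <- sample(c(0.5, 1.5, 2, 3), 1)
    seg <- data.frame(chrom = "chr1", start = start, end = start + len - 1,
                      state = state)
    pl <- plant_cnv_track(c(chr1 = 200L), seg, n_timepoints = 3,
                          noise_sd = 0.15, seed = 600 + i)
    calls <- call_cnvs(pl$tracks, 0.15^2, n_windows = c(chr1 = 200L))
    hit <- nrow(calls) >= 1 &&
      any(calls$state == state & abs(calls$start - start) <= 1 &
          abs(calls$end - (start + len - 1)) <= 1)
    n_rec <- n_rec + hit
  }
  expect_gte(n_rec / n_seg, 0.95)
})
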