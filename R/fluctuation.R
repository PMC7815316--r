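## Mutation-rate estimation from fluctuation assays.
##
## Under the Luria-Delbruck process, the number of mutant colonies per
## parallel culture follows a heavy-tailed "jackpot" distribution indexed by
## m, the expected number of mutation events per culture. The
## Ma-Sandri-Sarkar (MSS) recursion gives its probability mass function
## exactly, and the MLE of m divided by the final cell count N_t estimates
## the per-cell per-generation mutation rate.

#' Luria-Delbruck probability mass function (Ma-Sandri-Sarkar recursion)
#'
#' `p_0 = exp(-m)`; `p_n = (m/n) * sum_{j=0}^{n-1} p_j / (n - j + 1)`.
#' Probabilities beyond `n_max` are pooled into a tail class so the returned
#' distribution sums to one.
#'
#' @param m Expected mutation events per culture (>= 0).
#' @param n_max Largest individually resolved count (>= 0).
#' @return Numeric vector of length `n_max + 2`: probabilities of counts
#'   `0..n_max` followed by the pooled tail mass (named `"tail"`).
#' @export
msr_pmf <- function(m, n_max) {
  if (m < 0) stop("m must be >= 0")
  if (n_max < 0) stop("n_max must be >= 0")
  p <- numeric(n_max + 1)
  p[1] <- exp(-m)
  if (n_max >= 1) {
    for (n in seq_len(n_max)) {
      j <- 0:(n - 1)
      p[n + 1] <- (m / n) * sum(p[j + 1] / (n - j + 1))
    }
  }
  tail_mass <- max(0, 1 - sum(p))
  stats::setNames(c(p, tail_mass), c(as.character(0:n_max), "tail"))
}

#' Ma-Sandri-Sarkar maximum-likelihood mutation-rate estimate
#'
#' Maximizes the MSS likelihood of the observed per-culture mutant counts
#' over m by one-dimensional bounded search. Counts above `n_max` (large
#' colony counts are unreliable to resolve) are pooled into the tail class.
#' The mutation rate is `m / N_t` per cell per generation. An optional
#' bootstrap (resampling cultures with replacement) gives a confidence
#' interval.
#'
#' @param counts Integer vector of mutant colony counts (or a
#'   `"fluctuation_experiment"` from [simulate_luria_delbruck()]).
#' @param N_t Final cells per culture (needed for the rate; taken from the
#'   experiment object when given).
#' @param n_max Tail-pooling bound (default 150).
#' @param n_boot Bootstrap replicates for the CI (default 0 = none).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return Object of class `"mss_fit"`: list with `m` (MLE), `rate`
#'   (`m/N_t`, NA if `N_t` missing), `N_t`, `n_cultures`, `loglik`,
#'   `ci_m`/`ci_rate` (when bootstrapped), `all_tail` flag (all counts at
#'   the tail bound).
#' @export
msr_mle <- function(counts, N_t = NULL, n_max = 150L, n_boot = 0L,
                    conf = 0.95, seed = 1L) {
  if (inherits(counts, "fluctuation_experiment")) {
    if (is.null(N_t)) N_t <- counts$N_t
    counts <- counts$counts
  }
  if (!length(counts)) stop("need at least one culture")
  if (any(counts < 0)) stop("counts must be non-negative")
  cls <- pmin(counts, n_max + 1L)          # n_max+1 = tail class
  tabulated <- tabulate(cls + 1L, nbins = n_max + 2L)
  loglik <- function(m) {
    p <- msr_pmf(m, n_max)
    p <- pmax(p, 1e-300)
    sum(tabulated * log(p))
  }
  fit_m <- function(tab) {
    if (sum(tab[-1]) == 0) return(0)       # all cultures at zero: boundary MLE
    nz <- sum(tab[-1]) / sum(tab)
    upper <- max(5, 10 * -log(max(1 - nz, 1e-6)), 20)
    opt <- stats::optimize(function(m) {
      p <- pmax(msr_pmf(m, n_max), 1e-300)
      -sum(tab * log(p))
    }, interval = c(1e-9, upper))
    opt$minimum
  }
  m_hat <- fit_m(tabulated)
  out <- list(m = m_hat, rate = if (is.null(N_t)) NA_real_ else m_hat / N_t,
              N_t = N_t, n_cultures = length(counts),
              loglik = loglik(max(m_hat, 0)),
              all_tail = all(cls == n_max + 1L))
  if (n_boot > 0) {
    set.seed(seed)
    mb <- vapply(seq_len(n_boot), function(b) {
      cb <- sample(cls, replace = TRUE)
      fit_m(tabulate(cb + 1L, nbins = n_max + 2L))
    }, 0)
    a <- (1 - conf) / 2
    out$ci_m <- unname(stats::quantile(mb, c(a, 1 - a)))
    if (!is.null(N_t)) out$ci_rate <- out$ci_m / N_t
    out$boot_m <- mb
  }
  class(out) <- "mss_fit"
  out
}

#' @export
print.mss_fit <- function(x, ...) {
  cat(sprintf("MSS fluctuation fit: m = %.4g over %d cultures", x$m,
              x$n_cultures))
  if (!is.na(x$rate)) cat(sprintf(", rate = %.3g per cell per generation",
                                  x$rate))
  cat("\n")
  if (!is.null(x$ci_m))
    cat(sprintf("  bootstrap CI for m: [%.4g, %.4g]\n", x$ci_m[1], x$ci_m[2]))
  if (x$all_tail) cat("  warning: all counts at the tail bound\n")
  invisible(x)
}

#' @export
coef.mss_fit <- function(object, ...) c(m = object$m, rate = object$rate)

#' Fold change between two mutation-rate estimates
#'
#' Ratio of the rates of two fluctuation experiments, with a bootstrap
#' interval obtained by resampling cultures with replacement in both
#' experiments and refitting.
#'
#' @param counts_a,counts_b Culture counts (integer vectors or
#'   `"fluctuation_experiment"` objects, which also supply `N_t`).
#' @param N_t_a,N_t_b Final cell counts.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param n_max Tail-pooling bound (default 150).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return List with `fold` (rate_a / rate_b), and `ci` when bootstrapped.
#' @export
fold_change <- function(counts_a, counts_b, N_t_a, N_t_b, n_boot = 1000L,
                        n_max = 150L, conf = 0.95, seed = 1L) {
  if (inherits(counts_a, "fluctuation_experiment")) {
    N_t_a <- counts_a$N_t; counts_a <- counts_a$counts
  }
  if (inherits(counts_b, "fluctuation_experiment")) {
    N_t_b <- counts_b$N_t; counts_b <- counts_b$counts
  }
  fa <- msr_mle(counts_a, N_t_a, n_max = n_max)
  fb <- msr_mle(counts_b, N_t_b, n_max = n_max)
  if (fb$rate == 0) stop("reference rate is zero; fold change undefined")
  out <- list(fold = fa$rate / fb$rate, rate_a = fa$rate, rate_b = fb$rate)
  if (n_boot > 0) {
    set.seed(seed)
    fb_ <- vapply(seq_len(n_boot), function(b) {
      ra <- msr_mle(sample(counts_a, replace = TRUE), N_t_a,
                    n_max = n_max)$rate
      rb <- msr_mle(sample(counts_b, replace = TRUE), N_t_b,
                    n_max = n_max)$rate
      if (rb == 0) NA_real_ else ra / rb
    }, 0)
    a <- (1 - conf) / 2
    out$ci <- unname(stats::quantile(fb_, c(a, 1 - a), na.rm = TRUE))
  }
  out
}
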