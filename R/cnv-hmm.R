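## Copy-number detection from windowed read depth with a fixed-parameter HMM.
##
## A sample's depth track is a named list: chromosome -> numeric vector of
## mean depths in non-overlapping 500-bp windows. Copy-number states are
## multiples of the ancestral copy number, so a standardized track has
## expectation 1 everywhere that copy number is unchanged.

#' HMM copy-number state set
#' @return Numeric vector of allowed relative copy-number states.
#' @export
cnv_hmm_states <- function() c(0, 0.5, 1, 1.5, 2, 3, 4)

#' Fixed HMM parameters for CNV detection
#'
#' Emissions are Gaussian with mean equal to the state value and variance
#' equal to the sample's standardized-depth variance multiplied by the state
#' (state 0 uses a 0.5 multiplier, since depth noise does not vanish at zero
#' copies). Initial probabilities are 0.94 for state 1 and 0.01 for each of
#' the six other states; transitions are 0.0001 off-diagonal and 0.9994 on
#' the diagonal.
#'
#' @param variance Sample variance of standardized depth (state-1 variance).
#' @return List with `states`, `means`, `variances`, `init`, `trans`.
#' @export
cnv_hmm_params <- function(variance) {
  states <- cnv_hmm_states()
  if (variance <= 0) variance <- 1e-6     # numerical floor for noiseless input
  mult <- ifelse(states == 0, 0.5, states)
  k <- length(states)
  trans <- matrix(1e-4, k, k)
  diag(trans) <- 1 - 6e-4
  init <- ifelse(states == 1, 0.94, 0.01)
  stopifnot(abs(sum(init) - 1) < 1e-12, all(abs(rowSums(trans) - 1) < 1e-12))
  list(states = states, means = states, variances = variance * mult,
       init = init, trans = trans)
}

#' Average per-site depth in non-overlapping windows
#'
#' @param depth data.frame with columns `chrom`, `pos` (1-based), `depth`.
#' @param window_size Window size in bp (default 500).
#' @param chrom_lengths Optional named vector of chromosome lengths; windows
#'   with no sites get depth 0.
#' @return Named list: chromosome -> numeric vector of mean window depths.
#' @export
window_depth <- function(depth, window_size = 500L, chrom_lengths = NULL) {
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths)
            else unique(depth$chrom)
  out <- lapply(chroms, function(ch) {
    d <- depth[depth$chrom == ch, , drop = FALSE]
    n_win <- if (!is.null(chrom_lengths))
      ceiling(chrom_lengths[[ch]] / window_size)
    else ceiling(max(d$pos) / window_size)
    idx <- factor(((d$pos - 1L) %/% window_size) + 1L, levels = seq_len(n_win))
    m <- tapply(d$depth, idx, mean)
    m[is.na(m)] <- 0
    as.numeric(m)
  })
  names(out) <- chroms
  out
}

#' Standardize depth tracks against sample medians and ancestral copy number
#'
#' Divides each sample's window depths by its genome-wide median window depth
#' ("relative depth"), then divides by the per-window mean relative depth of
#' first-timepoint samples of the same strain ("standardized depth"), so that
#' regions at a different copy number in the ancestor map to 1. Windows whose
#' first-timepoint mean relative depth is below `min_rel` are masked (NA).
#'
#' @param tracks List of depth tracks (one per sample; each a named list of
#'   per-chromosome window-depth vectors, identical window grids).
#' @param metadata data.frame with one row per sample: `sample`,
#'   `population`, `timepoint`, `strain`. `timepoint` 1 is the first
#'   sequenced timepoint used as the ancestral reference.
#' @param min_rel Masking threshold on first-timepoint relative depth
#'   (default 0.25).
#' @return List with `std` (standardized tracks, NA at masked windows),
#'   `variance` (per-sample variance of standardized depth over unmasked
#'   windows), `mask` (per-strain list of per-chromosome logical vectors),
#'   and `metadata`.
#' @export
standardize_depth <- function(tracks, metadata, min_rel = 0.25) {
  stopifnot(length(tracks) == nrow(metadata))
  rel <- lapply(tracks, function(tr) {
    all_w <- unlist(tr, use.names = FALSE)
    med <- stats::median(all_w)
    if (med <= 0) stop("all-zero sample: genome-wide median depth is 0")
    lapply(tr, function(v) v / med)
  })
  chroms <- names(tracks[[1]])
  strains <- unique(metadata$strain)
  t0mean <- list(); mask <- list()
  for (s in strains) {
    idx <- which(metadata$strain == s & metadata$timepoint == 1)
    if (!length(idx)) stop("no first-timepoint samples for strain ", s)
    t0mean[[s]] <- lapply(chroms, function(ch)
      rowMeans(do.call(cbind, lapply(rel[idx], `[[`, ch))))
    names(t0mean[[s]]) <- chroms
    mask[[s]] <- lapply(t0mean[[s]], function(v) v < min_rel)
  }
  std <- vector("list", length(tracks))
  variance <- numeric(length(tracks))
  for (i in seq_along(tracks)) {
    s <- metadata$strain[i]
    std[[i]] <- lapply(chroms, function(ch) {
      v <- rel[[i]][[ch]] / t0mean[[s]][[ch]]
      v[mask[[s]][[ch]]] <- NA_real_
      v
    })
    names(std[[i]]) <- chroms
    allv <- unlist(std[[i]], use.names = FALSE)
    variance[i] <- stats::var(allv[!is.na(allv)])
  }
  list(std = std, variance = variance, mask = mask, metadata = metadata)
}

## Viterbi decoding of one chromosome's standardized depths (no NAs).
viterbi_path <- function(obs, params) {
  k <- length(params$states)
  n <- length(obs)
  log_trans <- log(params$trans)
  emit <- function(x) {
    e <- stats::dnorm(x, params$means, sqrt(params$variances), log = TRUE)
    pmax(e, log(1e-300))
  }
  delta <- log(params$init) + emit(obs[1])
  back <- matrix(0L, n, k)
  if (n > 1) {
    for (t in 2:n) {
      cand <- delta + log_trans            # k x k: prev state x next state
      best_prev <- max.col(t(cand), ties.method = "first")
      delta <- cand[cbind(best_prev, seq_len(k))] + emit(obs[t])
      back[t, ] <- best_prev
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  params$states[path]
}

#' Decode copy-number states along each chromosome
#'
#' Runs Viterbi decoding of the fixed-parameter Gaussian HMM on a sample's
#' standardized depth track, one chromosome at a time. Masked (NA) windows
#' are skipped: the path is decoded over the unmasked windows, so a tract
#' bridges masked gaps, and masked windows carry state NA in the output.
#'
#' @param std Named list of per-chromosome standardized-depth vectors (NA =
#'   masked).
#' @param variance Sample variance of standardized depth (see
#'   [cnv_hmm_params()]).
#' @return Named list of per-chromosome state vectors (NA at masked
#'   windows).
#' @export
decode_states <- function(std, variance) {
  params <- cnv_hmm_params(variance)
  lapply(std, function(v) {
    ok <- !is.na(v)
    out <- rep(NA_real_, length(v))
    if (any(ok)) out[ok] <- viterbi_path(v[ok], params)
    out
  })
}

## Extract non-1 tracts from one chromosome's state path, bridging NA
## windows between consecutive unmasked windows of equal state.
path_tracts <- function(states, chrom) {
  ok <- which(!is.na(states))
  if (!length(ok))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), state = numeric(0)))
  s <- states[ok]
  brk <- c(TRUE, s[-1] != s[-length(s)])
  run_id <- cumsum(brk)
  res <- lapply(split(seq_along(s), run_id), function(ii) {
    data.frame(chrom = chrom, start = ok[ii[1]], end = ok[ii[length(ii)]],
               state = s[ii[1]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[out$state != 1, , drop = FALSE]
}

#' Log-probability of a fixed state path
#'
#' Joint log-probability (initial + transitions + emissions) of a given
#' state sequence for an observation vector under the CNV HMM. Validation
#' utility.
#'
#' @param obs Standardized-depth observations (no NAs).
#' @param states State values (subset of [cnv_hmm_states()]), same length.
#' @param params HMM parameters from [cnv_hmm_params()].
#' @return Scalar log-probability.
#' @export
hmm_path_loglik <- function(obs, states, params) {
  idx <- match(states, params$states)
  if (anyNA(idx)) stop("states outside the HMM state set")
  em <- vapply(seq_along(obs), function(t)
    max(stats::dnorm(obs[t], params$means[idx[t]],
                     sqrt(params$variances[idx[t]]), log = TRUE),
        log(1e-300)), 0)
  tr <- if (length(idx) > 1)
    sum(log(params$trans[cbind(idx[-length(idx)], idx[-1])])) else 0
  log(params$init[idx[1]]) + tr + sum(em)
}

#' Exhaustive maximum-probability state path (branch and bound)
#'
#' Finds the globally best state path by depth-first enumeration of all
#' state sequences with an admissible upper bound for pruning. Exponential
#' in sequence length; intended as an independent check of the Viterbi
#' decoder on short instances (<= ~12 windows).
#'
#' @param obs Standardized-depth observations (no NAs).
#' @param params HMM parameters from [cnv_hmm_params()].
#' @return List with `states` (best path, state values) and `loglik`.
#' @export
exhaustive_best_path <- function(obs, params) {
  k <- length(params$states)
  n <- length(obs)
  em <- vapply(seq_len(n), function(t)
    pmax(stats::dnorm(obs[t], params$means, sqrt(params$variances),
                      log = TRUE), log(1e-300)), numeric(k))
  em <- matrix(em, nrow = k)
  li <- log(params$init); lt <- log(params$trans)
  max_em <- apply(em, 2, max)
  suffix <- rev(cumsum(rev(max_em)))       # suffix[t] = sum_{u >= t} max em
  max_lt <- max(lt)
  best <- -Inf; best_path <- integer(n)
  path <- integer(n)
  rec <- function(t, prev, score) {
    if (score + suffix[t] + (n - t + 1) * max_lt < best) return(invisible())
    tr <- if (t == 1) li else lt[prev, ]
    cand <- tr + em[, t]
    for (s in order(cand, decreasing = TRUE)) {
      sc <- score + cand[s]
      path[t] <<- s
      if (t == n) {
        if (sc > best) { best <<- sc; best_path <<- path }
      } else if (sc + suffix[t + 1] + (n - t) * max_lt >= best) {
        rec(t + 1, s, sc)
      }
    }
    invisible()
  }
  rec(1, 0L, 0)
  list(states = params$states[best_path], loglik = best)
}

#' Merge per-timepoint CNV tracts and apply the filtering rules
#'
#' Non-1 state tracts decoded at each timepoint are merged into CNV calls
#' when they lie on the same chromosome, have the same state, and overlap by
#' at least one window. Surviving calls must be detected at
#' `min_timepoints` or more timepoints, span at least `min_windows` windows,
#' and fall outside the telomere and high-copy-array masks.
#'
#' @param paths_by_timepoint List over timepoints of decoded state paths
#'   (each a named list of per-chromosome state vectors, as from
#'   [decode_states()]).
#' @param telomere_mask Optional data.frame (`chrom`, `start`, `end`,
#'   1-based inclusive window indices); defaults via [telomere_window_mask()]
#'   when `n_windows` is given.
#' @param array_mask Optional mask for high-copy tandem arrays (same
#'   format).
#' @param n_windows Named vector of windows per chromosome, used only to
#'   build the default telomere mask.
#' @param telomere_windows Windows masked at each chromosome end by the
#'   default mask (default 20, i.e. 10 kb).
#' @param min_timepoints,min_windows Filtering thresholds (defaults 2 and
#'   4).
#' @return data.frame of CNV calls: `chrom`, `start`, `end` (window
#'   indices), `state`, `n_timepoints`, `timepoints` (comma-joined).
#' @export
merge_and_filter <- function(paths_by_timepoint, telomere_mask = NULL,
                             array_mask = NULL, n_windows = NULL,
                             telomere_windows = 20L, min_timepoints = 2L,
                             min_windows = 4L) {
  if (is.null(telomere_mask) && !is.null(n_windows))
    telomere_mask <- telomere_window_mask(n_windows, telomere_windows)
  tracts <- list()
  for (tp in seq_along(paths_by_timepoint)) {
    for (ch in names(paths_by_timepoint[[tp]])) {
      tr <- path_tracts(paths_by_timepoint[[tp]][[ch]], ch)
      if (nrow(tr)) { tr$timepoint <- tp; tracts[[length(tracts) + 1]] <- tr }
    }
  }
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), state = numeric(0),
                      n_timepoints = integer(0), timepoints = character(0))
  if (!length(tracts)) return(empty)
  tr <- do.call(rbind, tracts)
  n <- nrow(tr)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n) {
    if (tr$chrom[i] == tr$chrom[j] && tr$state[i] == tr$state[j] &&
        tr$start[j] <= tr$end[i] && tr$start[i] <= tr$end[j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  ## consensus boundaries across timepoints: the median start/end of the
  ## contributing records, so one timepoint's boundary wobble cannot widen
  ## the merged call
  calls <- lapply(split(seq_len(n), roots), function(ii) {
    tps <- sort(unique(tr$timepoint[ii]))
    data.frame(chrom = tr$chrom[ii[1]],
               start = floor(stats::median(tr$start[ii]) + 0.5),
               end = floor(stats::median(tr$end[ii]) + 0.5),
               state = tr$state[ii[1]],
               n_timepoints = length(tps),
               timepoints = paste(tps, collapse = ","),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  keep <- calls$n_timepoints >= min_timepoints &
          (calls$end - calls$start + 1) >= min_windows
  overlaps_mask <- function(calls, mask) {
    if (is.null(mask) || !nrow(mask)) return(rep(FALSE, nrow(calls)))
    hit <- rep(FALSE, nrow(calls))
    for (r in seq_len(nrow(mask)))
      hit <- hit | (calls$chrom == mask$chrom[r] &
                    calls$start <= mask$end[r] & calls$end >= mask$start[r])
    hit
  }
  keep <- keep & !overlaps_mask(calls, telomere_mask) &
          !overlaps_mask(calls, array_mask)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) return(empty)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Default telomeric window mask
#'
#' Masks the terminal `k` windows (default 20, i.e. 10 kb of 500-bp windows)
#' at both ends of every chromosome.
#'
#' @param n_windows Named integer vector of windows per chromosome.
#' @param k Windows masked at each end.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive window
#'   indices).
#' @export
telomere_window_mask <- function(n_windows, k = 20L) {
  do.call(rbind, lapply(names(n_windows), function(ch) {
    nw <- n_windows[[ch]]
    data.frame(chrom = ch,
               start = c(1L, max(nw - k + 1L, 1L)),
               end = c(min(k, nw), nw), stringsAsFactors = FALSE)
  }))
}

#' Detect CNVs for one population across timepoints
#'
#' Convenience wrapper: decode every timepoint's standardized track, then
#' merge and filter across timepoints.
#'
#' @param std_by_timepoint List over timepoints of standardized tracks
#'   (named lists of per-chromosome vectors).
#' @param variance Per-timepoint variance vector (recycled if length 1).
#' @param ... Passed to [merge_and_filter()].
#' @return CNV call table (see [merge_and_filter()]).
#' @export
call_cnvs <- function(std_by_timepoint, variance, ...) {
  variance <- rep_len(variance, length(std_by_timepoint))
  paths <- lapply(seq_along(std_by_timepoint), function(i)
    decode_states(std_by_timepoint[[i]], variance[i]))
  merge_and_filter(paths, ...)
}
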