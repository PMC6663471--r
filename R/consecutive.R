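#' Segmentation configuration for the consecutive scheme
#'
#' @param accuracy_param admission threshold `a` for the running mean
#'   similarity during segmentation, strictly in (0, 1), or `"auto"`
#'   (default) to use the arithmetic mean of the thresholded and filtered
#'   similarity matrix. The mean adapts the threshold to the overall
#'   similarity level: a fixed high value can erase genuine states in a
#'   low-similarity matrix and a fixed low value can glue distinct states
#'   in a high-similarity one.
#' @param j_min segment-length cutoff: a closed segment is kept only if
#'   it has more than `j_min` windows (default 1, which only discards
#'   single-window segments -- appropriate when each window already spans
#'   enough data points).
#' @param median_kernel odd kernel size of the 2-D median filter
#'   (default 3).
#' @param fdr_q Benjamini-Hochberg level for the similarity-matrix
#'   threshold (default 0.05).
#' @param null_draws number of label-permutation null draws shared by all
#'   entries of the p-value map (default 1000).
#' @param seed integer seed for the null draws.
#' @return a list of class `segmentation_config`.
#' @export
segmentation_config <- function(accuracy_param = "auto", j_min = 1,
                                median_kernel = 3, fdr_q = 0.05,
                                null_draws = 1000, seed = 1) {
  if (!identical(accuracy_param, "auto"))
    stopifnot_scalar_in(accuracy_param, 0, 1, "accuracy_param",
                        open_lo = TRUE, open_hi = TRUE)
  stopifnot(j_min >= 1)
  if (median_kernel %% 2 != 1 || median_kernel < 1)
    stop("`median_kernel` must be an odd positive integer", call. = FALSE)
  stopifnot_scalar_in(fdr_q, 0, 1, "fdr_q", open_lo = TRUE, open_hi = TRUE)
  structure(list(accuracy_param = accuracy_param,
                 j_min = as.integer(j_min),
                 median_kernel = as.integer(median_kernel),
                 fdr_q = fdr_q,
                 null_draws = as.integer(null_draws),
                 seed = as.integer(seed)),
            class = "segmentation_config")
}

#' FDR threshold of a similarity matrix
#'
#' Converts the similarity matrix into an empirical p-value map and
#' thresholds it by Benjamini-Hochberg at level `q`. The null similarity
#' distribution is built once and reused across entries: each draw picks
#' a random pair of windows, permutes both partitions' labels across
#' nodes (preserving module sizes) and records their normalized
#' similarity. Entries whose similarity is not significantly above this
#' null are set to 0; the diagonal participates in the p-value map like
#' any other entry.
#'
#' @param sim a [similarity_matrix()].
#' @param partitions per-window partitions the matrix was built from
#'   (source of the permutation null).
#' @param q FDR level in (0, 1).
#' @param null_draws number of null similarity draws.
#' @param seed integer seed.
#' @return thresholded [similarity_matrix()].
#' @export
fdr_threshold_similarity <- function(sim, partitions, q = 0.05,
                                     null_draws = 1000, seed = 1) {
  sim <- as_similarity(sim)
  stopifnot_scalar_in(q, 0, 1, "q", open_lo = TRUE, open_hi = TRUE)
  partitions <- lapply(partitions, as_partition)
  tt <- sim$n_windows
  if (length(partitions) != tt)
    stop("`partitions` must have one entry per window", call. = FALSE)
  n <- length(partitions[[1]])
  null <- with_seed(seed, {
    vapply(seq_len(null_draws), function(d) {
      lm <- sample.int(tt, 2)
      normalized_similarity(partitions[[lm[1]]][sample.int(n)],
                            partitions[[lm[2]]][sample.int(n)])
    }, 0)
  })
  null <- sort(null)
  s <- sim$values
  keep_ut <- upper.tri(s, diag = TRUE)
  v <- s[keep_ut]
  # p = (1 + #{null >= v}) / (1 + n_draws), via the sorted null
  n_ge <- length(null) - findInterval(v, null, left.open = TRUE)
  p <- (1 + n_ge) / (1 + length(null))
  drop <- stats::p.adjust(p, method = "BH") > q
  v[drop] <- 0
  s[keep_ut] <- v
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  sim$values <- s
  sim
}

#' Median filter of a similarity matrix
#'
#' 2-D median smoothing with edge-replication padding, preserving
#' symmetry. Removes isolated spikes so that the subsequent diagonal
#' segmentation reacts to blocks, not to single-window accidents.
#'
#' @param sim a [similarity_matrix()].
#' @param kernel odd kernel size (1 = identity).
#' @return filtered [similarity_matrix()].
#' @export
median_filter_similarity <- function(sim, kernel = 3) {
  sim <- as_similarity(sim)
  if (kernel %% 2 != 1 || kernel < 1)
    stop("`kernel` must be an odd positive integer", call. = FALSE)
  if (kernel == 1) return(sim)
  f <- cpp_median_filter(sim$values, as.integer(kernel))
  sim$values <- (f + t(f)) / 2
  sim
}

#' Sequential segmentation of a similarity matrix
#'
#' Scans the (thresholded, filtered) similarity matrix along its diagonal
#' and grows square segments of mutually similar consecutive windows. A
#' segment anchors at window `i` only if the (filtered) self-similarity
#' `a_ii` exceeds the accuracy parameter `a`; with the segment spanning
#' windows `i..i+j`, the next window is admitted iff the mean of its
#' similarities to all segment windows (both triangles, counting its
#' self-similarity once) also exceeds `a`. On rejection the segment
#' closes, is kept iff it spans more than `j_min` windows, and the
#' rejecting window becomes the next candidate anchor. Windows never
#' belong to two segments.
#'
#' @param sim_filtered thresholded and filtered [similarity_matrix()].
#' @param config a [segmentation_config()]; `accuracy_param = "auto"`
#'   resolves to the mean of all entries of `sim_filtered`.
#' @return data.frame with columns `start`, `end` (inclusive, 1-based)
#'   and attribute `"accuracy_param"` holding the resolved `a`.
#' @export
segment_similarity <- function(sim_filtered,
                               config = segmentation_config()) {
  sim_filtered <- as_similarity(sim_filtered)
  A <- sim_filtered$values
  tt <- sim_filtered$n_windows
  a <- config$accuracy_param
  if (identical(a, "auto")) {
    # a is strictly bounded in (0,1); clamp the degenerate all-ones case
    # (uniformly identical windows) so a single spanning segment survives
    a <- min(mean(A), 1 - sqrt(.Machine$double.eps))
  }
  j_min <- config$j_min
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= tt) {
    if (A[i, i] > a) {
      j <- 0L
      while (i + j + 1L <= tt) {
        idx <- i + j + 1L          # candidate window
        ks <- i:idx                # segment windows incl. candidate
        s_run <- (sum(A[idx, ks]) + sum(A[ks, idx]) - A[idx, idx]) /
          (2 * (j + 1L) + 1)
        if (s_run > a) j <- j + 1L else break
      }
      if (j + 1L > j_min) {
        starts <- c(starts, i)
        ends <- c(ends, i + j)
      }
      i <- i + j + 1L
    } else {
      i <- i + 1L
    }
  }
  out <- data.frame(start = starts, end = ends)
  attr(out, "accuracy_param") <- a
  out
}

#' Consecutive modular states
#'
#' Full consecutive pipeline: per-window consensus partitions (when given
#' a tensor), similarity matrix, FDR threshold, median filter, sequential
#' segmentation, and per-segment consensus summarization with
#' [state_partition()]. States are contiguous window ranges in temporal
#' order.
#'
#' @param x a [dyn_tensor()] or a list of per-window partitions.
#' @param consensus a [consensus_config()].
#' @param segmentation a [segmentation_config()].
#' @return list with `states` (each with `state_id`, `windows`, `start`,
#'   `end`, `partition`), `segments`, `similarity`,
#'   `similarity_filtered`, `accuracy_param` and `partitions`.
#' @export
detect_consecutive <- function(x, consensus = consensus_config(),
                               segmentation = segmentation_config()) {
  partitions <- if (inherits(x, "dyn_tensor"))
    window_partitions(x, consensus) else lapply(x, as_partition)
  sim <- similarity_matrix(partitions)
  thr <- fdr_threshold_similarity(sim, partitions, segmentation$fdr_q,
                                  segmentation$null_draws,
                                  segmentation$seed)
  fil <- median_filter_similarity(thr, segmentation$median_kernel)
  segs <- segment_similarity(fil, segmentation)
  states <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    win <- segs$start[k]:segs$end[k]
    states[[k]] <- list(state_id = k, windows = win,
                        start = segs$start[k], end = segs$end[k],
                        partition = state_partition(win, partitions,
                                                    consensus))
  }
  list(states = states, segments = segs,
       similarity = sim, similarity_filtered = fil,
       accuracy_param = attr(segs, "accuracy_param"),
       partitions = partitions)
}

#' Per-window consensus decompositions of a tensor
#'
#' Applies [consensus_partition()] to every window of a dynamic
#' connectivity tensor. Window `t` uses master seed `seed + 1009 * t`, so
#' the whole sweep is reproducible and windows are independent.
#'
#' @param tensor a [dyn_tensor()].
#' @param config a [consensus_config()].
#' @return list of T canonical partition vectors.
#' @export
window_partitions <- function(tensor, config = consensus_config()) {
  stopifnot(inherits(tensor, "dyn_tensor"))
  lapply(seq_len(tensor$n_windows), function(t) {
    cfg <- config
    cfg$seed <- config$seed + 1009L * t
    consensus_partition(tensor$weights[, , t], cfg)
  })
}
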