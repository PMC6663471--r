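# Per-partition pair-counting statistics used by the z-Rand moments:
#   m1  - number of co-assigned node pairs
#   ch  - number of unordered pairs of distinct co-pairs sharing one node
#   dis - number of unordered pairs of disjoint co-pairs
pair_stats <- function(labels) {
  sz <- tabulate(as_partition(labels))
  m1 <- sum(choose(sz, 2))
  ch <- 3 * sum(choose(sz, 3))
  list(m1 = m1, ch = ch, dis = choose(m1, 2) - ch)
}

# Exact mean and variance of w = |co-pairs(p1) ∩ pi(co-pairs(p2))| under a
# uniformly random node permutation pi (module sizes fixed). Derived by
# classifying ordered pairs of co-pairs by node overlap (identical / one
# shared node / disjoint).
zrand_moments <- function(s1, s2, n) {
  m <- choose(n, 2)
  mu <- s1$m1 * s2$m1 / m
  t3 <- 3 * choose(n, 3)
  t4 <- 3 * choose(n, 4)
  ew2 <- mu +
    2 * (if (t3 > 0) s1$ch * s2$ch / t3 else 0) +
    2 * (if (t4 > 0) s1$dis * s2$dis / t4 else 0)
  list(mu = mu, var = max(ew2 - mu^2, 0))
}

#' z-score of the Rand coefficient between two partitions
#'
#' Pair-counting similarity: `w` is the number of node pairs co-assigned
#' to one module in both partitions, standardized by its exact mean and
#' standard deviation under the permutation model that fixes both
#' partitions' module sizes. Exact moments are computed combinatorially
#' (identical / node-sharing / disjoint pairs of co-pairs), matching
#' exhaustive enumeration over all node permutations.
#'
#' @param p1,p2 partition vectors over the same node set (N >= 2).
#' @return the z-score; 0 with a warning when the null standard deviation
#'   is zero (e.g., all-singleton or single-module partitions).
#' @examples
#' zrand(c(1, 1, 2, 2), c(1, 1, 2, 2))
#' @export
zrand <- function(p1, p2) {
  p1 <- as_partition(p1); p2 <- as_partition(p2)
  n <- length(p1)
  if (length(p2) != n) stop("partitions must cover the same node set",
                            call. = FALSE)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  w <- sum(choose(table(p1, p2), 2))
  mo <- zrand_moments(pair_stats(p1), pair_stats(p2), n)
  if (mo$var <= .Machine$double.eps) {
    warning("degenerate partition pair (zero null variance); z-Rand = 0")
    return(0)
  }
  (w - mo$mu) / sqrt(mo$var)
}

#' Normalized partition similarity in [0, 1]
#'
#' The raw z-Rand score is unbounded; dividing by the geometric mean of
#' the two self-similarity z-scores and clipping negatives to zero yields
#' a coefficient bounded by 0 (no more pair agreement than chance) and 1
#' (identical partitions up to module relabeling). Degenerate partitions
#' (zero self z-score) give 0.
#'
#' @inheritParams zrand
#' @return similarity in [0, 1].
#' @export
normalized_similarity <- function(p1, p2) {
  z11 <- suppressWarnings(zrand(p1, p1))
  z22 <- suppressWarnings(zrand(p2, p2))
  if (z11 <= 0 || z22 <= 0) return(0)
  z12 <- suppressWarnings(zrand(p1, p2))
  min(max(z12, 0) / sqrt(z11 * z22), 1)
}

#' Window-by-window partition similarity matrix
#'
#' Assembles the T x T matrix of pairwise [normalized_similarity()] values
#' between the per-window modular decompositions. Symmetric, entries in
#' [0, 1], diagonal 1. All pair-counting statistics are vectorized, so
#' the cost is one contingency-table pass per window pair.
#'
#' @param partitions list of T partition vectors over a common node set.
#' @return object of class `similarity_matrix`: list with `values`
#'   (T x T) and `n_windows`.
#' @export
similarity_matrix <- function(partitions) {
  labs <- partitions_to_matrix(partitions)
  if (ncol(labs) < 2) stop("need at least 2 windows", call. = FALSE)
  n <- nrow(labs)
  tt <- ncol(labs)
  st <- apply(labs, 2, pair_stats)
  m1 <- vapply(st, `[[`, 0, "m1")
  ch <- vapply(st, `[[`, 0, "ch")
  dis <- vapply(st, `[[`, 0, "dis")
  m <- choose(n, 2)
  t3 <- 3 * choose(n, 3)
  t4 <- 3 * choose(n, 4)
  w <- cpp_pair_w(labs)
  mu <- outer(m1, m1) / m
  ew2 <- mu +
    (if (t3 > 0) 2 * outer(ch, ch) / t3 else 0) +
    (if (t4 > 0) 2 * outer(dis, dis) / t4 else 0)
  va <- pmax(ew2 - mu^2, 0)
  z <- (w - mu) / sqrt(va)
  z[va <= .Machine$double.eps] <- 0
  zself <- diag(z)
  s <- pmax(z, 0) / sqrt(outer(pmax(zself, 0), pmax(zself, 0)))
  s[!is.finite(s)] <- 0
  s[zself <= 0, ] <- 0
  s[, zself <= 0] <- 0
  s <- pmin(s, 1)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  structure(list(values = s, n_windows = tt), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("Partition similarity matrix: %d windows, mean %.3f\n",
              x$n_windows, mean(x$values)))
  invisible(x)
}

as_similarity <- function(sim) {
  if (inherits(sim, "similarity_matrix")) return(sim)
  if (is.matrix(sim) && nrow(sim) == ncol(sim))
    return(structure(list(values = sim, n_windows = nrow(sim)),
                     class = "similarity_matrix"))
  stop("`sim` must be a similarity_matrix or a square matrix", call. = FALSE)
}
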