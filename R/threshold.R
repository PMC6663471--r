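#' Proportional edge threshold
#'
#' Per window, keeps only the strongest fraction of off-diagonal edge
#' weights (each undirected edge counted once) and zeroes the rest;
#' surviving weights are unchanged. A 10% proportional threshold is the
#' usual convention when equal edge density across groups matters. Ties at
#' the cutoff value are all retained, so the realized density may slightly
#' exceed the nominal fraction; this makes the operation deterministic and
#' independent of node ordering, and also idempotent.
#'
#' @param tensor a [dyn_tensor()].
#' @param keep_fraction fraction of edges to keep, in (0, 1].
#' @return thresholded [dyn_tensor()].
#' @examples
#' tn <- simulate_dfc(sim_config(n_nodes = 20, duration_s = 3, seed = 1))$tensor
#' th <- proportional_threshold(tn, 0.1)
#' @export
proportional_threshold <- function(tensor, keep_fraction) {
  stopifnot(inherits(tensor, "dyn_tensor"))
  stopifnot_scalar_in(keep_fraction, 0, 1, "keep_fraction", open_lo = TRUE)
  if (keep_fraction == 1) return(tensor)
  w <- tensor$weights
  ut <- upper.tri(w[, , 1])
  n_keep <- ceiling(keep_fraction * sum(ut))
  for (t in seq_len(tensor$n_windows)) {
    s <- w[, , t]
    v <- s[ut]
    cutoff <- sort(v, decreasing = TRUE)[n_keep]
    s[s < cutoff] <- 0
    diag(s) <- 0
    w[, , t] <- s
  }
  tensor$weights <- w
  tensor
}

#' FDR edge threshold for a connectivity tensor
#'
#' Per window, each edge weight receives an empirical p-value against a
#' permutation null built by shuffling that window's off-diagonal weights
#' over edge positions; Benjamini-Hochberg step-up at level `q` then
#' decides which edges survive. Sub-threshold edges are zeroed, surviving
#' weights kept, so the result is thresholded and weighted. The p-value
#' counts null draws strictly greater than the observed weight (a weight
#' never counts as evidence against itself; ties between distinct edges
#' are measure-zero for continuous weights), with the usual add-one
#' correction.
#'
#' @param tensor a [dyn_tensor()].
#' @param q FDR level in (0, 1).
#' @param null_samples number of shuffles per window (values below 100
#'   trigger a warning: the p-value resolution `1/(null_samples+1)` may be
#'   too coarse for BH).
#' @param seed integer seed for the shuffles.
#' @return thresholded [dyn_tensor()].
#' @export
fdr_threshold_tensor <- function(tensor, q = 0.05, null_samples = 500,
                                 seed = 1) {
  stopifnot(inherits(tensor, "dyn_tensor"))
  stopifnot_scalar_in(q, 0, 1, "q", open_lo = TRUE, open_hi = TRUE)
  if (null_samples < 100)
    warning("null_samples < 100 gives coarse empirical p-values")
  w <- tensor$weights
  ut <- upper.tri(w[, , 1])
  with_seed(seed, {
    for (t in seq_len(tensor$n_windows)) {
      s <- w[, , t]
      v <- s[ut]
      m <- length(v)
      exceed <- integer(m)
      for (b in seq_len(null_samples)) {
        exceed <- exceed + (sample(v) > v)
      }
      p <- (1 + exceed) / (1 + null_samples)
      keep <- stats::p.adjust(p, method = "BH") <= q
      v[!keep] <- 0
      s[ut] <- v
      s[lower.tri(s)] <- t(s)[lower.tri(s)]
      w[, , t] <- s
    }
  })
  tensor$weights <- w
  tensor
}
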