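# Shared fixtures and independent oracles, all built in code.

# planted graph: cliques of the given sizes, weak inter-clique links
planted_cliques <- function(sizes, within = 1, between = 0.05) {
  n <- sum(sizes)
  w <- matrix(between, n, n)
  pos <- 1L
  for (s in sizes) {
    idx <- pos:(pos + s - 1L)
    w[idx, idx] <- within
    pos <- pos + s
  }
  diag(w) <- 0
  w
}

planted_labels <- function(sizes) rep(seq_along(sizes), sizes)

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n, max_k = n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(min(k + 1L, max_k)))
      rec(c(labels, lab), max(k, lab))
  }
  rec(integer(0), 0L)
  out
}

# Newman-Girvan modularity of a partition on weighted graph w, written
# from the definition (independent of any package code)
modularity_of <- function(w, labels) {
  m2 <- sum(w)
  k <- rowSums(w)
  same <- outer(labels, labels, "==")
  sum((w - outer(k, k) / m2)[same]) / m2
}

# exhaustive modularity maximization over all partitions (tiny n only)
best_partition_bruteforce <- function(w, max_k = nrow(w)) {
  parts <- all_partitions(nrow(w), max_k)
  q <- vapply(parts, function(p) modularity_of(w, p), 0)
  modstates::canonicalize_partition(parts[[which.max(q)]])
}

# all permutations of a vector (n <= 8)
all_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# pair-counting w statistic, from the definition
w_stat <- function(p1, p2) sum(choose(table(p1, p2), 2))

# z-Rand by exhaustive enumeration of all node permutations of p2
zrand_enum <- function(p1, p2) {
  ws <- vapply(all_perms(seq_along(p1)), function(pp) w_stat(p1, p2[pp]), 0)
  mu <- mean(ws)
  sd_w <- sqrt(mean(ws^2) - mu^2)
  if (sd_w < 1e-12) return(0)
  (w_stat(p1, p2) - mu) / sd_w
}

# small consensus settings so tests stay fast
fast_config <- function(seed = 1, runs = 10)
  consensus_config(runs_per_algorithm = runs, null_permutations = 25,
                   recluster_runs = 8, seed = seed)

# brute-force assignment: minimal total cost over all row->column maps
assignment_bruteforce <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- NULL; best_cost <- Inf
  for (p in all_perms(seq_len(m))) {
    cols <- p[seq_len(n)]
    tc <- sum(cost[cbind(seq_len(n), cols)])
    if (tc < best_cost) { best_cost <- tc; best <- cols }
  }
  list(assign = best, cost = best_cost)
}
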