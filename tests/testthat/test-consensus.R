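test_that("Louvain and Newman recover planted cliques", {
  w <- planted_cliques(c(4, 4), between = 0.01)
  expect_equal(louvain_partition(w, seed = 1), planted_labels(c(4, 4)))
  expect_equal(newman_partition(w), planted_labels(c(4, 4)))

  # fully connected uniform graph: a single module
  u <- matrix(1, 6, 6); diag(u) <- 0
  expect_equal(louvain_partition(u, seed = 2), rep(1, 6))

  # empty graph: singletons with a warning
  z <- matrix(0, 5, 5)
  expect_warning(p <- louvain_partition(z), "no edges")
  expect_equal(p, 1:5)
  expect_warning(pn <- newman_partition(z), "no edges")
  expect_equal(pn, 1:5)
})

test_that("Louvain agrees with exhaustive modularity maximization on a
           small planted graph", {
  w <- planted_cliques(c(3, 3, 3), between = 0.05)
  oracle <- best_partition_bruteforce(w, max_k = 4)
  expect_equal(oracle, planted_labels(c(3, 3, 3)))  # sanity of the oracle
  for (s in 1:5)
    expect_equal(louvain_partition(w, seed = s), oracle)
  expect_equal(newman_partition(w), oracle)
})

test_that("signed Louvain reduces to classic on nonnegative input and
           uses negative weights as repulsion", {
  # two cliques joined by strongly negative cross edges: never merged,
  # even when a weak positive bridge exists
  w <- planted_cliques(c(4, 4), between = 0)
  w[1:4, 5:8] <- w[5:8, 1:4] <- -1
  w[4, 5] <- w[5, 4] <- 0.2
  expect_equal(louvain_partition(w, seed = 1), planted_labels(c(4, 4)))

  # a pure-noise signed graph fragments instead of forming one module
  set.seed(8)
  n <- 40
  e <- matrix(0, n, n)
  e[upper.tri(e)] <- rnorm(choose(n, 2), 0, 0.2)
  e <- e + t(e)
  p <- louvain_partition(e, seed = 3)
  expect_gt(n_modules(p), 2)
})

test_that("association matrix counts co-assignments with diagonal R", {
  p1 <- c(1, 1, 2); p2 <- c(1, 2, 2)
  a <- association_from_partitions(list(p1, p2))
  expect_equal(a$n_runs, 2)
  expect_equal(diag(a$counts), rep(2, 3))
  expect_equal(a$counts[1, 2], 1)
  expect_equal(a$counts[2, 3], 1)
  expect_equal(a$counts[1, 3], 0)
  expect_equal(a$counts, t(a$counts))

  # R identical partitions: counts = R where co-assigned, else 0
  reps <- replicate(7, c(1, 1, 2, 2), simplify = FALSE)
  ar <- association_from_partitions(reps)
  expect_equal(ar$counts[1, 2], 7)
  expect_equal(ar$counts[3, 4], 7)
  expect_equal(ar$counts[1, 3], 0)

  expect_error(association_from_partitions(list(c(1, 2), c(1, 2, 3))),
               "same node set")
})

test_that("null association cutoff matches the closed-form binomial for
           equal two-module partitions", {
  # 100 nodes in 2 equal modules: chance co-assignment prob per partition
  # is 2 * C(50,2) / C(100,2) = 0.4949...; with R independent partitions
  # the pooled null counts are Binomial(R, p) up to permutation coupling
  p <- rep(1:2, each = 50)
  parts <- replicate(12, p, simplify = FALSE)
  cut <- null_association_cutoff(parts, alpha = 0.05, n_perm = 60, seed = 2)
  pr <- 2 * choose(50, 2) / choose(100, 2)
  expect_lt(abs(cut - qbinom(0.95, 12, pr)), 1.5)

  # invariant partitions: permutation leaves all-one-module unchanged
  ones <- replicate(5, rep(1, 10), simplify = FALSE)
  expect_equal(null_association_cutoff(ones, 0.05, 30, seed = 1), 5)

  # alpha -> 1 gives the minimum of the null distribution
  cut_lo <- null_association_cutoff(parts, alpha = 0.999, n_perm = 40,
                                    seed = 3)
  expect_lte(cut_lo, cut)
  expect_warning(null_association_cutoff(parts, 0.05, n_perm = 10, seed = 1),
                 "n_perm")
})

test_that("consensus partition is exact and seed-stable on planted
           structure", {
  w <- planted_cliques(c(4, 4), between = 0.01)
  for (s in c(1, 5, 9))
    expect_equal(consensus_partition(w, fast_config(seed = s)),
                 planted_labels(c(4, 4)))

  w3 <- planted_cliques(c(3, 3, 3), between = 0.05)
  oracle <- best_partition_bruteforce(w3, max_k = 4)
  hits <- sum(vapply(1:20, function(s)
    identical(consensus_partition(w3, fast_config(seed = s)), oracle),
    logical(1)))
  expect_gte(hits, 19)
})

test_that("consensus partition is bit-reproducible under a fixed master
           seed and leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  w <- planted_cliques(c(5, 5), between = 0.2)
  p1 <- consensus_partition(w, fast_config(seed = 4))
  expect_identical(.Random.seed, before)
  p2 <- consensus_partition(w, fast_config(seed = 4))
  expect_identical(p1, p2)
})

test_that("consensus modules never span disconnected components", {
  w <- matrix(0, 9, 9)
  w[1:4, 1:4] <- 0.8; w[5:9, 5:9] <- 0.8
  diag(w) <- 0
  p <- consensus_partition(w, fast_config(seed = 2))
  comp <- c(rep(1, 4), rep(2, 5))
  for (k in unique(p))
    expect_equal(length(unique(comp[p == k])), 1)
})

test_that("node relabeling conjugates the consensus partition", {
  w <- planted_cliques(c(4, 3, 4), between = 0.02)
  set.seed(31)
  perm <- sample(nrow(w))
  p <- consensus_partition(w, fast_config(seed = 6))
  pp <- consensus_partition(w[perm, perm], fast_config(seed = 6))
  # same grouping of the permuted nodes, up to module relabeling
  expect_equal(normalized_similarity(pp, p[perm]), 1)
})
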