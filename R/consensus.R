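#' Consensus community-detection configuration
#'
#' Settings for the ensemble consensus procedure used to decompose one
#' weighted network into modules: `runs_per_algorithm` seeded Louvain runs
#' plus one (deterministic) leading-eigenvector run form an ensemble; node
#' co-assignment counts across the ensemble are pruned against a
#' permutation null and the surviving association matrix is reclustered.
#'
#' @param runs_per_algorithm number of seeded Louvain runs (default 200;
#'   the leading-eigenvector method is deterministic, so it contributes a
#'   single additional run).
#' @param algorithms character subset of `c("louvain", "newman")`.
#' @param resolution Louvain resolution parameter (gamma), default 1.
#' @param null_alpha significance level for the permutation-null pruning
#'   of the association matrix.
#' @param null_permutations number of label permutations for the null.
#' @param recluster_runs number of seeded Louvain runs used when
#'   reclustering the pruned association matrix.
#' @param seed master seed; every stochastic step derives its own seed
#'   from it (`seed + run index` and fixed offsets), so a full consensus
#'   call is bit-reproducible.
#' @return a list of class `consensus_config`.
#' @export
consensus_config <- function(runs_per_algorithm = 200,
                             algorithms = c("louvain", "newman"),
                             resolution = 1,
                             null_alpha = 0.05,
                             null_permutations = 100,
                             recluster_runs = 20,
                             seed = 1) {
  stopifnot(runs_per_algorithm >= 1, recluster_runs >= 1)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  stopifnot_scalar_in(null_alpha, 0, 1, "null_alpha",
                      open_lo = TRUE, open_hi = TRUE)
  structure(list(runs_per_algorithm = as.integer(runs_per_algorithm),
                 algorithms = algorithms,
                 resolution = resolution,
                 null_alpha = null_alpha,
                 null_permutations = as.integer(null_permutations),
                 recluster_runs = as.integer(recluster_runs),
                 seed = as.integer(seed)),
            class = "consensus_config")
}

check_adjacency <- function(W, allow_negative = FALSE) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("`W` must be a square matrix", call. = FALSE)
  if (!allow_negative && any(W < 0))
    stop("`W` must be nonnegative", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-9) stop("`W` must be symmetric", call. = FALSE)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

graph_from_w <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE)
}

#' Single Louvain modularity partition
#'
#' One seeded run of multilevel (Louvain) modularity optimization on a
#' weighted undirected network. Weights may be signed: positive and
#' negative weights enter as separate layers with their own
#' configuration-model null terms (two-layer signed modularity), which on
#' a nonnegative matrix reduces exactly to classic weighted Louvain. The
#' algorithm visits nodes in random order, so different seeds explore
#' different local optima; a fixed seed is bit-reproducible.
#'
#' @param W symmetric adjacency matrix, zero diagonal (negative weights
#'   allowed and treated as repulsion).
#' @param resolution resolution parameter gamma (1 = classic modularity).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return canonical partition vector (see [canonicalize_partition()]).
#' @export
louvain_partition <- function(W, resolution = 1, seed = NULL) {
  W <- check_adjacency(W, allow_negative = TRUE)
  if (all(W == 0)) {
    warning("graph has no edges; every node is its own module")
    return(seq_len(nrow(W)))
  }
  with_seed(seed, louvain_on_matrix(W, resolution))
}

louvain_on_matrix <- function(W, resolution = 1) {
  canonicalize_partition(as.integer(cpp_louvain(W, resolution)))
}

#' Leading-eigenvector (divisive) modularity partition
#'
#' Deterministic spectral bisection partition. Degenerate inputs (no
#' positive edges) fall back to singleton modules with a warning; if the
#' eigen solver fails the connected components are returned as modules.
#'
#' On signed input only the positive weight layer is used (the spectral
#' method requires nonnegative weights).
#'
#' @inheritParams louvain_partition
#' @return canonical partition vector.
#' @export
newman_partition <- function(W) {
  W <- check_adjacency(W, allow_negative = TRUE)
  W <- pmax(W, 0)
  if (all(W == 0)) {
    warning("graph has no edges; every node is its own module")
    return(seq_len(nrow(W)))
  }
  newman_on_graph(graph_from_w(W))
}

newman_on_graph <- function(g) {
  memb <- tryCatch(
    as.integer(igraph::membership(
      igraph::cluster_leading_eigen(g, weights = igraph::E(g)$weight))),
    error = function(e)
      as.integer(igraph::components(g)$membership))
  canonicalize_partition(memb)
}

#' Association matrix of an ensemble of partitions
#'
#' Counts, for every node pair, how many partitions of the ensemble
#' co-assign the pair to one module. The diagonal equals the ensemble size
#' R.
#'
#' @param partitions list of partition vectors over a common node set.
#' @return list with `counts` (N x N integer matrix) and `n_runs` (R).
#' @export
association_from_partitions <- function(partitions) {
  labs <- partitions_to_matrix(partitions)
  list(counts = cpp_assoc_counts(labs), n_runs = ncol(labs))
}

partitions_to_matrix <- function(partitions) {
  if (!is.list(partitions) || length(partitions) == 0L)
    stop("`partitions` must be a nonempty list", call. = FALSE)
  partitions <- lapply(partitions, as_partition)
  n <- length(partitions[[1]])
  if (any(lengths(partitions) != n))
    stop("all partitions must cover the same node set", call. = FALSE)
  matrix(unlist(partitions), nrow = n)
}

#' Permutation-null cutoff for association counts
#'
#' Repeatedly permutes each partition's labels across nodes (preserving
#' module sizes), rebuilds the association matrix, and pools the
#' off-diagonal null counts; returns their `1 - alpha` quantile. Counts in
#' the observed association matrix that do not exceed this cutoff are
#' considered explainable by chance co-assignment.
#'
#' @param partitions list of partition vectors.
#' @param alpha significance level.
#' @param n_perm number of permutation repetitions (< 20 warns: the
#'   quantile becomes unstable).
#' @param seed integer seed.
#' @return numeric cutoff on the count scale.
#' @export
null_association_cutoff <- function(partitions, alpha = 0.05, n_perm = 100,
                                    seed = 1) {
  labs <- partitions_to_matrix(partitions)
  stopifnot_scalar_in(alpha, 0, 1, "alpha", open_lo = TRUE)
  if (n_perm < 20) warning("n_perm < 20 gives an unstable null quantile")
  with_seed(seed, cpp_null_assoc_cutoff(labs, as.integer(n_perm),
                                        1 - alpha))
}

# Recluster a (pruned) association matrix with `runs` seeded Louvain runs;
# returns the list of canonical partitions found.
recluster_runs_of <- function(A, runs, resolution, seed) {
  if (all(A == 0)) return(list(seq_len(nrow(A))))
  A <- A * 1.0
  lapply(seq_len(runs), function(r)
    with_seed(seed + r, louvain_on_matrix(A, resolution)))
}

modal_partition <- function(parts) {
  keys <- vapply(parts, paste, character(1), collapse = ",")
  parts[[which.max(tabulate(match(keys, unique(keys))))[1]]]
  # which.max over counts of first occurrence order
}

#' Consensus modular decomposition of one network
#'
#' Runs the full consensus procedure on a weighted network: (1) ensemble
#' of `runs_per_algorithm` seeded Louvain runs plus one
#' leading-eigenvector run; (2) association matrix of node co-assignment
#' counts; (3) counts not exceeding the permutation-null cutoff (strict
#' `>` retained, ties zeroed) are removed; (4) the surviving association
#' matrix is reclustered with seeded Louvain. If the reclustering runs
#' disagree, the procedure recurses once on the association matrix of the
#' reclustered ensemble and the majority partition is returned.
#'
#' @param W symmetric adjacency matrix, zero diagonal (signed weights
#'   allowed, see [louvain_partition()]).
#' @param config a [consensus_config()].
#' @return canonical partition vector.
#' @examples
#' W <- matrix(0, 8, 8)
#' W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
#' consensus_partition(W, consensus_config(runs_per_algorithm = 10, seed = 2))
#' @export
consensus_partition <- function(W, config = consensus_config()) {
  W <- check_adjacency(W, allow_negative = TRUE)
  if (all(W == 0)) {
    warning("graph has no edges; every node is its own module")
    return(seq_len(nrow(W)))
  }
  ens <- ensemble_partitions(W, config)
  consensus_of_partitions(ens, config)
}

ensemble_partitions <- function(W, config) {
  ens <- list()
  if ("louvain" %in% config$algorithms)
    ens <- lapply(seq_len(config$runs_per_algorithm), function(r)
      with_seed(config$seed + r, louvain_on_matrix(W, config$resolution)))
  if ("newman" %in% config$algorithms) {
    Wp <- pmax(W, 0)
    # ARPACK may consume RNG draws; keep it under the master seed too
    ens <- c(ens, if (all(Wp == 0)) list(seq_len(nrow(W)))
                  else list(with_seed(config$seed,
                                      newman_on_graph(graph_from_w(Wp)))))
  }
  ens
}

# Association -> null pruning -> recluster (+ one recursion on
# disagreement). Shared by consensus_partition and the per-state
# summarization of window ensembles.
consensus_of_partitions <- function(partitions, config) {
  assoc <- association_from_partitions(partitions)
  cutoff <- null_association_cutoff(partitions, config$null_alpha,
                                    config$null_permutations,
                                    config$seed + 7919L)
  A <- assoc$counts
  A[A <= cutoff] <- 0
  diag(A) <- 0
  if (all(A == 0)) {
    warning("association matrix empty after null pruning; returning singletons")
    return(seq_len(nrow(A)))
  }
  parts1 <- recluster_runs_of(A, config$recluster_runs, config$resolution,
                              config$seed + 104729L)
  if (length(unique(parts1)) == 1L) return(parts1[[1]])
  assoc2 <- association_from_partitions(parts1)
  cutoff2 <- null_association_cutoff(parts1, config$null_alpha,
                                     config$null_permutations,
                                     config$seed + 15485863L)
  A2 <- assoc2$counts
  A2[A2 <= cutoff2] <- 0
  diag(A2) <- 0
  if (all(A2 == 0)) {
    warning("association matrix empty after null pruning; returning singletons")
    return(seq_len(nrow(A2)))
  }
  parts2 <- recluster_runs_of(A2, config$recluster_runs, config$resolution,
                              config$seed + 32452843L)
  modal_partition(parts2)
}
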