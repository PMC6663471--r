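#' Simulation configuration
#'
#' Parameters of the synthetic dynamic-network scenario: several reference
#' modular networks whose edge weights are modulated over the recording by
#' unit-amplitude Hanning windows (signal scale `a_signal`) plus Gaussian
#' amplitude fluctuations (scale `b_noise`), summed and corrupted by
#' additive Gaussian edge noise.
#'
#' @param n_nodes number of regions (default 221, a subdivided anatomical
#'   atlas).
#' @param sample_rate_hz connectivity sampling rate; the default 10/3 Hz
#'   corresponds to one sliding window every 0.3 s.
#' @param duration_s total duration in seconds (default 60).
#' @param a_signal Hanning modulation amplitude (default 0.45).
#' @param b_noise amplitude-fluctuation scale (default 0.15).
#' @param b_noise_corr_s correlation time (seconds) of the amplitude
#'   fluctuations: `f2_j` is a unit-variance AR(1) process with
#'   autocorrelation `exp(-step / b_noise_corr_s)` between consecutive
#'   samples (default 1 s, the timescale of slow envelope fluctuations;
#'   0 gives white noise).
#' @param tensor_noise_std standard deviation of the additive Gaussian
#'   edge noise; the scenario is studied over 0.2-0.5 (default 0.2).
#' @param clip_negative zero out negative simulated weights (default
#'   `FALSE`: the zero-mean noise keeps its sign, and the signed Louvain
#'   treats negative weights as repulsion -- see [louvain_partition()].
#'   Clipping discards the repulsive evidence and lets spurious modules
#'   form in pure-noise windows).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_nodes = 221, sample_rate_hz = 10 / 3,
                       duration_s = 60, a_signal = 0.45, b_noise = 0.15,
                       b_noise_corr_s = 1, tensor_noise_std = 0.2,
                       clip_negative = FALSE, seed = 1) {
  stopifnot(n_nodes >= 2, sample_rate_hz > 0, duration_s > 0,
            a_signal >= 0, b_noise >= 0, b_noise_corr_s >= 0,
            tensor_noise_std >= 0)
  structure(list(n_nodes = as.integer(n_nodes),
                 sample_rate_hz = sample_rate_hz,
                 duration_s = duration_s,
                 a_signal = a_signal, b_noise = b_noise,
                 b_noise_corr_s = b_noise_corr_s,
                 tensor_noise_std = tensor_noise_std,
                 clip_negative = isTRUE(clip_negative),
                 seed = as.integer(seed)),
            class = "sim_config")
}

default_scenario <- function() {
  jsonlite::fromJSON(system.file("extdata", "default_scenario.json",
                                 package = "modstates"),
                     simplifyVector = FALSE)
}

#' Default reference-network layouts
#'
#' The shipped scenario: four reference networks, each a coarse modular
#' decomposition of the full 221-region atlas into 2-3 large modules,
#' with node membership shuffled independently per network so the four
#' planted partitions are mutually near-orthogonal. Layouts are read
#' from the editable fixture `extdata/default_scenario.json`.
#'
#' @return list of layouts, each a list with `network_id`, `start` (first
#'   node) and `sizes` (module sizes).
#' @export
default_layouts <- function() {
  lapply(default_scenario()$layouts, function(l)
    list(network_id = l$network_id, assign = l$assign %||% "contiguous",
         start = l$start %||% 1L, sizes = as.integer(unlist(l$sizes))))
}

#' Default activation timeline
#'
#' Five Hanning-modulated epochs over 60 s -- networks 1 to 4 in sequence
#' with background gaps, plus a repeated short activation of network 2 at
#' 57-60 s -- read from `extdata/default_scenario.json`.
#'
#' @return a [timeline()].
#' @export
default_timeline <- function() {
  sc <- default_scenario()
  ep <- do.call(rbind, lapply(sc$timeline$epochs, function(e)
    data.frame(network_id = e$network_id, onset_s = e$onset_s,
               offset_s = e$offset_s)))
  timeline(ep, sc$timeline$duration_s)
}

#' Activation timeline
#'
#' @param epochs data.frame with columns `network_id`, `onset_s`,
#'   `offset_s`; epochs must be non-overlapping and within
#'   `[0, duration_s]`. Time outside every epoch is background.
#' @param duration_s total duration in seconds.
#' @return list of class `sim_timeline`.
#' @export
timeline <- function(epochs, duration_s = 60) {
  stopifnot(is.data.frame(epochs),
            all(c("network_id", "onset_s", "offset_s") %in% names(epochs)))
  epochs <- epochs[order(epochs$onset_s), , drop = FALSE]
  if (any(epochs$onset_s < 0 | epochs$offset_s > duration_s |
          epochs$onset_s >= epochs$offset_s))
    stop("epochs must satisfy 0 <= onset < offset <= duration", call. = FALSE)
  if (nrow(epochs) > 1 &&
      any(epochs$onset_s[-1] < epochs$offset_s[-nrow(epochs)]))
    stop("epochs must not overlap", call. = FALSE)
  rownames(epochs) <- NULL
  structure(list(epochs = epochs, duration_s = duration_s),
            class = "sim_timeline")
}

#' Construct reference modular networks
#'
#' Each layout defines a planted modular structure: within-module node
#' pairs get `within_weight`, all other pairs 0; nodes not covered by a
#' layout are background (singleton modules in the planted partition).
#' Module node sets are placed either on consecutive nodes starting at
#' `start`, or -- with `assign = "shuffled"` -- on a seeded random
#' permutation of the nodes, which makes the reference partitions of
#' different networks mutually near-orthogonal (pairwise normalized
#' z-Rand similarity close to 0) while each network still covers the
#' regions its sizes ask for.
#'
#' @param n_nodes total number of nodes.
#' @param layouts list of layouts: either plain integer vectors of module
#'   sizes (placed from node 1) or lists with `sizes`, optional
#'   `network_id`, and either `start` (default 1) or
#'   `assign = "shuffled"`.
#' @param within_weight positive within-module edge weight (default 1).
#' @param seed integer seed for shuffled node assignment; network j uses
#'   `seed + network_id` so layouts are independent and reproducible.
#' @return list of reference networks, each with `adjacency`,
#'   `partition` and `network_id`.
#' @export
make_reference_networks <- function(n_nodes, layouts, within_weight = 1,
                                    seed = 1) {
  if (within_weight <= 0)
    stop("`within_weight` must be positive", call. = FALSE)
  out <- vector("list", length(layouts))
  for (k in seq_along(layouts)) {
    l <- layouts[[k]]
    if (!is.list(l)) l <- list(sizes = l)
    sizes <- as.integer(l$sizes)
    net_id <- as.integer(l$network_id %||% k)
    if (any(sizes < 1)) stop("module sizes must be positive", call. = FALSE)
    shuffled <- identical(l$assign, "shuffled")
    if (sum(sizes) > n_nodes ||
        (!shuffled && as.integer(l$start %||% 1L) + sum(sizes) - 1L > n_nodes))
      stop(sprintf("layout %d exceeds n_nodes", k), call. = FALSE)
    nodes_of <- if (shuffled) {
      perm <- with_seed(seed + net_id, sample.int(n_nodes))
      split(perm[seq_len(sum(sizes))], rep(seq_along(sizes), sizes))
    } else {
      start <- as.integer(l$start %||% 1L)
      ends <- start - 1L + cumsum(sizes)
      mapply(function(a, b) a:b, ends - sizes + 1L, ends, SIMPLIFY = FALSE)
    }
    part <- seq_len(n_nodes) + length(sizes)  # background: singletons
    adj <- matrix(0, n_nodes, n_nodes)
    for (mi in seq_along(sizes)) {
      nodes <- nodes_of[[mi]]
      part[nodes] <- mi
      adj[nodes, nodes] <- within_weight
    }
    diag(adj) <- 0
    out[[k]] <- list(adjacency = adj,
                     partition = canonicalize_partition(part),
                     network_id = net_id)
  }
  out
}

#' Hanning modulation of one network
#'
#' Unit-amplitude Hanning window over every activation epoch of the
#' network: `sin^2(pi * (t - onset) / (offset - onset))` inside an epoch,
#' 0 outside. Peaks at 1 mid-epoch and vanishes at epoch boundaries.
#'
#' @param tl a [timeline()].
#' @param network_id which network.
#' @param t_grid numeric vector of times (seconds) within the timeline.
#' @return numeric vector of modulation values along `t_grid`.
#' @export
modulation_series <- function(tl, network_id, t_grid) {
  stopifnot(inherits(tl, "sim_timeline"))
  f <- numeric(length(t_grid))
  ep <- tl$epochs[tl$epochs$network_id == network_id, , drop = FALSE]
  for (e in seq_len(nrow(ep))) {
    on <- ep$onset_s[e]; off <- ep$offset_s[e]
    inside <- t_grid >= on & t_grid <= off
    f[inside] <- sin(pi * (t_grid[inside] - on) / (off - on))^2
  }
  f
}

#' Generate a simulated dynamic connectivity tensor with ground truth
#'
#' At every time sample `t` (window centers, spaced `1/sample_rate_hz`):
#' `W(t) = sum_j M_j(t) P_j + E(t)` with
#' `M_j(t) = f1_j(t) * (a_signal + b_noise * g_j(t))` while network j is
#' active (a network exists only between the beginning and the end of its
#' epochs; outside them `M_j = 0`), where `f1_j` is the Hanning
#' modulation of network j and `g_j(t)` are standard Gaussian
#' amplitude fluctuations of the active network's time course, and
#' `E(t)` is symmetric Gaussian edge
#' noise with SD `tensor_noise_std`. Diagonals are zeroed; weights keep
#' their sign unless `clip_negative` is set (the signed Louvain uses
#' negative weights as repulsive evidence, which is what keeps pure-noise
#' windows from growing spurious modules).
#'
#' @param config a [sim_config()].
#' @param networks reference networks from [make_reference_networks()].
#' @param tl a [timeline()].
#' @return list with `tensor` (a [dyn_tensor()]) and `truth` (class
#'   `dfc_truth`: per-window true labels, planted partitions, epochs and
#'   per-epoch window sets).
#' @export
generate_tensor <- function(config, networks, tl) {
  stopifnot(inherits(config, "sim_config"), inherits(tl, "sim_timeline"))
  n <- config$n_nodes
  stopifnot(all(vapply(networks, function(p) nrow(p$adjacency), 0L) == n))
  step <- 1 / config$sample_rate_hz
  tt <- as.integer(round(config$duration_s * config$sample_rate_hz))
  centers <- (seq_len(tt) - 0.5) * step
  nets <- vapply(networks, function(x) as.integer(x$network_id), 0L)
  f1 <- vapply(nets, function(id) modulation_series(tl, id, centers),
               numeric(tt))                  # tt x n_networks
  active <- vapply(nets, function(id) {
    ep <- tl$epochs[tl$epochs$network_id == id, , drop = FALSE]
    on <- rep(FALSE, tt)
    for (e in seq_len(nrow(ep)))
      on <- on | (centers >= ep$onset_s[e] & centers <= ep$offset_s[e])
    on
  }, logical(tt))
  ut <- upper.tri(matrix(0, n, n))
  w <- array(0, c(n, n, tt))
  phi <- if (config$b_noise_corr_s > 0)
    exp(-step / config$b_noise_corr_s) else 0
  f2 <- with_seed(config$seed, {
    f2 <- matrix(stats::rnorm(tt * length(networks)), tt)
    if (phi > 0 && tt > 1)
      for (k in 2:tt)
        f2[k, ] <- phi * f2[k - 1, ] + sqrt(1 - phi^2) * f2[k, ]
    for (k in seq_len(tt)) {
      slice <- matrix(0, n, n)
      for (j in seq_along(networks)) {
        if (!active[k, j]) next
        mjt <- f1[k, j] * (config$a_signal + config$b_noise * f2[k, j])
        if (mjt != 0) slice <- slice + mjt * networks[[j]]$adjacency
      }
      noise <- matrix(0, n, n)
      noise[ut] <- stats::rnorm(sum(ut), sd = config$tensor_noise_std)
      slice <- slice + noise + t(noise)
      if (config$clip_negative) slice[slice < 0] <- 0
      diag(slice) <- 0
      w[, , k] <- slice
    }
    f2
  })
  tensor <- dyn_tensor(w, window_length_s = step, window_step_s = step,
                       allow_negative = TRUE)
  # per-window true label: the epoch covering the window center
  labels <- integer(tt)
  epoch_windows <- vector("list", nrow(tl$epochs))
  for (e in seq_len(nrow(tl$epochs))) {
    inside <- which(centers >= tl$epochs$onset_s[e] &
                    centers < tl$epochs$offset_s[e])
    labels[inside] <- tl$epochs$network_id[e]
    epoch_windows[[e]] <- inside
  }
  partitions <- stats::setNames(lapply(networks, `[[`, "partition"),
                                as.character(nets))
  truth <- structure(list(window_labels = labels,
                          network_partitions = partitions,
                          epochs = tl$epochs,
                          epoch_windows = epoch_windows,
                          window_centers_s = centers),
                     class = "dfc_truth")
  list(tensor = tensor, truth = truth)
}

#' One-call simulation of the default scenario
#'
#' Builds the shipped reference networks and timeline (rescaled to
#' `config$n_nodes` and `config$duration_s` when those differ from the
#' defaults is NOT attempted; pass custom `networks`/`tl` instead) and
#' generates the tensor. For small toy runs pass `n_networks = 2` to use
#' a reduced two-network scenario scaled to `n_nodes`.
#'
#' @param config a [sim_config()].
#' @param networks,tl optional custom networks and timeline; defaults to
#'   the shipped scenario when `n_nodes` and `duration_s` match it, or to
#'   a proportionally scaled version otherwise.
#' @return list with `tensor` and `truth` (see [generate_tensor()]).
#' @export
simulate_dfc <- function(config = sim_config(), networks = NULL, tl = NULL) {
  if (is.null(networks) || is.null(tl)) {
    sc <- default_scenario()
    if (config$n_nodes == sc$n_nodes && is.null(networks)) {
      networks <- make_reference_networks(config$n_nodes, default_layouts(),
                                          sc$within_weight,
                                          seed = sc$layout_seed)
    } else if (is.null(networks)) {
      networks <- make_reference_networks(
        config$n_nodes, scale_layouts(default_layouts(), sc$n_nodes,
                                      config$n_nodes),
        sc$within_weight, seed = sc$layout_seed)
    }
    if (is.null(tl)) {
      tl0 <- default_timeline()
      if (config$duration_s == tl0$duration_s) {
        tl <- tl0
      } else {
        f <- config$duration_s / tl0$duration_s
        ep <- tl0$epochs
        ep$onset_s <- ep$onset_s * f
        ep$offset_s <- ep$offset_s * f
        tl <- timeline(ep, config$duration_s)
      }
    }
  }
  generate_tensor(config, networks, tl)
}

# proportionally shrink/grow the default layouts to a different atlas size
scale_layouts <- function(layouts, n_from, n_to) {
  lapply(layouts, function(l) {
    start <- max(1L, as.integer(round((l$start - 1L) * n_to / n_from)) + 1L)
    sizes <- pmax(2L, as.integer(round(l$sizes * n_to / n_from)))
    while (start + sum(sizes) - 1L > n_to) {
      k <- which.max(sizes)
      sizes[k] <- sizes[k] - 1L
    }
    list(network_id = l$network_id, start = start, sizes = sizes)
  })
}

#' Ground-truth states
#'
#' Presents the simulation ground truth as a list of reference states for
#' matching: one per reference network (`by = "network"`, pooling all of
#' the network's activation epochs -- the categorical reading) or one per
#' activation epoch (`by = "epoch"` -- the consecutive reading).
#'
#' @param truth a `dfc_truth` object.
#' @param by `"network"` or `"epoch"`.
#' @return list of truth states with `truth_id`, `windows`, `partition`.
#' @export
truth_states <- function(truth, by = c("network", "epoch")) {
  stopifnot(inherits(truth, "dfc_truth"))
  by <- match.arg(by)
  if (by == "network") {
    ids <- as.integer(names(truth$network_partitions))
    out <- lapply(seq_along(ids), function(k) {
      list(truth_id = ids[k],
           windows = which(truth$window_labels == ids[k]),
           partition = truth$network_partitions[[k]])
    })
  } else {
    out <- lapply(seq_len(nrow(truth$epochs)), function(e) {
      id <- truth$epochs$network_id[e]
      list(truth_id = e,
           windows = truth$epoch_windows[[e]],
           partition = truth$network_partitions[[as.character(id)]])
    })
  }
  Filter(function(s) length(s$windows) > 0, out)
}

#' Ground truth as JSON
#'
#' @param truth a `dfc_truth` object.
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
truth_to_json <- function(truth, path = NULL) {
  stopifnot(inherits(truth, "dfc_truth"))
  x <- list(window_labels = truth$window_labels,
            partitions = truth$network_partitions,
            epochs = truth$epochs)
  js <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
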