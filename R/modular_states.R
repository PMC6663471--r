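#' Detect modular states in a dynamic connectivity tensor
#'
#' Main fitting function. Every time window's network is decomposed into
#' modules by seeded consensus community detection; pairwise normalized
#' z-Rand similarity between the window partitions forms a T x T
#' similarity matrix; modular states are then extracted either
#' \emph{categorically} (consensus clustering of the similarity matrix --
#' recurring structures, order ignored) or \emph{consecutively} (FDR
#' thresholding, median filtering and sequential segmentation along the
#' diagonal -- temporally contiguous states).
#'
#' @param x a [dyn_tensor()], or a list of per-window partition vectors
#'   (in which case the decomposition step is skipped).
#' @param mode `"categorical"` or `"consecutive"`.
#' @param consensus a [consensus_config()].
#' @param segmentation a [segmentation_config()] (consecutive mode only).
#' @param verbose print progress.
#' @return an object of class `modular_states` with elements `states`
#'   (list of states: `state_id`, `windows`, `partition`, and for
#'   consecutive mode `start`/`end`), `mode`, `partitions`, `similarity`,
#'   and for consecutive mode `similarity_filtered`, `segments` and
#'   `accuracy_param`. Methods: `print`, `summary`, `plot`.
#' @examples
#' \donttest{
#' sim <- simulate_dfc(sim_config(n_nodes = 40, duration_s = 12, seed = 3))
#' fit <- modular_states(sim$tensor, "consecutive",
#'                       consensus_config(runs_per_algorithm = 10,
#'                                        null_permutations = 25))
#' print(fit)
#' evaluate_states(fit, sim$truth)
#' }
#' @export
modular_states <- function(x, mode = c("categorical", "consecutive"),
                           consensus = consensus_config(),
                           segmentation = segmentation_config(),
                           verbose = FALSE) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (inherits(x, "dyn_tensor")) {
    if (verbose)
      message(sprintf("decomposing %d windows (%d+1 runs each) ...",
                      x$n_windows, consensus$runs_per_algorithm))
    partitions <- window_partitions(x, consensus)
  } else {
    partitions <- lapply(x, as_partition)
  }
  if (verbose) message("building similarity matrix ...")
  sim <- similarity_matrix(partitions)
  if (mode == "categorical") {
    states <- detect_categorical(sim, partitions, consensus)
    fit <- list(states = states, mode = mode, partitions = partitions,
                similarity = sim)
  } else {
    det <- detect_consecutive(partitions, consensus, segmentation)
    fit <- list(states = det$states, mode = mode, partitions = partitions,
                similarity = det$similarity,
                similarity_filtered = det$similarity_filtered,
                segments = det$segments, accuracy_param = det$accuracy_param)
  }
  fit$n_windows <- length(partitions)
  fit$n_nodes <- length(partitions[[1]])
  fit$consensus <- consensus
  fit$segmentation <- if (mode == "consecutive") segmentation else NULL
  fit$call <- cl
  class(fit) <- "modular_states"
  fit
}

#' @export
print.modular_states <- function(x, ...) {
  cat(sprintf("Modular states (%s scheme): %d states over %d windows\n",
              x$mode, length(x$states), x$n_windows))
  if (x$mode == "consecutive")
    cat(sprintf("  accuracy parameter a = %.3f, j_min = %d\n",
                x$accuracy_param, x$segmentation$j_min))
  for (s in x$states) {
    rng <- if (!is.null(s$start))
      sprintf("windows %d-%d", s$start, s$end)
    else sprintf("%d windows (first %d)", length(s$windows),
                 min(s$windows))
    cat(sprintf("  state %d: %s, %d modules\n", s$state_id, rng,
                n_modules(s$partition)))
  }
  invisible(x)
}

#' @export
summary.modular_states <- function(object, ...) {
  st <- object$states
  df <- data.frame(
    state_id = vapply(st, function(s) as.integer(s$state_id), 0L),
    n_windows = vapply(st, function(s) length(s$windows), 0L),
    first_window = vapply(st, function(s) min(s$windows), 0L),
    last_window = vapply(st, function(s) max(s$windows), 0L),
    n_modules = vapply(st, function(s) n_modules(s$partition), 0L),
    largest_module = vapply(st, function(s)
      max(tabulate(s$partition)), 0L))
  structure(list(mode = object$mode, n_windows = object$n_windows,
                 n_nodes = object$n_nodes, states = df,
                 coverage = sum(df$n_windows) / object$n_windows),
            class = "summary.modular_states")
}

#' @export
print.summary.modular_states <- function(x, ...) {
  cat(sprintf("Modular states (%s): %d nodes, %d windows, %.0f%% covered\n",
              x$mode, x$n_nodes, x$n_windows, 100 * x$coverage))
  print(x$states, row.names = FALSE)
  invisible(x)
}

#' Plot a modular-states fit
#'
#' Displays the window-by-window similarity matrix as an image (row 1 at
#' the bottom) with the detected states overlaid: squares along the
#' diagonal for consecutive segments, tick marks of state membership for
#' categorical states.
#'
#' @param x a `modular_states` object.
#' @param filtered for consecutive fits, show the thresholded and
#'   filtered matrix (default) rather than the raw one.
#' @param ... passed to [graphics::image()].
#' @export
plot.modular_states <- function(x, filtered = x$mode == "consecutive",
                                ...) {
  m <- if (filtered && !is.null(x$similarity_filtered))
    x$similarity_filtered$values else x$similarity$values
  tt <- ncol(m)
  graphics::image(seq_len(tt), seq_len(tt), m, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "time window", ylab = "time window", ...)
  for (s in x$states) {
    if (!is.null(s$start)) {
      graphics::rect(s$start - 0.5, s$start - 0.5, s$end + 0.5,
                     s$end + 0.5, border = "blue", lwd = 2)
    } else {
      graphics::points(s$windows, rep(-0.5, length(s$windows)),
                       pch = 15, cex = 0.5,
                       col = grDevices::palette()[1 + s$state_id %% 8],
                       xpd = NA)
    }
  }
  invisible(x)
}
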