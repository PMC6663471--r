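#' Categorical modular states from a similarity matrix
#'
#' Treats the window-by-window similarity matrix as a weighted graph over
#' time windows and applies the consensus community-detection procedure to
#' it: each resulting community of windows becomes one modular state,
#' regardless of temporal order. Each state's modular structure is then
#' summarized by [state_partition()] from the per-window decompositions of
#' its member windows. The similarity values are used as edge weights
#' directly (no re-thresholding). Communities of any size are kept as
#' states, including singletons. States are ordered by earliest member
#' window.
#'
#' @param sim a [similarity_matrix()] (or plain T x T matrix).
#' @param partitions the list of per-window partitions `sim` was built
#'   from.
#' @param config a [consensus_config()] governing both the window
#'   clustering and the per-state summarization.
#' @return list of modular states; each state is a list with `state_id`,
#'   `windows` (1-based window indices) and `partition`.
#' @export
detect_categorical <- function(sim, partitions, config = consensus_config()) {
  sim <- as_similarity(sim)
  partitions <- lapply(partitions, as_partition)
  if (sim$n_windows != length(partitions))
    stop("`partitions` must have one entry per window of `sim`",
         call. = FALSE)
  A <- sim$values
  diag(A) <- 0
  comm <- consensus_partition(A, config)
  if (length(unique(comm)) == 1L)
    warning("all windows fall in a single modular state")
  groups <- split(seq_along(comm), comm)
  groups <- groups[order(vapply(groups, min, 0L))]
  states <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    win <- as.integer(groups[[k]])
    states[[k]] <- list(
      state_id = k,
      windows = win,
      partition = state_partition(win, partitions, config))
  }
  states
}

#' Consensus modular structure of one state
#'
#' Summarizes a set of time windows by one partition: the association
#' matrix of the member windows' modular affiliations is pruned against
#' the permutation null and reclustered, exactly as in
#' [consensus_partition()]. Because each member window carries an
#' independent noise realization, spurious co-assignments average out and
#' only the reproducible modular backbone survives. A single-window state
#' returns that window's partition unchanged.
#'
#' @param state_windows integer vector of member window indices (1-based).
#' @param partitions list of all per-window partitions.
#' @param config a [consensus_config()].
#' @return canonical partition vector.
#' @export
state_partition <- function(state_windows, partitions,
                            config = consensus_config()) {
  state_windows <- as.integer(state_windows)
  if (length(state_windows) < 1L) stop("empty window set", call. = FALSE)
  member <- lapply(partitions[state_windows], as_partition)
  if (length(member) == 1L) return(canonicalize_partition(member[[1]]))
  consensus_of_partitions(member, config)
}

#' States as JSON
#'
#' Serializes a list of modular states to the interchange form
#' `[{"state_id", "window_indices", "partition", ...}]` (window indices
#' 1-based; consecutive states additionally carry `"start_window"` and
#' `"end_window"`).
#'
#' @param states list of modular states (as returned by
#'   [detect_categorical()], [detect_consecutive()] or
#'   [modular_states()]).
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
states_to_json <- function(states, path = NULL) {
  out <- lapply(states, function(s) {
    x <- list(state_id = s$state_id,
              window_indices = s$windows,
              partition = s$partition)
    if (!is.null(s$start)) {
      x$start_window <- s$start
      x$end_window <- s$end
    }
    x
  })
  js <- as.character(jsonlite::toJSON(out, auto_unbox = TRUE))
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
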