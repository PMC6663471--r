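# Exact assignment solver (Hungarian algorithm with potentials, O(n^3)),
# minimizing total cost over one-to-one row->column assignments; requires
# nrow <= ncol. Small n here (a handful of states), but exact either way.
hungarian_min <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  u <- numeric(n); v <- numeric(m)
  p <- integer(m)                      # p[j] = row assigned to column j
  for (i in seq_len(n)) {
    links <- integer(m)
    mins <- rep(Inf, m)
    visited <- logical(m)
    marked_i <- i; marked_j <- 0L; j <- 0L
    repeat {
      j <- 0L; delta <- Inf
      for (j1 in seq_len(m)) {
        if (!visited[j1]) {
          cur <- cost[marked_i, j1] - u[marked_i] - v[j1]
          if (cur < mins[j1]) { mins[j1] <- cur; links[j1] <- marked_j }
          if (mins[j1] < delta) { delta <- mins[j1]; j <- j1 }
        }
      }
      for (j1 in seq_len(m)) {
        if (visited[j1]) {
          u[p[j1]] <- u[p[j1]] + delta
          v[j1] <- v[j1] - delta
        } else {
          mins[j1] <- mins[j1] - delta
        }
      }
      u[i] <- u[i] + delta
      visited[j] <- TRUE
      marked_j <- j
      if (p[j] == 0L) break
      marked_i <- p[j]
    }
    repeat {                           # augment along alternating path
      j_prev <- links[j]
      p[j] <- if (j_prev == 0L) i else p[j_prev]
      j <- j_prev
      if (j == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assign[p[j]] <- j
  assign
}

#' Match detected states to ground-truth states
#'
#' One-to-one assignment between detected and true modular states
#' maximizing total spatial similarity (Hungarian algorithm on the
#' detected-by-truth similarity matrix), with a small temporal-overlap
#' bonus (weight 0.01) that breaks ties when several truth states share
#' one spatial structure (e.g. repeated activations of one network).
#' Detected states whose assigned spatial similarity falls below
#' `min_spatial` are left unmatched and treated as candidate false
#' positives.
#'
#' @param detected list of modular states (elements with `windows` and
#'   `partition`).
#' @param truth a `dfc_truth` object from [simulate_dfc()] /
#'   [generate_tensor()], or a list of truth states (elements with
#'   `truth_id`, `windows`, `partition`).
#' @param by `"network"` to match against the reference networks pooled
#'   over their epochs (categorical use) or `"epoch"` to match against
#'   individual activation epochs (consecutive use). Ignored when `truth`
#'   is already a list of truth states.
#' @param min_spatial matching threshold (default 0.5).
#' @return data.frame with one row per detected state: `state_id`,
#'   `truth_id` (NA if unmatched) and `spatial`.
#' @export
match_states <- function(detected, truth, by = c("network", "epoch"),
                         min_spatial = 0.5) {
  ts <- if (inherits(truth, "dfc_truth"))
    truth_states(truth, match.arg(by)) else truth
  if (length(ts) == 0L) stop("empty ground truth", call. = FALSE)
  nd <- length(detected); nt <- length(ts)
  sim <- matrix(0, nd, nt)
  score <- matrix(0, nd, nt)
  for (i in seq_len(nd))
    for (j in seq_len(nt)) {
      sim[i, j] <- spatial_similarity(detected[[i]]$partition,
                                      ts[[j]]$partition)
      score[i, j] <- sim[i, j] +
        0.01 * temporal_similarity(detected[[i]]$windows, ts[[j]]$windows)
    }
  # pad so every detected state can go unassigned at zero gain
  k <- max(nd, nt)
  cost <- matrix(max(score), nd, k)
  cost[, seq_len(nt)] <- max(score) - score
  assign <- hungarian_min(cost)
  truth_id <- vapply(ts, function(s) s$truth_id, 0L)
  out <- data.frame(
    state_id = vapply(detected, function(s) as.integer(s$state_id), 0L),
    truth_id = NA_integer_, spatial = NA_real_)
  for (i in seq_len(nd)) {
    j <- assign[i]
    if (j <= nt && sim[i, j] >= min_spatial) {
      out$truth_id[i] <- truth_id[j]
      out$spatial[i] <- sim[i, j]
    }
  }
  out
}

#' Spatial similarity between a detected and a true modular structure
#'
#' Alias for [normalized_similarity()]: the normalized z-Rand coefficient
#' between the two partitions.
#'
#' @inheritParams zrand
#' @return similarity in [0, 1].
#' @export
spatial_similarity <- function(p1, p2) normalized_similarity(p1, p2)

#' Temporal similarity of a detected state
#'
#' Rate of correct affiliation of time windows: the fraction of the true
#' state's windows claimed by the detected state (recall). Extra windows
#' claimed by the detected state do not lower this rate; they surface in
#' the false positive rate instead.
#'
#' @param detected_windows integer vector of detected window indices.
#' @param truth_windows integer vector of true window indices (nonempty).
#' @return rate in [0, 1].
#' @export
temporal_similarity <- function(detected_windows, truth_windows) {
  if (length(truth_windows) == 0L) stop("empty truth window set",
                                        call. = FALSE)
  length(intersect(detected_windows, truth_windows)) /
    length(unique(truth_windows))
}

#' False positive rate of a detection
#'
#' Fraction of all T time windows claimed by detected states that match
#' no simulated network.
#'
#' @param detected list of modular states.
#' @param matching data.frame from [match_states()].
#' @param n_windows total number of windows T.
#' @return rate in [0, 1].
#' @export
false_positive_rate <- function(detected, matching, n_windows) {
  if (length(detected) == 0L) return(0)
  unmatched <- is.na(matching$truth_id)
  fp <- sum(vapply(detected[unmatched], function(s) length(s$windows), 0L))
  fp / n_windows
}

#' Score detected states against simulation ground truth
#'
#' Computes the full evaluation report: optimal state matching, per-state
#' spatial (normalized z-Rand) and temporal (window recall) similarities,
#' their averages over matched states, and the false positive rate.
#'
#' @param detected list of modular states or a `modular_states` fit.
#' @param truth a `dfc_truth` object.
#' @param by `"network"` (categorical scheme) or `"epoch"` (consecutive
#'   scheme); defaults to the fit's mode when `detected` is a
#'   `modular_states` object.
#' @param min_spatial matching threshold passed to [match_states()].
#' @return object of class `ms_evaluation`: list with `per_state`
#'   data.frame, `average_spatial`, `average_temporal`,
#'   `false_positive_rate`, `n_detected`, `n_truth`, `n_matched`.
#' @export
evaluate_states <- function(detected, truth, by = NULL, min_spatial = 0.5) {
  if (inherits(detected, "modular_states")) {
    if (is.null(by))
      by <- if (detected$mode == "consecutive") "epoch" else "network"
    detected <- detected$states
  }
  by <- match.arg(by %||% "network", c("network", "epoch"))
  stopifnot(inherits(truth, "dfc_truth"))
  ts <- truth_states(truth, by)
  matching <- match_states(detected, ts)
  truth_windows <- lapply(ts, `[[`, "windows")
  names(truth_windows) <- vapply(ts, function(s) as.character(s$truth_id), "")
  temporal <- rep(NA_real_, nrow(matching))
  for (i in seq_len(nrow(matching))) {
    tid <- matching$truth_id[i]
    if (!is.na(tid))
      temporal[i] <- temporal_similarity(detected[[i]]$windows,
                                         truth_windows[[as.character(tid)]])
  }
  per_state <- cbind(matching, temporal = temporal,
                     n_windows = vapply(detected, function(s)
                       length(s$windows), 0L))
  matched <- !is.na(per_state$truth_id)
  structure(list(
    per_state = per_state,
    average_spatial = if (any(matched)) mean(per_state$spatial[matched])
                      else NA_real_,
    average_temporal = if (any(matched)) mean(per_state$temporal[matched])
                       else NA_real_,
    false_positive_rate = false_positive_rate(detected, matching,
                                              length(truth$window_labels)),
    n_detected = length(detected),
    n_truth = length(ts),
    n_matched = sum(matched)),
    class = "ms_evaluation")
}

#' @export
print.ms_evaluation <- function(x, ...) {
  cat(sprintf("Modular-state evaluation: %d detected, %d truth, %d matched\n",
              x$n_detected, x$n_truth, x$n_matched))
  cat(sprintf("  average spatial similarity  %.3f\n", x$average_spatial))
  cat(sprintf("  average temporal similarity %.3f\n", x$average_temporal))
  cat(sprintf("  false positive rate         %.3f\n",
              x$false_positive_rate))
  invisible(x)
}
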