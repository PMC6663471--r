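#' Dynamic connectivity tensor
#'
#' Container for a stack of weighted connectivity matrices, one per sliding
#' time window: an `N x N x T` array of symmetric, nonnegative weights with
#' zero diagonal, plus window timing metadata. This is the input object of
#' the modular-state pipeline; how the connectivity was computed (PLV,
#' amplitude-envelope correlation, ...) is irrelevant to the detector.
#'
#' Each slice is symmetrized by averaging with its transpose; a warning is
#' emitted if the maximum asymmetry exceeds `1e-6`. The diagonal is forced
#' to zero. Windows are half-open intervals
#' `[k * step, k * step + length)`, `k = 0..T-1`.
#'
#' @param weights numeric `N x N x T` array (an `N x N` matrix is accepted
#'   as a single window).
#' @param window_length_s window length in seconds.
#' @param window_step_s spacing between consecutive window onsets, seconds.
#' @param node_labels optional character vector of region names, length N.
#' @param allow_negative permit signed weights (used by the simulator,
#'   whose additive noise is zero-mean; loaded connectivity data is
#'   expected to be nonnegative).
#' @return object of class `dyn_tensor` with elements `weights`,
#'   `n_nodes`, `n_windows`, `window_length_s`, `window_step_s`,
#'   `node_labels`.
#' @examples
#' w <- array(0, c(3, 3, 2))
#' w[1, 2, ] <- w[2, 1, ] <- 1
#' dyn_tensor(w, window_length_s = 0.3, window_step_s = 0.3)
#' @export
dyn_tensor <- function(weights, window_length_s = 1, window_step_s = 1,
                       node_labels = NULL, allow_negative = FALSE) {
  if (is.matrix(weights)) weights <- array(weights, c(dim(weights), 1L))
  if (!is.array(weights) || length(dim(weights)) != 3L)
    stop("`weights` must be an N x N x T array", call. = FALSE)
  d <- dim(weights)
  if (d[1] != d[2])
    stop(sprintf("slices must be square, got %d x %d", d[1], d[2]),
         call. = FALSE)
  if (anyNA(weights)) stop("`weights` contains NA", call. = FALSE)
  max_asym <- 0
  for (t in seq_len(d[3])) {
    s <- weights[, , t]
    max_asym <- max(max_asym, max(abs(s - t(s))))
    s <- (s + t(s)) / 2
    diag(s) <- 0
    if (!allow_negative && any(s < 0))
      stop(sprintf("negative weights in slice %d", t), call. = FALSE)
    weights[, , t] <- s
  }
  if (max_asym > 1e-6)
    warning(sprintf("asymmetry up to %.3g symmetrized by (A + t(A))/2",
                    max_asym))
  if (!is.null(node_labels) && length(node_labels) != d[1])
    stop("`node_labels` must have one entry per node", call. = FALSE)
  structure(
    list(weights = weights, n_nodes = d[1], n_windows = d[3],
         window_length_s = window_length_s, window_step_s = window_step_s,
         node_labels = node_labels),
    class = "dyn_tensor")
}

#' @export
print.dyn_tensor <- function(x, ...) {
  cat(sprintf(
    "Dynamic connectivity tensor: %d nodes x %d windows (%.2g s step)\n",
    x$n_nodes, x$n_windows, x$window_step_s))
  dens <- mean(apply(x$weights, 3, function(s) mean(s[upper.tri(s)] > 0)))
  cat(sprintf("  mean edge density %.2f, weight range [%.3g, %.3g]\n",
              dens, min(x$weights), max(x$weights)))
  invisible(x)
}

#' @export
as.array.dyn_tensor <- function(x, ...) x$weights

#' Read / write a dynamic connectivity tensor
#'
#' Supported formats: `"csv"` -- long-format text with header
#' `window,node_i,node_j,weight`, one row per undirected edge per window
#' (nodes 1-based, zero edges may be omitted); `"rds"` -- native
#' serialization of the `dyn_tensor` object. `"auto"` infers the format
#' from the file extension.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"csv"`, `"rds"`.
#' @param n_nodes,n_windows optional dimensions for CSV input; inferred
#'   from the maxima in the file when omitted.
#' @param window_length_s,window_step_s timing metadata attached on CSV
#'   input.
#' @param allow_negative accept signed weights (e.g. tensors written by
#'   the simulator); measured connectivity is expected nonnegative and
#'   rejected by default.
#' @return `load_tensor()`: a validated [dyn_tensor()]; `save_tensor()`:
#'   the path, invisibly.
#' @export
load_tensor <- function(path, format = c("auto", "csv", "rds"),
                        n_nodes = NULL, n_windows = NULL,
                        window_length_s = 1, window_step_s = 1,
                        allow_negative = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", rds = "rds",
                     stop(sprintf("cannot infer format from extension '%s'",
                                  ext), call. = FALSE))
  }
  if (format == "rds") {
    x <- readRDS(path)
    if (!inherits(x, "dyn_tensor")) stop("RDS file is not a dyn_tensor",
                                         call. = FALSE)
    return(dyn_tensor(x$weights, x$window_length_s, x$window_step_s,
                      x$node_labels, allow_negative = allow_negative))
  }
  df <- utils::read.csv(path)
  need <- c("window", "node_i", "node_j", "weight")
  if (!all(need %in% names(df)))
    stop("CSV must have columns window,node_i,node_j,weight", call. = FALSE)
  n <- n_nodes %||% max(df$node_i, df$node_j)
  tt <- n_windows %||% max(df$window)
  if (any(df$node_i < 1 | df$node_i > n | df$node_j < 1 | df$node_j > n |
          df$window < 1 | df$window > tt))
    stop("CSV indices out of range", call. = FALSE)
  w <- array(0, c(n, n, tt))
  idx1 <- cbind(df$node_i, df$node_j, df$window)
  idx2 <- cbind(df$node_j, df$node_i, df$window)
  w[idx1] <- df$weight
  w[idx2] <- df$weight
  dyn_tensor(w, window_length_s, window_step_s,
             allow_negative = allow_negative)
}

#' @rdname load_tensor
#' @param tensor a [dyn_tensor()].
#' @export
save_tensor <- function(tensor, path, format = c("auto", "csv", "rds")) {
  stopifnot(inherits(tensor, "dyn_tensor"))
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), csv = "csv",
                     rds = "rds",
                     stop("cannot infer format from extension", call. = FALSE))
  if (format == "rds") {
    saveRDS(tensor, path)
    return(invisible(path))
  }
  rows <- do.call(rbind, lapply(seq_len(tensor$n_windows), function(t) {
    s <- tensor$weights[, , t]
    ij <- which(upper.tri(s) & s != 0, arr.ind = TRUE)
    if (nrow(ij) == 0L) return(NULL)
    data.frame(window = t, node_i = ij[, 1], node_j = ij[, 2],
               weight = s[ij])
  }))
  if (is.null(rows))
    rows <- data.frame(window = integer(), node_i = integer(),
                       node_j = integer(), weight = numeric())
  utils::write.csv(format(rows, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
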