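#' Canonicalize a module partition
#'
#' A partition is stored as an integer vector of module labels, one per
#' node. Canonical form renumbers modules 1..K in order of first
#' appearance along the node index, which makes partitions produced by
#' different stochastic runs directly comparable.
#'
#' @param labels integer vector of module labels (any positive coding).
#' @return integer vector with labels renumbered 1..K by first occurrence.
#' @examples
#' canonicalize_partition(c(7, 7, 2, 2, 9))
#' @export
canonicalize_partition <- function(labels) {
  labels <- as_partition(labels)
  first <- unique(labels)
  match(labels, first)
}

# Validate and coerce a partition vector: every node exactly one positive
# integer module id.
as_partition <- function(labels) {
  if (is.list(labels) && !is.null(labels$labels)) labels <- labels$labels
  labels <- as.integer(labels)
  if (length(labels) < 1L || anyNA(labels) || any(labels < 1L))
    stop("a partition must be a vector of positive integer module labels",
         call. = FALSE)
  labels
}

#' Number of modules in a partition
#' @param labels partition vector (see [canonicalize_partition()]).
#' @return integer count of distinct modules.
#' @export
n_modules <- function(labels) length(unique(as_partition(labels)))

#' Serialize / deserialize partitions as JSON
#'
#' The JSON form is `{"n_nodes": N, "labels": [...]}`.
#'
#' @param labels partition vector.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `partition_to_json()`: JSON string (invisibly, if written to
#'   file); `partition_from_json()`: integer label vector.
#' @export
partition_to_json <- function(labels, path = NULL) {
  labels <- as_partition(labels)
  x <- list(n_nodes = length(labels), labels = labels)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' @rdname partition_to_json
#' @param json JSON string or file path.
#' @export
partition_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  labels <- as_partition(x$labels)
  if (!is.null(x$n_nodes) && length(labels) != x$n_nodes)
    stop("JSON partition: `labels` length disagrees with `n_nodes`",
         call. = FALSE)
  labels
}

# Apply a node permutation pi to a partition: node i of the output is node
# pi[i] of the input. Used in invariance checks and null models.
relabel_nodes <- function(labels, perm) as_partition(labels)[perm]
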