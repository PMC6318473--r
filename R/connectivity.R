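# Functional connectivity: per-session correlation matrices and the
# sessions x edges design matrix consumed by the PLS stage.

#' Upper-triangle edge index for a set of nodes
#'
#' Enumerates the unordered node pairs (i, j) with i < j in row-major order:
#' (1,2), (1,3), ..., (1,k), (2,3), ... This ordering is a frozen contract —
#' every edge vector in the package follows it, so vectors, bootstrap-ratio
#' maps and serialized datasets are mutually consistent.
#'
#' @param node_ids character vector of node labels (length k >= 2).
#' @return data.frame with integer columns `i`, `j` and character columns
#'   `node_i`, `node_j`; k(k-1)/2 rows.
#' @export
edge_index <- function(node_ids) {
  k <- length(node_ids)
  if (k < 2L) stop("need at least 2 nodes to enumerate edges", call. = FALSE)
  if (anyDuplicated(node_ids)) stop("node_ids must be unique", call. = FALSE)
  i <- rep.int(seq_len(k - 1L), times = (k - 1L):1L)
  j <- sequence((k - 1L):1L, from = 2:k)
  data.frame(i = i, j = j,
             node_i = as.character(node_ids)[i],
             node_j = as.character(node_ids)[j],
             stringsAsFactors = FALSE)
}

#' Session functional-connectivity matrix
#'
#' FC is the zero-lag Pearson correlation between regional activity time
#' series within one session.
#'
#' @param ts numeric matrix, time points x nodes, at least 3 rows. Column
#'   names are used as node labels (generated as `n001`, ... when absent).
#' @return symmetric k x k correlation matrix with unit diagonal.
#' @export
fc_matrix <- function(ts) {
  ts <- check_matrix(ts, "ts")
  if (nrow(ts) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (is.null(colnames(ts))) colnames(ts) <- sprintf("n%03d", seq_len(ncol(ts)))
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    stop("zero-variance time series for node(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fc <- stats::cor(ts)
  diag(fc) <- 1
  fc
}

#' Vectorize the upper triangle of an FC matrix
#'
#' @param fc symmetric node x node matrix.
#' @param index optional precomputed [edge_index()] for the matrix's nodes.
#' @return numeric vector of length k(k-1)/2, named `node_i--node_j`,
#'   ordered per the edge-index contract.
#' @export
vectorize_upper <- function(fc, index = NULL) {
  fc <- check_matrix(fc, "fc")
  if (nrow(fc) != ncol(fc)) stop("`fc` must be square", call. = FALSE)
  if (is.null(index)) index <- edge_index(colnames(fc) %||% sprintf("n%03d", seq_len(ncol(fc))))
  v <- fc[cbind(index$i, index$j)]
  names(v) <- paste(index$node_i, index$node_j, sep = "--")
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rebuild a symmetric matrix from an edge vector
#'
#' Exact inverse of [vectorize_upper()] off the diagonal; the diagonal is
#' set to zero (edge statistics such as bootstrap ratios have no self-term).
#'
#' @param values numeric edge vector in edge-index order.
#' @param index [edge_index()] data.frame the vector follows.
#' @param node_ids ordered node labels; defaults to those in `index`.
#' @return symmetric k x k matrix with zero diagonal.
#' @export
edge_vector_to_matrix <- function(values, index, node_ids = NULL) {
  if (length(values) != nrow(index))
    stop(sprintf("edge vector length %d does not match edge index (%d rows)",
                 length(values), nrow(index)), call. = FALSE)
  if (is.null(node_ids)) node_ids <- unique(c(index$node_i, index$node_j))
  k <- length(node_ids)
  m <- matrix(0, k, k, dimnames = list(node_ids, node_ids))
  m[cbind(index$i, index$j)] <- values
  m[cbind(index$j, index$i)] <- values
  m
}

#' Sessions x edges design matrix from per-session time series
#'
#' Computes each session's FC matrix and stacks the vectorized upper
#' triangles into the left PLS block X. All sessions must share the node set
#' and order.
#'
#' @param series list of time x node matrices, one per session.
#' @param session_ids optional session labels; defaults to list names or
#'   `ses001`, ...
#' @return an object of class `edge_dataset`: list with `X` (sessions x
#'   edges), `edge_index`, `node_ids`, `session_ids`.
#' @export
build_edge_dataset <- function(series, session_ids = NULL) {
  if (!is.list(series) || length(series) < 1L)
    stop("`series` must be a non-empty list of time x node matrices", call. = FALSE)
  first <- series[[1L]]
  if (is.null(colnames(first))) colnames(first) <- sprintf("n%03d", seq_len(ncol(first)))
  nodes <- colnames(first)
  bad <- vapply(series, function(s) {
    cn <- colnames(s) %||% sprintf("n%03d", seq_len(ncol(s)))
    ncol(s) != length(nodes) || !identical(cn, nodes)
  }, logical(1L))
  if (any(bad))
    stop("sessions with inconsistent node sets: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  if (is.null(session_ids))
    session_ids <- names(series) %||% sprintf("ses%03d", seq_along(series))
  idx <- edge_index(nodes)
  X <- t(vapply(series, function(s) {
    colnames(s) <- nodes
    vectorize_upper(fc_matrix(s), idx)
  }, numeric(nrow(idx))))
  rownames(X) <- session_ids
  new_edge_dataset(X, idx, nodes, session_ids)
}

new_edge_dataset <- function(X, index, node_ids, session_ids) {
  structure(list(X = X, edge_index = index, node_ids = node_ids,
                 session_ids = session_ids),
            class = "edge_dataset")
}

#' @export
print.edge_dataset <- function(x, ...) {
  cat(sprintf("edge_dataset: %d sessions x %d edges (%d nodes)\n",
              nrow(x$X), ncol(x$X), length(x$node_ids)))
  invisible(x)
}

#' Node strength: mean FC of a node with all other nodes
#'
#' The signed mean of the node's off-diagonal row (no absolute value, no
#' Fisher transform): "average correlation to other brain areas".
#'
#' @param fc symmetric FC matrix with node names.
#' @param node node label, or NULL for all nodes.
#' @return named numeric scalar (or vector for `node = NULL`).
#' @export
node_strength <- function(fc, node = NULL) {
  fc <- check_matrix(fc, "fc")
  k <- nrow(fc)
  s <- (rowSums(fc) - diag(fc)) / (k - 1L)
  if (is.null(node)) return(s)
  if (!node %in% rownames(fc)) stop("unknown node: ", node, call. = FALSE)
  s[node]
}

#' Mean FC between a seed node and each community
#'
#' The seed is excluded from its own community's average; a community whose
#' only member is the seed yields NA (flagged, never silently zero).
#'
#' @param fc symmetric FC matrix with node names.
#' @param seed seed node label.
#' @param partition named factor mapping every node to a community.
#' @return named numeric vector, one mean per community level.
#' @export
seed_to_community_fc <- function(fc, seed, partition) {
  fc <- check_matrix(fc, "fc")
  if (!seed %in% rownames(fc)) stop("unknown seed node: ", seed, call. = FALSE)
  partition <- as_partition(partition, rownames(fc))
  out <- vapply(levels(partition), function(cm) {
    members <- setdiff(names(partition)[partition == cm], seed)
    if (length(members) == 0L) return(NA_real_)
    mean(fc[seed, members])
  }, numeric(1L))
  if (anyNA(out))
    warning("community containing only the seed: undefined mean flagged as NA",
            call. = FALSE)
  out
}

# Coerce a partition-like object (named factor/character/integer) to a named
# factor covering exactly `node_ids`.
as_partition <- function(partition, node_ids = NULL) {
  if (is.null(names(partition)) && !is.null(node_ids) &&
      length(partition) == length(node_ids))
    names(partition) <- node_ids
  p <- factor(partition)
  names(p) <- names(partition)
  if (!is.null(node_ids)) {
    if (!all(node_ids %in% names(p)))
      stop("partition does not cover all nodes", call. = FALSE)
    p <- p[node_ids]
  }
  p
}
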