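# Plain-text readers and writers for the pipeline's artifacts: TSV for
# matrices/tables, JSON sidecars for structural metadata.

write_tsv <- function(df, path, row_col = NULL) {
  if (!is.null(row_col)) {
    df <- cbind(stats::setNames(data.frame(rownames(df),
                                           stringsAsFactors = FALSE), row_col),
                as.data.frame(df, stringsAsFactors = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a session time-series matrix as TSV
#'
#' T rows x N columns, header row = node IDs.
#'
#' @param ts time x node matrix.
#' @param path file path.
#' @return the path (writer) / the matrix (reader).
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(vapply(df, is.numeric, logical(1L))))
    stop("malformed time-series TSV (non-numeric column): ", path, call. = FALSE)
  as.matrix(df)
}

#' Write / read a mood table as TSV
#'
#' One row per session with a leading `session_id` column; remaining
#' columns are the mood scales.
#'
#' @param mood sessions x scales matrix with session-id rownames.
#' @param path file path.
#' @export
write_mood_table <- function(mood, path) {
  write_tsv(mood, path, row_col = "session_id")
}

#' @rdname write_mood_table
#' @export
read_mood_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write / read a node partition as two-column TSV
#'
#' Columns `node_id` and `community`.
#'
#' @param partition named factor node -> community.
#' @param path file path.
#' @export
write_partition <- function(partition, path) {
  write_tsv(data.frame(node_id = names(partition),
                       community = as.character(partition),
                       stringsAsFactors = FALSE), path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  p <- factor(df$community)
  names(p) <- df$node_id
  p
}

#' Write / read a covariate table as TSV
#'
#' @param covariates data.frame with `session_id` and numeric columns.
#' @param path file path.
#' @export
write_covariates <- function(covariates, path) write_tsv(covariates, path)

#' @rdname write_covariates
#' @export
read_covariates <- function(path) utils::read.delim(path, check.names = FALSE)

#' Write / read an edge dataset (TSV matrix + JSON sidecar)
#'
#' The sessions x edges matrix goes to `<path>`; node IDs, session IDs and
#' the edge-index contract go to `<path>.json`, so the edge ordering reloads
#' identically.
#'
#' @param edges an `edge_dataset`.
#' @param path TSV file path.
#' @export
write_edge_dataset <- function(edges, path) {
  stopifnot(inherits(edges, "edge_dataset"))
  write_tsv(edges$X, path, row_col = "session_id")
  jsonlite::write_json(
    list(node_ids = edges$node_ids, session_ids = edges$session_ids,
         edge_i = edges$edge_index$i, edge_j = edges$edge_index$j),
    paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_edge_dataset
#' @export
read_edge_dataset <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.delim(path, check.names = FALSE)
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- df[[1L]]
  idx <- edge_index(meta$node_ids)
  if (!identical(idx$i, as.integer(meta$edge_i)) ||
      !identical(idx$j, as.integer(meta$edge_j)))
    stop("edge index in sidecar does not follow the package ordering contract",
         call. = FALSE)
  new_edge_dataset(X, idx, meta$node_ids, meta$session_ids)
}

#' Serialize a fitted PLS model to JSON
#'
#' Stores singular vectors with their edge/scale labels, singular values,
#' effect sizes and per-session scores.
#'
#' @param model a `pls_model`.
#' @param path output path.
#' @param lv latent variables to store (default: all).
#' @export
write_pls_model <- function(model, path, lv = seq_along(model$d)) {
  jsonlite::write_json(list(
    edge_names = rownames(model$u), scale_names = rownames(model$v),
    u = model$u[, lv, drop = FALSE], v = model$v[, lv, drop = FALSE],
    sigma = model$d, eta = model$eta,
    x_scores = model$x_scores[, lv, drop = FALSE],
    y_scores = model$y_scores[, lv, drop = FALSE],
    n_sessions = model$n_sessions
  ), path, digits = NA)
  invisible(path)
}
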