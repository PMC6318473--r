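# Small fixtures built in code; tests stay text-only and deterministic.

node_labels <- function(k) sprintf("n%03d", seq_len(k))

# random symmetric matrix with zero diagonal (an edge-statistic map)
random_symmetric <- function(k, seed = 1) {
  withr_seed(seed)
  m <- matrix(rnorm(k * k), k, k)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(node_labels(k), node_labels(k))
  m
}

# random correlation-like FC matrix (unit diagonal)
random_fc <- function(k, seed = 1) {
  withr_seed(seed)
  ts <- matrix(rnorm(40 * k), 40, k, dimnames = list(NULL, node_labels(k)))
  fc_matrix(ts)
}

# edge dataset assembled from a list of FC matrices
edge_dataset_from_fc <- function(fc_list) {
  idx <- edge_index(rownames(fc_list[[1]]))
  X <- t(vapply(fc_list, vectorize_upper, numeric(nrow(idx)), index = idx))
  rownames(X) <- sprintf("ses%03d", seq_along(fc_list))
  structure(list(X = X, edge_index = idx, node_ids = rownames(fc_list[[1]]),
                 session_ids = rownames(X)),
            class = "edge_dataset")
}

withr_seed <- function(seed) set.seed(seed)

withr_tempfile <- function(ext = ".tsv") tempfile(fileext = ext)

# draw under a temporary seed without touching the ambient RNG stream
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
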