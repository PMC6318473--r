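# Community-level characterization of edge statistics and per-session
# segregation-integration measures, with label-permuting null models.

#' Mean incident-edge value per node
#'
#' For a symmetric edge-statistic matrix (e.g. bootstrap ratios mapped back
#' to node pairs), returns each node's mean over its k - 1 incident edges —
#' the regional contribution map.
#'
#' @param mat symmetric node x node matrix with zero (ignored) diagonal.
#' @return named per-node vector.
#' @export
regional_mean_bsr <- function(mat) {
  mat <- check_matrix(mat, "mat")
  k <- nrow(mat)
  (rowSums(mat) - diag(mat)) / (k - 1L)
}

#' Top fraction of nodes by a regional statistic
#'
#' Ranks nodes by value (descending for `positive` and `absolute`,
#' ascending for `negative`) and returns the top `ceiling(fraction * k)`.
#' Ties are broken by node index for determinism.
#'
#' @param values named per-node vector.
#' @param fraction fraction of nodes, in (0, 1).
#' @param mode `"positive"`, `"negative"` or `"absolute"`.
#' @return character vector of node labels (or indices when unnamed).
#' @export
top_fraction_nodes <- function(values, fraction = 0.05,
                               mode = c("positive", "negative", "absolute")) {
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  k <- length(values)
  n_top <- as.integer(ceiling(fraction * k))
  key <- switch(mode, positive = values, negative = -values,
                absolute = abs(values))
  ord <- order(-key, seq_len(k))
  ids <- names(values) %||% as.character(seq_len(k))
  ids[ord[seq_len(n_top)]]
}

#' Sign-restricted mean edge statistic per community block
#'
#' For every community pair (including the diagonal), averages the entries
#' of the block's edges restricted by sign: `positive` averages only
#' entries > 0; `negative` averages only entries < 0 and reports their
#' magnitudes. Blocks with no qualifying edge are NA (flagged via the
#' `counts` attribute, never silently zero).
#'
#' @param mat symmetric node x node edge-statistic matrix.
#' @param partition named factor node -> community (>= 2 communities).
#' @param sign `"positive"` or `"negative"`.
#' @return symmetric K x K matrix of block means with a `counts` attribute.
#' @export
rsn_block_means <- function(mat, partition, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  mat <- check_matrix(mat, "mat")
  partition <- as_partition(partition, rownames(mat) %||% names(partition))
  if (nlevels(partition) < 2L)
    stop("block statistics need at least 2 communities", call. = FALSE)
  K <- nlevels(partition)
  lv <- levels(partition)
  out <- matrix(NA_real_, K, K, dimnames = list(lv, lv))
  counts <- matrix(0L, K, K, dimnames = list(lv, lv))
  ut <- upper.tri(mat)
  qual <- if (sign == "positive") mat > 0 else mat < 0
  for (a in seq_len(K)) for (b in a:K) {
    in_a <- partition == lv[a]; in_b <- partition == lv[b]
    block <- (outer(in_a, in_b) | outer(in_b, in_a)) & ut
    sel <- block & qual
    counts[a, b] <- counts[b, a] <- sum(sel)
    if (any(sel)) {
      m <- mean(mat[sel])
      out[a, b] <- out[b, a] <- if (sign == "negative") abs(m) else m
    }
  }
  attr(out, "counts") <- counts
  out
}

#' Label-permuting null for a partition-dependent statistic
#'
#' Recomputes `statistic_fn` under uniformly random permutations of the
#' node-to-community labels and expresses the observed values as z-scores
#' against the null. p-values are two-sided with the (count + 1)/(n + 1)
#' convention. A zero null sd (e.g. constant input) yields NA z with a
#' diagnostic attribute.
#'
#' @param statistic_fn function(partition) returning a numeric vector or
#'   matrix (constant shape).
#' @param partition named factor node -> community.
#' @param n_perm number of label permutations (>= 100).
#' @param seed RNG seed.
#' @return list with `observed`, `z`, `p`, `null_mean`, `null_sd`,
#'   `null` (n_perm x n_stat matrix).
#' @export
label_permutation_null <- function(statistic_fn, partition, n_perm = 1000,
                                   seed = NULL) {
  n_perm <- check_count(n_perm, "n_perm", 100L)
  partition <- as_partition(partition)
  observed <- statistic_fn(partition)
  obs_vec <- as.vector(observed)
  k <- length(partition)
  null <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) {
      pp <- partition
      pp[] <- partition[sample.int(k)]
      as.vector(statistic_fn(pp))
    }, numeric(length(obs_vec))))
  })
  if (length(obs_vec) == 1L) null <- matrix(null, ncol = 1L)
  # a replicate can leave a block with no qualifying edges (NA); summarize
  # each statistic over its defined replicates
  mu <- colMeans(null, na.rm = TRUE)
  sdv <- apply(null, 2L, stats::sd, na.rm = TRUE)
  z <- (obs_vec - mu) / sdv
  z[!is.finite(z) | (!is.na(sdv) & sdv == 0)] <- NA_real_
  cnt <- colSums(abs(sweep(null, 2L, mu)) >= rep(abs(obs_vec - mu),
                                                 each = nrow(null)),
                 na.rm = TRUE)
  n_def <- colSums(!is.na(null))
  p <- perm_p(cnt, pmax(n_def, 1L))
  p[is.na(obs_vec)] <- NA_real_
  shape_like <- function(v) {
    if (is.matrix(observed))
      matrix(v, nrow(observed), ncol(observed), dimnames = dimnames(observed))
    else stats::setNames(v, names(observed))
  }
  out <- list(observed = observed, z = shape_like(z), p = shape_like(p),
              null_mean = shape_like(mu), null_sd = shape_like(sdv),
              null = null, n_perm = n_perm, seed = seed)
  if (anyNA(z))
    attr(out, "degenerate") <- "zero or undefined null sd: z flagged as NA"
  out
}

#' Mean within- and between-community connectivity
#'
#' Means of the raw signed FC weights over the within-block and
#' between-block edge sets (diagonal excluded).
#'
#' @param fc symmetric FC (or edge-statistic) matrix.
#' @param partition named factor node -> community (>= 2 communities).
#' @return named vector `c(within = , between = )`.
#' @export
within_between_density <- function(fc, partition) {
  fc <- check_matrix(fc, "fc")
  partition <- as_partition(partition, rownames(fc) %||% names(partition))
  if (nlevels(partition) < 2L)
    stop("need at least 2 communities", call. = FALSE)
  same <- outer(as.integer(partition), as.integer(partition), "==")
  ut <- upper.tri(fc)
  c(within = mean(fc[same & ut]), between = mean(fc[!same & ut]))
}

#' Weighted modularity under the configuration model
#'
#' Q = (1/2m) sum_ij [w_ij - s_i s_j / 2m] delta(c_i, c_j) over ordered node
#' pairs (w_ii = 0), with negative weights zeroed, s_i the positive node
#' strength and m the total positive edge weight. `normalize = FALSE` drops
#' the leading 1/2m and returns the bare configuration-model excess, which
#' scales with network size.
#'
#' @param fc symmetric weighted matrix.
#' @param partition named factor node -> community.
#' @param normalize include the 1/2m normalization (default TRUE).
#' @return scalar Q (in [-1, 1] when normalized).
#' @export
modularity <- function(fc, partition, normalize = TRUE) {
  fc <- check_matrix(fc, "fc")
  partition <- as_partition(partition, rownames(fc) %||% names(partition))
  W <- pmax(fc, 0)
  diag(W) <- 0
  two_m <- sum(W)
  if (two_m == 0)
    stop("no positive weights: modularity undefined", call. = FALSE)
  s <- rowSums(W)
  q <- 0
  for (cm in levels(partition)) {
    idx <- which(partition == cm)
    q <- q + sum(W[idx, idx]) - sum(s[idx])^2 / two_m
  }
  if (normalize) q / two_m else q
}

#' System segregation
#'
#' S = (Z_w - Z_b) / Z_w, the normalized difference of the mean within- and
#' between-community connection weights (raw signed means).
#'
#' @param fc symmetric weighted matrix.
#' @param partition named factor node -> community.
#' @return scalar S; errors when Z_w = 0.
#' @export
system_segregation <- function(fc, partition) {
  d <- within_between_density(fc, partition)
  if (d[["within"]] == 0)
    stop("mean within-community weight is zero: segregation undefined",
         call. = FALSE)
  (d[["within"]] - d[["between"]]) / d[["within"]]
}

#' Spearman correlation of a per-session network measure with behaviour
#'
#' @param measures per-session network measure.
#' @param behavior_scores per-session behaviour scores (same length, >= 8).
#' @return list with `r` (Spearman rho) and `p` (asymptotic, two-sided).
#' @export
measure_behavior_correlation <- function(measures, behavior_scores) {
  if (length(measures) != length(behavior_scores) || length(measures) < 8L)
    stop("need paired vectors of at least 8 sessions", call. = FALSE)
  if (stats::sd(measures) == 0 || stats::sd(behavior_scores) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(measures, behavior_scores, method = "spearman",
                        exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value)
}

# Per-session segregation-integration measures from a sessions x edges
# matrix, vectorized across sessions for a given partition. Returns a list
# of per-session vectors. Internal engine shared by the public wrappers and
# the session-consistent null.
session_measures_engine <- function(X, index, partition) {
  within_edge <- as.integer(partition[index$i]) == as.integer(partition[index$j])
  Wpos <- pmax(X, 0)
  # node strengths per session: each positive edge adds to both endpoints
  k <- length(partition)
  p <- nrow(index)
  inc <- matrix(0, p, k)
  inc[cbind(seq_len(p), index$i)] <- 1
  inc[cbind(seq_len(p), index$j)] <- 1
  S <- Wpos %*% inc                       # sessions x nodes
  two_m <- 2 * rowSums(Wpos)
  # community strength sums
  M <- stats::model.matrix(~ 0 + partition)
  Sc <- S %*% M                           # sessions x communities
  within_sum <- Wpos %*% within_edge
  Q <- drop((2 * within_sum - rowSums(Sc^2) / two_m) / two_m)
  Zw <- rowMeans(X[, within_edge, drop = FALSE])
  Zb <- rowMeans(X[, !within_edge, drop = FALSE])
  list(within_density = Zw, between_density = Zb, modularity = Q,
       segregation = (Zw - Zb) / Zw)
}

#' Per-session segregation-integration measures
#'
#' Computes, for every session of an edge dataset, the mean within- and
#' between-community connectivity, the weighted modularity Q and the system
#' segregation S.
#'
#' @param edges an `edge_dataset` (or sessions x edges matrix with an
#'   `index` supplied).
#' @param partition named factor node -> community.
#' @param index [edge_index()] when `edges` is a bare matrix.
#' @return data.frame with one row per session.
#' @export
session_network_measures <- function(edges, partition, index = NULL) {
  if (inherits(edges, "edge_dataset")) { index <- edges$edge_index; X <- edges$X }
  else X <- check_matrix(edges, "edges")
  if (is.null(index)) stop("`index` required for a bare edge matrix", call. = FALSE)
  partition <- as_partition(partition)
  m <- session_measures_engine(X, index, partition)
  data.frame(session_id = rownames(X) %||% seq_len(nrow(X)),
             within_density = m$within_density,
             between_density = m$between_density,
             modularity = m$modularity, segregation = m$segregation,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Session-consistent label-permutation null for measure-behaviour coupling
#'
#' Tests whether the Spearman correlations between behaviour and the four
#' per-session measures (within density, between density, modularity,
#' segregation) depend on the actual community assignment rather than
#' non-specific density fluctuations: each replicate draws one label
#' permutation, applies it identically to every session, and recomputes all
#' four correlations. p per measure is the proportion of null |rho| at or
#' above the observed |rho| (with the +1 convention).
#'
#' @param edges an `edge_dataset`.
#' @param partition named factor node -> community.
#' @param behavior_scores per-session behaviour scores.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list with `observed` (4 rho values), `p`, `null` (n_perm x 4).
#' @export
session_consistent_label_null <- function(edges, partition, behavior_scores,
                                          n_perm = 1000, seed = NULL) {
  stopifnot(inherits(edges, "edge_dataset"))
  n_perm <- check_count(n_perm, "n_perm", 100L)
  X <- edges$X; index <- edges$edge_index
  partition <- as_partition(partition, edges$node_ids)
  if (length(behavior_scores) != nrow(X))
    stop("behaviour scores must have one entry per session", call. = FALSE)
  rb <- rank(behavior_scores)
  spearman4 <- function(part) {
    m <- session_measures_engine(X, index, part)
    vapply(m, function(v) stats::cor(rank(v), rb), numeric(1L))
  }
  observed <- spearman4(partition)
  k <- length(partition)
  null <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) {
      pp <- partition
      pp[] <- partition[sample.int(k)]
      spearman4(pp)
    }, numeric(4L)))
  })
  colnames(null) <- names(observed)
  p <- perm_p(colSums(abs(null) >= rep(abs(observed), each = n_perm)), n_perm)
  list(observed = observed, p = p, null = null, n_perm = n_perm, seed = seed)
}

#' Seed-node connectivity fingerprint against a label-permuting null
#'
#' For a chosen seed region, correlates (across sessions) the mean seed-to-
#' community FC with a positive-mood score, for every community. The null
#' permutes the community labels of all non-seed nodes (the seed keeps its
#' label and is excluded from every community average) and pools the
#' resulting null correlations into a single distribution; observed
#' correlations are expressed as z-scores against the pool, with two-sided
#' pooled p-values.
#'
#' @param fc_list list of per-session FC matrices (shared node set).
#' @param seed_node seed node label.
#' @param partition named factor node -> community.
#' @param positive_mood per-session positive-mood scores (non-constant).
#' @param n_perm number of label permutations (>= 100).
#' @param seed RNG seed.
#' @return list with per-community `observed` r, `z`, `p`, and the pooled
#'   `null` vector.
#' @export
seed_fingerprint_analysis <- function(fc_list, seed_node, partition,
                                      positive_mood, n_perm = 1000,
                                      seed = NULL) {
  n_perm <- check_count(n_perm, "n_perm", 100L)
  if (stats::sd(positive_mood) == 0)
    stop("constant mood vector: correlation undefined", call. = FALSE)
  nodes <- rownames(fc_list[[1L]])
  partition <- as_partition(partition, nodes)
  if (!seed_node %in% nodes) stop("unknown seed node: ", seed_node, call. = FALSE)
  if (length(fc_list) != length(positive_mood))
    stop("one mood score per session required", call. = FALSE)
  # sessions x nodes matrix of the seed's FC row (seed column dropped)
  others <- setdiff(nodes, seed_node)
  Fmat <- t(vapply(fc_list, function(fc) fc[seed_node, others],
                   numeric(length(others))))
  part_others <- partition[others]
  lv <- levels(partition)
  comm_r <- function(po) {
    vapply(lv, function(cm) {
      members <- which(po == cm)
      if (length(members) == 0L) return(NA_real_)
      stats::cor(rowMeans(Fmat[, members, drop = FALSE]), positive_mood)
    }, numeric(1L))
  }
  observed <- comm_r(part_others)
  null <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(b) {
      comm_r(part_others[sample.int(length(part_others))])
    }))
  })
  null <- null[is.finite(null)]
  z <- (observed - mean(null)) / stats::sd(null)
  p <- vapply(observed, function(r)
    perm_p(sum(abs(null) >= abs(r)), length(null)), numeric(1L))
  list(observed = observed, z = z, p = stats::setNames(p, lv),
       null = null, n_perm = n_perm, seed = seed)
}
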