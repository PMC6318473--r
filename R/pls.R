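# Behavioural PLS: SVD of the cross-correlation between a standardized
# sessions x edges block X and a standardized sessions x scales block Y.
# Each latent variable pairs an edge pattern u with a scale pattern v whose
# session projections maximally covary.

#' Column-wise standardization
#'
#' Centers and scales every column to mean 0, sd 1 (denominator n - 1).
#' Zero-variance columns are a hard error, never silently dropped.
#'
#' @param M numeric matrix with at least 3 rows.
#' @return matrix with attributes `scaled:center` and `scaled:scale`.
#' @export
standardize_columns <- function(M) {
  M <- check_matrix(M, "M")
  if (nrow(M) < 3L) stop("need at least 3 rows to standardize", call. = FALSE)
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(M) %||% as.character(seq_len(ncol(M)))
    stop("zero-variance column(s): ", paste(bad[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  scale(M, center = TRUE, scale = sds)
}

#' Cross-correlation matrix between two standardized blocks
#'
#' R = Xz' Yz / (n - 1). With both blocks standardized every entry is a
#' plain Pearson correlation; singular vectors and effect sizes are
#' invariant to the 1/(n-1) constant, so it is kept for interpretability.
#'
#' @param Xz,Yz standardized matrices with equal row counts.
#' @return p x q matrix of correlations.
#' @export
cross_correlation <- function(Xz, Yz) {
  Xz <- check_matrix(Xz, "Xz"); Yz <- check_matrix(Yz, "Yz")
  if (nrow(Xz) != nrow(Yz))
    stop(sprintf("row-count mismatch: %d vs %d", nrow(Xz), nrow(Yz)), call. = FALSE)
  crossprod(Xz, Yz) / (nrow(Xz) - 1L)
}

#' Singular value decomposition of a cross-correlation matrix
#'
#' @param R finite numeric matrix (edges x scales).
#' @return list with `u` (p x r), `v` (q x r), `d` (non-increasing singular
#'   values), r = min(p, q).
#' @export
pls_svd <- function(R) {
  R <- check_matrix(R, "R")
  if (!all(is.finite(R))) stop("`R` contains non-finite entries", call. = FALSE)
  s <- svd(R)
  list(u = s$u, v = s$v, d = s$d)
}

#' Effect size of each latent variable
#'
#' eta_i = sigma_i^2 / sum_j sigma_j^2: the fraction of total cross-block
#' covariance a latent variable accounts for.
#'
#' @param sigmas non-negative singular values, at least one positive.
#' @return vector of fractions summing to 1.
#' @export
effect_size <- function(sigmas) {
  if (any(sigmas < 0)) stop("singular values must be non-negative", call. = FALSE)
  tot <- sum(sigmas^2)
  if (tot == 0) stop("all singular values are zero: effect size undefined", call. = FALSE)
  sigmas^2 / tot
}

#' Per-session latent scores
#'
#' Projects each session's standardized data onto a latent variable's
#' singular vectors: x_scores = Xz u, y_scores = Yz v. The correlation of
#' the two score vectors is the brain-behaviour score correlation.
#'
#' @param Xz,Yz standardized blocks.
#' @param u,v singular vectors conforming to the block widths.
#' @return list with `x_scores` and `y_scores`.
#' @export
session_scores <- function(Xz, Yz, u, v) {
  if (ncol(Xz) != length(u) || ncol(Yz) != length(v))
    stop("singular vector length does not match block width", call. = FALSE)
  list(x_scores = drop(Xz %*% u), y_scores = drop(Yz %*% v))
}

#' Scale loadings: correlation of raw mood scales with network scores
#'
#' @param Y raw (unstandardized) sessions x scales matrix.
#' @param x_scores per-session network scores.
#' @return named vector of Pearson correlations; constant scale columns are
#'   flagged as NA with a warning.
#' @export
scale_loadings <- function(Y, x_scores) {
  Y <- check_matrix(Y, "Y")
  if (nrow(Y) < 4L) stop("need at least 4 sessions for loadings", call. = FALSE)
  sds <- apply(Y, 2L, stats::sd)
  out <- rep(NA_real_, ncol(Y))
  names(out) <- colnames(Y)
  ok <- sds > 0
  if (any(!ok)) warning("constant scale column(s): loading undefined (NA)", call. = FALSE)
  out[ok] <- drop(stats::cor(Y[, ok, drop = FALSE], x_scores))
  out
}

#' Fit a behavioural PLS model
#'
#' Standardizes both blocks, computes the cross-correlation matrix, takes
#' its SVD, and derives effect sizes, per-session scores and scale loadings
#' for every latent variable.
#'
#' SVD signs are arbitrary; each (u, v) pair is flipped jointly so the sum
#' of v over the anchor scales is non-negative. With the default anchor
#' ("positive_affect" when present, else all scales) positive edge weights
#' consistently align with positive mood.
#'
#' @param X sessions x edges matrix or an `edge_dataset`.
#' @param Y sessions x scales mood matrix.
#' @param anchor character vector of Y column names fixing the sign
#'   convention.
#' @return object of class `pls_model`: `u`, `v`, `d`, `eta`, `x_scores`,
#'   `y_scores` (columns = latent variables), `loadings` (scales x LVs,
#'   LV-wise correlations of raw scales with x_scores), standardization
#'   parameters, `n_sessions`.
#' @export
pls_fit <- function(X, Y, anchor = NULL) {
  if (inherits(X, "edge_dataset")) X <- X$X
  X <- check_matrix(X, "X"); Y <- check_matrix(Y, "Y")
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same sessions", call. = FALSE)
  Xz <- standardize_columns(X)
  Yz <- standardize_columns(Y)
  R <- cross_correlation(Xz, Yz)
  s <- pls_svd(R)
  if (is.null(anchor))
    anchor <- if ("positive_affect" %in% colnames(Y)) "positive_affect" else colnames(Y) %||% seq_len(ncol(Y))
  a_idx <- if (is.character(anchor)) match(anchor, colnames(Y)) else anchor
  if (anyNA(a_idx)) stop("anchor scale(s) not found in Y", call. = FALSE)
  for (l in seq_along(s$d)) {
    if (sum(s$v[a_idx, l]) < 0) {
      s$u[, l] <- -s$u[, l]
      s$v[, l] <- -s$v[, l]
    }
  }
  xs <- Xz %*% s$u
  ys <- Yz %*% s$v
  loadings <- stats::cor(Y, xs)
  dimnames(s$u) <- list(colnames(X), paste0("LV", seq_along(s$d)))
  dimnames(s$v) <- list(colnames(Y), paste0("LV", seq_along(s$d)))
  colnames(xs) <- colnames(ys) <- colnames(loadings) <- paste0("LV", seq_along(s$d))
  structure(list(
    u = s$u, v = s$v, d = s$d, eta = effect_size(s$d),
    x_scores = xs, y_scores = ys, loadings = loadings,
    x_center = attr(Xz, "scaled:center"), x_scale = attr(Xz, "scaled:scale"),
    y_center = attr(Yz, "scaled:center"), y_scale = attr(Yz, "scaled:scale"),
    anchor = anchor, n_sessions = nrow(X)
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  r1 <- stats::cor(x$x_scores[, 1L], x$y_scores[, 1L])
  cat(sprintf("Behavioural PLS model: %d sessions, %d edges, %d scales\n",
              x$n_sessions, nrow(x$u), nrow(x$v)))
  cat(sprintf("LV1: sigma = %.3f, covariance explained = %.1f%%, score r = %.2f\n",
              x$d[1L], 100 * x$eta[1L], r1))
  invisible(x)
}

#' Project new sessions onto a fitted PLS model
#'
#' New data are standardized with the training-set means and sds (never
#' their own), so held-out projections are leakage-free.
#'
#' @param model a `pls_model`.
#' @param X,Y new sessions' raw blocks (either may be NULL).
#' @param lv latent variable index.
#' @return list with `x_scores` and/or `y_scores`.
#' @export
pls_project <- function(model, X = NULL, Y = NULL, lv = 1L) {
  out <- list()
  if (!is.null(X)) {
    Xz <- scale(X, center = model$x_center, scale = model$x_scale)
    out$x_scores <- drop(Xz %*% model$u[, lv])
  }
  if (!is.null(Y)) {
    Yz <- scale(Y, center = model$y_center, scale = model$y_scale)
    out$y_scores <- drop(Yz %*% model$v[, lv])
  }
  out
}

#' The 13 PANAS-X mood scales
#'
#' Two general dimension scales (negative and positive affect) and 11
#' specific scales, the standard distillation of the 60-item schedule.
#'
#' @return character vector of 13 scale names.
#' @export
panasx_scales <- function() {
  c("negative_affect", "positive_affect", "fear", "hostility", "guilt",
    "sadness", "joviality", "self_assurance", "attentiveness", "shyness",
    "fatigue", "serenity", "surprise")
}

#' Score mood scales from item-level ratings
#'
#' Each scale is the mean of its items' ratings. The item-to-scale map is
#' user-supplied (the schedule's item wording is not redistributable).
#'
#' @param items sessions x items numeric matrix of ratings.
#' @param map named list: scale name -> character vector of item columns.
#' @param range allowed rating range, default the 0-5 Likert scale.
#' @return sessions x scales matrix, one column per scale in `map`.
#' @export
score_scales <- function(items, map, range = c(0, 5)) {
  items <- check_matrix(items, "items")
  all_items <- unique(unlist(map))
  missing <- setdiff(all_items, colnames(items))
  if (length(missing))
    stop("mapped item(s) absent from the item table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  used <- items[, all_items, drop = FALSE]
  if (any(used < range[1L] | used > range[2L]))
    stop(sprintf("item ratings outside the declared range [%g, %g]",
                 range[1L], range[2L]), call. = FALSE)
  out <- vapply(map, function(cols) rowMeans(items[, cols, drop = FALSE]),
                numeric(nrow(items)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(items),
                                     dimnames = list(rownames(items), names(map)))
  rownames(out) <- rownames(items)
  out
}
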