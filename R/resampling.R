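# Inference around the decomposition: permutation significance of the
# singular values, bootstrap reliability of the weights, split-half pattern
# stability, and out-of-sample cross-validation of the score pairing.
# All p-values use the (count + 1)/(n + 1) convention, so they are valid
# finite-sample p-values and never exactly zero.

perm_p <- function(count, n) (count + 1) / (n + 1)

#' Permutation test of latent-variable significance
#'
#' The rows of X are randomly permuted, breaking the session pairing with Y;
#' the cross-correlation matrix and its singular values are recomputed for
#' each replicate. Per latent variable, p is the proportion of null singular
#' values at the same rank that reach the observed one. (Column means and
#' sds are invariant to row order, so permuting the standardized X is
#' identical to re-standardizing the permuted raw X.)
#'
#' @param X sessions x edges matrix or `edge_dataset`.
#' @param Y sessions x scales matrix.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param max_sigma_null if TRUE, compare every observed singular value to
#'   the null distribution of the largest singular value instead of the
#'   rank-matched one.
#' @return object of class `pls_permutation`: `observed` singular values,
#'   `null` (n_perm x r), `p`, `n_perm`, `seed`.
#' @export
permutation_test <- function(X, Y, n_perm = 1000, seed = NULL,
                             max_sigma_null = FALSE) {
  if (inherits(X, "edge_dataset")) X <- X$X
  n_perm <- check_count(n_perm, "n_perm", 100L)
  Xz <- standardize_columns(X)
  Yz <- standardize_columns(Y)
  n <- nrow(Xz)
  obs <- svd(cross_correlation(Xz, Yz), nu = 0, nv = 0)$d
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      svd(crossprod(Xz[sample.int(n), , drop = FALSE], Yz) / (n - 1),
          nu = 0, nv = 0)$d
    }, numeric(length(obs)))
  })
  null <- matrix(null, nrow = n_perm, ncol = length(obs), byrow = TRUE)
  cmp <- if (max_sigma_null) matrix(apply(null, 1L, max), n_perm, length(obs)) else null
  p <- perm_p(colSums(sweep(cmp, 2L, obs, ">=")), n_perm)
  structure(list(observed = obs, null = null, p = p, n_perm = n_perm,
                 seed = seed, max_sigma_null = max_sigma_null),
            class = "pls_permutation")
}

#' @export
print.pls_permutation <- function(x, ...) {
  cat(sprintf("PLS permutation test (%d permutations)\n", x$n_perm))
  cat(sprintf("LV1: sigma = %.3f, p = %.4g\n", x$observed[1L], x$p[1L]))
  invisible(x)
}

#' Bootstrap ratio
#'
#' A weight divided by its bootstrap-estimated standard error; a z-like
#' reliability statistic for an edge or scale.
#'
#' @param w original-sample weight(s).
#' @param se bootstrap standard error(s).
#' @return w / se, with 0/0 defined as 0 and se = 0 for a nonzero weight
#'   flagged as NA.
#' @export
bootstrap_ratio <- function(w, se) {
  out <- ifelse(se > 0, w / se, ifelse(w == 0, 0, NA_real_))
  if (anyNA(out)) warning("zero bootstrap SE for nonzero weight(s): NA flagged",
                          call. = FALSE)
  out
}

#' Bootstrap reliability of PLS weights
#'
#' Sessions (rows of X and Y jointly) are resampled with replacement; the
#' decomposition is recomputed per replicate and each latent variable's
#' (u, v) pair is reflected to align with the original fit (joint sign flip
#' when the u dot product is negative). The bootstrap ratio divides the
#' original-sample weight by the bootstrap standard deviation; loading
#' confidence intervals are percentile 2.5/97.5 over replicates.
#'
#' @param X sessions x edges matrix or `edge_dataset`.
#' @param Y sessions x scales matrix.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @param lv latent variable index to summarize.
#' @param numerator `"original"` (the original weight, default) or
#'   `"bootstrap_mean"`.
#' @param re_standardize re-standardize each resample (default TRUE).
#' @return object of class `pls_bootstrap`: `bsr` (per-edge bootstrap
#'   ratios), `v_bsr` (per-scale), `loading_ci` (scales x 2),
#'   `u_se`, `n_discarded`, `n_boot`, `seed`.
#' @export
pls_bootstrap <- function(X, Y, n_boot = 1000, seed = NULL, lv = 1L,
                          numerator = c("original", "bootstrap_mean"),
                          re_standardize = TRUE) {
  if (inherits(X, "edge_dataset")) X <- X$X
  n_boot <- check_count(n_boot, "n_boot", 100L)
  numerator <- match.arg(numerator)
  n <- nrow(X)
  if (n < 10L) stop("bootstrap needs at least 10 sessions", call. = FALSE)
  fit <- pls_fit(X, Y)
  u0 <- fit$u[, lv]; v0 <- fit$v[, lv]
  u_rep <- matrix(NA_real_, n_boot, length(u0))
  v_rep <- matrix(NA_real_, n_boot, length(v0))
  load_rep <- matrix(NA_real_, n_boot, ncol(Y))
  n_discard <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(idx)) < 2L) { n_discard <- n_discard + 1L; next }
      Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      res <- tryCatch({
        Xzb <- if (re_standardize) standardize_columns(Xb) else
          scale(Xb, fit$x_center, fit$x_scale)
        Yzb <- if (re_standardize) standardize_columns(Yb) else
          scale(Yb, fit$y_center, fit$y_scale)
        s <- svd(cross_correlation(Xzb, Yzb))
        ub <- s$u[, lv]; vb <- s$v[, lv]
        if (sum(ub * u0) < 0) { ub <- -ub; vb <- -vb }
        xs <- drop(Xzb %*% ub)
        list(u = ub, v = vb, load = drop(stats::cor(Yb, xs)))
      }, error = function(e) NULL)
      if (is.null(res)) { n_discard <- n_discard + 1L; next }
      u_rep[b, ] <- res$u; v_rep[b, ] <- res$v; load_rep[b, ] <- res$load
    }
  })
  if (n_discard > 0.01 * n_boot)
    warning(sprintf("%d of %d bootstrap replicates discarded as degenerate",
                    n_discard, n_boot), call. = FALSE)
  keep <- stats::complete.cases(u_rep)
  u_se <- apply(u_rep[keep, , drop = FALSE], 2L, stats::sd)
  v_se <- apply(v_rep[keep, , drop = FALSE], 2L, stats::sd)
  wu <- if (numerator == "original") u0 else colMeans(u_rep[keep, , drop = FALSE])
  wv <- if (numerator == "original") v0 else colMeans(v_rep[keep, , drop = FALSE])
  ci <- t(apply(load_rep[keep, , drop = FALSE], 2L, stats::quantile,
                probs = c(0.025, 0.975)))
  dimnames(ci) <- list(colnames(Y), c("lo", "hi"))
  structure(list(bsr = stats::setNames(bootstrap_ratio(wu, u_se), names(u0)),
                 v_bsr = stats::setNames(bootstrap_ratio(wv, v_se), names(v0)),
                 loading_ci = ci, u_se = u_se, v_se = v_se,
                 n_discarded = n_discard, n_boot = n_boot, lv = lv,
                 seed = seed),
            class = "pls_bootstrap")
}

#' Split-half stability of the latent patterns
#'
#' Sessions are repeatedly divided into halves (sizes differing by at most
#' one); each half's cross-correlation matrix R_h is projected onto the
#' full-sample singular vectors, U_h = R_h V S^-1 and V_h = R_h' U S^-1,
#' and the per-latent-variable correlation between the two halves'
#' projected patterns is recorded.
#'
#' @param X sessions x edges matrix or `edge_dataset`.
#' @param Y sessions x scales matrix.
#' @param n_splits number of random splits (>= 100).
#' @param seed RNG seed.
#' @return object of class `pls_stability`: `u_corr`, `v_corr`
#'   (n_splits x r), `mean_u_corr`, `mean_v_corr`, 95% percentile CIs.
#' @export
split_half_stability <- function(X, Y, n_splits = 1000, seed = NULL) {
  if (inherits(X, "edge_dataset")) X <- X$X
  n_splits <- check_count(n_splits, "n_splits", 100L)
  n <- nrow(X)
  if (n < 8L) stop("split-half stability needs at least 8 sessions", call. = FALSE)
  fit <- pls_fit(X, Y)
  keep_lv <- which(fit$d > max(fit$d) * 1e-10)
  if (length(keep_lv) < length(fit$d))
    message("excluding ", length(fit$d) - length(keep_lv),
            " latent variable(s) with numerically zero singular value")
  U <- fit$u[, keep_lv, drop = FALSE]
  V <- fit$v[, keep_lv, drop = FALSE]
  dinv <- 1 / fit$d[keep_lv]
  n1 <- ceiling(n / 2)
  half_proj <- function(rows) {
    Rh <- cross_correlation(standardize_columns(X[rows, , drop = FALSE]),
                            standardize_columns(Y[rows, , drop = FALSE]))
    list(U = Rh %*% V %*% diag(dinv, length(dinv)),
         V = crossprod(Rh, U) %*% diag(dinv, length(dinv)))
  }
  res <- with_seed(seed, {
    lapply(seq_len(n_splits), function(s) {
      h1 <- sample.int(n, n1)
      p1 <- half_proj(h1); p2 <- half_proj(setdiff(seq_len(n), h1))
      list(u = diag(stats::cor(p1$U, p2$U)), v = diag(stats::cor(p1$V, p2$V)))
    })
  })
  u_corr <- do.call(rbind, lapply(res, `[[`, "u"))
  v_corr <- do.call(rbind, lapply(res, `[[`, "v"))
  ci <- function(m) apply(m, 2L, stats::quantile, probs = c(0.025, 0.975))
  structure(list(u_corr = u_corr, v_corr = v_corr,
                 mean_u_corr = colMeans(u_corr), mean_v_corr = colMeans(v_corr),
                 u_ci = ci(u_corr), v_ci = ci(v_corr),
                 n_splits = n_splits, seed = seed, lv_kept = keep_lv),
            class = "pls_stability")
}

#' Out-of-sample cross-validation of the score pairing
#'
#' Repeated random train/test splits; the model (including standardization
#' parameters) is fit on the training sessions only, held-out sessions are
#' projected onto the first latent variable's singular vectors, and the
#' correlation between held-out network and mood scores is recorded. The
#' test-set size is `ceiling(test_fraction * n)`. Significance is assessed
#' by permuting X's rows and repeating the whole procedure.
#'
#' @param X sessions x edges matrix or `edge_dataset`.
#' @param Y sessions x scales matrix.
#' @param n_splits number of train/test splits (>= 10).
#' @param test_fraction fraction of sessions held out, in (0, 0.5).
#' @param seed RNG seed.
#' @param n_perm permutation replicates for the p-value (0 = skip).
#' @return object of class `pls_cv`: `split_r`, `mean_r`, `n_test`, `p`
#'   (NA when n_perm = 0), `n_splits`, `seed`.
#' @export
out_of_sample_cv <- function(X, Y, n_splits = 100, test_fraction = 0.25,
                             seed = NULL, n_perm = 0) {
  if (inherits(X, "edge_dataset")) X <- X$X
  n_splits <- check_count(n_splits, "n_splits", 10L)
  if (test_fraction <= 0 || test_fraction >= 0.5)
    stop("`test_fraction` must lie in (0, 0.5)", call. = FALSE)
  n <- nrow(X)
  n_test <- as.integer(ceiling(test_fraction * n))
  if (n_test < 3L) stop("test sets would have fewer than 3 sessions", call. = FALSE)
  cv_mean_r <- function(Xm, test_sets) {
    r <- vapply(test_sets, function(test) {
      train <- setdiff(seq_len(n), test)
      fit <- pls_fit(Xm[train, , drop = FALSE], Y[train, , drop = FALSE])
      pr <- pls_project(fit, Xm[test, , drop = FALSE], Y[test, , drop = FALSE])
      stats::cor(pr$x_scores, pr$y_scores)
    }, numeric(1L))
    r
  }
  with_seed(seed, {
    test_sets <- lapply(seq_len(n_splits), function(s) sample.int(n, n_test))
    split_r <- cv_mean_r(X, test_sets)
    p <- NA_real_
    if (n_perm > 0) {
      n_perm <- check_count(n_perm, "n_perm", 1L)
      null_r <- vapply(seq_len(n_perm), function(b) {
        mean(cv_mean_r(X[sample.int(n), , drop = FALSE], test_sets))
      }, numeric(1L))
      p <- perm_p(sum(null_r >= mean(split_r)), n_perm)
    }
  })
  structure(list(split_r = split_r, mean_r = mean(split_r), n_test = n_test,
                 p = p, n_splits = n_splits, test_fraction = test_fraction,
                 seed = seed),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("out-of-sample CV: mean r = %.3f over %d splits (%d test sessions)\n",
              x$mean_r, x$n_splits, x$n_test))
  if (!is.na(x$p)) cat(sprintf("permutation p = %.4g\n", x$p))
  invisible(x)
}
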