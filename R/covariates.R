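# Session-covariate analyses: fasting contrasts on the PLS scores,
# per-group score correlations with a Fisher difference test, and
# FDR-corrected lifestyle regressions.

#' Two-group contrast of per-session scores
#'
#' Pooled-variance (Student) two-sample t-test, df = n1 + n2 - 2. The
#' contrast is group 1 minus group 0.
#'
#' @param scores per-session scores.
#' @param group binary indicator (0/1, logical, or two-level factor).
#' @return object of class `group_contrast`: `t_statistic`, `df`, `p_value`,
#'   `group_means`, `group_ns`.
#' @export
group_compare_scores <- function(scores, group) {
  g <- as_binary_group(group, length(scores))
  n1 <- sum(g == 1L); n0 <- sum(g == 0L)
  if (n1 < 2L || n0 < 2L)
    stop("each group needs at least 2 sessions", call. = FALSE)
  tt <- stats::t.test(scores[g == 1L], scores[g == 0L], var.equal = TRUE)
  structure(list(t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 group_means = c(g1 = mean(scores[g == 1L]),
                                 g0 = mean(scores[g == 0L])),
                 group_ns = c(g1 = n1, g0 = n0)),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("t(%d) = %.2f, p = %.3g\n", x$df, x$t_statistic, x$p_value))
  invisible(x)
}

as_binary_group <- function(group, n) {
  if (length(group) != n) stop("group indicator length mismatch", call. = FALSE)
  if (is.factor(group) || is.character(group)) {
    lv <- unique(as.character(group))
    if (length(lv) != 2L) stop("group must have exactly 2 levels", call. = FALSE)
    return(as.integer(as.character(group) == lv[1L]))
  }
  g <- as.integer(group)
  if (!all(g %in% c(0L, 1L))) stop("group must be binary 0/1", call. = FALSE)
  g
}

#' Compare the score correlation between two groups (Fisher's test)
#'
#' Pearson r between network and mood scores within each group; the
#' difference is tested with the Fisher z transform:
#' z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)), two-sided normal p.
#'
#' @param x_scores,y_scores per-session network and mood scores.
#' @param group binary indicator (group 1 vs group 0).
#' @return object of class `correlation_comparison`: `r1`, `n1`, `r2`, `n2`,
#'   `fisher_z`, `p_value`.
#' @export
per_group_score_correlation <- function(x_scores, y_scores, group) {
  g <- as_binary_group(group, length(x_scores))
  n1 <- sum(g == 1L); n2 <- sum(g == 0L)
  if (n1 < 4L || n2 < 4L)
    stop("Fisher transform needs at least 4 sessions per group", call. = FALSE)
  r1 <- stats::cor(x_scores[g == 1L], y_scores[g == 1L])
  r2 <- stats::cor(x_scores[g == 0L], y_scores[g == 0L])
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| = 1: Fisher transform undefined", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, fisher_z = z,
                 p_value = 2 * stats::pnorm(-abs(z))),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("r1 = %.2f (n = %d), r2 = %.2f (n = %d); Fisher z = %.2f, p = %.3g\n",
              x$r1, x$n1, x$r2, x$n2, x$fisher_z, x$p_value))
  invisible(x)
}

#' Per-covariate lifestyle regressions with FDR correction
#'
#' One simple linear regression of each score type on each covariate;
#' Benjamini-Hochberg adjustment across the whole covariate x score-type
#' family. Constant covariates are excluded from the family with a warning.
#'
#' @param scores named list of per-session score vectors (e.g.
#'   `list(mood = ..., network = ...)`), or a single vector.
#' @param covariate_table data.frame of numeric covariates (non-numeric
#'   columns such as `session_id` are ignored).
#' @return data.frame with `score_type`, `covariate`, `slope`, `p`, `q`.
#' @export
lifestyle_regression <- function(scores, covariate_table) {
  if (!is.list(scores)) scores <- list(score = scores)
  num <- vapply(covariate_table, is.numeric, logical(1L))
  covs <- covariate_table[num]
  const <- vapply(covs, function(v) stats::sd(v) == 0, logical(1L))
  if (any(const)) {
    warning("constant covariate(s) excluded: ",
            paste(names(covs)[const], collapse = ", "), call. = FALSE)
    covs <- covs[!const]
  }
  rows <- list()
  for (st in names(scores)) for (cv in names(covs)) {
    fit <- stats::lm(scores[[st]] ~ covs[[cv]])
    cf <- summary(fit)$coefficients
    rows[[length(rows) + 1L]] <- data.frame(
      score_type = st, covariate = cv,
      slope = cf[2L, 1L], p = cf[2L, 4L], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
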