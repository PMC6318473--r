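test_that("column standardization gives mean 0, sd 1 and rejects constants", {
  M <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  Z <- standardize_columns(M)
  expect_equal(unname(Z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(Z[, "b"]), c(-1, 0, 1))
  # already standardized input is unchanged
  withr_seed(2)
  M2 <- scale(matrix(rnorm(40), 10, 4))
  expect_equal(standardize_columns(M2), M2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(standardize_columns(cbind(a = c(1, 2, 3), b = c(7, 7, 7))), "b")
})

test_that("cross_correlation returns Pearson correlations", {
  withr_seed(3)
  X <- matrix(rnorm(4 * 2), 4, 2)
  Y <- matrix(rnorm(4 * 2), 4, 2)
  R <- cross_correlation(standardize_columns(X), standardize_columns(Y))
  for (i in 1:2) for (j in 1:2)
    expect_equal(R[i, j], cor(X[, i], Y[, j]))
  # shared column -> entry exactly 1
  Y2 <- Y; Y2[, 1] <- X[, 2]
  R2 <- cross_correlation(standardize_columns(X), standardize_columns(Y2))
  expect_equal(R2[2, 1], 1)
  expect_error(cross_correlation(standardize_columns(X),
                                 standardize_columns(Y[1:3, ])), "mismatch")
})

test_that("pls_svd reconstructs R and orders singular values", {
  s <- pls_svd(diag(c(3, 2)))
  expect_equal(s$d, c(3, 2))
  s2 <- pls_svd(matrix(c(1, 0, 0, 0), 2))
  expect_equal(s2$d, c(1, 0))
  expect_equal(abs(s2$u[, 1]), c(1, 0))

  withr_seed(7)
  R <- matrix(rnorm(18), 6, 3)
  s3 <- pls_svd(R)
  expect_lt(max(abs(s3$u %*% diag(s3$d) %*% t(s3$v) - R)), 1e-10)
  expect_true(all(diff(s3$d) <= 0))
  expect_error(pls_svd(matrix(c(1, NA, 0, 1), 2)), "non-finite")
})

test_that("first latent variable maximizes cross-block covariance", {
  withr_seed(13)
  n <- 20
  X <- matrix(rnorm(n * 8), n, 8)
  Y <- matrix(rnorm(n * 3), n, 3)
  Xz <- standardize_columns(X); Yz <- standardize_columns(Y)
  s <- pls_svd(cross_correlation(Xz, Yz))
  best <- abs(cov(Xz %*% s$u[, 1], Yz %*% s$v[, 1]))
  # brute-force oracle: random unit direction pairs never beat (u1, v1)
  for (i in 1:2000) {
    a <- rnorm(8); a <- a / sqrt(sum(a^2))
    b <- rnorm(3); b <- b / sqrt(sum(b^2))
    expect_lte(abs(cov(Xz %*% a, Yz %*% b)), best + 1e-12)
  }
})

test_that("effect sizes are squared-singular-value fractions", {
  expect_equal(effect_size(c(2, 1, 1)), c(2/3, 1/6, 1/6))
  expect_equal(effect_size(1), 1)
  expect_equal(effect_size(c(3, 4)), c(9/25, 16/25))
  expect_error(effect_size(c(0, 0)), "undefined")
  expect_error(effect_size(c(-1, 2)), "non-negative")
})

test_that("session scores are projections and ignore zero-weight variables", {
  withr_seed(5)
  Xz <- standardize_columns(matrix(rnorm(30), 10, 3))
  Yz <- standardize_columns(matrix(rnorm(20), 10, 2))
  u <- c(0, 1, 0); v <- c(1, 0)
  sc <- session_scores(Xz, Yz, u, v)
  expect_equal(sc$x_scores, unname(Xz[, 2]))
  expect_equal(sc$y_scores, unname(Yz[, 1]))
  # appending zero-weight variables leaves scores untouched
  sc2 <- session_scores(cbind(Xz, Xz[, 1]), Yz, c(u, 0), v)
  expect_equal(sc2$x_scores, sc$x_scores)
  expect_error(session_scores(Xz, Yz, c(1, 2), v), "length")
})

test_that("scale loadings are correlations with network scores", {
  withr_seed(6)
  xs <- rnorm(12)
  Y <- cbind(same = xs, anti = -xs, noise = rnorm(12))
  ld <- scale_loadings(Y, xs)
  expect_equal(ld[["same"]], 1)
  expect_equal(ld[["anti"]], -1)
  expect_equal(ld[["noise"]], cor(Y[, "noise"], xs))
  Yc <- cbind(ok = xs, flat = rep(2, 12))
  expect_warning(ld2 <- scale_loadings(Yc, xs), "constant")
  expect_true(is.na(ld2[["flat"]]))
})

test_that("pls_fit recovers a planted rank-1 pattern and orients to positive affect", {
  cfg <- sim_config(n_sessions = 100, n_nodes = 20, signal_strength = 10,
                    seed = 42)
  sim <- generate_edge_dataset(cfg)
  fit <- pls_fit(sim$edges, sim$mood)
  expect_gt(abs(cor(fit$u[, 1], sim$truth$u_star)), 0.9)
  expect_gt(abs(cor(fit$v[, 1], sim$truth$v_star)), 0.9)
  expect_gt(cor(fit$x_scores[, 1], fit$y_scores[, 1]), 0.8)
  # sign convention: positive_affect weight sum non-negative
  expect_gte(fit$v["positive_affect", 1], 0)
  # eta sums to one
  expect_equal(sum(fit$eta), 1)
  # the dominant planted scale carries the largest |loading|
  expect_equal(names(which.max(abs(fit$loadings[, 1]))), "positive_affect")
})

test_that("pls_fit is equivariant under variable permutation and scale doubling", {
  cfg <- sim_config(n_sessions = 30, n_nodes = 8, signal_strength = 3, seed = 9)
  sim <- generate_edge_dataset(cfg)
  fit <- pls_fit(sim$edges$X, sim$mood)
  perm <- sample(ncol(sim$edges$X))
  fit_p <- pls_fit(sim$edges$X[, perm], sim$mood)
  expect_equal(unname(fit_p$u[, 1]), unname(fit$u[perm, 1]), tolerance = 1e-8)
  # doubling Y columns (re-standardized away) changes nothing
  fit_d <- pls_fit(sim$edges$X, 2 * sim$mood)
  expect_equal(fit_d$u[, 1], fit$u[, 1], tolerance = 1e-10)
  expect_equal(fit_d$v[, 1], fit$v[, 1], tolerance = 1e-10)
  expect_equal(fit_d$eta, fit$eta, tolerance = 1e-12)
})

test_that("effect size of the first LV grows with planted signal strength", {
  eta1 <- vapply(c(1, 2, 5, 10), function(d) {
    mean(vapply(1:8, function(s) {
      sim <- generate_edge_dataset(sim_config(n_sessions = 60, n_nodes = 10,
                                              signal_strength = d, seed = s))
      pls_fit(sim$edges, sim$mood)$eta[1]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(eta1) > 0))
})

test_that("score_scales averages item ratings by scale", {
  items <- cbind(i1 = c(2, 0), i2 = c(4, 0), i3 = c(1, 0))
  rownames(items) <- c("s1", "s2")
  map <- list(calm = c("i1", "i2"), alert = "i3")
  sc <- score_scales(items, map)
  expect_equal(sc["s1", "calm"], 3)
  expect_equal(unname(sc["s2", ]), c(0, 0))
  # brute-force group means on random ratings
  withr_seed(10)
  items2 <- matrix(sample(0:5, 8 * 6, TRUE), 8, 6,
                   dimnames = list(NULL, paste0("q", 1:6)))
  map2 <- list(a = c("q1", "q4"), b = c("q2", "q3", "q5"), c = "q6")
  sc2 <- score_scales(items2, map2)
  for (s in names(map2))
    expect_equal(unname(sc2[, s]), rowMeans(items2[, map2[[s]], drop = FALSE]))
  expect_error(score_scales(items, list(x = "missing_item")), "absent")
  expect_error(score_scales(items + 3, map), "range")
})
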