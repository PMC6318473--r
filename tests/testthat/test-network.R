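test_that("regional means average each node's incident edges", {
  m <- matrix(0, 4, 4, dimnames = rep(list(node_labels(4)), 2))
  m[1, 2:4] <- m[2:4, 1] <- 2
  rm_ <- regional_mean_bsr(m)
  expect_equal(rm_[["n001"]], 2)
  expect_equal(rm_[["n002"]], 2/3)
  expect_equal(unname(regional_mean_bsr(matrix(1.5, 5, 5) - 1.5 * diag(5))),
               rep(1.5, 5))
  r8 <- random_symmetric(8, seed = 2)
  expect_equal(regional_mean_bsr(r8),
               apply(r8, 1, function(row) mean(row[-which(row == 0)[1]])),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("top-fraction node selection uses ceiling and deterministic ties", {
  v <- setNames(1:20, node_labels(20))
  expect_length(top_fraction_nodes(v, 0.05, "positive"), 1L)
  expect_equal(ceiling(0.05 * 630), 32)
  expect_equal(top_fraction_nodes(v, 0.2, "positive"),
               node_labels(20)[20:17])
  expect_equal(top_fraction_nodes(v - 10.5, 0.2, "negative"),
               node_labels(20)[1:4])
  ties <- setNames(rep(1, 10), node_labels(10))
  expect_equal(top_fraction_nodes(ties, 0.3, "positive"), node_labels(10)[1:3])
  expect_error(top_fraction_nodes(v, 1.2), "fraction")
})

test_that("sign-restricted block means mask by sign and flag empty blocks", {
  k <- 6
  part <- factor(c("A", "A", "A", "B", "B", "B")); names(part) <- node_labels(k)
  m <- matrix(-1, k, k, dimnames = rep(list(node_labels(k)), 2))
  m[1:3, 1:3] <- 2
  diag(m) <- 0
  pos <- rsn_block_means(m, part, "positive")
  expect_equal(pos["A", "A"], 2)
  expect_true(is.na(pos["A", "B"]) && is.na(pos["B", "B"]))
  neg <- rsn_block_means(m, part, "negative")
  expect_true(is.na(neg["A", "A"]))
  expect_equal(neg["A", "B"], 1)  # magnitudes
  expect_equal(neg["B", "B"], 1)

  # brute-force masked averaging on a random matrix
  r <- random_symmetric(9, seed = 7)
  p3 <- generate_partition(9, 3, seed = 1, node_ids = rownames(r))
  got <- rsn_block_means(r, p3, "positive")
  for (a in levels(p3)) for (b in levels(p3)) {
    vals <- c()
    for (x in 1:8) for (y in (x + 1):9)
      if (setequal(c(as.character(p3[x]), as.character(p3[y])), unique(c(a, b))))
        vals <- c(vals, r[x, y])
    vals <- vals[vals > 0]
    if (length(vals)) expect_equal(got[a, b], mean(vals))
    else expect_true(is.na(got[a, b]))
  }
  counts <- attr(got, "counts")
  expect_equal(got, t(got), ignore_attr = TRUE)
})

test_that("within/between densities match brute force and simple blocks", {
  k <- 6
  part <- factor(rep(c("A", "B"), each = 3)); names(part) <- node_labels(k)
  m <- matrix(0.2, k, k, dimnames = rep(list(node_labels(k)), 2))
  m[1:3, 1:3] <- 0.8; m[4:6, 4:6] <- 0.8; diag(m) <- 0
  d <- within_between_density(m, part)
  expect_equal(d, c(within = 0.8, between = 0.2))
  # all-equal off-diagonals -> equal means
  e <- matrix(0.3, k, k); diag(e) <- 0
  dimnames(e) <- rep(list(node_labels(k)), 2)
  de <- within_between_density(e, part)
  expect_equal(de[["within"]], de[["between"]])
  # brute force
  r <- random_symmetric(8, seed = 3)
  p <- generate_partition(8, 3, seed = 5, node_ids = rownames(r))
  got <- within_between_density(r, p)
  w <- b <- c()
  for (x in 1:7) for (y in (x + 1):8) {
    if (p[x] == p[y]) w <- c(w, r[x, y]) else b <- c(b, r[x, y])
  }
  expect_equal(got, c(within = mean(w), between = mean(b)))
})

test_that("modularity follows the configuration model closed form", {
  W <- matrix(0, 4, 4, dimnames = rep(list(node_labels(4)), 2))
  W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  part2 <- factor(c("A", "A", "B", "B")); names(part2) <- node_labels(4)
  expect_equal(modularity(W, part2), 0.5)
  one <- factor(rep("A", 4)); names(one) <- node_labels(4)
  expect_equal(modularity(W, one), 0, tolerance = 1e-12)
  # unnormalized flag reproduces the bare sum (0.5 * 2m = 2 here)
  expect_equal(modularity(W, part2, normalize = FALSE), 2)

  # brute-force double loop on a random positive-clipped graph
  r <- abs(random_symmetric(9, seed = 11))
  p <- generate_partition(9, 3, seed = 3, node_ids = rownames(r))
  Wp <- pmax(r, 0); diag(Wp) <- 0
  s <- rowSums(Wp); two_m <- sum(Wp)
  q <- 0
  for (x in 1:9) for (y in 1:9)
    if (p[x] == p[y]) q <- q + Wp[x, y] - s[x] * s[y] / two_m
  expect_equal(modularity(r, p), unname(q / two_m), tolerance = 1e-12)
  expect_error(modularity(-abs(r), p), "no positive weights")

  # random graph + random partition: |Q| small on average
  qs <- vapply(1:100, function(s1) {
    rr <- abs(random_symmetric(10, seed = s1))
    modularity(rr, generate_partition(10, 3, seed = s1 + 1000,
                                      node_ids = rownames(rr)))
  }, numeric(1))
  expect_lt(mean(abs(qs)), 0.1)
})

test_that("modularity and segregation are invariant to community relabeling", {
  r <- abs(random_symmetric(10, seed = 4))
  p <- generate_partition(10, 3, seed = 2, node_ids = rownames(r))
  p2 <- factor(as.character(p), levels = levels(p),
               labels = c("zeta", "alpha", "mid"))
  names(p2) <- names(p)
  expect_equal(modularity(r, p2), modularity(r, p))
  expect_equal(system_segregation(r, p2), system_segregation(r, p))
})

test_that("system segregation is the normalized within/between difference", {
  k <- 6
  part <- factor(rep(c("A", "B"), each = 3)); names(part) <- node_labels(k)
  mk <- function(w, b) {
    m <- matrix(b, k, k); m[1:3, 1:3] <- w; m[4:6, 4:6] <- w; diag(m) <- 0
    dimnames(m) <- rep(list(node_labels(k)), 2); m
  }
  expect_equal(system_segregation(mk(0.5, 0.25), part), 0.5)
  expect_equal(system_segregation(mk(0.4, 0.4), part), 0)
  expect_equal(system_segregation(mk(0.4, 0), part), 1)
  # strictly decreasing in between-coupling at fixed within-coupling
  ss <- vapply(c(0, 0.1, 0.2, 0.3), function(b)
    system_segregation(mk(0.5, b), part), numeric(1))
  expect_true(all(diff(ss) < 0))
})

test_that("planted two-block structure beats its own label-permuted nulls", {
  part <- generate_partition(10, 2, seed = 1)
  cfg <- sim_config(n_sessions = 8, n_nodes = 10, n_timepoints = 600,
                    within_coupling = 0.6, between_coupling = 0.05,
                    modulation_gain = 0, seed = 1)
  fc <- fc_matrix(generate_session_timeseries(cfg, part, 0, seed = 2))
  q_obs <- modularity(fc, part)
  q_null <- with_seed_local(5, vapply(1:300, function(i) {
    pp <- part; pp[] <- part[sample.int(10)]
    modularity(fc, pp)
  }, numeric(1)))
  expect_gt(q_obs, mean(q_null))
  # strong planted blocks dominate every null (permutations equivalent to the
  # planted split can tie, never exceed)
  expect_gte(q_obs, max(q_null))
})

test_that("label-permutation null detects planted within-block elevation", {
  det <- vapply(1:25, function(s) {
    r <- random_symmetric(12, seed = s)
    p <- generate_partition(12, 3, seed = 100 + s)
    idx <- which(p == "C1")
    r[idx, idx] <- r[idx, idx] + 3
    diag(r) <- 0
    ln <- label_permutation_null(
      function(pp) within_between_density(r, pp)[["within"]], p,
      n_perm = 200, seed = 200 + s)
    ln$z[[1]]
  }, numeric(1))
  expect_gte(mean(det > 2), 0.95)

  # constant input -> undefined z, explicit flag
  const <- matrix(1, 8, 8); diag(const) <- 0
  dimnames(const) <- rep(list(node_labels(8)), 2)
  pc <- generate_partition(8, 2, seed = 1)
  lnc <- label_permutation_null(
    function(pp) within_between_density(const, pp)[["within"]], pc,
    n_perm = 100, seed = 3)
  expect_true(is.na(lnc$z[[1]]))
  expect_match(attr(lnc, "degenerate"), "NA")
})

test_that("Spearman measure-behaviour correlation matches rank arithmetic", {
  b <- c(3, 1, 4, 1.5, 5, 9, 2.6, 5.3)
  expect_equal(measure_behavior_correlation(b, b)$r, 1)
  expect_equal(measure_behavior_correlation(-b, b)$r, -1)
  withr_seed(6)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(measure_behavior_correlation(x, y)$r,
               cor(rank(x), rank(y)))
  expect_error(measure_behavior_correlation(rep(1, 10), rnorm(10)), "constant")
})

test_that("per-session measures agree with per-matrix brute force", {
  withr_seed(31)
  fcl <- lapply(1:6, function(i) random_fc(9, seed = 40 + i))
  ed <- edge_dataset_from_fc(fcl)
  part <- generate_partition(9, 3, seed = 4)
  sm <- session_network_measures(ed, part)
  for (i in 1:6) {
    m <- fcl[[i]]; diag(m) <- 0
    expect_equal(sm$within_density[i], within_between_density(m, part)[["within"]])
    expect_equal(sm$between_density[i], within_between_density(m, part)[["between"]])
    expect_equal(sm$modularity[i], modularity(m, part))
    expect_equal(sm$segregation[i], system_segregation(m, part))
  }
})

test_that("session-consistent label null detects latent-modulated integration", {
  cfg <- sim_config(n_sessions = 73, n_nodes = 40, n_timepoints = 300,
                    seed = 17)
  st <- generate_timeseries_study(cfg)
  ed <- build_edge_dataset(st$series)
  res <- session_consistent_label_null(ed, st$partition,
                                       st$truth$latent_scores,
                                       n_perm = 200, seed = 3)
  expect_lt(res$p[["between_density"]], 0.05)
  expect_gt(res$observed[["between_density"]], 0)
  # fixed seed reproducibility
  res2 <- session_consistent_label_null(ed, st$partition,
                                        st$truth$latent_scores,
                                        n_perm = 200, seed = 3)
  expect_identical(res$null, res2$null)
})

test_that("seed fingerprint flags a planted seed-community decoupling", {
  # the seed's FC with one (non-own) community decreases as mood rises;
  # everything else is flat noise
  k <- 30
  part <- generate_partition(k, 6, seed = 2)
  seed_node <- "n001"
  target <- levels(part)[levels(part) != as.character(part[seed_node])][1]
  mood <- seq(-1.5, 1.5, length.out = 30)
  make_study <- function(rep_seed, slope) {
    with_seed_local(rep_seed, lapply(mood, function(mo) {
      fc <- matrix(0.3, k, k, dimnames = rep(list(node_labels(k)), 2))
      a <- setdiff(names(part)[part == target], seed_node)
      fc[seed_node, a] <- fc[a, seed_node] <- 0.3 - slope * mo
      fc <- fc + matrix(rnorm(k * k, sd = 0.4), k, k)
      fc <- (fc + t(fc)) / 2; diag(fc) <- 1
      fc
    }))
  }
  z_tgt <- vapply(1:8, function(rp) {
    res <- seed_fingerprint_analysis(make_study(rp * 7, 0.25), seed_node,
                                     part, mood, n_perm = 200, seed = rp)
    res$z[[target]]
  }, numeric(1))
  expect_lt(mean(z_tgt), -2)

  # no planted effect: z stays within +/- 2 for nearly all communities
  z_null <- unlist(lapply(1:15, function(rp) {
    res <- seed_fingerprint_analysis(make_study(100 + rp, 0), seed_node,
                                     part, mood, n_perm = 200, seed = rp)
    res$z
  }))
  expect_gte(mean(abs(z_null) < 2), 0.93)

  expect_error(seed_fingerprint_analysis(make_study(1, 0), seed_node, part,
                                         rep(1, 30), n_perm = 100),
               "constant")
})
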