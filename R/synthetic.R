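# Synthetic multi-session study generators. Two levels are provided:
# a direct edge-level generator with a planted rank-1 edge x scale
# cross-covariance (exact control over the PLS input) and a time-series
# generator with planted modular correlation structure whose between-block
# coupling is modulated by the session's latent mood (raw input for the FC
# pipeline). Both return the planted truth for recovery tests.

#' Simulation configuration
#'
#' Defaults emulate the study design being modelled: 73 scan sessions, 13
#' mood scales, 518 time points per session, and a lag-1 autocorrelation
#' typical of filtered BOLD signals. The node count defaults to a desk-scale
#' 60 regions (the full-size recordings use 630).
#'
#' @param n_sessions number of sessions (>= 8).
#' @param n_nodes number of brain regions (>= 4).
#' @param n_scales number of mood scales.
#' @param n_timepoints time points per session.
#' @param ar_coefficient lag-1 temporal autocorrelation, in [0, 1).
#' @param signal_strength planted cross-covariance strength d (>= 0);
#'   X = d t u*' + E, Y = d t v*' + F.
#' @param within_coupling,between_coupling target FC inside / across
#'   communities, |value| < 1.
#' @param modulation_gain increment of between-community coupling per unit
#'   of the session latent score (network integration tracking mood).
#' @param n_communities communities in the generated partition.
#' @param seed RNG seed; all generators are pure in (config, seed).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sessions = 73, n_nodes = 60, n_scales = 13,
                       n_timepoints = 518, ar_coefficient = 0.4,
                       signal_strength = 5, within_coupling = 0.35,
                       between_coupling = 0.1, modulation_gain = 0.1,
                       n_communities = 4, seed = 1L) {
  n_sessions <- check_count(n_sessions, "n_sessions", 8L)
  n_nodes <- check_count(n_nodes, "n_nodes", 4L)
  n_scales <- check_count(n_scales, "n_scales", 2L)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", 3L)
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("`ar_coefficient` must lie in [0, 1)", call. = FALSE)
  if (signal_strength < 0) stop("`signal_strength` must be >= 0", call. = FALSE)
  if (abs(within_coupling) >= 1 || abs(between_coupling) >= 1)
    stop("coupling magnitudes must be < 1", call. = FALSE)
  structure(list(n_sessions = n_sessions, n_nodes = n_nodes,
                 n_scales = n_scales, n_timepoints = n_timepoints,
                 ar_coefficient = ar_coefficient,
                 signal_strength = signal_strength,
                 within_coupling = within_coupling,
                 between_coupling = between_coupling,
                 modulation_gain = modulation_gain,
                 n_communities = check_count(n_communities, "n_communities", 2L),
                 seed = seed),
            class = "sim_config")
}

#' Balanced random node partition
#'
#' Assigns every node to exactly one community with community sizes
#' differing by at most one (a stand-in for a resting-state-network atlas).
#'
#' @param n_nodes node count.
#' @param n_communities community count (<= n_nodes).
#' @param seed RNG seed.
#' @param node_ids optional node labels, default `n001`, ...
#' @return named factor: node id -> community label (`C1`, `C2`, ...).
#' @export
generate_partition <- function(n_nodes, n_communities, seed = 1L,
                               node_ids = NULL) {
  n_nodes <- check_count(n_nodes, "n_nodes", 2L)
  n_communities <- check_count(n_communities, "n_communities", 1L)
  if (n_communities > n_nodes)
    stop("n_communities exceeds n_nodes", call. = FALSE)
  if (is.null(node_ids)) node_ids <- sprintf("n%03d", seq_len(n_nodes))
  sizes <- rep(n_nodes %/% n_communities, n_communities)
  extra <- n_nodes %% n_communities
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(paste0("C", seq_len(n_communities)), times = sizes)
  labels <- with_seed(seed, sample(labels))
  p <- factor(labels, levels = paste0("C", seq_len(n_communities)))
  names(p) <- node_ids
  p
}

# Canonical planted scale pattern for the 13 standard mood scales: dominant
# positive-affect weight, positive-valence scales positive, negative-valence
# scales negative. For other scale counts a seeded random pattern with a
# dominant first scale is used.
planted_scale_pattern <- function(n_scales, seed) {
  if (n_scales == 13L) {
    v <- c(negative_affect = -0.5, positive_affect = 1, fear = -0.35,
           hostility = -0.35, guilt = -0.35, sadness = -0.35,
           joviality = 0.45, self_assurance = 0.45, attentiveness = 0.45,
           shyness = -0.25, fatigue = -0.45, serenity = 0.35,
           surprise = 0.1)
  } else {
    v <- with_seed(derive_seed(seed, 101L), stats::rnorm(n_scales, sd = 0.3))
    v[1L] <- 1
    names(v) <- sprintf("scale%02d", seq_len(n_scales))
  }
  v / sqrt(sum(v^2))
}

#' Edge-level synthetic dataset with planted rank-1 cross-covariance
#'
#' Generates X = d t u*' + E (sessions x edges) and Y = d t v*' + F
#' (sessions x scales) with i.i.d. standard-normal latent scores t and
#' noise, a unit-norm edge pattern u* and a unit-norm scale pattern v* with
#' one dominant scale. By default u* is spread over the whole connectome
#' (mood-related connectivity patterns are brain-wide); lowering
#' `support_fraction` plants a sparse pattern, useful for on/off-support
#' reliability contrasts. This is the exact latent-variable structure the
#' PLS decomposition assumes, so the returned truth supports direct
#' recovery tests.
#'
#' @param cfg a [sim_config()].
#' @param support_fraction fraction of edges carrying the planted pattern
#'   (default 1: fully distributed).
#' @return list with `edges` (an `edge_dataset`), `mood` (sessions x scales
#'   matrix), and `truth` (u_star, v_star, latent_scores, signal_strength,
#'   partition).
#' @export
generate_edge_dataset <- function(cfg, support_fraction = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  node_ids <- sprintf("n%03d", seq_len(cfg$n_nodes))
  idx <- edge_index(node_ids)
  p <- nrow(idx)
  partition <- generate_partition(cfg$n_nodes, cfg$n_communities,
                                  seed = derive_seed(cfg$seed, 7L))
  v_star <- planted_scale_pattern(cfg$n_scales, cfg$seed)
  with_seed(cfg$seed, {
    support <- sort(sample.int(p, max(2L, round(support_fraction * p))))
    u_star <- numeric(p)
    u_star[support] <- stats::rnorm(length(support))
    u_star <- u_star / sqrt(sum(u_star^2))
    t_s <- stats::rnorm(cfg$n_sessions)
    d <- cfg$signal_strength
    X <- d * tcrossprod(t_s, u_star) + matrix(stats::rnorm(cfg$n_sessions * p),
                                              cfg$n_sessions, p)
    Y <- d * tcrossprod(t_s, v_star) +
      matrix(stats::rnorm(cfg$n_sessions * cfg$n_scales),
             cfg$n_sessions, cfg$n_scales)
  })
  session_ids <- sprintf("ses%03d", seq_len(cfg$n_sessions))
  dimnames(X) <- list(session_ids, paste(idx$node_i, idx$node_j, sep = "--"))
  dimnames(Y) <- list(session_ids, names(v_star))
  names(u_star) <- colnames(X)
  names(t_s) <- session_ids
  list(edges = new_edge_dataset(X, idx, node_ids, session_ids),
       mood = Y,
       truth = list(u_star = u_star, v_star = v_star, latent_scores = t_s,
                    signal_strength = cfg$signal_strength,
                    partition = partition))
}

# Target node correlation matrix for one session: within_coupling inside
# community blocks, between_coupling + modulation_gain * latent across
# blocks. Positive definiteness is enforced by clipping eigenvalues at 1e-8
# and renormalizing to unit diagonal, guaranteeing a valid correlation target.
session_target_correlation <- function(partition, within, between_eff) {
  if (abs(between_eff) >= 1)
    stop(sprintf("effective between-community coupling %.3f is not a valid correlation",
                 between_eff), call. = FALSE)
  same <- outer(as.integer(partition), as.integer(partition), "==")
  S <- ifelse(same, within, between_eff)
  diag(S) <- 1
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-8)
    S <- ev$vectors %*% (vals * t(ev$vectors))
    Dh <- 1 / sqrt(diag(S))
    S <- S * tcrossprod(Dh)
  }
  dimnames(S) <- list(names(partition), names(partition))
  S
}

#' Session time series with planted modular FC structure
#'
#' Draws a stationary multivariate AR(1) series whose cross-sectional
#' correlation targets a block structure: `within_coupling` inside
#' communities, `between_coupling + modulation_gain * session_latent` across
#' communities. Higher latent (more positive mood) therefore means more
#' integrated FC, which is the planted ground truth for the
#' segregation-integration analyses.
#'
#' @param cfg a [sim_config()].
#' @param partition named factor node -> community.
#' @param session_latent this session's latent mood score.
#' @param seed optional RNG seed for a standalone deterministic draw; when
#'   NULL the current RNG stream is used (as inside
#'   [generate_timeseries_study()]).
#' @return n_timepoints x n_nodes matrix, columns named by node.
#' @export
generate_session_timeseries <- function(cfg, partition, session_latent = 0,
                                        seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, generate_session_timeseries(cfg, partition,
                                                       session_latent)))
  stopifnot(inherits(cfg, "sim_config"))
  partition <- as_partition(partition)
  k <- length(partition)
  Sg <- session_target_correlation(partition, cfg$within_coupling,
                                   cfg$between_coupling +
                                     cfg$modulation_gain * session_latent)
  L <- chol(Sg)
  phi <- cfg$ar_coefficient
  Tn <- cfg$n_timepoints
  Z <- matrix(stats::rnorm(Tn * k), Tn, k) %*% L
  X <- matrix(0, Tn, k)
  X[1L, ] <- Z[1L, ]
  if (Tn > 1L) {
    a <- sqrt(1 - phi^2)
    for (t in 2:Tn) X[t, ] <- phi * X[t - 1L, ] + a * Z[t, ]
  }
  colnames(X) <- names(partition)
  X
}

#' Full synthetic time-series study
#'
#' Draws per-session latent mood scores, generates every session's AR(1)
#' time series with latent-modulated between-community coupling, and a
#' planted mood table Y = d t v*' + F. The latent scores double as the
#' ground-truth behaviour signal.
#'
#' @param cfg a [sim_config()].
#' @param partition optional partition; generated from `cfg` when NULL.
#' @return list with `series` (list of time x node matrices), `mood`,
#'   `partition`, `truth` (latent_scores, v_star).
#' @export
generate_timeseries_study <- function(cfg, partition = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(partition))
    partition <- generate_partition(cfg$n_nodes, cfg$n_communities,
                                    seed = derive_seed(cfg$seed, 7L))
  v_star <- planted_scale_pattern(cfg$n_scales, cfg$seed)
  session_ids <- sprintf("ses%03d", seq_len(cfg$n_sessions))
  with_seed(cfg$seed, {
    t_s <- stats::rnorm(cfg$n_sessions)
    series <- lapply(t_s, function(ti)
      generate_session_timeseries(cfg, partition, ti))
    Y <- cfg$signal_strength * tcrossprod(t_s, v_star) +
      matrix(stats::rnorm(cfg$n_sessions * cfg$n_scales),
             cfg$n_sessions, cfg$n_scales)
  })
  names(series) <- session_ids
  dimnames(Y) <- list(session_ids, names(v_star))
  names(t_s) <- session_ids
  list(series = series, mood = Y, partition = partition,
       truth = list(latent_scores = t_s, v_star = v_star,
                    signal_strength = cfg$signal_strength))
}

#' Session covariate table emulating the study design
#'
#' A strictly alternating fasting indicator (the participant fasted on
#' alternate scan days, so split sizes differ by at most one) plus
#' continuous lifestyle and weather variables drawn independently of any
#' latent mood signal: alcohol consumption, gut health, psoriasis severity,
#' stress, time outdoors, sleep durations (total/light/deep/REM),
#' precipitation and temperature extremes.
#'
#' @param n_sessions number of sessions (>= 2).
#' @param seed RNG seed.
#' @return data.frame: `session_id`, binary `fasting`, numeric lifestyle
#'   columns.
#' @export
generate_covariates <- function(n_sessions, seed = 1L) {
  n_sessions <- check_count(n_sessions, "n_sessions", 2L)
  fasting <- rep_len(c(1L, 0L), n_sessions)
  with_seed(seed, {
    df <- data.frame(
      session_id = sprintf("ses%03d", seq_len(n_sessions)),
      fasting = fasting,
      alcohol = pmax(0, stats::rnorm(n_sessions, 1, 1)),
      gut_health = stats::rnorm(n_sessions, 3, 1),
      psoriasis = pmax(0, stats::rnorm(n_sessions, 1, 0.5)),
      stress = stats::rnorm(n_sessions, 2, 1),
      time_outdoors = pmax(0, stats::rnorm(n_sessions, 1.5, 1)),
      sleep_total = stats::rnorm(n_sessions, 7.5, 0.8),
      sleep_light = stats::rnorm(n_sessions, 4, 0.6),
      sleep_deep = stats::rnorm(n_sessions, 1.5, 0.4),
      sleep_rem = stats::rnorm(n_sessions, 1.8, 0.4),
      precipitation = pmax(0, stats::rnorm(n_sessions, 0.5, 1)),
      temp_low = stats::rnorm(n_sessions, 10, 8),
      temp_high = stats::rnorm(n_sessions, 20, 8),
      stringsAsFactors = FALSE
    )
  })
  df
}
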