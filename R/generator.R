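#' Configuration for the synthetic benchmark generator
#'
#' Defaults reproduce the benchmark study conditions: N = 500 nodes, K = 3
#' equal-size unmixed communities, inverse temperature beta = 5, scores drawn
#' from a 3-league Gaussian mixture with means (-4, 0, 4) and standard
#' deviations (1, 0.5, 1), out-group rate delta0 = 0.01, and edge rates
#' calibrated to an average degree of 20. League weights default to equal
#' because only means and spreads are prescribed for the benchmark tiers.
#'
#' @param N node count.
#' @param K number of planted communities.
#' @param mu_gt ground-truth type prior in `[0, 1]` (expected fraction of
#'   hierarchy-preferring nodes).
#' @param league_means,league_sds,league_weights Gaussian mixture spec for the
#'   planted score leagues; equal-length vectors, weights on the simplex.
#' @param beta positive inverse temperature of the ranking mechanism.
#' @param delta0 non-negative out-group rate.
#' @param avg_degree target expected (out-)degree; the planted `w` and `c` are
#'   rescaled so the expected total number of directed edges is `N * avg_degree`.
#' @param assortativity ratio of diagonal to off-diagonal entries of the
#'   planted affinity matrix `w`.
#' @param seed integer seed; expands into per-stage child seeds.
#' @return A validated list of class `"comrank_config"`.
#' @export
comrank_config <- function(N = 500, K = 3, mu_gt = 0.5,
                           league_means = c(-4, 0, 4),
                           league_sds = c(1, 0.5, 1),
                           league_weights = NULL,
                           beta = 5, delta0 = 0.01, avg_degree = 20,
                           assortativity = 10, seed = 1) {
  l <- length(league_means)
  if (is.null(league_weights)) league_weights <- rep(1 / l, l)
  if (l < 1 || length(league_sds) != l || length(league_weights) != l)
    stop_invalid("league means, sds and weights must have equal length >= 1")
  if (any(league_sds < 0)) stop_invalid("league sds must be non-negative")
  if (abs(sum(league_weights) - 1) > 1e-8 || any(league_weights < 0))
    stop_invalid("league weights must be non-negative and sum to 1")
  if (mu_gt < 0 || mu_gt > 1) stop_invalid("'mu_gt' must lie in [0, 1]")
  if (avg_degree <= 0) stop_invalid("'avg_degree' must be positive")
  if (beta <= 0) stop_invalid("'beta' must be positive")
  if (delta0 < 0) stop_invalid("'delta0' must be non-negative")
  if (K < 1 || K > N) stop_invalid("'K' must satisfy 1 <= K <= N")
  structure(
    list(N = as.integer(N), K = as.integer(K), mu_gt = mu_gt,
         league_means = league_means, league_sds = league_sds,
         league_weights = league_weights, beta = beta, delta0 = delta0,
         avg_degree = avg_degree, assortativity = assortativity,
         seed = as.integer(seed)),
    class = "comrank_config"
  )
}

#' Sample latent node types
#'
#' Independent Bernoulli(mu) draws: type 1 prefers hierarchy-based
#' interactions, type 0 community-based ones.
#'
#' @param N node count.
#' @param mu type prior in `[0, 1]`.
#' @param seed optional integer seed.
#' @return Integer vector of 0/1 types.
#' @export
sample_node_types <- function(N, mu, seed = NULL) {
  if (!is.finite(mu) || mu < 0 || mu > 1) stop_invalid("'mu' must lie in [0, 1]")
  with_seed(seed, rbinom(N, 1L, mu))
}

#' Sample planted community structure
#'
#' Assigns nodes to K equal-size unmixed communities (when K does not divide N,
#' the first `N %% K` communities get one extra node) in a randomly shuffled
#' order, and builds indicator memberships `u = v` plus an assortative affinity
#' matrix with diagonal/off-diagonal ratio `assortativity`.
#'
#' @param N node count.
#' @param K community count, `1 <= K <= N`.
#' @param seed optional integer seed (shuffles the node-to-community map).
#' @param assortativity diagonal dominance ratio of the planted `w`.
#' @return List with `u`, `v` (N x K indicators), `w` (K x K) and the integer
#'   `community` labels.
#' @export
sample_community_structure <- function(N, K, seed = NULL, assortativity = 10) {
  if (K > N) stop_invalid("'K' cannot exceed 'N'")
  if (K < 1) stop_invalid("'K' must be at least 1")
  sizes <- rep(N %/% K, K) + c(rep(1L, N %% K), rep(0L, K - N %% K))
  labels <- rep(seq_len(K), times = sizes)
  labels <- with_seed(seed, sample(labels))
  u <- matrix(0, N, K)
  u[cbind(seq_len(N), labels)] <- 1
  w <- matrix(1, K, K)
  diag(w) <- assortativity
  list(u = u, v = u, w = w, community = labels)
}

#' Sample planted ranking scores from a league mixture
#'
#' Each node first draws a league from `league_weights`, then a Gaussian score
#' from that league's component. Leagues create tiers in the synthetic
#' hierarchy.
#'
#' @inheritParams comrank_config
#' @param seed optional integer seed.
#' @return List with the numeric `s` scores and the integer `league` of each
#'   node.
#' @export
sample_scores <- function(N, league_means, league_sds, league_weights = NULL,
                          seed = NULL) {
  l <- length(league_means)
  if (is.null(league_weights)) league_weights <- rep(1 / l, l)
  if (length(league_sds) != l || length(league_weights) != l)
    stop_invalid("league means, sds and weights must have equal length")
  if (any(league_sds < 0)) stop_invalid("league sds must be non-negative")
  with_seed(seed, {
    league <- sample.int(l, N, replace = TRUE, prob = league_weights)
    s <- rnorm(N, mean = league_means[league], sd = league_sds[league])
    list(s = s, league = league)
  })
}

# Expected directed-edge totals per branch given fixed types.
expected_edge_totals <- function(gt, beta, delta0) {
  sigma <- gt$sigma
  N <- length(sigma)
  same <- outer(sigma, sigma, "==")
  diag(same) <- NA
  M <- community_mean(gt$u, gt$v, gt$w)
  S <- ranking_mean(gt$s, gt$c, beta)
  both0 <- same & (outer(sigma, sigma, "+") == 0)
  both1 <- same & (outer(sigma, sigma, "+") == 2)
  mixed <- !same
  list(
    community = sum(M[which(both0)]),
    hierarchy = sum(S[which(both1)]),
    out_group = sum(mixed, na.rm = TRUE) * delta0,
    n_pairs0 = sum(both0, na.rm = TRUE),
    n_pairs1 = sum(both1, na.rm = TRUE)
  )
}

#' Calibrate generator density to a target average degree
#'
#' Rescales the planted affinity `w` (community block) and density scale `c`
#' (hierarchy block) multiplicatively so that the expected total number of
#' directed edges, given the realised types, equals `N * avg_degree`. The
#' out-group contribution `delta0` is left as configured; the remaining budget
#' is split between the two in-group blocks proportionally to their numbers of
#' ordered in-group pairs, keeping the mechanisms comparable in density.
#'
#' @param gt ground-truth list with `sigma`, `u`, `v`, `w`, `s`, `c`.
#' @param cfg a [comrank_config()].
#' @return List with multiplicative factors `w_scale` and `c_scale` and the
#'   implied `expected_edges` after calibration.
#' @export
calibrate_density <- function(gt, cfg) {
  tot <- expected_edge_totals(gt, cfg$beta, cfg$delta0)
  target <- cfg$N * cfg$avg_degree
  budget <- target - tot$out_group
  if (budget <= 0)
    stop_invalid("out-group rate alone exceeds the target density; calibration impossible")
  n_in <- tot$n_pairs0 + tot$n_pairs1
  if (n_in == 0)
    stop_invalid("no in-group pairs; calibration impossible")
  t0 <- budget * tot$n_pairs0 / n_in
  t1 <- budget * tot$n_pairs1 / n_in
  w_scale <- 1
  c_scale <- 1
  if (tot$n_pairs0 > 0) {
    if (tot$community <= 0)
      stop_invalid("expected community rates are all zero; calibration impossible")
    w_scale <- t0 / tot$community
  }
  if (tot$n_pairs1 > 0) {
    if (tot$hierarchy <= 0)
      stop_invalid("expected hierarchy rates are all zero; calibration impossible")
    c_scale <- t1 / tot$hierarchy
  }
  list(w_scale = w_scale, c_scale = c_scale,
       expected_edges = tot$out_group + t0 + t1)
}

#' Sample a network given planted structure
#'
#' Draws independent Poisson edge counts for every ordered pair `i != j`:
#' rate `S_ij` when both endpoints prefer hierarchy, `M_ij` when both prefer
#' community, `delta0` across types. Self-loops are never generated.
#'
#' @param gt ground-truth list with `sigma`, `u`, `v`, `w`, `s`, `c` and `beta`.
#' @param delta0 non-negative out-group rate.
#' @param seed optional integer seed.
#' @return Integer adjacency matrix with zero diagonal.
#' @export
sample_network <- function(gt, delta0, seed = NULL) {
  if (delta0 < 0) stop_invalid("'delta0' must be non-negative")
  sigma <- gt$sigma
  N <- length(sigma)
  M <- community_mean(gt$u, gt$v, gt$w)
  S <- ranking_mean(gt$s, gt$c, gt$beta)
  lam <- branch_rates(sigma, S, M, delta0)
  if (any(!is.finite(lam)) || any(lam < 0))
    stop_invalid("edge rates must be finite and non-negative")
  diag(lam) <- 0
  A <- with_seed(seed, matrix(rpois(N * N, lam), N, N))
  storage.mode(A) <- "integer"
  A
}

#' Sample a full synthetic benchmark instance
#'
#' Runs the complete generative pipeline: node types, equal-size unmixed
#' communities, league-mixture scores, density calibration to the target
#' average degree, and Poisson edge sampling. Stage seeds are derived from
#' `cfg$seed`, so identical configurations reproduce identical networks.
#'
#' @param cfg a [comrank_config()].
#' @return A list of class `"comrank_sim"` with the adjacency matrix `A`, the
#'   ground truth (`sigma`, `u`, `v`, `w`, `s`, `c`, `community`, `league`) and
#'   the generating `config`.
#' @export
sample_comrank <- function(cfg = comrank_config()) {
  stopifnot(inherits(cfg, "comrank_config"))
  seeds <- child_seeds(cfg$seed, 4L)
  sigma <- sample_node_types(cfg$N, cfg$mu_gt, seeds[1])
  comm <- sample_community_structure(cfg$N, cfg$K, seeds[2], cfg$assortativity)
  sc <- sample_scores(cfg$N, cfg$league_means, cfg$league_sds,
                      cfg$league_weights, seeds[3])
  gt <- list(sigma = sigma, u = comm$u, v = comm$v, w = comm$w,
             s = sc$s, c = 1, beta = cfg$beta)
  cal <- calibrate_density(gt, cfg)
  gt$w <- gt$w * cal$w_scale
  gt$c <- gt$c * cal$c_scale
  A <- sample_network(gt, cfg$delta0, seeds[4])
  structure(
    list(A = A, sigma = sigma, u = gt$u, v = gt$v, w = gt$w, s = gt$s,
         c = gt$c, community = comm$community, league = sc$league,
         expected_edges = cal$expected_edges, config = cfg),
    class = "comrank_sim"
  )
}

#' @export
print.comrank_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic network: N = %d, K = %d, mu_gt = %.2f, %d directed edges (%d interactions)\n",
    x$config$N, x$config$K, x$config$mu_gt, sum(x$A > 0), sum(x$A)))
  invisible(x)
}
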