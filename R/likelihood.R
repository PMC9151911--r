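#' Expected community interactions
#'
#' Mean of the Poisson edge count under the mixed-membership block mechanism,
#' `M_ij = sum_{k,h} u_ik v_jh w_kh`. With `i`/`j` given, only the requested
#' block of pairs is materialised, so sparse-sum consumers never need the full
#' N x N matrix.
#'
#' @param u,v non-negative N x K membership matrices (out-going / in-coming).
#' @param w non-negative K x K affinity matrix.
#' @param i,j optional integer vectors of row/column node indices.
#' @return Matrix of non-negative rates, `length(i)` x `length(j)` (all pairs
#'   by default). The diagonal of the full matrix is not meaningful; pair sums
#'   in this package always exclude `i == j`.
#' @export
community_mean <- function(u, v, w, i = NULL, j = NULL) {
  u <- as.matrix(u); v <- as.matrix(v); w <- as.matrix(w)
  if (any(u < 0) || any(v < 0) || any(w < 0))
    stop_invalid("community parameters must be non-negative")
  if (!is.null(i)) u <- u[i, , drop = FALSE]
  if (!is.null(j)) v <- v[j, , drop = FALSE]
  u %*% w %*% t(v)
}

#' Expected hierarchical interactions
#'
#' Mean of the Poisson edge count under the ranking mechanism,
#' `S_ij = c * exp(-beta/2 * (s_i - s_j - 1)^2)`: a Boltzmann weight of the
#' spring energy that is maximal (`= c`) when node i sits exactly one rank
#' above node j.
#'
#' @param s numeric vector of ranking scores.
#' @param c positive density scale.
#' @param beta positive inverse temperature.
#' @param i,j optional node index vectors, as in [community_mean()].
#' @return Matrix of rates in `(0, c]`.
#' @export
ranking_mean <- function(s, c, beta, i = NULL, j = NULL) {
  if (!is.finite(c) || c <= 0) stop_invalid("'c' must be positive")
  if (!is.finite(beta) || beta <= 0) stop_invalid("'beta' must be positive")
  si <- if (is.null(i)) s else s[i]
  sj <- if (is.null(j)) s else s[j]
  d <- outer(si, sj, "-") - 1
  c * exp(-beta / 2 * d^2)
}

# Poisson log-pmf with floored rate; the A! term is dropped where it cancels
# across mechanism branches and retained for absolute log-likelihoods.
log_pois <- function(A, rate, drop_factorial = TRUE) {
  out <- A * log(clip_rate(rate)) - rate
  if (!drop_factorial) out <- out - lfactorial(A)
  out
}

#' Joint log-likelihood of a network given node types
#'
#' Log of the three-branch Poisson likelihood: an ordered pair (i, j) with
#' `sigma_i == sigma_j` follows the hierarchy rate `S_ij` (types 1) or the
#' community rate `M_ij` (types 0); pairs of unlike type follow the constant
#' out-group rate `delta0`. With `prior = TRUE` the Bernoulli(mu) log-prior of
#' `sigma` is added, giving `log P(sigma, A | theta)` up to the dropped
#' factorial constant.
#'
#' With all types 0 this reduces to the pure block-model log-likelihood; with
#' all types 1, to the pure ranking-model log-likelihood.
#'
#' @param A square matrix of non-negative integer edge counts.
#' @param params a [comrank_params()] object.
#' @param sigma binary vector of node types.
#' @param prior add the Bernoulli type prior term?
#' @param drop_factorial drop the `log A_ij!` constant (default) or include it
#'   for absolute values.
#' @param mask optional matrix; non-zero entries mark observed ordered pairs.
#'   `NULL` means all pairs `i != j`.
#' @return A scalar; `-Inf` is possible when a rate is (floored to) zero with a
#'   positive count.
#' @export
joint_loglik <- function(A, params, sigma, prior = FALSE,
                         drop_factorial = TRUE, mask = NULL) {
  A <- check_adjacency(A)
  N <- nrow(A)
  sigma <- as.numeric(sigma)
  if (length(sigma) != N || any(!sigma %in% c(0, 1)))
    stop_invalid("'sigma' must be a binary vector of length N")
  mask <- as_pair_mask(mask, N)
  M <- community_mean(params$u, params$v, params$w)
  S <- ranking_mean(params$s, params$c, params$beta)
  lam <- branch_rates(sigma, S, M, params$delta0)
  ll <- sum(mask * log_pois(A, lam, drop_factorial))
  if (prior) {
    mu <- clip_mu(params$mu)
    ll <- ll + sum(sigma * log(mu) + (1 - sigma) * log(1 - mu))
  }
  ll
}

#' Ising representation of the node-type posterior
#'
#' The posterior over binary node types, `P(sigma | theta, A)`, is exactly a
#' Boltzmann distribution over spins `m_i = 2 sigma_i - 1` with asymmetric
#' pairwise couplings `J` and fields `h`:
#' `log P(sigma | theta, A) = const + sum_{i != j} J_ij m_i m_j + sum_i h_i m_i`.
#' Each coupling compares the per-pair log-evidence of the three Poisson
#' branches; the field collects the node-wise part plus the prior term
#' `[log mu - log(1 - mu)] / 2`. Rates are floored so all entries are finite.
#'
#' @inheritParams joint_loglik
#' @return A list with components `J` (N x N, zero on unobserved pairs) and
#'   `h` (length N), of class `"comrank_ising"`.
#' @export
ising_map <- function(A, params, mask = NULL) {
  A <- check_adjacency(A)
  N <- nrow(A)
  mask <- as_pair_mask(mask, N)
  M <- community_mean(params$u, params$v, params$w)
  out <- cpp_ising_fields(A, mask, M, params$s, params$c, params$beta,
                          params$delta0, params$mu, RATE_FLOOR, MU_FLOOR)
  structure(list(J = out$J, h = as.numeric(out$h)), class = "comrank_ising")
}

#' Variational lower bound (ELBO)
#'
#' Evidence lower bound of the factorised Bernoulli variational posterior
#' `q(sigma) = prod_i Be(sigma_i; Q_i)`:
#' `L(q, theta) = E_q[log P(sigma, A | theta)] + H(q)`, with
#' `E_q[sigma_i sigma_j] = Q_i Q_j` for `i != j`. Optional exponential priors
#' on the memberships subtract `lambda_uv * sum(u + v) + lambda_w * sum(w)`.
#' The bound never exceeds the log-evidence `log sum_sigma P(sigma, A | theta)`
#' and is tight when `q` equals the exact posterior.
#'
#' @inheritParams joint_loglik
#' @param Q numeric vector of type posterior means in `[0, 1]`.
#' @param lambda_uv,lambda_w non-negative exponential prior rates on `u`, `v`
#'   and on `w`.
#' @return The scalar bound.
#' @export
elbo <- function(A, params, Q, mask = NULL, drop_factorial = TRUE,
                 lambda_uv = 0, lambda_w = 0) {
  A <- check_adjacency(A)
  N <- nrow(A)
  Q <- as.numeric(Q)
  if (length(Q) != N || any(Q < 0) || any(Q > 1))
    stop_invalid("'Q' must be a length-N vector in [0, 1]")
  mask <- as_pair_mask(mask, N)
  out <- core_elbo(A, mask, params, Q, lambda_uv, lambda_w)
  if (!drop_factorial) out <- out - sum(mask * lfactorial(A))
  out
}

# elbo on pre-validated inputs; M may be passed to avoid recomputation.
core_elbo <- function(A, mask, params, Q, lambda_uv = 0, lambda_w = 0,
                      M = NULL) {
  if (is.null(M)) M <- params$u %*% params$w %*% t(params$v)
  pair <- cpp_pair_elbo(A, mask, Q, M, params$s, params$c, params$beta,
                        params$delta0, RATE_FLOOR)
  mu <- clip_mu(params$mu)
  prior <- sum(Q * log(mu) + (1 - Q) * log(1 - mu))
  reg <- -lambda_uv * (sum(params$u) + sum(params$v)) - lambda_w * sum(params$w)
  pair + prior + entropy_bernoulli(Q) + reg
}

#' Posterior-expected adjacency rates
#'
#' Edge-prediction scores: the expected Poisson rate of each ordered pair under
#' the factorised type posterior,
#' `lambda_ij = Q_i Q_j S_ij + (1 - Q_i)(1 - Q_j) M_ij +
#'  [Q_i (1 - Q_j) + (1 - Q_i) Q_j] delta0`.
#' Reduces to `S` when `Q` is identically 1 and to `M` when identically 0.
#'
#' @inheritParams elbo
#' @param i,j optional node index vectors restricting the computed block.
#' @return Matrix of non-negative rates.
#' @export
expected_adjacency <- function(params, Q, i = NULL, j = NULL) {
  N <- n_nodes(params)
  Q <- as.numeric(Q)
  if (length(Q) != N) stop_invalid("'Q' must have one entry per node")
  Qi <- if (is.null(i)) Q else Q[i]
  Qj <- if (is.null(j)) Q else Q[j]
  S <- ranking_mean(params$s, params$c, params$beta, i, j)
  M <- community_mean(params$u, params$v, params$w, i, j)
  qq <- outer(Qi, Qj)
  pp <- outer(1 - Qi, 1 - Qj)
  qq * S + pp * M + (1 - qq - pp) * params$delta0
}
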