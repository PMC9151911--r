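#' Model parameter container
#'
#' Bundles the full parameter set of the community/hierarchy mixture model:
#' out- and in-memberships `u`, `v` (N x K, non-negative), community affinity
#' `w` (K x K, non-negative), real-valued ranking scores `s`, hierarchy density
#' scale `c > 0`, inverse temperature `beta > 0` (a hyperparameter), out-group
#' rate `delta0 >= 0`, and node-type prior `mu` in `[0, 1]`.
#'
#' @param u,v numeric N x K matrices of non-negative out/in community
#'   memberships.
#' @param w numeric K x K non-negative affinity matrix.
#' @param s numeric length-N vector of ranking scores.
#' @param c positive scalar controlling hierarchy edge density.
#' @param beta positive inverse temperature of the ranking mechanism.
#' @param delta0 non-negative out-group interaction rate.
#' @param mu type prior in `[0, 1]` (probability a node prefers hierarchy).
#' @return An object of class `"comrank_params"`.
#' @export
comrank_params <- function(u, v, w, s, c, beta, delta0, mu) {
  u <- as.matrix(u); v <- as.matrix(v); w <- as.matrix(w)
  s <- as.numeric(s)
  N <- nrow(u); K <- ncol(u)
  if (!all(dim(v) == c(N, K))) stop_invalid("'u' and 'v' must have equal dimensions")
  if (!all(dim(w) == c(K, K))) stop_invalid("'w' must be K x K")
  if (length(s) != N) stop_invalid("'s' must have one score per node")
  if (any(u < 0) || any(v < 0) || any(w < 0))
    stop_invalid("community parameters must be non-negative")
  if (!is.finite(c) || c <= 0) stop_invalid("'c' must be positive")
  if (!is.finite(beta) || beta <= 0) stop_invalid("'beta' must be positive")
  if (!is.finite(delta0) || delta0 < 0) stop_invalid("'delta0' must be non-negative")
  if (!is.finite(mu) || mu < 0 || mu > 1) stop_invalid("'mu' must lie in [0, 1]")
  structure(
    list(u = u, v = v, w = w, s = s, c = c, beta = beta,
         delta0 = delta0, mu = mu),
    class = "comrank_params"
  )
}

#' @export
print.comrank_params <- function(x, ...) {
  cat(sprintf("Model parameters: N = %d nodes, K = %d communities\n",
              nrow(x$u), ncol(x$u)))
  cat(sprintf("  c = %.4g, beta = %.4g, delta0 = %.4g, mu = %.4g\n",
              x$c, x$beta, x$delta0, x$mu))
  invisible(x)
}

n_nodes <- function(params) nrow(params$u)
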