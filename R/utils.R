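# Numerical dialect of the model: Poisson rates are floored before logs so the
# Ising couplings and fields stay finite when delta0 = 0 or memberships vanish;
# the type prior mu is kept away from {0, 1} for the same reason.
RATE_FLOOR <- 1e-12
MU_FLOOR <- 1e-10

clip_mu <- function(mu) min(max(mu, MU_FLOOR), 1 - MU_FLOOR)

clip_rate <- function(x) pmax(x, RATE_FLOOR)

stop_invalid <- function(...) stop(..., call. = FALSE)

check_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop_invalid("'A' must be a square adjacency matrix")
  if (any(!is.finite(A)) || any(A < 0))
    stop_invalid("adjacency entries must be finite and non-negative")
  storage.mode(A) <- "double"
  A
}

# Observed-pair mask as a dense 0/1 double matrix with zero diagonal; NULL
# means all ordered pairs i != j.
as_pair_mask <- function(mask, N) {
  if (is.null(mask)) {
    mask <- matrix(1, N, N)
  } else {
    if (!is.matrix(mask) || nrow(mask) != N || ncol(mask) != N)
      stop_invalid("'mask' must be an ", N, "x", N, " matrix")
    mask <- matrix(as.double(mask != 0), N, N)
  }
  diag(mask) <- 0
  mask
}

# One user-facing seed expands into independent child seeds for the pipeline
# stages, so stages can be re-run in isolation and still reproduce.
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

entropy_bernoulli <- function(Q) {
  f <- function(p) ifelse(p <= 0 | p >= 1, 0, -p * log(p))
  sum(f(Q) + f(1 - Q))
}

# Per-pair Poisson rates given fixed types: S where both endpoints are type 1,
# M where both are type 0, delta0 across types.
branch_rates <- function(sigma, S, M, delta0) {
  both1 <- outer(sigma == 1, sigma == 1, "&")
  both0 <- outer(sigma == 0, sigma == 0, "&")
  lam <- matrix(delta0, length(sigma), length(sigma))
  lam[both1] <- S[both1]
  lam[both0] <- M[both0]
  lam
}

# Permutations of 1..n (n small), for community column alignment.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
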