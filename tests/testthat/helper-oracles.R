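# Independent oracles, written as plain loops so they share no code with the
# package internals they check.

# log P(sigma, A | theta) by direct evaluation of the three Poisson branches
# plus the Bernoulli type prior, over ordered pairs i != j.
oracle_joint_loglik <- function(A, params, sigma, prior = TRUE, mask = NULL) {
  N <- nrow(A)
  if (is.null(mask)) mask <- matrix(TRUE, N, N)
  ll <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j || !mask[i, j]) next
    if (sigma[i] == sigma[j]) {
      if (sigma[i] == 1) {
        rate <- params$c * exp(-params$beta / 2 * (params$s[i] - params$s[j] - 1)^2)
      } else {
        rate <- 0
        for (k in seq_len(ncol(params$u))) for (h in seq_len(ncol(params$u)))
          rate <- rate + params$u[i, k] * params$v[j, h] * params$w[k, h]
      }
    } else {
      rate <- params$delta0
    }
    ll <- ll + A[i, j] * log(max(rate, 1e-12)) - rate
  }
  if (prior)
    ll <- ll + sum(sigma * log(params$mu) + (1 - sigma) * log(1 - params$mu))
  ll
}

# All binary type vectors of length N.
all_sigmas <- function(N) as.matrix(expand.grid(rep(list(0:1), N)))

# Exact posterior P(sigma | theta, A) and log-evidence by enumeration.
oracle_enumerate <- function(A, params, mask = NULL) {
  sig <- all_sigmas(nrow(A))
  lp <- apply(sig, 1, function(s) oracle_joint_loglik(A, params, s, TRUE, mask))
  m <- max(lp)
  w <- exp(lp - m)
  list(prob = w / sum(w), sigma = sig, log_evidence = m + log(sum(w)))
}

# Boltzmann distribution of an Ising system (J possibly asymmetric) over all
# configurations, spins m = 2 sigma - 1:
# P(sigma) proportional to exp(sum_{i != j} J_ij m_i m_j + sum_i h_i m_i).
oracle_boltzmann <- function(J, h) {
  N <- length(h)
  sig <- all_sigmas(N)
  lp <- apply(sig, 1, function(s) {
    m <- 2 * s - 1
    e <- sum(h * m)
    for (i in seq_len(N)) for (j in seq_len(N))
      if (i != j) e <- e + J[i, j] * m[i] * m[j]
    e
  })
  w <- exp(lp - max(lp))
  w / sum(w)
}

# Reference unweighted mixed-membership block-model multiplicative update
# (one sweep: u, then v, then w, each from fresh rates), plain loops.
oracle_mt_update <- function(A, u, v, w, mask = NULL) {
  N <- nrow(A); K <- ncol(u)
  if (is.null(mask)) mask <- matrix(TRUE, N, N)
  diag(mask) <- FALSE
  rates <- function(u, v, w) {
    M <- matrix(0, N, N)
    for (i in 1:N) for (j in 1:N) for (k in 1:K) for (h in 1:K)
      M[i, j] <- M[i, j] + u[i, k] * v[j, h] * w[k, h]
    M
  }
  M <- rates(u, v, w)
  u_new <- u
  for (i in 1:N) for (k in 1:K) {
    num <- 0; den <- 0
    for (j in 1:N) {
      if (i == j || !mask[i, j]) next
      vw <- sum(v[j, ] * w[k, ])
      num <- num + A[i, j] / max(M[i, j], 1e-12) * vw
      den <- den + vw
    }
    u_new[i, k] <- if (den > 0) u[i, k] * num / den else 0
  }
  M <- rates(u_new, v, w)
  v_new <- v
  for (j in 1:N) for (h in 1:K) {
    num <- 0; den <- 0
    for (i in 1:N) {
      if (i == j || !mask[i, j]) next
      uw <- sum(u_new[i, ] * w[, h])
      num <- num + A[i, j] / max(M[i, j], 1e-12) * uw
      den <- den + uw
    }
    v_new[j, h] <- if (den > 0) v[j, h] * num / den else 0
  }
  M <- rates(u_new, v_new, w)
  w_new <- w
  for (k in 1:K) for (h in 1:K) {
    num <- 0; den <- 0
    for (i in 1:N) for (j in 1:N) {
      if (i == j || !mask[i, j]) next
      num <- num + A[i, j] / max(M[i, j], 1e-12) * u_new[i, k] * v_new[j, h]
      den <- den + u_new[i, k] * v_new[j, h]
    }
    w_new[k, h] <- if (den > 0) w[k, h] * num / den else 0
  }
  list(u = u_new, v = v_new, w = w_new)
}

# O(n^2) pairwise-comparison AUC (ties half-counted).
oracle_auc <- function(scores, labels) {
  pos <- which(labels > 0); neg <- which(labels <= 0)
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (scores[p] > scores[n]) + 0.5 * (scores[p] == scores[n])
  tot / (length(pos) * length(neg))
}

# Small random model instance for likelihood/inference tests.
random_instance <- function(N, K = 2, seed = 1, mu = 0.5, delta0 = NULL,
                            beta = 2) {
  set.seed(seed)
  u <- matrix(runif(N * K, 0.2, 1), N)
  v <- matrix(runif(N * K, 0.2, 1), N)
  w <- matrix(runif(K * K, 0.2, 1), K)
  if (is.null(delta0)) delta0 <- runif(1, 0.05, 0.5)
  params <- comrank_params(u, v, w, s = rnorm(N), c = runif(1, 0.5, 2),
                           beta = beta, delta0 = delta0, mu = mu)
  gt <- list(sigma = rbinom(N, 1, mu), u = u, v = v, w = w, s = params$s,
             c = params$c, beta = beta)
  A <- sample_network(gt, delta0, seed = seed + 1000)
  list(A = A, params = params, gt = gt)
}

# Objective-trace collector shared by the acceptance tests (criterion:
# monotone ascent must hold on every fitted instance).
trace_store <- new.env(parent = emptyenv())
trace_store$traces <- list()
record_trace <- function(fit) {
  trace_store$traces[[length(trace_store$traces) + 1]] <- fit$objective_trace
  invisible(fit)
}
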