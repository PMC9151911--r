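test_that("community mean matches brute-force summation", {
  # scalar case
  expect_equal(community_mean(matrix(1, 3, 1), matrix(1, 3, 1),
                              matrix(2, 1, 1)),
               matrix(2, 3, 3))
  # absorbing zero row
  u <- matrix(runif(8), 4); u[2, ] <- 0
  v <- matrix(runif(8), 4); w <- matrix(runif(4), 2)
  expect_true(all(community_mean(u, v, w)[2, ] == 0))
  # random 4-node K=2 instance against the triple loop
  set.seed(1)
  u <- matrix(runif(8), 4); v <- matrix(runif(8), 4); w <- matrix(runif(4), 2)
  M <- community_mean(u, v, w)
  for (i in 1:4) for (j in 1:4) {
    ref <- 0
    for (k in 1:2) for (h in 1:2) ref <- ref + u[i, k] * v[j, h] * w[k, h]
    expect_equal(M[i, j], ref)
  }
  expect_error(community_mean(-u, v, w), "non-negative")
})

test_that("ranking mean follows the spring-energy Boltzmann weight", {
  s <- c(1, 0)
  S <- ranking_mean(s, c = 3, beta = 5)
  expect_equal(S[1, 2], 3)                    # s_i - s_j = 1 gives the maximum
  expect_equal(ranking_mean(c(2, 2), 1, 5)[1, 2], exp(-2.5))
  # S_ij * S_ji depends on the score difference only through the identity
  set.seed(2)
  s <- rnorm(5); cc <- 1.3; beta <- 2
  S <- ranking_mean(s, cc, beta)
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    d <- s[i] - s[j]
    expect_equal(S[i, j] * S[j, i],
                 cc^2 * exp(-beta * ((d - 1)^2 + (d + 1)^2) / 2))
  }
  expect_error(ranking_mean(s, -1, 2), "positive")
})

test_that("joint log-likelihood reduces to the single-mechanism models", {
  inst <- random_instance(5, seed = 3)
  # all-community types reproduce the pure block-model log-likelihood
  sig0 <- rep(0, 5)
  expect_equal(joint_loglik(inst$A, inst$params, sig0),
               oracle_joint_loglik(inst$A, inst$params, sig0, prior = FALSE))
  # all-hierarchy types reproduce the pure ranking log-likelihood
  sig1 <- rep(1, 5)
  expect_equal(joint_loglik(inst$A, inst$params, sig1),
               oracle_joint_loglik(inst$A, inst$params, sig1, prior = FALSE))
  # zero counts: minus the sum of the rates
  A0 <- matrix(0L, 3, 3)
  p <- comrank_params(matrix(1, 3, 1), matrix(1, 3, 1), matrix(0.5, 1, 1),
                      s = c(0.5, 0, -0.5), c = 1, beta = 2, delta0 = 0.1,
                      mu = 0.5)
  lam <- comrank:::branch_rates(c(0, 1, 0), ranking_mean(p$s, p$c, p$beta),
                                community_mean(p$u, p$v, p$w), p$delta0)
  diag(lam) <- 0
  expect_equal(joint_loglik(A0, p, c(0, 1, 0)), -sum(lam))
  # mixed types on a 3-node toy match the per-edge oracle
  inst3 <- random_instance(3, seed = 4)
  for (sig in list(c(0, 1, 0), c(1, 1, 0), c(1, 0, 1))) {
    expect_equal(joint_loglik(inst3$A, inst3$params, sig, prior = TRUE),
                 oracle_joint_loglik(inst3$A, inst3$params, sig, prior = TRUE))
  }
})

test_that("Ising couplings and fields reproduce the exact posterior", {
  # identical branch rates give zero coupling
  p <- comrank_params(matrix(1, 2, 1), matrix(1, 2, 1), matrix(0.3, 1, 1),
                      s = c(1, 0), c = 0.3, beta = 1e-9, delta0 = 0.3,
                      mu = 0.5)
  A <- matrix(c(0L, 1L, 2L, 0L), 2)
  sys <- ising_map(A, p)
  expect_lt(max(abs(sys$J)), 1e-6)
  expect_lt(max(abs(sys$h)), 1e-6)  # mu = 0.5 contributes nothing

  # 2-node exhaustive check of the Boltzmann form against the posterior
  inst <- random_instance(2, seed = 5)
  sys <- ising_map(inst$A, inst$params)
  expect_lt(max(abs(oracle_boltzmann(sys$J, sys$h) -
                      oracle_enumerate(inst$A, inst$params)$prob)), 1e-12)
})

test_that("variational bound is a true lower bound and tight in the right limits", {
  inst <- random_instance(6, seed = 6)
  en <- oracle_enumerate(inst$A, inst$params)
  # point-mass q has zero entropy and recovers the joint log-likelihood
  sig <- c(0, 1, 1, 0, 0, 1)
  expect_equal(elbo(inst$A, inst$params, sig),
               joint_loglik(inst$A, inst$params, sig, prior = TRUE))
  # bounded by the enumerated log-evidence for arbitrary Q
  set.seed(7)
  for (r in 1:10) {
    Q <- runif(6)
    expect_lte(elbo(inst$A, inst$params, Q), en$log_evidence + 1e-9)
  }
  # with J identically 0 the factorized posterior is exact and the bound tight
  p <- comrank_params(matrix(1, 4, 1), matrix(1, 4, 1), matrix(0.4, 1, 1),
                      s = rnorm(4), c = 0.4, beta = 1e-12, delta0 = 0.4,
                      mu = 0.3)
  A <- matrix(rpois(16, 0.4), 4); diag(A) <- 0L
  en0 <- oracle_enumerate(A, p)
  marg <- colSums(en0$sigma * en0$prob)
  expect_lt(abs(elbo(A, p, marg) - en0$log_evidence), 1e-6)
})

test_that("variational bound is invariant under score translation", {
  inst <- random_instance(5, seed = 8)
  Q <- runif(5)
  shifted <- inst$params
  shifted$s <- shifted$s + 12.3
  expect_equal(elbo(inst$A, inst$params, Q), elbo(inst$A, shifted, Q),
               tolerance = 1e-10)
})

test_that("posterior-expected adjacency interpolates the mechanism rates", {
  inst <- random_instance(4, seed = 9)
  p <- inst$params
  S <- ranking_mean(p$s, p$c, p$beta)
  M <- community_mean(p$u, p$v, p$w)
  expect_equal(expected_adjacency(p, rep(1, 4)), S)
  expect_equal(expected_adjacency(p, rep(0, 4)), M)
  expect_equal(expected_adjacency(p, rep(0.5, 4)),
               (S + M + 2 * p$delta0) / 4)
})

test_that("dense pair kernels scale quadratically, not worse", {
  p1 <- random_instance(150, seed = 10)
  p2 <- random_instance(300, seed = 10)
  time_of <- function(inst) {
    mask <- comrank:::as_pair_mask(NULL, nrow(inst$A))
    median(vapply(1:5, function(k) {
      t0 <- Sys.time()
      elbo(inst$A, inst$params, rep(0.5, nrow(inst$A)), mask = mask)
      as.numeric(Sys.time() - t0)
    }, numeric(1)))
  }
  ratio <- time_of(p2) / max(time_of(p1), 1e-6)
  # doubling N should cost about 4x for an O(N^2) kernel; anything near
  # O(N^3) (~8x) or worse fails even with generous scheduling noise
  expect_lt(ratio, 7)
})
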