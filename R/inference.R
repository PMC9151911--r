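#' Algorithmic control parameters for model fitting
#'
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative tolerance on the variational bound; convergence is
#'   declared when the relative change stays below `tol` for `consecutive`
#'   successive iterations.
#' @param consecutive number of successive sub-tolerance checks required.
#' @param damping damping factor in `[0, 1)` applied to the mean-field
#'   fixed-point sweeps for the type posterior Q (synchronous updates).
#' @param fixed_point_max_sweeps cap on fixed-point sweeps per E-step.
#' @param fixed_point_tol max |Q change| at which a sweep is converged.
#' @param mem_inner multiplicative membership sub-iterations per EM iteration
#'   (the community block converges linearly; a few sub-iterations per E-step
#'   shorten the overall run considerably).
#' @param s_inner_iter linearisation iterations for the score block per EM
#'   iteration.
#' @param s_tol gradient infinity-norm target for the score stationarity solve.
#' @param max_rounds maximum score re-anchoring rounds after the first EM phase
#'   (each re-seeds the scores from the SpringRank solution of the currently
#'   inferred hierarchy subnetwork and continues EM; kept only while the bound
#'   improves).
#' @param round_gain minimum bound improvement (nats) for accepting a
#'   re-anchoring round.
#' @param verbose print per-iteration objectives.
#' @return A list of class `"comrank_control"`.
#' @export
comrank_control <- function(max_iter = 200, tol = 1e-5, consecutive = 3,
                            damping = 0.5, fixed_point_max_sweeps = 30,
                            fixed_point_tol = 1e-6, mem_inner = 6,
                            s_inner_iter = 1,
                            s_tol = 1e-6, max_rounds = 3, round_gain = 5,
                            verbose = FALSE) {
  if (damping < 0 || damping >= 1) stop_invalid("'damping' must lie in [0, 1)")
  if (tol <= 0) stop_invalid("'tol' must be positive")
  structure(as.list(environment()), class = "comrank_control")
}

#' Mean-field update of the node-type posterior
#'
#' Sweeps the Ising self-consistency fixed point
#' `m_i = tanh(h_i + sum_j (J_ij + J_ji) m_j)` in +/-1 magnetisation variables
#' (the symmetrised coupling arises because `sigma_i` multiplies both row i and
#' column i of the asymmetric J), maps back to `Q_i = (m_i + 1) / 2`, with
#' synchronous damped updates.
#'
#' @inheritParams joint_loglik
#' @param Q_old current posterior means, used as the sweep start.
#' @param damping damping factor in `[0, 1)`.
#' @param tol sweep convergence threshold on `max |Q_new - Q_old|`.
#' @param max_sweeps sweep cap.
#' @return Updated numeric Q vector.
#' @export
update_Q <- function(A, params, Q_old, damping = 0.5, tol = 1e-6,
                     max_sweeps = 100, mask = NULL) {
  A <- check_adjacency(A)
  mask <- as_pair_mask(mask, nrow(A))
  core_update_Q(A, mask, params, Q_old, damping, tol, max_sweeps)
}

core_update_Q <- function(A, mask, params, Q_old, damping, tol, max_sweeps) {
  M <- params$u %*% params$w %*% t(params$v)
  sys <- cpp_ising_fields_sym(A, mask, M, params$s, params$c, params$beta,
                              params$delta0, params$mu, RATE_FLOOR, MU_FLOOR)
  h <- as.numeric(sys$h)
  bad <- which(!is.finite(h))
  if (length(bad))
    stop_invalid("non-finite Ising field at node ", bad[1])
  if (any(!is.finite(sys$Jsym)))
    stop_invalid("non-finite Ising coupling encountered")
  m <- cpp_mf_sweeps(sys$Jsym, h, 2 * as.numeric(Q_old) - 1,
                     damping, tol, as.integer(max_sweeps))$m
  pmin(pmax((as.numeric(m) + 1) / 2, 0), 1)
}

#' Community-block update
#'
#' Multiplicative block-model updates for `(u, v, w)` in which every edge term
#' carries the mean-field weight `(1 - Q_i)(1 - Q_j)` and every normaliser term
#' the same weight summed over observed pairs. Exponential membership priors
#' add their rates to the denominators (`lambda_w = 10 * lambda_uv` under the
#' single-scalar regularisation convention used by [comrank()]). Updates are
#' performed sequentially (u, then v, then w), each guaranteeing ascent of the
#' community part of the bound; zero rows remain zero.
#'
#' @inheritParams elbo
#' @param lambda_uv,lambda_w exponential prior rates.
#' @return List with updated `u`, `v`, `w`. If the total community weight is
#'   numerically zero (a pure-hierarchy network) the block is returned frozen
#'   with a warning.
#' @export
update_memberships <- function(A, params, Q, lambda_uv = 0, lambda_w = 0,
                               mask = NULL) {
  A <- check_adjacency(A)
  mask <- as_pair_mask(mask, nrow(A))
  core_memberships(A, mask, params, Q, lambda_uv, lambda_w)
}

# Edge list (0-based indices and weights) of the observed positive entries.
edge_index <- function(mA) {
  nz <- which(mA > 0, arr.ind = TRUE)
  list(ij = matrix(as.integer(nz - 1L), ncol = 2), w = as.numeric(mA[nz]))
}

core_memberships <- function(A, mask, params, Q, lambda_uv = 0, lambda_w = 0,
                             n_reps = 1, edges = NULL) {
  Q <- as.numeric(Q)
  qm <- 1 - Q
  weight <- as.numeric(qm %*% mask %*% qm)
  if (weight < 1e-10) {
    warning("community block frozen: no pairs with appreciable weight (1-Q_i)(1-Q_j)",
            call. = FALSE)
    return(list(u = params$u, v = params$v, w = params$w))
  }
  if (is.null(edges)) edges <- edge_index(mask * A)
  out <- cpp_membership_update(edges$ij, edges$w, mask, Q, params$u, params$v,
                               params$w, lambda_uv, lambda_w, RATE_FLOOR,
                               as.integer(n_reps))
  list(u = out$u, v = out$v, w = out$w)
}

#' Ranking-block update
#'
#' Updates the density scale by its closed form
#' `c = sum_ij Q_iQ_j A_ij / sum_ij Q_iQ_j exp[-beta/2 (s_i - s_j - 1)^2]`
#' and drives the score stationarity condition
#' `sum_j Q_iQ_j (A_ij - S_ij)(s_i - s_j - 1) -
#'  sum_j Q_iQ_j (A_ji - S_ji)(s_j - s_i - 1) = 0`
#' towards zero by iterated linearisation: the residuals `B_ij = Q_iQ_j
#' (A_ij - S_ij)` are frozen at the current scores, the resulting weighted
#' linear system is solved (gauge fixed by centring), and the step is accepted
#' only if the hierarchy part of the bound does not decrease, with a damped
#' gradient step as fallback. Returned scores are centred to mean zero.
#'
#' @inheritParams elbo
#' @param max_iter linearisation iterations.
#' @param tol stop when the gradient infinity norm falls below this.
#' @return List with `s`, `c`, the final `grad_norm` and the objective value of
#'   the hierarchy block. If the total hierarchy weight is numerically zero (a
#'   pure-community network) the block is returned frozen with a warning.
#' @export
update_ranking <- function(A, params, Q, mask = NULL, max_iter = 20,
                           tol = 1e-6) {
  A <- check_adjacency(A)
  mask <- as_pair_mask(mask, nrow(A))
  core_ranking(A, mask, params, Q, max_iter, tol, polish = max_iter >= 20)
}

# Solve a symmetric system, Cholesky first (the usual case once the LM ridge
# makes it positive definite), LU as fallback.
sym_solve <- function(K, b) {
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (!is.null(ch)) return(backsolve(ch, backsolve(ch, b, transpose = TRUE)))
  tryCatch(solve(K, b), error = function(e) NULL)
}

core_ranking <- function(A, mask, params, Q, max_iter = 20, tol = 1e-6,
                         polish = FALSE) {
  N <- nrow(A)
  Q <- as.numeric(Q)
  weight <- as.numeric(Q %*% mask %*% Q)
  if (weight < 1e-10) {
    warning("ranking block frozen: no pairs with appreciable weight Q_i Q_j",
            call. = FALSE)
    return(list(s = params$s, c = params$c, grad_norm = NA_real_,
                objective = NA_real_))
  }
  s <- as.numeric(params$s)
  beta <- params$beta
  # Everything c-dependent is linear in c, so one kernel sweep gives the
  # closed-form c and the objective/gradient/linearised system at it.
  at_c <- function(pr) {
    cs <- max(pr$sumQQA / max(pr$sumQQE, RATE_FLOOR), RATE_FLOOR)
    list(pr = pr, c = cs,
         obj = log(cs) * pr$sumQQA - pr$sumQQAen - cs * pr$sumQQE,
         grad = as.numeric(pr$gA) - cs * as.numeric(pr$gE))
  }
  evaluate <- function(sv, system = TRUE)
    at_c(cpp_ranking_profile(A, mask, Q, sv, beta, RATE_FLOOR, system))
  light_candidates <- max_iter <= 1  # accepted step ends the call; no system needed
  cur <- evaluate(s)
  grad_norm <- max(abs(cur$grad))
  iter <- 0
  lam_prev <- 0
  while (grad_norm > tol && iter < max_iter) {
    iter <- iter + 1
    W <- cur$pr$Wa - cur$c * cur$pr$We
    b <- as.numeric(cur$pr$ba) - cur$c * as.numeric(cur$pr$be)
    Kmat <- diag(rowSums(W), N) - W + matrix(1 / N, N, N)  # rank-one gauge fix
    # Linearised solve with a Levenberg-Marquardt ridge: the frozen-residual
    # system can be indefinite or near-singular (residuals change sign), so a
    # ridge pulls the step back towards the current scores. At most two solves
    # per iteration (starting from the last successful ridge); if both are
    # rejected, fall back to cheap backtracked gradient steps.
    ridge0 <- mean(abs(diag(Kmat))) + 1e-8
    step_ok <- function(try) {
      # objective ascent, or (near the optimum, where objective comparisons
      # hit their precision floor) gradient-norm descent
      is.finite(try$obj) &&
        (try$obj >= cur$obj - 1e-12 * max(1, abs(cur$obj)) ||
           (max(abs(try$grad)) < 0.9 * grad_norm &&
              try$obj >= cur$obj - 1e-6 * max(1, abs(cur$obj))))
    }
    accepted <- FALSE
    for (lam_r in unique(c(lam_prev, max(ridge0, lam_prev * 100)))) {
      cand <- sym_solve(Kmat + diag(lam_r, N), b + lam_r * s)
      if (!is.null(cand) && all(is.finite(cand))) {
        cand <- as.numeric(cand - mean(cand))
        try <- evaluate(cand, system = !light_candidates)
        if (step_ok(try)) {
          s <- cand; cur <- try; accepted <- TRUE
          lam_prev <- lam_r / 10
          break
        }
      }
    }
    if (!accepted) {
      step <- 0.1 / max(max(abs(cur$grad)), 1e-12)
      for (bt in 0:3) {
        s_try <- s + step * 2^(-bt) * cur$grad
        s_try <- as.numeric(s_try - mean(s_try))
        try <- evaluate(s_try, system = !light_candidates)
        if (try$obj > cur$obj) {
          s <- s_try; cur <- try; accepted <- TRUE
          break
        }
      }
    }
    if (!accepted) break
    grad_norm <- max(abs(cur$grad))
  }
  if (grad_norm > tol && polish) {
    # The linearisation can limit-cycle above a tight tolerance; polish the
    # profile objective f(s) = obj(s, c(s)) with BFGS (by the envelope
    # theorem its gradient is the partial gradient at c(s)). fn and gr are
    # called at the same point, so the kernel sweep is memoised.
    memo <- new.env(parent = emptyenv())
    prof <- function(sv) {
      if (!is.null(memo$par) && identical(sv, memo$par)) return(memo$val)
      v <- evaluate(sv, system = FALSE)
      memo$par <- sv
      memo$val <- v
      v
    }
    opt <- tryCatch(
      stats::optim(s, fn = function(sv) -prof(sv)$obj,
                   gr = function(sv) -prof(sv)$grad, method = "BFGS",
                   control = list(maxit = 60, reltol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(opt)) {
      try <- evaluate(opt$par, system = FALSE)
      if (is.finite(try$obj) && try$obj >= cur$obj - 1e-9 * max(1, abs(cur$obj))) {
        s <- as.numeric(opt$par)
        cur <- try
        grad_norm <- max(abs(cur$grad))
      }
    }
    # BFGS line searches difference the objective and stall at a gradient
    # norm ~ sqrt(eps |obj| H); finish with exact Newton steps on the
    # (fixed-c) Hessian, accepted purely on gradient-norm descent, which has
    # no such floor and converges quadratically.
    it2 <- 0
    cur <- evaluate(s)
    grad_norm <- max(abs(cur$grad))
    while (grad_norm > tol && it2 < 15) {
      it2 <- it2 + 1
      Wp <- cur$pr$Wa - cur$c * cur$pr$WeH
      P <- params$beta * (diag(rowSums(Wp), N) - Wp) + matrix(1 / N, N, N)
      ridge <- 1e-10 * (mean(abs(diag(P))) + 1)
      delta <- sym_solve(P + diag(ridge, N), cur$grad)
      if (is.null(delta) || !all(is.finite(delta))) break
      cand <- as.numeric(s + delta)
      cand <- cand - mean(cand)
      try <- evaluate(cand)
      if (!all(is.finite(try$grad)) || max(abs(try$grad)) >= grad_norm) break
      s <- cand
      cur <- try
      grad_norm <- max(abs(cur$grad))
    }
  }
  s <- as.numeric(s - mean(s))
  list(s = s, c = cur$c, grad_norm = grad_norm, objective = cur$obj)
}

#' Out-group rate update
#'
#' Closed form `delta0 = sum_ij omega_ij A_ij / sum_ij omega_ij` with
#' `omega_ij = Q_i (1 - Q_j) + (1 - Q_i) Q_j`, the mean-field expectation of
#' the out-group indicator.
#'
#' @inheritParams elbo
#' @param current value returned (after a warning) when the total out-group
#'   weight is numerically zero.
#' @return Updated scalar rate.
#' @export
update_delta0 <- function(A, Q, mask = NULL, current = RATE_FLOOR) {
  A <- check_adjacency(A)
  mask <- as_pair_mask(mask, nrow(A))
  core_delta0(mask * A, mask, Q, current)
}

core_delta0 <- function(mA, mask, Q, current = RATE_FLOOR) {
  Q <- as.numeric(Q)
  qm <- 1 - Q
  num <- as.numeric(Q %*% mA %*% qm + qm %*% mA %*% Q)
  den <- as.numeric(Q %*% mask %*% qm + qm %*% mask %*% Q)
  if (den < 1e-12) {
    warning("no out-group weight; delta0 left at its current value", call. = FALSE)
    return(current)
  }
  num / den
}

#' Type-prior update
#'
#' Closed form `mu = mean(Q)`, clipped away from 0 and 1 by the package's
#' numerical floor so downstream log-odds stay finite.
#'
#' @param Q numeric vector of type posterior means.
#' @return Updated scalar prior.
#' @export
update_mu <- function(Q) clip_mu(mean(as.numeric(Q)))

#' Classic SpringRank scores
#'
#' Solves the regularised SpringRank linear system on the (optionally masked)
#' weighted network: minimises `sum_ij A_ij (s_i - s_j - 1)^2 / 2` plus a small
#' ridge `alpha`, with the translation gauge fixed by centring. Used both as a
#' standalone utility and as the informed initialisation of the ranking block
#' inside [comrank()].
#'
#' @param A adjacency matrix of non-negative weights.
#' @param alpha small ridge regularisation (also handles disconnected graphs).
#' @return Centred numeric score vector.
#' @export
springrank_scores <- function(A, alpha = 1e-4) {
  A <- check_adjacency(A)
  N <- nrow(A)
  W <- A + t(A)
  dout <- rowSums(A)
  din <- colSums(A)
  L <- diag(dout + din + alpha, N) - W + matrix(1 / N, N, N)
  s <- solve(L, dout - din)
  as.numeric(s - mean(s))
}

init_params <- function(A, mask, K, beta, fix_Q = NULL) {
  N <- nrow(A)
  obs <- sum(mask)
  mean_A <- if (obs > 0) sum(mask * A) / obs else 0.1
  mean_A <- max(mean_A, 1e-3)
  u <- matrix(runif(N * K, 0.1, 1), N, K)
  v <- matrix(runif(N * K, 0.1, 1), N, K)
  w <- matrix(runif(K * K, 0.1, 1), K, K)
  w <- w * mean_A / mean(community_mean(u, v, w))
  s <- rnorm(N)
  Q <- if (is.null(fix_Q)) runif(N) else rep(as.numeric(fix_Q), length.out = N)
  params <- comrank_params(u, v, w, s = s, c = mean_A, beta = beta,
                           delta0 = max(mean_A / 10, 1e-3), mu = 0.5)
  list(params = params, Q = Q)
}

# One EM phase: alternating E-step / parameter updates until the bound
# stabilises. Returns the fitted state plus the per-iteration objective trace.
em_run <- function(A, mask, params, Q, lambda_uv, lambda_w, fix_Q, control) {
  q_fixed <- !is.null(fix_Q)
  comm_frozen <- FALSE
  rank_frozen <- FALSE
  trace <- numeric(0)
  obj <- -Inf
  below <- 0
  converged <- FALSE
  last_grad <- NA_real_
  mA <- mask * A  # constant across iterations
  edges <- edge_index(mA)
  for (it in seq_len(control$max_iter)) {
    if (!q_fixed) {
      Q <- core_update_Q(A, mask, params, Q, control$damping,
                         control$fixed_point_tol,
                         control$fixed_point_max_sweeps)
    }
    params$mu <- update_mu(Q)
    params$delta0 <- suppressWarnings(core_delta0(mA, mask, Q, params$delta0))
    comm <- withCallingHandlers(
      core_memberships(A, mask, params, Q, lambda_uv, lambda_w,
                       n_reps = control$mem_inner, edges = edges),
      warning = function(w) {
        if (!comm_frozen) {
          comm_frozen <<- TRUE
          message("community block frozen (pure-hierarchy regime)")
        }
        invokeRestart("muffleWarning")
      })
    params$u <- comm$u; params$v <- comm$v; params$w <- comm$w
    rk <- withCallingHandlers(
      core_ranking(A, mask, params, Q, max_iter = control$s_inner_iter,
                   tol = control$s_tol),
      warning = function(w) {
        if (!rank_frozen) {
          rank_frozen <<- TRUE
          message("ranking block frozen (pure-community regime)")
        }
        invokeRestart("muffleWarning")
      })
    params$s <- rk$s; params$c <- rk$c
    last_grad <- rk$grad_norm
    obj_new <- core_elbo(A, mask, params, Q, lambda_uv, lambda_w)
    trace <- c(trace, obj_new)
    if (control$verbose)
      cat(sprintf("  iter %3d  elbo %.6f\n", it, obj_new))
    rel <- abs(obj_new - obj) / max(1, abs(obj_new))
    below <- if (is.finite(rel) && rel < control$tol) below + 1 else 0
    obj <- obj_new
    if (below >= control$consecutive) {
      converged <- TRUE
      break
    }
  }
  list(params = params, Q = Q, objective = obj, trace = trace,
       converged = converged, iterations = length(trace),
       frozen = c(community = comm_frozen, ranking = rank_frozen),
       last_grad = last_grad)
}

fit_one <- function(A, mask, K, beta, lambda, fix_Q, control, restart_seed,
                    style = c("plain", "ranking", "ranking_raw")) {
  style <- match.arg(style)
  set.seed(restart_seed)
  lambda_uv <- lambda
  lambda_w <- 10 * lambda
  st <- init_params(A, mask, K, beta, fix_Q)
  params <- st$params
  Q <- st$Q
  if (style != "plain" && !identical(fix_Q, 0)) {
    # Informed start for the ranking block: SpringRank solution of the
    # (training part of the) network, mildly perturbed for restart diversity.
    # Without it the spring energy of random scores is so poor that the type
    # posterior abandons the ranking mechanism before the scores can adapt.
    # "ranking" additionally refines (s, c) under full hierarchy weight before
    # EM, which helps when the hierarchy involves many nodes; "ranking_raw"
    # leaves the raw solution in place, which preserves the signal of a small
    # hierarchy subpopulation that full-weight refinement would wash out.
    s0 <- springrank_scores(mask * A)
    params$s <- s0 + rnorm(length(s0), 0, 0.05 * max(stats::sd(s0), 1e-8))
    if (style == "ranking") {
      rk <- suppressWarnings(
        core_ranking(A, mask, params, rep(1, nrow(A)), max_iter = 15,
                     tol = control$s_tol))
      params$s <- rk$s
      params$c <- rk$c
    }
  }
  run <- em_run(A, mask, params, Q, lambda_uv, lambda_w, fix_Q, control)
  if (is.null(fix_Q)) {
    # Continuation rounds: once a tentative hierarchy subset exists, re-anchor
    # the scores on the SpringRank solution of that subnetwork and let EM
    # refine from there; each round is kept only if the bound improves.
    for (round in seq_len(control$max_rounds)) {
      hi <- which(run$Q > 0.5)
      if (length(hi) < 10) {
        # few confident hierarchy nodes: seed from the most hierarchy-leaning
        # ones anyway; the round is kept only if the bound improves.
        hi <- order(run$Q, decreasing = TRUE)[1:20]
      }
      if (length(hi) >= nrow(A)) break
      p2 <- run$params
      sub <- matrix(0, nrow(A), ncol(A))
      sub[hi, hi] <- 1
      s2 <- tryCatch(springrank_scores(A * sub * mask), error = function(e) NULL)
      if (is.null(s2)) break
      p2$s <- s2
      rk <- suppressWarnings(
        core_ranking(A, mask, p2, as.numeric(run$Q), max_iter = 15,
                     tol = control$s_tol))
      p2$s <- rk$s; p2$c <- rk$c
      run2 <- em_run(A, mask, p2, run$Q, lambda_uv, lambda_w, fix_Q, control)
      if (run2$objective <= run$objective + control$round_gain) break
      run <- run2
    }
  }
  # final polish of the score stationarity once Q has settled
  if (!run$frozen["ranking"] && is.finite(run$last_grad) &&
      run$last_grad > control$s_tol) {
    rk <- suppressWarnings(
      core_ranking(A, mask, run$params, run$Q, max_iter = 50,
                   tol = control$s_tol, polish = TRUE))
    run$params$s <- rk$s; run$params$c <- rk$c
    run$objective <- core_elbo(A, mask, run$params, run$Q, lambda_uv, lambda_w)
    run$trace <- c(run$trace, run$objective)
    run$iterations <- length(run$trace)
  }
  run
}

#' Fit the community/hierarchy mixture model
#'
#' Variational EM: a mean-field Ising fixed point estimates the node-type
#' posterior Q (E-step), then closed-form or stationarity-based updates refresh
#' the type prior, the out-group rate, the community block (u, v, w) and the
#' ranking block (s, c). Each of `n_init` random restarts runs to convergence
#' of the variational bound; the restart with the best final bound is returned.
#'
#' @param A square matrix of non-negative integer edge counts (no self-loops;
#'   the diagonal is ignored). See [read_edgelist()] for building one from an
#'   edge list file.
#' @param K number of communities.
#' @param beta positive inverse temperature of the ranking mechanism
#'   (a hyperparameter, not fitted).
#' @param lambda single non-negative regularisation scalar; exponential priors
#'   with rates `lambda_u = lambda_v = lambda` and `lambda_w = 10 * lambda` are
#'   placed on the memberships and affinity. `0` (default) is the plain
#'   unregularised model.
#' @param n_init number of random restarts (the portfolio alternates
#'   ranking-informed and plain initialisations, so at least 2 are advisable
#'   when the dominant mechanism is unknown).
#' @param seed integer seed; restart seeds are derived from it.
#' @param mask optional matrix; non-zero entries mark observed (training)
#'   ordered pairs. Held-out pairs are removed from every sum, not zero-filled.
#' @param fix_Q optionally freeze the type posterior at a constant (0 gives the
#'   pure block-model limit, 1 the pure ranking limit).
#' @param control a [comrank_control()] list.
#' @return An object of class `"comrank"`: the fitted `params`
#'   ([comrank_params()]), the posterior `Q`, the per-iteration
#'   `objective_trace` of the winning restart, the final `objective`, the
#'   objectives of every restart, and convergence diagnostics.
#' @examples
#' sim <- sample_comrank(comrank_config(N = 60, K = 2, mu_gt = 0.1, seed = 7))
#' fit <- comrank(sim$A, K = 2, beta = 5, n_init = 1, seed = 7,
#'                control = comrank_control(max_iter = 60))
#' fit
#' @export
comrank <- function(A, K, beta, lambda = 0, n_init = 2, seed = 1, mask = NULL,
                    fix_Q = NULL, control = comrank_control()) {
  A <- check_adjacency(A)
  N <- nrow(A)
  if (N < 2) stop_invalid("the network must contain at least two nodes")
  if (any(abs(A - round(A)) > 1e-8))
    stop_invalid("edge weights must be integers")
  mask <- as_pair_mask(mask, N)
  if (sum(mask * A) == 0)
    stop_invalid("the (training part of the) network has no edges; nothing to fit")
  if (K < 1) stop_invalid("'K' must be at least 1")
  if (beta <= 0) stop_invalid("'beta' must be positive")
  if (lambda < 0) stop_invalid("'lambda' must be non-negative")
  if (!is.null(fix_Q) && (fix_Q < 0 || fix_Q > 1))
    stop_invalid("'fix_Q' must lie in [0, 1]")
  labels <- rownames(A)
  seeds <- child_seeds(seed, n_init)
  # Restart portfolio: alternate refined and raw SpringRank-informed
  # initialisations (complementary in which regimes they succeed); the
  # variational bound picks the winner. A frozen hierarchy baseline
  # (fix_Q = 1) always uses the refined start.
  styles <- if (identical(fix_Q, 1)) rep("ranking", n_init)
            else rep(c("ranking", "ranking_raw", "plain"), length.out = n_init)
  runs <- lapply(seq_len(n_init), function(r)
    fit_one(A, mask, K, beta, lambda, fix_Q, control, seeds[r], styles[r]))
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  best <- which.max(objs)
  run <- runs[[best]]
  structure(
    list(params = run$params, Q = run$Q, objective = run$objective,
         objective_trace = run$trace, restart_objectives = objs,
         converged = run$converged, best_of = n_init,
         iterations = run$iterations, frozen = run$frozen,
         K = as.integer(K), beta = beta, lambda = lambda, seed = seed,
         N = N, labels = labels, A = A, mask = mask,
         control = control, call = match.call()),
    class = "comrank"
  )
}
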