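#' Cross-validation split over ordered node pairs
#'
#' Assigns every ordered pair (i, j), i != j, uniformly at random to one of
#' `folds` folds. Training on fold f means masking that fold's pairs out of
#' every likelihood sum and update (they are removed, not zero-filled).
#'
#' @param N node count.
#' @param folds number of folds (>= 2).
#' @param seed optional integer seed.
#' @return Object of class `"comrank_cv"`: an N x N integer fold matrix with
#'   `NA` diagonal plus the fold count.
#' @export
make_cv_split <- function(N, folds = 5, seed = NULL) {
  n_pairs <- N * (N - 1)
  if (folds < 2) stop_invalid("'folds' must be at least 2")
  if (folds > n_pairs) stop_invalid("more folds than ordered pairs")
  assign_vec <- with_seed(seed, sample(rep_len(seq_len(folds), n_pairs)))
  fold <- matrix(NA_integer_, N, N)
  fold[row(fold) != col(fold)] <- assign_vec
  structure(list(fold = fold, n_folds = as.integer(folds), seed = seed),
            class = "comrank_cv")
}

#' Training mask for one fold
#'
#' @param split a [make_cv_split()] object.
#' @param fold fold index to hold out.
#' @return 0/1 matrix marking the training (observed) pairs.
#' @export
cv_train_mask <- function(split, fold) {
  m <- split$fold
  out <- matrix(as.double(!is.na(m) & m != fold), nrow(m), ncol(m))
  out
}

#' Test mask (logical) for one fold
#' @inheritParams cv_train_mask
#' @export
cv_test_mask <- function(split, fold) !is.na(split$fold) & split$fold == fold

# Rank-statistic AUC: probability that a random positive outscores a random
# negative, ties counted one half.
rank_auc <- function(scores, labels) {
  pos <- labels > 0
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop_invalid("AUC undefined: need both positive and negative instances")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Edge-prediction AUC on held-out pairs
#'
#' Probability that a uniformly random held-out pair with an edge
#' (`A_ij > 0`, any weight) receives a higher score than a uniformly random
#' held-out pair without one, ties counted one half; computed exactly via rank
#' statistics. Invariant under strictly monotone transforms of the scores.
#'
#' @param score_matrix matrix of pairwise scores (e.g. [expected_adjacency()]).
#' @param A adjacency matrix of observed counts.
#' @param test_pairs logical matrix selecting the held-out ordered pairs.
#' @return AUC in `[0, 1]`.
#' @export
edge_prediction_auc <- function(score_matrix, A, test_pairs) {
  test_pairs <- test_pairs & (row(A) != col(A))
  sc <- score_matrix[test_pairs]
  if (any(!is.finite(sc))) stop_invalid("non-finite scores on test pairs")
  rank_auc(sc, as.numeric(A[test_pairs] > 0))
}

#' Node-type classification AUC
#'
#' AUC of the posterior means Q as scores for the ground-truth type
#' `sigma = 1`.
#'
#' @param Q numeric vector of type posterior means.
#' @param sigma_gt binary ground-truth types (both classes must be present).
#' @export
node_type_auc <- function(Q, sigma_gt) rank_auc(as.numeric(Q), as.numeric(sigma_gt))

cosine_rows <- function(a, b) {
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  cs <- rowSums(a * b) / (na * nb)
  cs[na == 0 | nb == 0] <- 0
  cs
}

#' Permutation-aligned community cosine similarity
#'
#' Average per-node cosine similarity between inferred and ground-truth
#' membership rows, after choosing the column permutation of the inferred
#' matrix that maximises the average (exhaustive up to K = 8, greedy column
#' assignment above). Matrices with different K are zero-padded; nodes with an
#' all-zero ground-truth row are excluded from the average, and an all-zero
#' inferred row scores 0.
#'
#' @param u_hat inferred membership matrix (N x K1).
#' @param u_gt ground-truth membership matrix (N x K2).
#' @return Average cosine similarity in `[0, 1]` for non-negative memberships.
#' @export
community_cosine_similarity <- function(u_hat, u_gt) {
  u_hat <- as.matrix(u_hat); u_gt <- as.matrix(u_gt)
  if (nrow(u_hat) != nrow(u_gt)) stop_invalid("membership matrices must share N")
  keep <- rowSums(u_gt^2) > 0
  if (!any(keep)) stop_invalid("all-zero ground-truth memberships")
  K <- max(ncol(u_hat), ncol(u_gt))
  pad <- function(m) cbind(m, matrix(0, nrow(m), K - ncol(m)))
  u_hat <- pad(u_hat)[keep, , drop = FALSE]
  u_gt <- pad(u_gt)[keep, , drop = FALSE]
  score <- function(perm) mean(cosine_rows(u_hat[, perm, drop = FALSE], u_gt))
  if (K <= 8) {
    return(max(vapply(all_permutations(K), score, numeric(1))))
  }
  # greedy assignment on the K x K column-cosine matrix
  cc <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K)) {
    na <- sqrt(sum(u_hat[, a]^2)); nb <- sqrt(sum(u_gt[, b]^2))
    cc[a, b] <- if (na == 0 || nb == 0) 0 else sum(u_hat[, a] * u_gt[, b]) / (na * nb)
  }
  perm <- integer(K)
  free_a <- seq_len(K); free_b <- seq_len(K)
  while (length(free_a)) {
    idx <- which(cc[free_a, free_b, drop = FALSE] ==
                   max(cc[free_a, free_b]), arr.ind = TRUE)[1, ]
    perm[free_b[idx[2]]] <- free_a[idx[1]]
    free_a <- free_a[-idx[1]]; free_b <- free_b[-idx[2]]
  }
  score(perm)
}

#' Pearson correlation between score vectors
#'
#' Standard Pearson coefficient between inferred and ground-truth ranking
#' scores; invariant to affine rescaling of either argument.
#'
#' @param s_hat,s_gt numeric vectors (both non-constant).
#' @export
score_pearson <- function(s_hat, s_gt) {
  if (stats::sd(s_hat) == 0 || stats::sd(s_gt) == 0)
    stop_invalid("Pearson correlation undefined for constant scores")
  cor(s_hat, s_gt)
}

#' Reciprocity of a (sub)network
#'
#' Fraction of directed edges in the induced (binarised) subnetwork whose
#' reverse edge also exists.
#'
#' @param A adjacency matrix.
#' @param node_subset optional node indices inducing a subnetwork.
#' @export
reciprocity <- function(A, node_subset = NULL) {
  if (!is.null(node_subset)) A <- A[node_subset, node_subset, drop = FALSE]
  B <- (A > 0)
  diag(B) <- FALSE
  m <- sum(B)
  if (m == 0) stop_invalid("reciprocity undefined on an edgeless subnetwork")
  sum(B & t(B)) / m
}

#' Cross-validated edge prediction for one network
#'
#' For each fold: fit on the training pairs (held-out pairs removed from every
#' sum), score all pairs with the posterior-expected adjacency, and compute the
#' held-out edge AUC.
#'
#' @inheritParams comrank
#' @param folds number of CV folds.
#' @param cv_seed seed for the pair-to-fold assignment.
#' @param keep_fits return the per-fold fitted objects too?
#' @return List with per-fold `edge_auc`, the `fits` (if requested) and the
#'   split.
#' @export
comrank_cv <- function(A, K, beta, folds = 5, lambda = 0, n_init = 1,
                       seed = 1, cv_seed = seed, fix_Q = NULL,
                       control = comrank_control(), keep_fits = FALSE) {
  N <- nrow(A)
  split <- make_cv_split(N, folds, cv_seed)
  auc <- numeric(folds)
  fits <- vector("list", folds)
  for (f in seq_len(folds)) {
    fit <- comrank(A, K, beta, lambda = lambda, n_init = n_init,
                   seed = seed + f, mask = cv_train_mask(split, f),
                   fix_Q = fix_Q, control = control)
    auc[f] <- edge_prediction_auc(predict(fit, "adjacency"), A,
                                  cv_test_mask(split, f))
    if (keep_fits) fits[[f]] <- fit else fits[[f]] <- list(Q = fit$Q)
  }
  list(edge_auc = auc, fits = fits, split = split)
}

#' Select the number of communities by cross-validated edge prediction
#'
#' Fits every K in `K_grid` on each training fold and scores mean held-out
#' edge AUC; returns the K with the highest mean, ties broken towards the
#' smallest K. Failed fits are skipped with a warning.
#'
#' @inheritParams comrank_cv
#' @param K_grid integer vector of candidate community counts.
#' @return The selected K (integer), with the AUC-by-K table in attribute
#'   `"table"`.
#' @export
select_K <- function(A, K_grid, beta, folds = 5, lambda = 0, n_init = 1,
                     seed = 1, control = comrank_control()) {
  if (!length(K_grid)) stop_invalid("'K_grid' must be non-empty")
  split <- make_cv_split(nrow(A), folds, seed)
  mean_auc <- vapply(K_grid, function(K) {
    aucs <- vapply(seq_len(folds), function(f) {
      tryCatch({
        fit <- comrank(A, K, beta, lambda = lambda, n_init = n_init,
                       seed = seed + f, mask = cv_train_mask(split, f),
                       control = control)
        edge_prediction_auc(predict(fit, "adjacency"), A,
                            cv_test_mask(split, f))
      }, error = function(e) {
        warning("fit failed for K = ", K, ", fold ", f, ": ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- K_grid[order(-mean_auc, K_grid)][1]
  structure(as.integer(best),
            table = data.frame(K = K_grid, edge_auc = mean_auc))
}

#' Scaled synthetic study: edge prediction, node classification and
#' structure recovery across the mixing spectrum
#'
#' Runs the package's synthetic evaluation study at its reference conditions
#' (N = 500, average degree 20, beta = 5, K = 3 unmixed communities, 3 score
#' leagues, delta0 = 0.01) and summarises the four headline quantities:
#' cross-validated edge-prediction AUC in the intermediate mixing regime,
#' node-type AUC across the mixing grid, ranking Pearson correlation in the
#' hierarchy-dominated regime, and community cosine similarity in the
#' community-dominated regime — each reported as the minimum over its mu_gt
#' grid of the per-mu mean.
#'
#' @param seed master seed.
#' @param folds CV folds for the edge-prediction part.
#' @param cv_samples generated networks per grid point for the
#'   cross-validated part.
#' @param recovery_samples generated networks per grid point for the
#'   full-network structure-recovery part.
#' @param n_init restarts per cross-validated fit (the masked mixed-regime
#'   fits are the ones that need a deep restart portfolio).
#' @param recovery_n_init restarts per full-network recovery fit.
#' @param config template [comrank_config()] for the generator conditions.
#' @param cv_control fitting control for the cross-validated fits (a capped
#'   budget keeps the sweep tractable; held-out metrics saturate well before
#'   full convergence).
#' @param control fitting control for the full-network recovery fits.
#' @param monitor optional callback receiving every fitted object.
#' @return A list with the four summary values (`edge_auc_min`,
#'   `node_auc_min`, `pearson_min`, `cosine_min`), the grids used, and the
#'   per-fit tables `cv_table` and `recovery_table`.
#' @export
comrank_study <- function(seed = 1, folds = 2, cv_samples = 2,
                          recovery_samples = 2, n_init = 5,
                          recovery_n_init = 3,
                          config = comrank_config(),
                          cv_control = comrank_control(max_iter = 60,
                                                       tol = 1e-4,
                                                       consecutive = 2,
                                                       max_rounds = 1,
                                                       mem_inner = 8),
                          control = comrank_control(max_iter = 100,
                                                    max_rounds = 2),
                          monitor = NULL) {
  edge_grid <- c(0.2, 0.5, 0.8)
  node_grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  cv_grid <- sort(unique(c(edge_grid, node_grid)))
  pearson_grid <- c(0.8, 0.9, 1.0)
  cosine_grid <- c(0.0, 0.1, 0.2)
  seeds <- child_seeds(seed, 2L)
  cv <- comrank_benchmark(cv_grid, n_samples = cv_samples, folds = folds,
                          n_init = n_init, config = config, seed = seeds[1],
                          control = cv_control, full_fit = FALSE,
                          monitor = monitor)
  rec <- comrank_benchmark(sort(unique(c(pearson_grid, cosine_grid))),
                           n_samples = recovery_samples, folds = 0,
                           n_init = recovery_n_init, config = config,
                           seed = seeds[2],
                           control = control, full_fit = TRUE,
                           monitor = monitor)
  mu_mean <- function(df, col, grid) {
    vapply(grid, function(m) mean(df[[col]][df$mu_gt == m], na.rm = TRUE),
           numeric(1))
  }
  list(
    edge_auc_min = min(mu_mean(cv, "edge_auc", edge_grid)),
    node_auc_min = min(mu_mean(cv, "node_auc", node_grid)),
    pearson_min = min(mu_mean(rec, "pearson", pearson_grid)),
    cosine_min = min(mu_mean(rec, "cosine", cosine_grid)),
    edge_grid = edge_grid, node_grid = node_grid,
    pearson_grid = pearson_grid, cosine_grid = cosine_grid,
    cv_table = cv, recovery_table = rec
  )
}

#' Synthetic benchmark sweep
#'
#' Reproduces the synthetic evaluation protocol: for each ground-truth type
#' prior in `mu_grid` and each of `n_samples` independently generated networks,
#' runs `folds`-fold cross-validated edge prediction (recording held-out edge
#' AUC and node-type AUC per fold) plus one full-network fit from which ranking
#' Pearson correlation and permutation-aligned community cosine similarity
#' against the planted structure are computed. Optional baselines refit each
#' fold with the type posterior frozen at 0 (community-only) and 1
#' (hierarchy-only).
#'
#' @param mu_grid numeric vector of ground-truth type priors.
#' @param n_samples generated networks per grid point.
#' @param folds CV folds (0 skips the CV part).
#' @param n_init restarts per fit.
#' @param config template [comrank_config()]; its `mu_gt` and `seed` fields are
#'   overwritten per cell.
#' @param lambda regularisation passed to [comrank()].
#' @param seed master seed for the sweep.
#' @param baselines also run the frozen-Q limit fits per fold?
#' @param control a [comrank_control()].
#' @param full_fit run the full-network fit for structure recovery?
#' @param monitor optional function called with each fitted object (used to
#'   collect objective traces).
#' @return A data frame with one row per (mu_gt, sample, fold) and columns
#'   `edge_auc`, `node_auc`, `edge_auc_community`, `edge_auc_hierarchy`
#'   (baselines, else NA), plus per-sample rows (`fold = NA`) holding
#'   `pearson`, `cosine` and `mu_hat` from the full fit.
#' @export
comrank_benchmark <- function(mu_grid, n_samples = 2, folds = 5, n_init = 3,
                              config = comrank_config(), lambda = 0, seed = 1,
                              baselines = FALSE,
                              control = comrank_control(), full_fit = TRUE,
                              monitor = NULL) {
  rows <- list()
  cell_seeds <- child_seeds(seed, length(mu_grid) * n_samples * 3L)
  idx <- 0
  for (mu_gt in mu_grid) {
    for (sample_id in seq_len(n_samples)) {
      idx <- idx + 1
      gen_seed <- cell_seeds[3 * (idx - 1) + 1]
      fit_seed <- cell_seeds[3 * (idx - 1) + 2]
      cv_seed <- cell_seeds[3 * (idx - 1) + 3]
      cfg <- config
      cfg$mu_gt <- mu_gt
      cfg$seed <- gen_seed
      sim <- sample_comrank(cfg)
      two_class <- length(unique(sim$sigma)) == 2
      if (folds >= 2) {
        split <- make_cv_split(cfg$N, folds, cv_seed)
        for (f in seq_len(folds)) {
          fit <- comrank(sim$A, cfg$K, cfg$beta, lambda = lambda,
                         n_init = n_init, seed = fit_seed + f,
                         mask = cv_train_mask(split, f), control = control)
          if (!is.null(monitor)) monitor(fit)
          test <- cv_test_mask(split, f)
          row <- data.frame(
            mu_gt = mu_gt, sample = sample_id, fold = f,
            edge_auc = edge_prediction_auc(predict(fit, "adjacency"),
                                           sim$A, test),
            node_auc = if (two_class) node_type_auc(fit$Q, sim$sigma) else NA_real_,
            pearson = NA_real_, cosine = NA_real_, mu_hat = fit$params$mu,
            edge_auc_community = NA_real_, edge_auc_hierarchy = NA_real_)
          if (baselines) {
            for (lim in c(0, 1)) {
              bfit <- comrank(sim$A, cfg$K, cfg$beta, lambda = lambda,
                              n_init = n_init, seed = fit_seed + f,
                              mask = cv_train_mask(split, f), fix_Q = lim,
                              control = control)
              if (!is.null(monitor)) monitor(bfit)
              bauc <- edge_prediction_auc(predict(bfit, "adjacency"),
                                          sim$A, test)
              if (lim == 0) row$edge_auc_community <- bauc
              else row$edge_auc_hierarchy <- bauc
            }
          }
          rows[[length(rows) + 1]] <- row
        }
      }
      if (full_fit) {
        fit <- comrank(sim$A, cfg$K, cfg$beta, lambda = lambda,
                       n_init = n_init, seed = fit_seed, control = control)
        if (!is.null(monitor)) monitor(fit)
        rows[[length(rows) + 1]] <- data.frame(
          mu_gt = mu_gt, sample = sample_id, fold = NA_integer_,
          edge_auc = NA_real_,
          node_auc = if (two_class) node_type_auc(fit$Q, sim$sigma) else NA_real_,
          pearson = tryCatch(score_pearson(fit$params$s, sim$s),
                             error = function(e) NA_real_),
          cosine = community_cosine_similarity(fit$params$u, sim$u),
          mu_hat = fit$params$mu,
          edge_auc_community = NA_real_, edge_auc_hierarchy = NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}
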