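test_that("cross-validation splits partition the ordered pairs", {
  sp <- make_cv_split(3, 2, seed = 1)
  counts <- table(sp$fold[!is.na(sp$fold)])
  expect_equal(as.numeric(counts), c(3, 3))
  expect_true(all(is.na(diag(sp$fold))))
  # folds are a disjoint cover
  total <- Reduce(`+`, lapply(1:2, function(f) cv_test_mask(sp, f)))
  expect_true(all(total[row(total) != col(total)] == 1))
  expect_identical(make_cv_split(10, 5, seed = 3)$fold,
                   make_cv_split(10, 5, seed = 3)$fold)
  expect_error(make_cv_split(3, 10), "folds")
  expect_error(make_cv_split(3, 1), "folds")
})

test_that("edge-prediction AUC is an exact rank statistic", {
  set.seed(21)
  A <- matrix(rpois(36, 0.7), 6); diag(A) <- 0L
  test_pairs <- matrix(TRUE, 6, 6)
  # scores equal to the counts rank perfectly (ties between equal counts)
  sc <- A + 0.001 * matrix(runif(36), 6)
  expect_equal(edge_prediction_auc(sc, A, test_pairs), 1)
  # constant scores are pure ties
  expect_equal(edge_prediction_auc(matrix(1, 6, 6), A, test_pairs), 0.5)
  # random scores match the brute-force pair count
  for (r in 1:5) {
    sc <- matrix(rnorm(36), 6)
    off <- row(A) != col(A)
    expect_equal(edge_prediction_auc(sc, A, test_pairs),
                 oracle_auc(sc[off], as.numeric(A[off] > 0)))
  }
  expect_error(edge_prediction_auc(matrix(1, 6, 6), matrix(0L, 6, 6),
                                   test_pairs), "AUC")
})

test_that("AUC is invariant under monotone transforms of the scores", {
  set.seed(22)
  sc <- matrix(rnorm(25), 5)
  A <- matrix(rpois(25, 0.5), 5); diag(A) <- 0L
  tp <- matrix(TRUE, 5, 5)
  a0 <- edge_prediction_auc(sc, A, tp)
  expect_equal(edge_prediction_auc(exp(3 * sc), A, tp), a0)
  expect_equal(edge_prediction_auc(atan(sc) + 5, A, tp), a0)
})

test_that("node-type AUC behaves at the extremes and under a null", {
  sig <- c(1, 0, 1, 0)
  expect_equal(node_type_auc(sig, sig), 1)
  expect_equal(node_type_auc(1 - sig, sig), 0)
  set.seed(23)
  nulls <- vapply(1:200, function(k)
    node_type_auc(runif(100), rbinom(100, 1, 0.5)), numeric(1))
  expect_lt(abs(mean(nulls) - 0.5), 0.02)
  expect_error(node_type_auc(runif(4), rep(1, 4)), "AUC")
})

test_that("community cosine similarity aligns columns by permutation", {
  u <- diag(3)[c(1, 1, 2, 3), ]
  expect_equal(community_cosine_similarity(u, u), 1)
  expect_equal(community_cosine_similarity(u[, c(3, 1, 2)], u), 1)
  # K = 2 toy with one mismatched node, against the hand value
  u_gt <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  u_hat <- rbind(c(0, 1), c(0, 1), c(1, 0), c(0, 1))  # swapped labels, one off
  expect_equal(community_cosine_similarity(u_hat, u_gt), 3 / 4)
  # zero-padding across different K
  expect_equal(community_cosine_similarity(cbind(u_gt, 0), u_gt), 1)
  expect_error(community_cosine_similarity(u_gt * 0, u_gt * 0), "all-zero")
})

test_that("score correlation is affine-invariant Pearson", {
  s <- rnorm(10)
  expect_equal(score_pearson(2 * s + 7, s), 1)
  expect_equal(score_pearson(-s, s), -1)
  a <- c(1, 3, 2, 5, 4); b <- c(2, 1, 4, 3, 5)
  ref <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(score_pearson(a, b), ref)
  expect_error(score_pearson(rep(1, 5), s[1:5]), "constant")
})

test_that("reciprocity counts returned edges in the induced subnetwork", {
  A <- matrix(0L, 2, 2); A[1, 2] <- 1L; A[2, 1] <- 2L
  expect_equal(reciprocity(A), 1)
  A[2, 1] <- 0L
  expect_equal(reciprocity(A), 0)
  # 4-node toy: 8 directed edges, 5 reciprocated
  B <- matrix(0L, 4, 4)
  B[1, 2] <- B[2, 1] <- 1L          # pair 1-2 reciprocated (2 edges)
  B[3, 4] <- B[4, 3] <- 1L          # pair 3-4 reciprocated (2 edges)
  B[1, 3] <- B[3, 1] <- 1L          # pair 1-3 reciprocated (2 edges)
  B[1, 4] <- 1L; B[2, 3] <- 1L      # two one-way edges
  expect_equal(reciprocity(B), 6 / 8)
  expect_error(reciprocity(matrix(0L, 3, 3)), "edgeless")
  expect_equal(reciprocity(B, 1:2), 1)
})

test_that("held-out pairs never influence the trained parameters", {
  sim <- sample_comrank(comrank_config(N = 40, K = 2, mu_gt = 0.3,
                                       avg_degree = 6, seed = 25))
  sp <- make_cv_split(40, 4, seed = 2)
  mask <- cv_train_mask(sp, 1)
  ctrl <- comrank_control(max_iter = 25)
  f1 <- comrank(sim$A, K = 2, beta = 5, n_init = 1, seed = 2, mask = mask,
                control = ctrl)
  A2 <- sim$A
  A2[cv_test_mask(sp, 1)] <- A2[cv_test_mask(sp, 1)] + 5L
  f2 <- comrank(A2, K = 2, beta = 5, n_init = 1, seed = 2, mask = mask,
                control = ctrl)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$Q, f2$Q)
})

test_that("K selection recovers the planted community count", {
  sim <- sample_comrank(comrank_config(N = 150, K = 3, mu_gt = 0,
                                       avg_degree = 16, seed = 26))
  sel <- suppressMessages(suppressWarnings(
    select_K(sim$A, K_grid = 2:4, beta = 5, folds = 2, n_init = 2, seed = 4,
             control = comrank_control(max_iter = 80))))
  expect_equal(as.integer(sel), 3L)
  tab <- attr(sel, "table")
  expect_equal(tab$K, 2:4)
  # single-element grid short-circuits to that K
  sel1 <- suppressMessages(suppressWarnings(
    select_K(sim$A, K_grid = 2, beta = 5, folds = 2, n_init = 1, seed = 4,
             control = comrank_control(max_iter = 30))))
  expect_equal(as.integer(sel1), 2L)
})

test_that("edge prediction beats the single-mechanism baselines at the extremes", {
  ctrl <- comrank_control(max_iter = 120)
  cfg <- comrank_config(N = 150, K = 3, avg_degree = 16)
  ext <- suppressMessages(comrank_benchmark(
    mu_grid = c(0, 1), n_samples = 1, folds = 3, n_init = 3,
    config = cfg, seed = 7, baselines = TRUE, control = ctrl,
    full_fit = FALSE))
  agg <- aggregate(ext[c("edge_auc", "edge_auc_community",
                         "edge_auc_hierarchy")],
                   by = list(mu = ext$mu_gt), mean, na.rm = TRUE)
  for (mu in c(0, 1)) {
    row <- agg[agg$mu == mu, ]
    expect_gte(row$edge_auc,
               max(row$edge_auc_community, row$edge_auc_hierarchy) - 0.02)
  }
  # the node-type task is hardest in the mixed regime
  mid <- suppressMessages(comrank_benchmark(
    mu_grid = c(0.1, 0.5, 0.9), n_samples = 1, folds = 2, n_init = 3,
    config = cfg, seed = 7, baselines = FALSE, control = ctrl,
    full_fit = FALSE))
  node <- aggregate(mid["node_auc"], by = list(mu = mid$mu_gt), mean,
                    na.rm = TRUE)
  expect_lt(node$node_auc[node$mu == 0.5],
            max(node$node_auc[node$mu %in% c(0.1, 0.9)], na.rm = TRUE) + 1e-9)
})
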