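#' @export
print.comrank <- function(x, ...) {
  cat("Community/hierarchy mixture model fit\n")
  cat(sprintf("  N = %d nodes, K = %d communities, beta = %.3g, lambda = %.3g\n",
              x$N, x$K, x$beta, x$lambda))
  cat(sprintf("  variational bound: %.4f (%s, best of %d restarts; final phase %d iterations)\n",
              x$objective, if (x$converged) "converged" else "not converged",
              x$best_of, x$iterations))
  cat(sprintf("  mean node-type posterior mean(Q) = %.3f (mu = %.3f, delta0 = %.4g, c = %.4g)\n",
              mean(x$Q), x$params$mu, x$params$delta0, x$params$c))
  invisible(x)
}

#' @export
summary.comrank <- function(object, ...) {
  Q <- object$Q
  out <- list(
    fit = object,
    n_hierarchy = sum(Q > 0.5),
    n_community = sum(Q <= 0.5),
    q_quartiles = stats::quantile(Q, c(0, 0.25, 0.5, 0.75, 1)),
    community_sizes = tabulate(apply(object$params$u, 1, which.max),
                               nbins = object$K),
    score_range = range(object$params$s)
  )
  class(out) <- "summary.comrank"
  out
}

#' @export
print.summary.comrank <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  node types: %d hierarchy-preferring (Q > 0.5), %d community-preferring\n",
              x$n_hierarchy, x$n_community))
  cat("  Q quartiles: ", paste(sprintf("%.3f", x$q_quartiles), collapse = " "), "\n")
  cat("  community sizes (argmax u): ",
      paste(x$community_sizes, collapse = ", "), "\n")
  cat(sprintf("  score range: [%.3f, %.3f]\n", x$score_range[1], x$score_range[2]))
  invisible(x)
}

#' @export
coef.comrank <- function(object, ...) {
  p <- object$params
  list(u = p$u, v = p$v, w = p$w, s = p$s, c = p$c, delta0 = p$delta0,
       mu = p$mu, Q = object$Q)
}

#' Predictions from a fitted model
#'
#' `type = "adjacency"` returns the posterior-expected edge rates
#' ([expected_adjacency()]), the scores used for edge prediction;
#' `type = "types"` returns the node-type posterior means Q.
#'
#' @param object a fitted `"comrank"` object.
#' @param type what to predict.
#' @param ... unused.
#' @export
predict.comrank <- function(object, type = c("adjacency", "types"), ...) {
  type <- match.arg(type)
  if (type == "types") return(object$Q)
  expected_adjacency(object$params, object$Q)
}

#' @export
fitted.comrank <- function(object, ...) expected_adjacency(object$params, object$Q)

#' @export
residuals.comrank <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  lam <- expected_adjacency(object$params, object$Q)
  r <- object$A - lam
  if (type == "pearson") r <- r / sqrt(clip_rate(lam))
  diag(r) <- NA
  r
}

#' @export
logLik.comrank <- function(object, ...) {
  p <- object$params
  val <- object$objective
  df <- length(p$u) + length(p$v) + length(p$w) + length(p$s) + 3
  structure(val, df = df, nobs = sum(object$mask), class = "logLik")
}

#' Simulate networks from a fitted model
#'
#' Draws node types from the fitted posterior means Q (or from the prior mu
#' with `use_posterior = FALSE`) and then Poisson edge counts from the
#' mechanism rates, exactly as the generative model prescribes.
#'
#' @param object a fitted `"comrank"` object.
#' @param nsim number of networks.
#' @param seed optional integer seed.
#' @param use_posterior draw types from Q (default) rather than from mu.
#' @param ... unused.
#' @return A list of `nsim` integer adjacency matrices.
#' @export
simulate.comrank <- function(object, nsim = 1, seed = NULL,
                             use_posterior = TRUE, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$params
  gt_base <- list(u = p$u, v = p$v, w = p$w, s = p$s, c = p$c, beta = p$beta)
  lapply(seq_len(nsim), function(k) {
    prob <- if (use_posterior) object$Q else rep(p$mu, object$N)
    gt <- gt_base
    gt$sigma <- rbinom(object$N, 1L, prob)
    sample_network(gt, p$delta0)
  })
}

#' Diagnostic plots for a fitted model
#'
#' Left: the variational bound across EM iterations of the winning restart.
#' Right: histogram of the node-type posterior means Q (values near 0.5 signal
#' ambiguous type assignment).
#'
#' @param x a fitted `"comrank"` object.
#' @param ... passed to `plot`.
#' @export
plot.comrank <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(seq_along(x$objective_trace), x$objective_trace, type = "l",
       xlab = "EM iteration", ylab = "variational bound",
       main = "Objective trace", ...)
  graphics::hist(x$Q, breaks = seq(0, 1, by = 0.05),
                 xlab = "node-type posterior Q", main = "Type posteriors")
  invisible(x)
}
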