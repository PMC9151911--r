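#' Read a directed weighted edge list
#'
#' Accepts 2- or 3-column delimited text (whitespace or comma, auto-detected):
#' source label, target label, optional non-negative integer weight (default
#' 1). Node labels are arbitrary strings, indexed by first appearance.
#' Duplicate (i, j) rows are summed; self-loops are dropped with a message.
#'
#' @param path file path.
#' @return Integer adjacency matrix with node labels as dimnames.
#' @export
read_edgelist <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*#", lines)]
  if (!length(lines)) stop_invalid("empty edge list: ", path)
  delim_comma <- mean(grepl(",", lines)) > 0.5
  parts <- if (delim_comma) strsplit(lines, "\\s*,\\s*")
           else strsplit(trimws(lines), "\\s+")
  src <- character(length(parts)); dst <- character(length(parts))
  wt <- numeric(length(parts))
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (length(p) < 2)
      stop_invalid("line ", k, ": expected at least source and target")
    src[k] <- p[1]; dst[k] <- p[2]
    if (length(p) >= 3) {
      w <- suppressWarnings(as.numeric(p[3]))
      if (!is.finite(w) || w < 0 || abs(w - round(w)) > 1e-8)
        stop_invalid("line ", k, ": weight must be a non-negative integer, got '",
                     p[3], "'")
      wt[k] <- w
    } else {
      wt[k] <- 1
    }
  }
  self <- src == dst
  if (any(self)) {
    message("dropped ", sum(self), " self-loop row(s)")
    src <- src[!self]; dst <- dst[!self]; wt <- wt[!self]
  }
  if (!length(src)) stop_invalid("no edges left after dropping self-loops")
  labels <- unique(as.vector(rbind(src, dst)))  # first-appearance order
  N <- length(labels)
  A <- matrix(0L, N, N, dimnames = list(labels, labels))
  ij <- cbind(match(src, labels), match(dst, labels))
  for (k in seq_len(nrow(ij))) A[ij[k, 1], ij[k, 2]] <- A[ij[k, 1], ij[k, 2]] + wt[k]
  storage.mode(A) <- "integer"
  A
}

#' Write an adjacency matrix as an edge list
#'
#' One row per non-zero ordered pair: source label, target label, weight.
#' Round-trips through [read_edgelist()].
#'
#' @param A adjacency matrix (dimnames used as labels when present).
#' @param path output file path.
#' @param sep field separator.
#' @export
write_edgelist <- function(A, path, sep = " ") {
  labels <- rownames(A)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(A)))
  nz <- which(A != 0 & row(A) != col(A), arr.ind = TRUE)
  df <- data.frame(source = labels[nz[, 1]], target = labels[nz[, 2]],
                   weight = A[nz])
  df <- df[order(nz[, 1], nz[, 2]), ]
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a synthetic benchmark instance to disk
#'
#' Emits the sampled edge list, a per-node ground-truth sidecar (type, planted
#' community, score, league) and a metadata file echoing the generating
#' configuration, so a run directory is self-describing.
#'
#' @param sim a [sample_comrank()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- as.character(seq_len(nrow(sim$A)))
  dimnames(sim$A) <- list(labels, labels)
  write_edgelist(sim$A, file.path(dir, "network.edgelist"))
  gt <- data.frame(node = labels, sigma = sim$sigma,
                   community = sim$community, s = sim$s, league = sim$league)
  write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(sim$config), file.path(dir, "generate_config.yaml"))
  invisible(dir)
}

#' Write fit (and optional evaluation) results to a directory
#'
#' Emits headered delimited text files: a per-node table (Q, s, argmax
#' community, full u and v rows), a scalar table (c, delta0, mu, objective,
#' convergence), the affinity matrix w, the objective trace, a metrics table
#' when given, and a machine-readable run summary echoing the resolved
#' configuration. All tables reload with `read.delim`.
#'
#' @param fit a fitted `"comrank"` object.
#' @param dir output directory (created if needed).
#' @param metrics optional data frame of evaluation metrics; if `NULL` or
#'   empty the metrics file is omitted and the summary notes it.
#' @param config optional list echoed verbatim into the run summary.
#' @return The directory, invisibly.
#' @export
write_results <- function(fit, dir, metrics = NULL, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- if (is.null(fit$labels)) as.character(seq_len(fit$N)) else fit$labels
  p <- fit$params
  node <- data.frame(node = labels, Q = fit$Q, s = p$s,
                     community = apply(p$u, 1, function(r)
                       if (all(r == 0)) NA_integer_ else which.max(r)))
  colnames_u <- paste0("u", seq_len(ncol(p$u)))
  colnames_v <- paste0("v", seq_len(ncol(p$v)))
  node[colnames_u] <- p$u
  node[colnames_v] <- p$v
  write.table(node, file.path(dir, "node_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  scalars <- data.frame(
    parameter = c("c", "delta0", "mu", "objective", "converged", "best_of",
                  "K", "beta", "lambda"),
    value = c(p$c, p$delta0, p$mu, fit$objective, as.numeric(fit$converged),
              fit$best_of, fit$K, fit$beta, fit$lambda))
  write.table(scalars, file.path(dir, "scalars.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(p$w, file.path(dir, "w.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = paste0("k", seq_len(ncol(p$w))))
  write.table(data.frame(iteration = seq_along(fit$objective_trace),
                         objective = fit$objective_trace),
              file.path(dir, "trace.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  has_metrics <- !is.null(metrics) && nrow(as.data.frame(metrics)) > 0
  if (has_metrics)
    write.table(as.data.frame(metrics), file.path(dir, "metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    seed = fit$seed, K = fit$K, beta = fit$beta, lambda = fit$lambda,
    n_nodes = fit$N, objective = fit$objective, converged = fit$converged,
    best_of = fit$best_of, metrics_written = has_metrics)
  if (!has_metrics) summary$note <- "no metrics computed; metrics.tsv omitted"
  if (!is.null(config)) summary$config <- config
  yaml::write_yaml(summary, file.path(dir, "run_summary.yaml"))
  invisible(dir)
}
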