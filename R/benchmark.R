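# AUPR scoring and the benchmark protocol.

#' Precision-recall curve and area for ranked scores
#'
#' Candidates are ranked by decreasing score; tied scores are treated as a
#' single threshold step (equivalently, averaged over the tied block), and
#' the area is the step-wise sum of precision times recall increments.
#'
#' @param scores numeric vector of candidate scores (higher = more
#'   confident).
#' @param labels 0/1 (or logical) ground-truth labels.
#' @return A list with `precision`, `recall` (one point per distinct score,
#'   descending) and `aupr`.
#' @export
pr_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels != 0)
  pos <- sum(labels)
  if (pos == 0) stop("no positive labels")
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  block_end <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie block
  tp <- cumsum(l)[block_end]
  fp <- cumsum(1 - l)[block_end]
  precision <- tp / (tp + fp)
  recall <- tp / pos
  aupr <- sum(diff(c(0, recall)) * precision)
  list(precision = precision, recall = recall, aupr = aupr)
}

#' Area under the precision-recall curve for an edge score matrix
#'
#' Ranks off-diagonal entries of `scores` by magnitude against the binary
#' ground truth (signs of `truth` are dropped). Diagonal entries
#' (self-regulation) are excluded. In undirected mode both matrices are
#' symmetrised by the maximal magnitude over the two directions and
#' unordered pairs are scored.
#'
#' @param scores real edge score matrix (targets in rows, as in
#'   [coef.grn_fit()]).
#' @param truth adjacency matrix of the same shape; nonzero = true edge.
#' @param directed score ordered pairs (`TRUE`) or unordered pairs.
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(scores, truth, directed = TRUE) {
  scores <- as.matrix(scores)
  truth <- as.matrix(truth)
  if (!all(dim(scores) == dim(truth))) stop("shape mismatch")
  s <- abs(scores)
  l <- abs(sign(truth))
  if (directed) {
    mask <- row(s) != col(s)
    pr_curve(s[mask], l[mask])$aupr
  } else {
    sym <- function(m) pmax(m, t(m))
    s <- sym(s)
    l <- sym(l)
    mask <- upper.tri(s)
    pr_curve(s[mask], l[mask])$aupr
  }
}

#' Pearson-correlation baseline scorer
#'
#' Assigns each unordered edge the absolute Pearson correlation between the
#' two count columns, pooled over all timepoints (stimulus indicator
#' included as a node). Zero-variance genes score 0; the diagonal is 0.
#'
#' @param data a [snapshot_data()].
#' @return Symmetric nonnegative score matrix.
#' @export
pearson_baseline <- function(data) {
  stopifnot(inherits(data, "snapshot_data"))
  if (nrow(data$counts) < 2) stop("need at least two cells")
  m <- suppressWarnings(abs(cor(data$counts)))
  m[!is.finite(m)] <- 0
  diag(m) <- 0
  m
}

score_method <- function(method, data, net, seed) {
  switch(method,
    cardamom_like = {
      fit <- fit_grn(data, d0 = net$params$d0, d1 = net$params$d1,
                     seed = seed)
      fit$theta
    },
    pearson = pearson_baseline(data),
    random = with_seed(seed, {
      m <- matrix(as.numeric(runif((net$params$n_genes + 1)^2) < 0.5),
                  net$params$n_genes + 1, net$params$n_genes + 1)
      diag(m) <- 0
      m
    }),
    stop("unknown method '", method, "'"))
}

#' Run the snapshot-inference benchmark
#'
#' For every network and replicate, simulates an independent time-stamped
#' dataset, scores edges with each method and computes directed and
#' undirected AUPR against the ground truth. Methods: `cardamom_like` (the
#' package's own calibration, supplied with the true degradation rates),
#' `pearson` (absolute correlation baseline) and `random` (0/1 coin-flip
#' scores whose expected AUPR is the edge prevalence).
#'
#' @param networks a list of `benchmark_network` objects ([make_network()],
#'   [random_tree()]), or a single one.
#' @param methods subset of `c("cardamom_like", "pearson", "random")`.
#' @param n_replicates independently simulated datasets per network.
#' @param schedule a [simulation_schedule()]; default [benchmark_schedule()].
#' @param seed integer root seed; the whole table is reproducible from it.
#' @return A `benchmark_result`: data frame with columns `network`,
#'   `method`, `replicate`, `directed`, `aupr`.
#' @export
run_benchmark <- function(networks,
                          methods = c("cardamom_like", "pearson", "random"),
                          n_replicates = 10,
                          schedule = benchmark_schedule(), seed = 0) {
  if (inherits(networks, "benchmark_network")) networks <- list(networks)
  methods <- match.arg(methods, c("cardamom_like", "pearson", "random"),
                       several.ok = TRUE)
  rows <- list()
  for (nk in seq_along(networks)) {
    net <- networks[[nk]]
    for (rep in seq_len(n_replicates)) {
      sim_seed <- derive_seed(seed, nk * 10000L + rep)
      data <- simulate_snapshots(net$params, schedule, seed = sim_seed)
      for (method in methods) {
        sc <- score_method(method, data, net,
                           seed = derive_seed(sim_seed, match(method, methods)))
        for (dir in c(TRUE, FALSE)) {
          rows[[length(rows) + 1]] <- data.frame(
            network = net$name, method = method, replicate = rep,
            directed = dir, aupr = aupr(sc, net$truth, directed = dir))
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(network = character(), method = character(),
               replicate = integer(), directed = logical(), aupr = numeric())
  class(out) <- c("benchmark_result", "data.frame")
  out
}

#' @export
summary.benchmark_result <- function(object, ...) {
  df <- as.data.frame(object)
  if (!nrow(df)) return(df)
  agg <- aggregate(aupr ~ network + method + directed, df, function(v)
    c(median = median(v), q1 = quantile(v, 0.25, names = FALSE),
      q3 = quantile(v, 0.75, names = FALSE)))
  cbind(agg[, 1:3], as.data.frame(agg$aupr))
}

#' @export
plot.benchmark_result <- function(x, directed = FALSE, ...) {
  df <- as.data.frame(x)
  df <- df[df$directed == directed, ]
  graphics::boxplot(aupr ~ method + network, data = df, las = 2,
                    ylab = "AUPR", main = if (directed) "Directed" else "Undirected",
                    ...)
  invisible(x)
}

# Rebuild a schedule for one sweep value under the stated budget constraint.
sweep_schedule <- function(axis, value, base) {
  tp <- base$timepoints
  total <- sum(base$cells_per_timepoint)
  redistribute <- function(tp_new, total) {
    k <- length(tp_new)
    cells <- rep(total %/% k, k)
    spill <- total - sum(cells)
    if (spill > 0) cells[seq_len(spill)] <- cells[seq_len(spill)] + 1L
    if (any(cells < 1)) stop("infeasible schedule: more timepoints than cells")
    simulation_schedule(tp_new, cells, base$burnin, base$rate_scale_after)
  }
  switch(axis,
    cells = simulation_schedule(tp, value, base$burnin,
                                base$rate_scale_after),
    period_length = {
      gap <- tp[2] - tp[1]
      redistribute(seq(0, value, by = gap), total)
    },
    gap = redistribute(seq(0, tp[length(tp)], by = value), total),
    stop("axis must be one of 'cells', 'period_length', 'gap'"))
}

#' Experiment-design sweep
#'
#' Measures inference performance while varying one design axis: the number
#' of cells per timepoint (`cells`, timepoints unchanged), the length of the
#' measurement period (`period_length`, same gap between timepoints, total
#' cell budget fixed and redistributed evenly with spillover to the earliest
#' timepoints), or the gap between timepoints (`gap`, same final timepoint,
#' total cell budget fixed). Each value is benchmarked on fresh random tree
#' networks.
#'
#' @param axis one of `"cells"`, `"period_length"`, `"gap"`.
#' @param values numeric values of the swept axis.
#' @param base_schedule the reference [simulation_schedule()].
#' @param n_genes size of the random tree networks.
#' @param methods,n_replicates,seed as in [run_benchmark()].
#' @return A `benchmark_result` with an extra `axis_value` column.
#' @export
design_sweep <- function(axis, values, base_schedule = benchmark_schedule(),
                         n_genes = 10,
                         methods = c("cardamom_like", "pearson", "random"),
                         n_replicates = 10, seed = 0) {
  # the same tree networks are reused across axis values (paired design), so
  # the sweep measures the effect of the design axis, not tree-to-tree
  # variability
  nets <- lapply(seq_len(n_replicates), function(r)
    random_tree(n_genes, seed = derive_seed(seed, 500L + r)))
  rows <- list()
  for (vi in seq_along(values)) {
    sched <- sweep_schedule(axis, values[vi], base_schedule)
    res <- run_benchmark(nets, methods = methods, n_replicates = 1,
                         schedule = sched,
                         seed = derive_seed(seed, 777000L + vi))
    res$replicate <- match(res$network, unique(res$network))
    res$network <- sprintf("Tree(%d)", n_genes)
    res$axis <- axis
    res$axis_value <- values[vi]
    rows[[vi]] <- res
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_result", "data.frame")
  out
}
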