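# Ground-truth network zoo.
#
# The canonical topologies follow the published textual descriptions
# (feedback-loop networks FN4/FN8, cycling network CN5, branching network
# BN8 with a dominating toggle switch); the exact published edge weights are
# distributed only with external code, so all edges here default to
# magnitude 10 (negative for inhibitions) and all basal activities to -5,
# which keeps genes off until activated and lets an active regulator (protein
# on the [0, 1] scale) drive its targets to near-maximal burst frequency.
# Users with the original weights can swap them in through `edges`.

ZOO_EDGE_STRENGTH <- 10
ZOO_BASAL <- -5

zoo_edges <- list(
  # stimulus -> 1 branching into 2 and 3, chain to 4, 4 inhibits 1
  FN4 = data.frame(
    from = c(0, 1, 1, 3, 4),
    to   = c(1, 2, 3, 4, 1),
    sign = c(1, 1, 1, 1, -1)),
  # stimulus -> 1 and a 5-gene directed cycle
  CN5 = data.frame(
    from = c(0, 1, 2, 3, 4, 5),
    to   = c(1, 2, 3, 4, 5, 1),
    sign = c(1, 1, 1, 1, 1, 1)),
  # multiple branches with two inhibition feedback loops
  FN8 = data.frame(
    from = c(0, 1, 1, 2, 3, 4, 5, 6, 7, 8),
    to   = c(1, 2, 3, 4, 5, 6, 7, 8, 1, 2),
    sign = c(1, 1, 1, 1, 1, 1, 1, 1, -1, -1)),
  # branching network dominated by a toggle switch between 2 and 3
  BN8 = data.frame(
    from = c(0, 1, 1, 2, 3, 2, 4, 3, 6, 7),
    to   = c(1, 2, 3, 3, 2, 4, 5, 6, 7, 8),
    sign = c(1, 1, 1, -1, -1, 1, 1, 1, 1, 1))
)

edges_to_params <- function(n, edges, strength = ZOO_EDGE_STRENGTH,
                            basal = ZOO_BASAL) {
  theta <- matrix(0, n + 1, n + 1)
  theta[cbind(edges$to + 1, edges$from + 1)] <- edges$sign * strength
  grn_params(n, theta = theta, beta = basal)
}

#' Canonical benchmark networks
#'
#' Returns one of the ground-truth networks used for benchmarking
#' inference: `FN4` (4 genes, branching plus an inhibition feedback loop),
#' `CN5` (5 genes in a directed cycle fed by the stimulus), `FN8` (8 genes,
#' multiple branches with inhibition feedback loops) and `BN8` (8 genes,
#' branching dominated by a mutual-inhibition toggle switch). Edge
#' magnitudes default to 10 (negative for inhibitions) and basal activities
#' to -5; kinetic defaults are those of [grn_params()].
#'
#' @param name one of `"FN4"`, `"CN5"`, `"FN8"`, `"BN8"`.
#' @return An object of class `benchmark_network`: `name`, `params`
#'   (a [grn_params()]) and `truth` (the signed ground-truth adjacency,
#'   diagonal excluded).
#' @seealso [random_tree()], [run_benchmark()]
#' @export
make_network <- function(name) {
  if (!name %in% names(zoo_edges))
    stop("unknown network '", name, "'; available: ",
         paste(names(zoo_edges), collapse = ", "))
  edges <- zoo_edges[[name]]
  n <- max(edges$from, edges$to)
  params <- edges_to_params(n, edges)
  truth <- sign(params$theta)
  diag(truth) <- 0
  structure(list(name = name, params = params, truth = truth),
            class = "benchmark_network")
}

#' @export
print.benchmark_network <- function(x, ...) {
  cat(sprintf("Benchmark network %s: %d genes + stimulus, %d edges (%d inhibitory)\n",
              x$name, x$params$n_genes, sum(x$truth != 0), sum(x$truth < 0)))
  invisible(x)
}

#' Uniformly random tree-structured activation network
#'
#' Samples a labelled tree on `n_genes + 1` nodes uniformly at random
#' (Pruefer-sequence construction), roots it at the stimulus node and
#' directs all edges away from the root; every edge is an activation of the
#' default zoo strength.
#'
#' @param n_genes number of genes (tree has `n_genes + 1` nodes).
#' @param seed integer seed.
#' @return A `benchmark_network` (see [make_network()]).
#' @export
random_tree <- function(n_genes, seed = 0) {
  if (n_genes < 1) stop("n_genes must be at least 1")
  n_nodes <- n_genes + 1
  edges <- with_seed(seed, {
    if (n_nodes == 2) {
      matrix(c(1L, 2L), 1, 2)
    } else {
      prufer <- sample.int(n_nodes, n_nodes - 2, replace = TRUE)
      degree <- rep(1L, n_nodes)
      for (v in prufer) degree[v] <- degree[v] + 1L
      e <- matrix(0L, n_nodes - 1, 2)
      ptr <- 1L
      for (k in seq_along(prufer)) {
        leaf <- which(degree == 1L)[1]
        e[k, ] <- c(leaf, prufer[k])
        degree[leaf] <- 0L
        degree[prufer[k]] <- degree[prufer[k]] - 1L
      }
      e[n_nodes - 1, ] <- which(degree == 1L)
      e
    }
  })
  # orient away from the root (node 1 = stimulus) by BFS
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  from <- to <- integer(n_nodes - 1)
  visited <- rep(FALSE, n_nodes)
  visited[1] <- TRUE
  queue <- 1L
  k <- 0L
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (visited[w]) next
      k <- k + 1L
      from[k] <- v - 1L
      to[k] <- w - 1L
      visited[w] <- TRUE
      queue <- c(queue, w)
    }
  }
  edges_df <- data.frame(from = from, to = to, sign = 1)
  params <- edges_to_params(n_genes, edges_df)
  truth <- sign(params$theta)
  diag(truth) <- 0
  structure(list(name = sprintf("Tree(%d)", n_genes), params = params,
                 truth = truth), class = "benchmark_network")
}
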