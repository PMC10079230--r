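# Dataset-fidelity metrics: KS heatmaps, EMD curves, count summaries.

check_comparable <- function(reference, simulated) {
  stopifnot(inherits(reference, "snapshot_data"),
            inherits(simulated, "snapshot_data"))
  if (!identical(reference$gene_names, simulated$gene_names))
    stop("datasets have mismatched gene sets")
  tp <- sort(unique(reference$time))
  if (!setequal(tp, unique(simulated$time)))
    stop("datasets have mismatched timepoint sets")
  tp
}

#' Per-gene, per-timepoint Kolmogorov-Smirnov comparison
#'
#' Two-sample KS test between the count marginals of the two datasets, for
#' every gene at every timepoint. On discrete counts the test is
#' conservative (ties); it is used as-is, without continuity correction. A
#' cell of the heatmap is conventionally called "green" when p >= 0.05,
#' i.e. the simulated marginal is not significantly different from the
#' reference.
#'
#' @param reference,simulated [snapshot_data()] objects over the same genes
#'   and timepoints. The statistic is symmetric in the two arguments.
#' @return Matrix of p-values, genes x timepoints.
#' @seealso [emd_curve()], [compare_datasets()]
#' @export
ks_heatmap <- function(reference, simulated) {
  tp <- check_comparable(reference, simulated)
  genes <- reference$gene_names[-1]
  out <- matrix(NA_real_, length(genes), length(tp),
                dimnames = list(genes, tp))
  for (k in seq_along(tp)) {
    r <- reference$counts[reference$time == tp[k], -1, drop = FALSE]
    s <- simulated$counts[simulated$time == tp[k], -1, drop = FALSE]
    for (i in seq_along(genes)) {
      out[i, k] <- suppressWarnings(
        ks.test(r[, i], s[, i], exact = FALSE)$p.value)
    }
  }
  out
}

# 1-D earth mover's distance between two count samples: the L1 distance
# between their ECDFs over the integer grid (grid step 1).
emd_1d <- function(x, y) {
  hi <- max(x, y)
  grid <- 0:max(hi, 1)
  sum(abs(ecdf(x)(grid) - ecdf(y)(grid)))
}

#' Mean earth mover's distance per timepoint
#'
#' For each gene and timepoint, the 1-D earth mover's (Wasserstein-1)
#' distance between the two empirical count distributions, computed as the
#' sum of absolute ECDF differences over the integer count grid; averaged
#' over genes with equal weights per timepoint. Genes that are all-zero in
#' both datasets are excluded from the average.
#'
#' @inheritParams ks_heatmap
#' @return Named numeric vector, one mean EMD per timepoint.
#' @export
emd_curve <- function(reference, simulated) {
  tp <- check_comparable(reference, simulated)
  genes <- reference$gene_names[-1]
  degenerate <- colSums(reference$counts[, -1, drop = FALSE]) == 0 &
    colSums(simulated$counts[, -1, drop = FALSE]) == 0
  out <- setNames(numeric(length(tp)), tp)
  for (k in seq_along(tp)) {
    r <- reference$counts[reference$time == tp[k], -1, drop = FALSE]
    s <- simulated$counts[simulated$time == tp[k], -1, drop = FALSE]
    vals <- vapply(which(!degenerate), function(i) emd_1d(r[, i], s[, i]),
                   numeric(1))
    out[k] <- mean(vals)
  }
  out
}

#' Count summary statistics of a snapshot dataset
#'
#' The battery of per-dataset summaries used for dataset comparison:
#' per-cell library sizes (total counts excluding the stimulus column),
#' per-cell and per-gene zero fractions, gene-gene correlations over all
#' gene pairs, and cell-cell correlations over random seeded cell pairings.
#' In data shaped by a working network the cell-cell correlations are
#' bimodal (cells pair either with like-typed or with "antinomic" cells), a
#' signature of emerging cell types that no-interaction data lack.
#'
#' @param data a [snapshot_data()].
#' @param n_pairs number of random cell pairings.
#' @param seed integer seed for the pairings.
#' @return A list with `library_size`, `zero_fraction_cell`,
#'   `zero_fraction_gene`, `gene_gene_cor`, `cell_cell_cor`.
#' @export
summary_stats <- function(data, n_pairs = 10000, seed = 0) {
  stopifnot(inherits(data, "snapshot_data"))
  m <- data$counts[, -1, drop = FALSE]
  lib <- rowSums(m)
  zf_cell <- rowMeans(m == 0)
  zf_gene <- colMeans(m == 0)
  cc <- suppressWarnings(cor(m))
  gg <- cc[upper.tri(cc)]
  gg <- gg[is.finite(gg)]
  ccc <- with_seed(seed, {
    i <- sample.int(nrow(m), n_pairs, replace = TRUE)
    j <- sample.int(nrow(m), n_pairs, replace = TRUE)
    keep <- i != j
    vapply(which(keep), function(k)
      suppressWarnings(cor(m[i[k], ], m[j[k], ])), numeric(1))
  })
  ccc <- ccc[is.finite(ccc)]
  list(library_size = lib, zero_fraction_cell = zf_cell,
       zero_fraction_gene = zf_gene, gene_gene_cor = gg,
       cell_cell_cor = ccc)
}

#' Full fidelity report comparing two snapshot datasets
#'
#' Bundles the KS p-value heatmap, the per-timepoint mean p-values and mean
#' EMD curve, and the summary-statistics blocks of both datasets.
#'
#' @inheritParams ks_heatmap
#' @param seed seed for the random cell pairings in [summary_stats()].
#' @return An object of class `fidelity_report`.
#' @export
compare_datasets <- function(reference, simulated, seed = 0) {
  ks <- ks_heatmap(reference, simulated)
  structure(list(
    ks_pvalues = ks,
    mean_pvalue_by_time = colMeans(ks, na.rm = TRUE),
    emd_by_time = emd_curve(reference, simulated),
    green_fraction = mean(ks >= 0.05, na.rm = TRUE),
    summaries = list(reference = summary_stats(reference, seed = seed),
                     simulated = summary_stats(simulated, seed = seed))),
    class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("Dataset fidelity report\n")
  cat(sprintf("  KS green cells (p >= 0.05): %.1f%%\n",
              100 * x$green_fraction))
  cat("  mean EMD by timepoint:\n")
  print(round(x$emd_by_time, 2))
  cat("  mean KS p-value by timepoint:\n")
  print(round(x$mean_pvalue_by_time, 3))
  invisible(x)
}
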