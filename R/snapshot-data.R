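#' Time-stamped snapshot dataset
#'
#' Container for a time-stamped single-cell count matrix: one row per cell,
#' one column per node. Column 1 is the stimulus indicator (0 for cells
#' sampled before stimulus onset, 1 afterwards); the remaining columns hold
#' integer mRNA counts. Each cell carries the timepoint (hours) at which it
#' was sampled and destroyed — rows are independent cells, not trajectories.
#'
#' @param counts nonnegative integer matrix, cells x (n_genes + 1).
#' @param time numeric vector of per-cell time labels (hours).
#' @param gene_names node names (stimulus first); defaults to the column
#'   names of `counts`.
#' @return An object of class `snapshot_data` with fields `counts`, `time`,
#'   `gene_names`.
#' @seealso [simulate_snapshots()], [read_counts()], [fit_grn()]
#' @export
snapshot_data <- function(counts, time, gene_names = colnames(counts)) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (length(time) != nrow(counts))
    stop("time must have one label per cell (row)")
  if (!all(counts[, 1] %in% c(0L, 1L)))
    stop("stimulus column (column 1) must be 0/1")
  if (is.null(gene_names)) gene_names <- c("Stimulus", paste0("Gene", seq_len(ncol(counts) - 1)))
  colnames(counts) <- gene_names
  structure(list(counts = counts, time = as.numeric(time),
                 gene_names = gene_names), class = "snapshot_data")
}

#' @export
print.snapshot_data <- function(x, ...) {
  tp <- sort(unique(x$time))
  cat(sprintf("Time-stamped snapshot dataset: %d cells x %d genes (+ stimulus)\n",
              nrow(x$counts), ncol(x$counts) - 1))
  cat("  timepoints (h):", paste(tp, collapse = ", "), "\n")
  cat("  cells per timepoint:",
      paste(tabulate(match(x$time, tp)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.snapshot_data <- function(x) dim(x$counts)

#' Read / write time-stamped count files
#'
#' Tab-delimited layout with a header: a `cell` identifier column, a `time`
#' column (hours), a `Stimulus` indicator column and one integer count
#' column per gene. `write_counts()` followed by `read_counts()` restores
#' the dataset exactly.
#'
#' @param path file path.
#' @param data a [snapshot_data()] object.
#' @return `read_counts()` returns a [snapshot_data()]; `write_counts()`
#'   returns `path` invisibly.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("no such counts file: ", path)
  df <- read.delim(path, check.names = FALSE)
  for (col in c("cell", "time", "Stimulus"))
    if (!col %in% names(df))
      stop(sprintf("counts file must have a '%s' column", col))
  if (names(df)[1] != "cell" || names(df)[2] != "time")
    stop("counts file layout: first column 'cell', second column 'time', then counts")
  if (anyDuplicated(df$cell)) stop("duplicate cell ids in counts file")
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(counts) || any(counts != round(counts)))
    stop("count columns must be integers")
  counts <- counts[, c("Stimulus", setdiff(colnames(counts), "Stimulus")),
                   drop = FALSE]
  snapshot_data(counts, df$time)
}

#' @rdname read_counts
#' @export
write_counts <- function(data, path) {
  stopifnot(inherits(data, "snapshot_data"))
  df <- data.frame(cell = paste0("cell", seq_len(nrow(data$counts))),
                   time = data$time, data$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
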