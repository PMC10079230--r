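#' Parameterisation of the bursty GRN model
#'
#' Builds the full generative parameterisation of the mechanistic network
#' model. Each gene follows a bursty two-state expression process: mRNA is
#' produced in instantaneous bursts of exponentially distributed size (mean
#' `burst_size_mean`, in mRNA copies), occurring at a protein-dependent
#' frequency between `k0` and `k1` (per hour); mRNA decays at rate `d0` and
#' is translated into protein at rate `s1`, protein decaying at rate `d1`.
#' Genes are coupled through the burst frequency
#' \deqn{k_{on,i}(P) = k_{0,i} + (k_{1,i} - k_{0,i})\,
#'   \sigma(\beta_i + \textstyle\sum_j \theta_{ij} P_j),}
#' where \eqn{\sigma} is the logistic function, \eqn{\beta_i} the basal
#' activity of gene i and \eqn{\theta_{ij}} the signed strength of the
#' interaction j -> i. Node 0 is the experimental stimulus: a virtual gene
#' with a protein level only, equal to 0 before time 0 and 1 afterwards.
#' Row 0 of `theta` is therefore constrained to zero.
#'
#' By default `s1` is set to `d0 * d1 / (k1 * burst_size_mean)`, which makes
#' the stationary mean protein level of a gene bursting at its maximal
#' frequency equal to 1, so proteins live on the same `[0, 1]` scale as the
#' stimulus and `theta`/`beta` are scale-free.
#'
#' @param n_genes number of modelled genes (stimulus excluded).
#' @param theta `(n_genes+1) x (n_genes+1)` signed interaction matrix; entry
#'   `[i+1, j+1]` is the strength of interaction j -> i (0-based node
#'   indices, node 0 = stimulus). Defaults to no interactions.
#' @param beta basal activities, recycled to length `n_genes`.
#' @param k0,k1 minimal and maximal burst frequencies (per hour).
#' @param burst_size_mean mean burst size (mRNA copies per burst).
#' @param s1 protein synthesis rate per mRNA per hour; see Details for the
#'   default normalisation.
#' @param d0,d1 mRNA and protein degradation rates (per hour).
#' @param gene_names names of the `n_genes + 1` nodes; element 1 is the
#'   stimulus label.
#'
#' @return An object of class `grn_params`.
#' @examples
#' p <- grn_params(2)
#' p$theta[2, 1] <- 10  # stimulus activates gene 1
#' p$theta[3, 2] <- 10  # gene 1 activates gene 2
#' validate_grn_params(p)
#' @seealso [burst_frequency()], [simulate_snapshots()], [make_network()]
#' @export
grn_params <- function(n_genes, theta = NULL, beta = 0, k0 = 0, k1 = 2,
                       burst_size_mean = 50, s1 = NULL, d0 = 0.5, d1 = 0.1,
                       gene_names = NULL) {
  stopifnot(is.numeric(n_genes), length(n_genes) == 1, n_genes >= 1)
  n <- as.integer(n_genes)
  if (is.null(theta)) theta <- matrix(0, n + 1, n + 1)
  theta <- as.matrix(theta)
  rec <- function(x) rep_len(as.numeric(x), n)
  k0 <- rec(k0); k1 <- rec(k1); burst_size_mean <- rec(burst_size_mean)
  d0 <- rec(d0); d1 <- rec(d1); beta <- rec(beta)
  if (is.null(s1)) s1 <- d0 * d1 / (k1 * burst_size_mean) else s1 <- rec(s1)
  if (is.null(gene_names)) gene_names <- c("Stimulus", paste0("Gene", seq_len(n)))
  dimnames(theta) <- list(gene_names, gene_names)
  obj <- structure(list(
    n_genes = n, theta = theta, beta = beta, k0 = k0, k1 = k1,
    burst_size_mean = burst_size_mean, s1 = s1, d0 = d0, d1 = d1,
    gene_names = gene_names), class = "grn_params")
  bad <- validate_grn_params(obj)
  if (length(bad)) stop("invalid grn_params: ", paste(bad, collapse = "; "))
  obj
}

#' Validate a GRN parameterisation
#'
#' Checks the structural invariants of a [grn_params()] object and reports
#' violations instead of raising, so callers can surface them all at once.
#'
#' @param params a `grn_params` object (or a list with the same fields).
#' @return A character vector of violation descriptions; empty if valid.
#' @export
validate_grn_params <- function(params) {
  v <- character()
  n <- params$n_genes
  chk_len <- function(x, nm) {
    if (length(params[[x]]) != n) v <<- c(v, sprintf("%s must have length %d", nm, n))
  }
  for (f in c("beta", "k0", "k1", "burst_size_mean", "s1", "d0", "d1"))
    chk_len(f, f)
  num <- function(x) is.numeric(params[[x]]) && all(is.finite(params[[x]]))
  for (f in c("theta", "beta", "k0", "k1", "burst_size_mean", "s1", "d0", "d1"))
    if (!num(f)) v <- c(v, sprintf("%s must be finite numeric", f))
  if (num("k0") && any(params$k0 < 0)) v <- c(v, "k0 must be nonnegative")
  for (f in c("k1", "burst_size_mean", "s1", "d0", "d1"))
    if (num(f) && any(params[[f]] <= 0))
      v <- c(v, sprintf("%s must be strictly positive", f))
  if (num("k0") && num("k1") && length(params$k0) == length(params$k1) &&
      any(params$k0 > params$k1))
    v <- c(v, "k0 must not exceed k1")
  th <- params$theta
  if (!is.matrix(th) || nrow(th) != n + 1 || ncol(th) != n + 1)
    v <- c(v, sprintf("theta must be a %d x %d matrix", n + 1, n + 1))
  else if (is.numeric(th) && any(th[1, ] != 0))
    v <- c(v, "theta stimulus row (row 0) must be all zeros: nothing regulates the stimulus")
  if (length(params$gene_names) != n + 1)
    v <- c(v, sprintf("gene_names must have length %d", n + 1))
  v
}

#' Burst frequency of a gene given protein levels
#'
#' Evaluates \eqn{k_{on,i}(P) = k_{0,i} + (k_{1,i}-k_{0,i})\sigma(\beta_i +
#' \sum_j \theta_{ij} P_j)}, the instantaneous transcriptional burst
#' frequency of gene `i` under protein state `P`. Strictly between `k0[i]`
#' and `k1[i]` for finite arguments when `k0[i] < k1[i]`.
#'
#' @param params a [grn_params()] object.
#' @param P nonnegative protein vector of length `n_genes + 1`; `P[1]` is the
#'   stimulus protein level in `[0, 1]`.
#' @param i gene index in `1..n_genes` (may be a vector).
#' @return Burst frequency (per hour), same length as `i`.
#' @examples
#' p <- grn_params(1, beta = 0)
#' burst_frequency(p, c(0, 0), 1)  # 2 * sigmoid(0) = 1
#' @export
burst_frequency <- function(params, P, i = seq_len(params$n_genes)) {
  P <- as.numeric(P)
  if (length(P) != params$n_genes + 1)
    stop("P must have length n_genes + 1 (including the stimulus entry)")
  if (!all(is.finite(P))) stop("non-finite protein levels")
  if (any(i < 1 | i > params$n_genes)) stop("gene index out of range")
  x <- params$beta[i] + drop(params$theta[i + 1, , drop = FALSE] %*% P)
  unname(params$k0[i] + (params$k1[i] - params$k0[i]) * sigmoid(x))
}

#' Read / write a network parameter file pair
#'
#' A network is stored as two tab-delimited files under a common prefix:
#' `<prefix>.theta.tsv`, the `(n+1) x (n+1)` interaction matrix with a header
#' row and a leading column of node names (node 0 = `"Stimulus"`), and
#' `<prefix>.rates.tsv`, a table with columns `gene`, `k0`, `k1`,
#' `burst_size_mean`, `s1`, `d0`, `d1`, `beta` (one row per modelled gene).
#' `write_network()` followed by `read_network()` is the identity up to
#' floating-point round-trip.
#'
#' @param path file prefix (without the `.theta.tsv` / `.rates.tsv` suffix).
#' @param params a [grn_params()] object.
#' @return `read_network()` returns a `grn_params` object; `write_network()`
#'   returns `path` invisibly.
#' @export
read_network <- function(path) {
  theta_file <- paste0(path, ".theta.tsv")
  rates_file <- paste0(path, ".rates.tsv")
  for (f in c(theta_file, rates_file))
    if (!file.exists(f)) stop("missing network file: ", f)
  th <- read.delim(theta_file, check.names = FALSE)
  gene_names <- as.character(th[[1]])
  theta <- as.matrix(th[, -1, drop = FALSE])
  if (nrow(theta) != ncol(theta))
    stop("malformed theta file: matrix is not square")
  storage.mode(theta) <- "double"
  rates <- read.delim(rates_file, check.names = FALSE)
  need <- c("gene", "k0", "k1", "burst_size_mean", "s1", "d0", "d1", "beta")
  if (!all(need %in% names(rates)))
    stop("rate table must have columns: ", paste(need, collapse = ", "))
  n <- nrow(theta) - 1
  if (nrow(rates) != n)
    stop(sprintf("dimension mismatch: theta implies %d genes but rate table has %d rows",
                 n, nrow(rates)))
  obj <- structure(list(
    n_genes = as.integer(n), theta = theta, beta = rates$beta, k0 = rates$k0,
    k1 = rates$k1, burst_size_mean = rates$burst_size_mean, s1 = rates$s1,
    d0 = rates$d0, d1 = rates$d1, gene_names = gene_names),
    class = "grn_params")
  dimnames(obj$theta) <- list(gene_names, gene_names)
  bad <- validate_grn_params(obj)
  if (length(bad)) stop("invalid network file: ", paste(bad, collapse = "; "))
  obj
}

#' @rdname read_network
#' @export
write_network <- function(params, path) {
  stopifnot(inherits(params, "grn_params"))
  th <- data.frame(gene = params$gene_names, params$theta, check.names = FALSE)
  names(th)[-1] <- params$gene_names
  write.table(th, paste0(path, ".theta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  rates <- data.frame(gene = params$gene_names[-1], k0 = params$k0,
                      k1 = params$k1, burst_size_mean = params$burst_size_mean,
                      s1 = params$s1, d0 = params$d0, d1 = params$d1,
                      beta = params$beta)
  write.table(rates, paste0(path, ".rates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.grn_params <- function(x, ...) {
  cat(sprintf("Bursty GRN model: %d genes + stimulus\n", x$n_genes))
  nz <- sum(x$theta != 0)
  cat(sprintf("  interactions: %d nonzero (of %d off-stimulus-row entries)\n",
              nz, (x$n_genes + 1) * x$n_genes))
  cat(sprintf("  burst frequency: k0 in [%g, %g], k1 in [%g, %g] per hour\n",
              min(x$k0), max(x$k0), min(x$k1), max(x$k1)))
  cat(sprintf("  burst size mean: %g-%g mRNA copies; d0 %g-%g, d1 %g-%g per hour\n",
              min(x$burst_size_mean), max(x$burst_size_mean),
              min(x$d0), max(x$d0), min(x$d1), max(x$d1)))
  invisible(x)
}
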