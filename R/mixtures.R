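# Per-gene two-mode negative binomial mixtures with time-varying weights.
#
# Marginal count model for gene i at timepoint t:
#   x ~ (1 - w_t) NB(a0, b) + w_t NB(a1, b),   a0 < a1, shared b,
# where NB(a, b) has density C(x+a-1, x) b^a (1-b)^x. The shapes are burst
# frequencies in units of the mRNA degradation rate (a = kon/d0) and
# b = 1/(1 + burst_size_mean); only the mode weights w_t move over time.

# log-density of NB in (shape, scale-prob) parameterisation
dnb_log <- function(x, a, b) dnbinom(x, size = a, prob = b, log = TRUE)

# Method-of-moments (shape, prob) for a sample; falls back gracefully when
# under-dispersed.
nb_moment_fit <- function(x) {
  m <- mean(x)
  v <- var(x)
  if (!is.finite(v) || v <= m) v <- m * 1.5 + 1e-3
  b <- clamp(m / v, 1e-4, 1 - 1e-4)
  a <- clamp(m * b / (1 - b), 1e-6, 1e6)
  c(a = a, b = b)
}

# One EM pass for a single gene. Returns updated parameter list.
em_gene <- function(x, tp_index, n_tp, par, max_iter, tol) {
  a0 <- par$a0; a1 <- par$a1; b <- par$b
  w <- par$w  # length n_tp, weight of the high mode per timepoint
  ll_old <- -Inf
  u <- c(log(max(a0, 1e-8)), log(max(a1 - a0, 1e-8)), qlogis(b))
  for (iter in seq_len(max_iter)) {
    l0 <- dnb_log(x, a0, b)
    l1 <- dnb_log(x, a1, b)
    lw <- log(clamp(w[tp_index], 1e-12, 1 - 1e-12))
    lw0 <- log(clamp(1 - w[tp_index], 1e-12, 1 - 1e-12))
    mx <- pmax(l1 + lw, l0 + lw0)
    den <- mx + log(exp(l1 + lw - mx) + exp(l0 + lw0 - mx))
    ll <- sum(den)
    g <- exp(l1 + lw - den)  # posterior of the high mode
    # weights tied within timepoints
    w <- clamp(as.numeric(tapply(g, tp_index, mean)[as.character(seq_len(n_tp))]),
               1e-6, 1 - 1e-6)
    w[is.na(w)] <- 0.5
    # shapes and shared scale-prob by penalised-free weighted MLE,
    # parameterised to enforce 0 < a0 < a1 and 0 < b < 1
    obj <- function(u) {
      a0u <- exp(u[1]); a1u <- a0u + exp(u[2]); bu <- plogis(u[3])
      -sum((1 - g) * dnb_log(x, a0u, bu) + g * dnb_log(x, a1u, bu))
    }
    grad <- function(u) {
      a0u <- exp(u[1]); a1u <- a0u + exp(u[2]); bu <- plogis(u[3])
      ga0 <- sum((1 - g) * (digamma(x + a0u) - digamma(a0u) + log(bu)))
      ga1 <- sum(g * (digamma(x + a1u) - digamma(a1u) + log(bu)))
      gb <- sum((1 - g) * (a0u / bu - x / (1 - bu)) +
                g * (a1u / bu - x / (1 - bu)))
      -c((ga0 + ga1) * a0u, ga1 * exp(u[2]), gb * bu * (1 - bu))
    }
    opt <- optim(u, obj, grad, method = "L-BFGS-B",
                 lower = c(log(1e-8), log(1e-8), qlogis(1e-6)),
                 upper = c(log(1e6), log(1e6), qlogis(1 - 1e-6)),
                 control = list(maxit = 15))
    u <- opt$par
    a0 <- exp(u[1]); a1 <- a0 + exp(u[2]); b <- plogis(u[3])
    if (is.finite(ll) && ll - ll_old < tol && iter > 1) break
    ll_old <- ll
  }
  list(a0 = a0, a1 = a1, b = b, w = w, loglik = ll, iterations = iter,
       converged = iter < max_iter)
}

#' Fit per-gene negative binomial mixtures with time-varying mode weights
#'
#' First calibration step: for every gene, a two-component negative binomial
#' mixture is fitted by EM over all cells jointly. The two shapes (low and
#' high burst-frequency modes, in units of the gene's mRNA degradation rate)
#' and the shared scale probability are constant in time; only the weight of
#' the high mode varies, tied across cells within a timepoint. EM is started
#' from a method-of-moments split at the gene's median positive count plus
#' jittered restarts run for a few iterations each; the best is continued to
#' convergence (log-likelihood gain below `tol`).
#'
#' @param data a [snapshot_data()] with at least two timepoints.
#' @param d0 optional per-gene mRNA degradation rates (scalar broadcast);
#'   when supplied the burst-frequency estimates `k0_hat = a0 * d0` and
#'   `k1_hat = a1 * d0` are returned as well.
#' @param n_restarts number of jittered EM starts (short-run strategy).
#' @param max_iter maximum EM iterations for the final run.
#' @param tol log-likelihood convergence tolerance.
#' @param seed integer seed for the restart jitter.
#' @return An object of class `gene_mixture_fit`: vectors `a0`, `a1`, `b`
#'   (per gene), matrix `weights` (timepoints x genes, high-mode weight),
#'   logical `degenerate` (all-zero genes, excluded from regression), and
#'   `k0_hat`/`k1_hat`/`burst_size_mean_hat` when `d0` is given.
#' @seealso [binarize()], [fit_grn()]
#' @export
fit_gene_mixtures <- function(data, d0 = NULL, n_restarts = 10,
                              max_iter = 200, tol = 1e-6, seed = 0) {
  stopifnot(inherits(data, "snapshot_data"))
  tp <- sort(unique(data$time))
  if (length(tp) < 2) stop("need at least two timepoints")
  tp_index <- match(data$time, tp)
  genes <- data$gene_names[-1]
  n <- length(genes)
  counts <- data$counts[, -1, drop = FALSE]
  a0 <- a1 <- b <- loglik <- numeric(n)
  degenerate <- logical(n)
  weights <- matrix(0, length(tp), n, dimnames = list(tp, genes))
  for (i in seq_len(n)) {
    x <- counts[, i]
    if (all(x == 0)) {
      degenerate[i] <- TRUE
      a0[i] <- 0; a1[i] <- 0; b[i] <- 0.5; loglik[i] <- 0
      next
    }
    split <- median(x[x > 0])
    lo <- x <= split
    f_lo <- nb_moment_fit(x[lo])
    f_hi <- if (any(!lo)) nb_moment_fit(x[!lo]) else f_lo * c(4, 1)
    base <- list(a0 = min(f_lo["a"], f_hi["a"]),
                 a1 = max(f_hi["a"], f_lo["a"] * 1.5 + 1e-3),
                 b = clamp(mean(c(f_lo["b"], f_hi["b"])), 1e-4, 1 - 1e-4),
                 w = rep(mean(!lo), length(tp)))
    best <- NULL
    for (r in seq_len(n_restarts)) {
      par <- base
      if (r > 1) {
        jit <- with_seed(derive_seed(seed, i * 1000L + r),
                         exp(rnorm(3, 0, 0.4)))
        par$a0 <- clamp(par$a0 * jit[1], 1e-8, 1e6)
        par$a1 <- max(par$a1 * jit[2], par$a0 * 1.2 + 1e-6)
        par$b <- clamp(par$b * jit[3], 1e-4, 1 - 1e-4)
      }
      fit <- em_gene(x, tp_index, length(tp), par, max_iter = 5, tol = tol)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    fit <- em_gene(x, tp_index, length(tp), best, max_iter = max_iter,
                   tol = tol)
    # Parsimony guard: a gene whose marginal is a single negative binomial
    # (e.g. unregulated, always in one mode) is fitted by a one-component
    # model unless the mixture's likelihood gain pays for its extra
    # parameters (one extra shape + one weight per timepoint, AIC-style).
    sf <- optim(c(log(max(fit$a1, 1e-4)), qlogis(fit$b)), function(u)
      -sum(dnb_log(x, exp(u[1]), plogis(u[2]))), method = "Nelder-Mead")
    if (fit$loglik - (-sf$value) < 1 + length(tp)) {
      fit$a1 <- exp(sf$par[1])
      fit$b <- plogis(sf$par[2])
      fit$a0 <- 0
      fit$w <- rep(1, length(tp))
      fit$loglik <- -sf$value
    }
    # canonical order: a0 is the low-frequency mode
    if (fit$a0 > fit$a1) {
      tmp <- fit$a0; fit$a0 <- fit$a1; fit$a1 <- tmp
      fit$w <- 1 - fit$w
    }
    a0[i] <- fit$a0; a1[i] <- fit$a1; b[i] <- fit$b
    weights[, i] <- fit$w
    loglik[i] <- fit$loglik
  }
  out <- structure(list(a0 = setNames(a0, genes), a1 = setNames(a1, genes),
                        b = setNames(b, genes), weights = weights,
                        degenerate = setNames(degenerate, genes),
                        loglik = setNames(loglik, genes),
                        timepoints = tp, gene_names = genes),
                   class = "gene_mixture_fit")
  if (!is.null(d0)) {
    d0 <- rep_len(d0, n)
    out$k0_hat <- setNames(a0 * d0, genes)
    out$k1_hat <- setNames(a1 * d0, genes)
    out$d0 <- d0
  }
  out$burst_size_mean_hat <- setNames(ifelse(degenerate, NA, (1 - b) / b),
                                      genes)
  out
}

#' @export
print.gene_mixture_fit <- function(x, ...) {
  cat(sprintf("Two-mode NB mixture fit: %d genes, %d timepoints\n",
              length(x$a0), length(x$timepoints)))
  if (any(x$degenerate))
    cat("  degenerate (all-zero) genes:",
        paste(names(which(x$degenerate)), collapse = ", "), "\n")
  df <- data.frame(a0 = round(x$a0, 3), a1 = round(x$a1, 3),
                   b = signif(x$b, 3),
                   burst_size = round(x$burst_size_mean_hat, 1))
  print(head(df, 10))
  if (nrow(df) > 10) cat("  ...", nrow(df) - 10, "more genes\n")
  invisible(x)
}

#' Posterior mode indicators (model-based binarization)
#'
#' For each cell and gene, the posterior probability that the observed count
#' arose from the high burst-frequency mode of the fitted mixture, using the
#' cell's timepoint weight as prior — the statistically derived,
#' model-based thresholding that starts the calibration. The stimulus column
#' passes through unchanged. Degenerate genes get indicator 0.
#'
#' @param data a [snapshot_data()].
#' @param fit a [fit_gene_mixtures()] result covering all genes of `data`.
#' @param hard if `TRUE`, threshold the posterior at 0.5 (ties go to the
#'   high mode) and return 0/1 indicators.
#' @return Numeric matrix, cells x (n_genes + 1), values in `[0, 1]`.
#' @export
binarize <- function(data, fit, hard = FALSE) {
  stopifnot(inherits(data, "snapshot_data"),
            inherits(fit, "gene_mixture_fit"))
  if (!identical(data$gene_names[-1], fit$gene_names))
    stop("mixture fit does not cover the dataset's genes")
  tp_index <- match(data$time, fit$timepoints)
  if (anyNA(tp_index)) stop("dataset contains timepoints unseen by the fit")
  out <- matrix(0, nrow(data$counts), ncol(data$counts),
                dimnames = dimnames(data$counts))
  out[, 1] <- data$counts[, 1]
  for (i in seq_along(fit$gene_names)) {
    if (fit$degenerate[i]) next
    x <- data$counts[, i + 1]
    w <- clamp(fit$weights[tp_index, i], 1e-12, 1 - 1e-12)
    l1 <- dnb_log(x, fit$a1[i], fit$b[i]) + log(w)
    l0 <- dnb_log(x, fit$a0[i], fit$b[i]) + log(1 - w)
    out[, i + 1] <- 1 / (1 + exp(l0 - l1))
  }
  if (hard) {
    z <- out
    z[, -1] <- ifelse(out[, -1, drop = FALSE] >= 0.5, 1, 0)
    return(z)
  }
  out
}
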