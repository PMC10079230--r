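test_that("mixture fitting recovers the parameters of an unregulated gene", {
  p <- saturated_gene()  # kon/d0 = 4, burst size 50
  d <- simulate_snapshots(p, simulation_schedule(c(0, 6), 1000), seed = 5)
  fit <- fit_gene_mixtures(d, d0 = 0.5, seed = 1)
  expect_equal(unname(fit$a1[1]), 4, tolerance = 0.15)
  expect_equal(unname(fit$b[1]), 1 / 51, tolerance = 0.15)
  expect_equal(unname(fit$k1_hat[1]), 2, tolerance = 0.15)
})

test_that("time-varying weights capture an off-to-on switch", {
  set.seed(2)
  x <- c(rnbinom(300, size = 0.05, prob = 1 / 51),
         rnbinom(300, size = 4, prob = 1 / 51))
  d <- snapshot_data(cbind(Stimulus = rep(0:1, each = 300), Gene1 = x),
                     rep(c(0, 6), each = 300))
  fit <- fit_gene_mixtures(d, seed = 1)
  expect_lt(fit$weights[1, 1], 0.05)
  expect_gt(fit$weights[2, 1], 0.95)
  expect_lt(fit$a0[1], fit$a1[1])
})

test_that("an all-zero gene is flagged degenerate", {
  d <- snapshot_data(cbind(Stimulus = rep(0:1, each = 10),
                           Gene1 = rep(c(0L, 5L), each = 10),
                           Gene2 = 0L),
                     rep(c(0, 6), each = 10))
  fit <- fit_gene_mixtures(d, seed = 1)
  expect_true(fit$degenerate["Gene2"])
  expect_false(fit$degenerate["Gene1"])
})

test_that("binarization is the exact posterior of the high mode", {
  # hand-built mixture, equal weights
  fit <- structure(list(
    a0 = c(Gene1 = 0.1), a1 = c(Gene1 = 4), b = c(Gene1 = 1 / 51),
    weights = matrix(0.5, 2, 1, dimnames = list(c(0, 6), "Gene1")),
    degenerate = c(Gene1 = FALSE), timepoints = c(0, 6),
    gene_names = "Gene1"), class = "gene_mixture_fit")
  counts <- cbind(Stimulus = 1L, Gene1 = c(0L, 3L, 1000L))
  d <- snapshot_data(counts, rep(6, 3))
  z <- binarize(d, fit)
  # oracle: explicit Bayes ratio
  post <- function(x) {
    l1 <- dnbinom(x, size = 4, prob = 1 / 51) * 0.5
    l0 <- dnbinom(x, size = 0.1, prob = 1 / 51) * 0.5
    l1 / (l0 + l1)
  }
  expect_equal(unname(z[, 2]), post(c(0, 3, 1000)), tolerance = 1e-8)
  expect_lt(z[1, 2], 0.01)   # zero count, well-separated modes -> low
  expect_gt(z[3, 2], 0.99)   # far above both means -> high saturates
  # at the likelihood crossing the posterior is 1/2
  xs <- 0:200
  lr <- dnbinom(xs, size = 4, prob = 1 / 51) /
    dnbinom(xs, size = 0.1, prob = 1 / 51)
  xc <- xs[which.min(abs(lr - 1))]
  dc <- snapshot_data(cbind(Stimulus = 1L, Gene1 = xc), 6)
  expect_equal(unname(binarize(dc, fit)[1, 2]), post(xc), tolerance = 1e-8)
  expect_equal(unname(binarize(dc, fit)[1, 2]), 0.5, tolerance = 0.1)
  # hard binarization thresholds at 0.5, ties to the high mode
  zh <- binarize(d, fit, hard = TRUE)
  expect_identical(unname(zh[, 2]), c(0, 0, 1))
})

test_that("a two-gene cascade is recovered across seeded replicates", {
  p <- chain_params(2)
  hits <- 0L
  for (r in 1:10) {
    d <- simulate_snapshots(p, benchmark_schedule(100), seed = 100 + r)
    fit <- fit_grn(d, d0 = 0.5, seed = r)
    th <- fit$theta
    true_vals <- c(th["Gene1", "Stimulus"], th["Gene2", "Gene1"])
    absent <- max(abs(th["Gene1", "Gene2"]), abs(th["Gene2", "Stimulus"]))
    if (all(true_vals > 0) && min(true_vals) > absent) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("a null network yields weaker edges than true cascade edges", {
  null <- grn_params(2, beta = 0)
  d0 <- simulate_snapshots(null, benchmark_schedule(100), seed = 31)
  f0 <- fit_grn(d0, d0 = 0.5, seed = 1)
  off <- row(f0$theta) != col(f0$theta) & row(f0$theta) != 1
  null_mean <- mean(abs(f0$theta[off]))

  p <- chain_params(2)
  d1 <- simulate_snapshots(p, benchmark_schedule(100), seed = 31)
  f1 <- fit_grn(d1, d0 = 0.5, seed = 1)
  chain_mean <- mean(c(abs(f1$theta["Gene1", "Stimulus"]),
                       abs(f1$theta["Gene2", "Gene1"])))
  expect_lte(null_mean, chain_mean)
})

test_that("inference is invariant to cell order within timepoints", {
  p <- chain_params(2)
  d <- simulate_snapshots(p, simulation_schedule(c(0, 12, 24), 60), seed = 3)
  set.seed(9)
  perm <- unlist(lapply(split(seq_along(d$time), d$time), sample))
  dp <- snapshot_data(d$counts[perm, ], d$time[perm], d$gene_names)
  f1 <- fit_grn(d, d0 = 0.5, seed = 4)
  f2 <- fit_grn(dp, d0 = 0.5, seed = 4)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-8)
})

test_that("the stimulus row of inferred theta is exactly zero", {
  p <- chain_params(2)
  d <- simulate_snapshots(p, simulation_schedule(c(0, 12, 24), 50), seed = 8)
  fit <- fit_grn(d, d0 = 0.5, seed = 1)
  expect_true(all(fit$theta[1, ] == 0))
  expect_true(all(vapply(fit$per_timepoint, function(m) all(m[1, ] == 0),
                         logical(1))))
})

test_that("dropping later timepoints cannot add consolidated edges", {
  p <- chain_params(3)
  d <- simulate_snapshots(p, benchmark_schedule(80), seed = 17)
  full <- fit_grn(d, d0 = 0.5, seed = 1)
  keep <- d$time <= 6  # only the first transition
  trunc <- snapshot_data(d$counts[keep, ], d$time[keep], d$gene_names)
  part <- fit_grn(trunc, d0 = 0.5, seed = 1)
  expect_lte(sum(part$theta != 0), sum(full$theta != 0))
})

test_that("temporal decomposition assigns edges to their strongest transition", {
  per <- list(
    "t0->t6" = rbind(Stimulus = c(0, 0), Gene1 = c(0, 2)),
    "t6->t12" = rbind(Stimulus = c(0, 0), Gene1 = c(3, 2)),
    "t12->t24" = rbind(Stimulus = c(0, 0), Gene1 = c(1, 0)))
  for (k in seq_along(per))
    dimnames(per[[k]]) <- list(c("Stimulus", "Gene1"), c("Stimulus", "Gene1"))
  td <- temporal_decomposition(per)
  edge_st <- td[td$from == "Stimulus" & td$to == "Gene1", ]
  expect_equal(edge_st$transition, "t6->t12")  # values (0, 3, 1)
  expect_equal(edge_st$strength, 3)
  edge_self <- td[td$from == "Gene1" & td$to == "Gene1", ]
  expect_equal(edge_self$transition, "t0->t6")  # tie (2, 2) -> earliest
  # stimulus row is all zero in every transition: no edges into the stimulus
  expect_false(any(td$to == "Stimulus"))
})

test_that("top_edges keeps the strongest edges of each sign per target", {
  th <- matrix(c(0, 5, 1, -3, -0.1,
                 rep(0, 20)), 5, 5, byrow = TRUE)
  pruned <- top_edges(th, fraction = 0.25)  # ceiling(0.25 * 4) = 1 per sign
  expect_equal(pruned[1, ], c(0, 5, 0, -3, 0))
  expect_true(all(pruned[2:5, ] == 0))
  # fraction 1 is the identity off the diagonal
  set.seed(1)
  m <- matrix(rnorm(25), 5, 5)
  full <- top_edges(m, fraction = 1)
  off <- row(m) != col(m)
  expect_equal(full[off], m[off])
  expect_true(all(diag(full) == 0))
  expect_error(top_edges(m, fraction = 0), "fraction")
})

test_that("re-simulating the calibrated chain reproduces the marginals", {
  p <- chain_params(4)
  d <- simulate_snapshots(p, benchmark_schedule(100), seed = 1)
  loop <- self_consistency_loop(d, d0 = 0.5, seed = 1)
  # most gene x timepoint marginals are statistically indistinguishable
  expect_gte(mean(loop$report_network$ks_pvalues >= 0.05), 0.8)
  # and the calibrated model dominates the no-interaction control
  expect_gt(loop$report_network$green_fraction,
            loop$report_null$green_fraction)
})
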