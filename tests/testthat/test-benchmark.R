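test_that("the network zoo matches its textual descriptions", {
  fn4 <- make_network("FN4")
  expect_equal(fn4$params$n_genes, 4L)
  expect_gte(sum(fn4$truth < 0), 1)  # inhibition feedback loop

  cn5 <- make_network("CN5")
  gene_block <- cn5$truth[-1, -1]
  expect_true(all(rowSums(gene_block != 0) <= 1))
  expect_equal(sum(gene_block != 0), 5)  # 1->2->3->4->5->1 cycle
  expect_true(all(colSums(gene_block != 0) == 1))

  bn8 <- make_network("BN8")
  tg <- bn8$truth
  toggle <- any(tg[-1, -1] < 0 & t(tg[-1, -1]) < 0)
  expect_true(toggle)  # mutual inhibition pair dominates BN8

  fn8 <- make_network("FN8")
  expect_equal(fn8$params$n_genes, 8L)
  expect_gte(sum(fn8$truth < 0), 2)  # multiple feedback loops

  for (nm in c("FN4", "CN5", "FN8", "BN8")) {
    net <- make_network(nm)
    # truth pattern equals the off-diagonal nonzero pattern of theta
    tt <- sign(net$params$theta)
    diag(tt) <- 0
    expect_identical(net$truth, tt)
    expect_true(all(net$truth[1, ] == 0))
  }
  expect_error(make_network("XYZ"), "unknown network")
})

test_that("random trees are uniform over labelled trees", {
  t1 <- random_tree(1, seed = 0)
  expect_equal(sum(t1$truth != 0), 1)
  expect_equal(t1$truth[2, 1], 1)  # single edge stimulus -> gene 1

  # n = 3: 4 nodes, Cayley 4^2 = 16 labelled trees
  n_draw <- 16000
  ids <- vapply(seq_len(n_draw), function(s) {
    tr <- random_tree(3, seed = s)
    und <- tr$truth + t(tr$truth)
    paste(which(und[upper.tri(und)] != 0), collapse = ",")
  }, character(1))
  freq <- table(ids)
  expect_equal(length(freq), 16L)
  se <- sqrt((1 / 16) * (15 / 16) / n_draw)
  expect_true(all(abs(freq / n_draw - 1 / 16) < 3.5 * se))
})

test_that("every tree node is reachable from the stimulus", {
  for (s in 1:5) {
    tr <- random_tree(8, seed = s)
    adj <- tr$truth != 0
    reach <- rep(FALSE, 9)
    reach[1] <- TRUE
    for (step in 1:9) reach <- reach | (adj %*% reach) > 0
    expect_true(all(reach))
  }
})

test_that("precision-recall areas match brute-force enumeration", {
  # hand toy: scores (0.9, 0.5, 0.1) against truth (1, 0, 1)
  pr <- pr_curve(c(0.9, 0.5, 0.1), c(1, 0, 1))
  # oracle: enumerate thresholds directly
  brute_aupr <- function(s, l) {
    ths <- sort(unique(s), decreasing = TRUE)
    rec_prev <- 0
    area <- 0
    for (th in ths) {
      sel <- s >= th
      prec <- sum(l[sel]) / sum(sel)
      rec <- sum(l[sel]) / sum(l)
      area <- area + (rec - rec_prev) * prec
      rec_prev <- rec
    }
    area
  }
  expect_equal(pr$aupr, brute_aupr(c(0.9, 0.5, 0.1), c(1, 0, 1)))
  expect_equal(pr$aupr, 0.5 * 1 + 0.5 * (2 / 3))

  set.seed(33)
  for (rep in 1:20) {
    s <- sample(c(runif(8), runif(4)))  # includes tied values sometimes
    s <- round(s, 1)
    l <- rbinom(12, 1, 0.4)
    if (sum(l) == 0) l[1] <- 1
    expect_equal(pr_curve(s, l)$aupr, brute_aupr(s, l), tolerance = 1e-12)
  }
})

test_that("aupr on matrices: perfect scorer scores 1, diagonal is ignored", {
  for (nm in c("FN4", "CN5", "FN8", "BN8")) {
    net <- make_network(nm)
    expect_equal(aupr(net$truth, net$truth, directed = TRUE), 1)
    expect_equal(aupr(net$truth, net$truth, directed = FALSE), 1)
    # self-loops in the scores must not change anything
    noisy <- net$truth
    diag(noisy) <- 99
    expect_equal(aupr(noisy, net$truth, directed = TRUE), 1)
  }
  expect_error(aupr(matrix(0, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("the Pearson baseline scores correlation magnitude", {
  set.seed(8)
  x <- rpois(200, 30)
  counts <- cbind(Stimulus = rep(0:1, each = 100), A = x, B = x,
                  C = rpois(200, 10), D = 5L)
  d <- snapshot_data(counts, rep(c(0, 6), each = 100))
  m <- pearson_baseline(d)
  expect_equal(m["A", "B"], 1)           # duplicated column
  expect_true(all(m["D", ] == 0))        # constant gene
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m, t(m))
})

test_that("independent genes stay near zero correlation", {
  p <- grn_params(3, beta = 0)  # three unregulated genes
  d <- simulate_snapshots(p, simulation_schedule(c(0, 48), 500), seed = 12)
  m <- pearson_baseline(d)
  gg <- m[-1, -1]
  expect_lte(max(gg[upper.tri(gg)]), 0.15)
})

test_that("symmetrisation can only help a symmetric scorer", {
  net <- make_network("FN4")
  d <- simulate_snapshots(net$params, simulation_schedule(c(0, 24, 48), 60),
                          seed = 3)
  sc <- pearson_baseline(d)
  expect_lte(aupr(sc, net$truth, directed = TRUE),
             aupr(sc, net$truth, directed = FALSE))
})

test_that("benchmark tables are reproducible and empty runs are empty", {
  net <- make_network("FN4")
  sched <- simulation_schedule(c(0, 24, 48), 40)
  r1 <- run_benchmark(net, methods = c("pearson", "random"),
                      n_replicates = 2, schedule = sched, seed = 5)
  r2 <- run_benchmark(net, methods = c("pearson", "random"),
                      n_replicates = 2, schedule = sched, seed = 5)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 2 * 2 * 2)  # methods x replicates x directed flag
  expect_true(all(r1$aupr >= 0 & r1$aupr <= 1))

  r0 <- run_benchmark(net, methods = "random", n_replicates = 0,
                      schedule = sched, seed = 5)
  expect_equal(nrow(r0), 0)
})

test_that("design sweeps rebuild schedules under the stated constraints", {
  base <- benchmark_schedule(100)
  # gap axis: final time fixed at 96 h, gap 48 h -> (0, 48, 96)
  s_gap <- burstgrn:::sweep_schedule("gap", 48, base)
  expect_equal(s_gap$timepoints, c(0, 48, 96))
  expect_equal(sum(s_gap$cells_per_timepoint), 1000)

  # period axis: same 6 h gap, shorter window, constant total cells
  s_per <- burstgrn:::sweep_schedule("period_length", 24, base)
  expect_equal(s_per$timepoints, c(0, 6, 12, 18, 24))
  expect_equal(sum(s_per$cells_per_timepoint), 1000)
  # spillover goes to the earliest timepoints
  expect_true(all(diff(s_per$cells_per_timepoint) <= 0))

  # cells axis: same timepoints, new per-timepoint count
  s_cells <- burstgrn:::sweep_schedule("cells", 10, base)
  expect_equal(s_cells$timepoints, base$timepoints)
  expect_true(all(s_cells$cells_per_timepoint == 10))

  expect_error(burstgrn:::sweep_schedule("nope", 1, base), "axis")
})
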