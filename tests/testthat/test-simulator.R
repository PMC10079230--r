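test_that("with burst frequency driven to zero, mRNA decays deterministically", {
  p <- grn_params(1, beta = -500)
  init <- cell_state(0, 80, c(1, 0))
  traj <- simulate_cell(p, 10, init, seed = 1)
  expect_equal(nrow(traj$bursts), 0L)
  expect_equal(traj$final$M, 80 * exp(-0.5 * 10), tolerance = 1e-10)
  mid <- trajectory_state(traj, 4)
  expect_equal(mid$M, 80 * exp(-0.5 * 4), tolerance = 1e-10)
})

test_that("thinned burst counts match the direct exponential-gap oracle", {
  # constant kon = 1 (theta = 0, beta = 0, k0 = 0, k1 = 2); the thinned
  # simulator proposes at rate 2 and accepts half the candidates
  p <- grn_params(1, beta = 0)
  T_end <- 5
  n_runs <- 10000
  thinned <- vapply(seq_len(n_runs), function(r) n_bursts(p, T_end, seed = r),
                    numeric(1))
  # oracle: direct simulation with Exponential(kon) gaps, no thinning
  set.seed(999)
  direct <- vapply(seq_len(n_runs), function(r) {
    t <- 0
    k <- 0L
    repeat {
      t <- t + rexp(1, rate = 1)
      if (t >= T_end) break
      k <- k + 1L
    }
    k
  }, integer(1))
  expect_equal(mean(thinned), T_end, tolerance = 0.05)
  breaks <- c(-0.5, seq(0.5, 10.5), Inf)
  tab <- rbind(table(cut(thinned, breaks)), table(cut(direct, breaks)))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.05)
})

test_that("burst sizes are exponential with the benchmark mean of 50", {
  p <- saturated_gene()
  sizes <- unlist(lapply(1:60, function(r) {
    init <- cell_state(0, 0, c(1, 0))
    simulate_cell(p, 50, init, seed = r)$bursts$size
  }))
  expect_gt(length(sizes), 3000)
  expect_equal(mean(sizes), 50, tolerance = 0.05)
  expect_gt(ks.test(sizes, pexp, rate = 1 / 50)$p.value, 0.05)
})

test_that("the pre-stimulus stationary law of an isolated gene is Gamma", {
  p <- saturated_gene()  # kon = k1 = 2, d0 = 0.5 -> Gamma(shape 4, scale 50)
  M <- vapply(1:2000, function(r) stationary_cell(p, seed = r)$M, numeric(1))
  expect_equal(mean(M), 200, tolerance = 0.05)
  expect_gt(ks.test(M, pgamma, shape = 4, scale = 50)$p.value, 0.05)
})

test_that("a silent gene stays empty through burn-in", {
  p <- grn_params(1, beta = -500)
  s <- stationary_cell(p, seed = 4)
  expect_equal(s$M, 0)
  expect_equal(s$P, c(0, 0))
})

test_that("the Poisson layer preserves means and maps zero to zero", {
  expect_identical(poisson_layer(matrix(0, 5, 3)), matrix(0L, 5, 3))
  expect_error(poisson_layer(matrix(-1)), "nonnegative")

  set.seed(21)
  mu <- matrix(rexp(30000, 1 / 20), 10000, 3)
  cnt <- poisson_layer(mu, seed = 2)
  se <- sqrt(colMeans(mu) / nrow(mu))
  expect_true(all(abs(colMeans(cnt) - colMeans(mu)) < 3 * se))
})

test_that("Poisson layer on the stationary law gives negative binomial counts", {
  p <- saturated_gene()
  M <- vapply(1:2000, function(r) stationary_cell(p, seed = r)$M, numeric(1))
  cnt <- poisson_layer(matrix(M), seed = 7)
  expect_gt(suppressWarnings(
    ks.test(cnt, pnbinom, size = 4, prob = 1 / 51))$p.value, 0.05)
})

test_that("negative binomial moments follow the printed identities", {
  m <- nb_moments(1, 1 / 2)
  expect_equal(m$mean, 1)
  expect_equal(m$var, 2)
  expect_equal(m$cv2, 2)
  expect_equal(nb_moments(4, 1 / 51)$mean, 200)
  set.seed(5)
  for (rep in 1:10) {
    a <- rexp(1, 1 / 3)
    b <- runif(1, 0.01, 0.99)
    mm <- nb_moments(a, b)
    expect_equal(mm$cv2 * mm$mean, 1 / b)
  }
  expect_error(nb_moments(0, 0.5), "positive")
  expect_error(nb_moments(1, 1.2), "in \\(0, 1\\)")
})

test_that("snapshot simulation follows the sampling protocol", {
  p <- chain_params(2)
  d <- simulate_snapshots(p, benchmark_schedule(100), seed = 1)
  expect_equal(nrow(d$counts), 1000L)
  expect_equal(sort(unique(d$time)), c(0, 6, 12, 24, 36, 48, 60, 72, 84, 96))
  expect_true(all(d$counts[d$time == 0, 1] == 0))
  expect_true(all(d$counts[d$time > 0, 1] == 1))
})

test_that("identical seeds give identical datasets, different seeds differ", {
  p <- chain_params(2)
  sched <- simulation_schedule(c(0, 12), 30)
  d1 <- simulate_snapshots(p, sched, seed = 5)
  d2 <- simulate_snapshots(p, sched, seed = 5)
  d3 <- simulate_snapshots(p, sched, seed = 6)
  expect_identical(d1$counts, d2$counts)
  expect_false(identical(d1$counts, d3$counts))
})

test_that("without interactions every timepoint reproduces the stationary law", {
  p <- grn_params(1, beta = 0)  # constant kon = 1, unaffected by stimulus
  d <- simulate_snapshots(p, simulation_schedule(c(0, 48, 96), 400), seed = 2)
  x0 <- d$counts[d$time == 0, 2]
  for (tt in c(48, 96))
    expect_gt(suppressWarnings(
      ks.test(x0, d$counts[d$time == tt, 2])$p.value), 0.05)
})

test_that("single cells jump while the population average is smooth", {
  p <- saturated_gene()
  grid <- seq(0, 24, by = 0.05)
  # reconstruct M(t) from burst events in closed form
  m_curve <- function(traj) {
    b <- traj$bursts
    m0 <- traj$initial$M
    vapply(grid, function(t) {
      keep <- b$time <= t
      m0 * exp(-0.5 * t) + sum(b$size[keep] * exp(-0.5 * (t - b$time[keep])))
    }, numeric(1))
  }
  curves <- vapply(1:600, function(r) {
    init <- cell_state(0, 0, c(1, 0))
    m_curve(simulate_cell(p, 24, init, seed = r))
  }, numeric(length(grid)))
  single <- curves[, 1]
  avg <- rowMeans(curves)
  jump <- function(v) max(abs(diff(v))) / diff(range(v))
  expect_gt(jump(single), 0.15)  # bursts dominate one cell
  expect_lt(jump(avg), 0.05)     # averaging smooths them out
})

test_that("rate scaling accelerates dynamics but preserves the stationary law", {
  p <- grn_params(1, beta = 50)
  sched <- simulation_schedule(c(0, 96), 400,
                               rate_scale_after = list(time = 72, factor = 6))
  d <- simulate_snapshots(p, sched, seed = 9)
  base <- simulate_snapshots(p, simulation_schedule(c(0, 96), 400), seed = 10)
  expect_gt(suppressWarnings(ks.test(d$counts[d$time == 96, 2],
                                     base$counts[base$time == 96, 2])$p.value),
            0.05)
})
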