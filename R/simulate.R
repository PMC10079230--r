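#' Cell state of the mechanistic model
#'
#' A snapshot of one cell: time `t` (hours), continuous mRNA copy numbers `M`
#' (length `n_genes`) and protein levels `P` (length `n_genes + 1`, entry 1
#' being the stimulus protein, 0 before time 0 and 1 afterwards).
#'
#' @param t time in hours.
#' @param M nonnegative mRNA vector.
#' @param P nonnegative protein vector (stimulus first).
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(t, M, P) {
  stopifnot(all(is.finite(M)), all(is.finite(P)), all(M >= 0), all(P >= 0),
            length(P) == length(M) + 1, P[1] %in% c(0, 1))
  structure(list(t = t, M = as.numeric(M), P = as.numeric(P)),
            class = "cell_state")
}

# Scale the kinetic rates of `params` by factor f (burst frequencies and
# synthesis/degradation rates; burst size untouched). Time-rescaling: the
# stationary law is preserved, only the speed of the dynamics changes.
scale_rates <- function(params, f) {
  params$k0 <- params$k0 * f
  params$k1 <- params$k1 * f
  params$d0 <- params$d0 * f
  params$d1 <- params$d1 * f
  params$s1 <- params$s1 * f
  params
}

# Low-level exact simulation of one interval with constant stimulus level.
sim_interval <- function(params, state, stim, t1, record = FALSE) {
  res <- .sim_cell_interval(state$M, state$P, stim, state$t, t1,
                            params$k0, params$k1, params$burst_size_mean,
                            params$s1, params$d0, params$d1, params$beta,
                            params$theta, record)
  list(state = cell_state(t1, res$M, res$P),
       bursts = data.frame(time = res$burst_times, gene = res$burst_genes,
                           size = res$burst_sizes))
}

#' Exact simulation of a single-cell trajectory
#'
#' Simulates the piecewise-deterministic bursty model for one cell from
#' `initial$t` to `t_final`. Between bursts, mRNA decays exponentially and
#' protein follows its linear ODE in closed form, so no numerical
#' integration is involved; burst times are sampled exactly by thinning a
#' majorising Poisson process of rate `sum(k1)` (candidates accepted with
#' probability `kon/k1` evaluated at the candidate time). At a burst of gene
#' i, `M[i]` jumps by an exponential draw with mean `burst_size_mean[i]`.
#' The stimulus protein is 0 while `t < 0` and 1 for `t >= 0`; intervals
#' straddling 0 are split at the switch.
#'
#' @param params a [grn_params()] object.
#' @param t_final end time (hours), greater than `initial$t`.
#' @param initial a [cell_state()]; defaults to an empty cell at time 0.
#' @param seed optional integer seed.
#' @return An object of class `cell_trajectory`: the initial state, a
#'   data frame of burst events (`time`, `gene`, `size`) and the final
#'   [cell_state()]. The state at any intermediate time can be reconstructed
#'   with [trajectory_state()].
#' @seealso [stationary_cell()], [simulate_snapshots()]
#' @export
simulate_cell <- function(params, t_final, initial = NULL, seed = NULL) {
  stopifnot(inherits(params, "grn_params"))
  if (is.null(initial))
    initial <- cell_state(0, rep(0, params$n_genes),
                          c(1, rep(0, params$n_genes)))
  if (t_final <= initial$t) stop("t_final must exceed initial$t")
  with_seed(seed, {
    segs <- list()
    state <- initial
    if (state$t < 0) {
      end0 <- min(0, t_final)
      segs[[1]] <- sim_interval(params, state, stim = 0, end0, record = TRUE)
      state <- segs[[1]]$state
    }
    if (t_final > 0) {
      state$P[1] <- 1
      segs[[length(segs) + 1]] <-
        sim_interval(params, state, stim = 1, t_final, record = TRUE)
      state <- segs[[length(segs)]]$state
    }
    bursts <- do.call(rbind, lapply(segs, `[[`, "bursts"))
    structure(list(params = params, initial = initial, bursts = bursts,
                   final = state), class = "cell_trajectory")
  })
}

# Deterministic flow of the model between bursts, in closed form: mRNA
# decays exponentially, protein solves dP/dt = s1*M - d1*P.
flow_state <- function(params, state, stim, t1) {
  dt <- t1 - state$t
  em <- exp(-params$d0 * dt)
  ep <- exp(-params$d1 * dt)
  coef <- ifelse(abs(params$d0 - params$d1) < 1e-12 * (params$d0 + params$d1),
                 dt * em, (em - ep) / (params$d1 - params$d0))
  P <- state$P
  P[-1] <- P[-1] * ep + params$s1 * state$M * coef
  P[1] <- stim
  cell_state(t1, state$M * em, P)
}

#' Reconstruct the state of a simulated trajectory at an arbitrary time
#'
#' Replays the deterministic flow between the recorded burst events, so the
#' returned state is exact (not interpolated). The stimulus is off for
#' query times `t < 0` (and at `t = 0` when the trajectory started before
#' stimulus onset) and on afterwards.
#'
#' @param trajectory a `cell_trajectory` from [simulate_cell()].
#' @param t query time within the simulated window.
#' @return A [cell_state()] at time `t`.
#' @export
trajectory_state <- function(trajectory, t) {
  init <- trajectory$initial
  if (t < init$t || t > trajectory$final$t)
    stop("t outside the simulated window")
  p <- trajectory$params
  pre_stim <- function(tt) tt < 0 || (tt == 0 && init$t < 0)
  advance <- function(state, t1) {
    if (state$t < 0 && t1 > 0) {
      state <- flow_state(p, state, stim = 0, t1 = 0)
      state$P[1] <- 1
    }
    flow_state(p, state, stim = if (pre_stim(t1)) 0 else 1, t1 = t1)
  }
  state <- init
  if (!pre_stim(init$t)) state$P[1] <- 1
  b <- trajectory$bursts
  b <- b[b$time <= t, , drop = FALSE]
  for (k in seq_len(nrow(b))) {
    state <- advance(state, b$time[k])
    state$M[b$gene[k]] <- state$M[b$gene[k]] + b$size[k]
  }
  advance(state, t)
}

#' Sample a cell from the pre-stimulus stationary regime
#'
#' Runs the model with the stimulus off from an empty cell (`M = 0, P = 0`)
#' for `burnin` hours, several protein half-lives by default, and returns the
#' state reached, taken as a draw from the stochastic steady state at time 0
#' (just before stimulus onset). For an isolated, unregulated gene the
#' stationary mRNA law is exactly Gamma with shape `kon/d0` and scale
#' `burst_size_mean`.
#'
#' @param params a [grn_params()] object.
#' @param burnin burn-in duration in hours; defaults to `4 / min(d1)`.
#' @param seed optional integer seed.
#' @return A [cell_state()] at time 0 with the stimulus still off.
#' @export
stationary_cell <- function(params, burnin = NULL, seed = NULL) {
  stopifnot(inherits(params, "grn_params"))
  burnin <- burnin %||% (4 / min(params$d1))
  stopifnot(burnin > 0)
  with_seed(seed, {
    state <- cell_state(-burnin, rep(0, params$n_genes),
                        rep(0, params$n_genes + 1))
    sim_interval(params, state, stim = 0, t1 = 0)$state
  })
}

#' Poisson measurement layer
#'
#' Turns simulated continuous expression levels into integer counts by
#' entrywise Poisson sampling with the expression level as mean, the
#' measurement model that maps Gamma stationary marginals onto negative
#' binomial count marginals.
#'
#' @param expression nonnegative numeric matrix (or vector) of expression
#'   means.
#' @param seed optional integer seed.
#' @return Integer matrix (or vector) of the same shape.
#' @export
poisson_layer <- function(expression, seed = NULL) {
  if (any(expression < 0) || any(!is.finite(expression)))
    stop("expression means must be finite and nonnegative")
  with_seed(seed, {
    out <- rpois(length(expression), as.numeric(expression))
    if (is.matrix(expression)) {
      out <- matrix(out, nrow(expression), ncol(expression),
                    dimnames = dimnames(expression))
    }
    out
  })
}

#' Negative binomial moments in (shape, scale-probability) form
#'
#' For counts distributed NB(a, b) with density proportional to
#' `b^a (1-b)^x`, returns the mean `m = a(1-b)/b`, variance
#' `v = a(1-b)/b^2` and squared coefficient of variation
#' `CV^2 = 1/(a(1-b)) = (1/b)(1/m)` — the inverse mean-CV² scaling
#' characteristic of single-cell count data.
#'
#' @param a shape, positive.
#' @param b scale probability in (0, 1); for a gene with burst size mean
#'   `s0/koff` this is `koff/(koff + s0) = 1/(1 + burst_size_mean)`.
#' @return A list with elements `mean`, `var`, `cv2`.
#' @export
nb_moments <- function(a, b) {
  if (any(a <= 0)) stop("shape a must be positive")
  if (any(b <= 0 | b >= 1)) stop("scale-prob b must be in (0, 1)")
  m <- a * (1 - b) / b
  v <- a * (1 - b) / b^2
  list(mean = m, var = v, cv2 = v / m^2)
}

#' Schedule of a time-stamped snapshot experiment
#'
#' @param timepoints strictly increasing nonnegative sampling times (hours).
#' @param cells_per_timepoint number of independent cells sampled (and
#'   destroyed) at each timepoint; recycled to the number of timepoints.
#' @param burnin pre-stimulus burn-in duration (hours); default
#'   `4 / min(d1)` at simulation time.
#' @param rate_scale_after optional `list(time =, factor =)`: from `time`
#'   onwards, burst frequencies and synthesis/degradation rates are
#'   multiplied by `factor` (burst size unchanged), accelerating the
#'   dynamics while preserving the stationary law. Mirrors the device of
#'   speeding up the final transition so the steady state is reached by the
#'   last timepoint.
#' @return An object of class `simulation_schedule`.
#' @export
simulation_schedule <- function(timepoints, cells_per_timepoint = 100,
                                burnin = NULL, rate_scale_after = NULL) {
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) < 1 || any(timepoints < 0) ||
      any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing and nonnegative")
  cells <- as.integer(rep_len(cells_per_timepoint, length(timepoints)))
  if (any(cells < 1)) stop("cells_per_timepoint must be positive")
  if (!is.null(burnin) && burnin <= 0) stop("burnin must be positive")
  if (!is.null(rate_scale_after)) {
    stopifnot(is.list(rate_scale_after),
              all(c("time", "factor") %in% names(rate_scale_after)),
              rate_scale_after$factor > 0)
  }
  structure(list(timepoints = timepoints, cells_per_timepoint = cells,
                 burnin = burnin, rate_scale_after = rate_scale_after),
            class = "simulation_schedule")
}

#' The benchmark sampling schedule
#'
#' Ten timepoints at 0, 6, 12, 24, 36, 48, 60, 72, 84 and 96 hours with 100
#' cells per timepoint (1000 cells per dataset).
#'
#' @param cells_per_timepoint override the per-timepoint cell count.
#' @return A [simulation_schedule()].
#' @export
benchmark_schedule <- function(cells_per_timepoint = 100) {
  simulation_schedule(c(0, 6, 12, 24, 36, 48, 60, 72, 84, 96),
                      cells_per_timepoint)
}

#' Simulate a time-stamped snapshot dataset
#'
#' For each scheduled timepoint t and each cell, draws an independent
#' pre-stimulus stationary state, switches the stimulus on at time 0,
#' simulates exactly to t and applies the Poisson count layer to the mRNA
#' levels. Cells are independent within and across timepoints (sampling is
#' destructive); each cell gets its own RNG stream derived from `seed` and a
#' cell counter, so results do not depend on evaluation order. Cells at
#' t = 0 are sampled just before stimulus onset and carry a stimulus
#' indicator of 0; all later cells carry 1.
#'
#' @param params a [grn_params()] object.
#' @param schedule a [simulation_schedule()].
#' @param seed integer root seed.
#' @return A [snapshot_data()] object: integer counts
#'   (cells x (n_genes + 1), column 1 the stimulus indicator) plus per-cell
#'   time labels.
#' @examples
#' net <- make_network("FN4")
#' d <- simulate_snapshots(net$params, benchmark_schedule(10), seed = 1)
#' dim(d$counts)
#' @export
simulate_snapshots <- function(params, schedule, seed = 0) {
  stopifnot(inherits(params, "grn_params"),
            inherits(schedule, "simulation_schedule"))
  burnin <- schedule$burnin %||% (4 / min(params$d1))
  rsa <- schedule$rate_scale_after
  n <- params$n_genes
  total <- sum(schedule$cells_per_timepoint)
  counts <- matrix(0L, total, n + 1,
                   dimnames = list(NULL, params$gene_names))
  time <- numeric(total)
  counter <- 0L
  row <- 0L
  for (k in seq_along(schedule$timepoints)) {
    tk <- schedule$timepoints[k]
    for (cell in seq_len(schedule$cells_per_timepoint[k])) {
      counter <- counter + 1L
      row <- row + 1L
      cs <- derive_seed(seed, counter)
      counts[row, ] <- with_seed(cs, {
        state <- cell_state(-burnin, rep(0, n), rep(0, n + 1))
        state <- sim_interval(params, state, stim = 0, t1 = 0)$state
        if (tk > 0) {
          state$P[1] <- 1
          if (!is.null(rsa) && tk > rsa$time) {
            if (rsa$time > 0)
              state <- sim_interval(params, state, stim = 1, rsa$time)$state
            state <- sim_interval(scale_rates(params, rsa$factor), state,
                                  stim = 1, tk)$state
          } else {
            state <- sim_interval(params, state, stim = 1, tk)$state
          }
        }
        c(if (tk > 0) 1L else 0L, rpois(n, state$M))
      })
      time[row] <- tk
    }
  }
  snapshot_data(counts, time, params$gene_names)
}

#' Simulate snapshot datasets from a GRN parameterisation
#'
#' [stats::simulate()] method wrapping [simulate_snapshots()].
#'
#' @param object a [grn_params()] object.
#' @param nsim number of independent datasets.
#' @param seed integer root seed.
#' @param schedule a [simulation_schedule()]; defaults to
#'   [benchmark_schedule()].
#' @param ... unused.
#' @return A [snapshot_data()] if `nsim = 1`, otherwise a list of them.
#' @export
simulate.grn_params <- function(object, nsim = 1, seed = 0,
                                schedule = benchmark_schedule(), ...) {
  out <- lapply(seq_len(nsim), function(r)
    simulate_snapshots(object, schedule, seed = derive_seed(seed, r)))
  if (nsim == 1) out[[1]] else out
}
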