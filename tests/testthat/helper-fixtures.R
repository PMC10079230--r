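# Shared fixtures built in code.

# A linear activation cascade Stimulus -> 1 -> ... -> n with the default
# benchmark kinetics and strongly switching edges.
chain_params <- function(n, strength = 10, basal = -5) {
  theta <- matrix(0, n + 1, n + 1)
  for (k in seq_len(n)) theta[k + 1, k] <- strength
  grn_params(n, theta = theta, beta = basal)
}

# An isolated, unregulated gene bursting at its maximal frequency
# (saturated sigmoid), the closed-form Gamma/NB reference case.
saturated_gene <- function() grn_params(1, beta = 50)

# Count burst events of a single simulated cell over [0, t_final].
n_bursts <- function(params, t_final, seed) {
  init <- cell_state(0, rep(0, params$n_genes), c(1, rep(0, params$n_genes)))
  nrow(simulate_cell(params, t_final, init, seed = seed)$bursts)
}
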