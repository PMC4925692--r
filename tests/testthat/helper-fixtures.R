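# Shared fixtures for the suite. All data are generated in code.

# the three-point dataset whose correction round-trip is known in closed form
tiny_dataset <- function(alpha_true = 0.5) {
  simulate_dataset(alpha_true = alpha_true, nl = 0,
                   flows = c(0.5, 1, 2))
}

# a small noiseless study-condition dataset
noiseless_dataset <- function(n = 1000, seed = 101) {
  simulate_dataset(n = n, nl = 0, seed = seed)
}

# quick sweep config kept small for unit tests
small_config <- function(...) {
  sweep_config(alpha_grid = c(0.5, 1, 1.5), nl_list = c(0, 0.05),
               replicates = 2, n = 100, seed = 7, ...)
}
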