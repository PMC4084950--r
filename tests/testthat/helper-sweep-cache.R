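# Reduced-scale parameter sweep shared by the acceptance tests: 20
# replicates per condition, 3000 h horizon, final-500-h medians. Built
# lazily once per test run and cached.
sweep_cache <- new.env(parent = emptyenv())

acceptance_sweep <- function() {
  if (!is.null(sweep_cache$runs)) {
    return(sweep_cache$runs)
  }
  grid <- tibble::tibble(
    arm = c("P5", "P20", "mu_low", "mu_high"),
    P = c(5L, 20L, 10L, 10L),
    mu = c(5e-7, 5e-7, 1e-7, 1e-6)
  )
  runs <- run_sweep(grid[, c("P", "mu")], replicates = 20,
                    base_params = sim_params(t_end = 3000), seed = 20140707)
  runs$arm <- grid$arm[runs$condition]
  sweep_cache$runs <- runs
  runs
}
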