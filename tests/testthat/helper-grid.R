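# The 20-scenario Type I error grid at Nsim = 10,000 is shared by several
# acceptance checks; compute it once per test run, lazily.
.grid_cache <- new.env()

acceptance_grid <- function() {
  if (is.null(.grid_cache$grid)) {
    specs <- table1_scenarios(nsim = 10000, alpha = 0.05, seed = 101)
    .grid_cache$grid <- run_grid(specs, keep = 10000)
  }
  .grid_cache$grid
}
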