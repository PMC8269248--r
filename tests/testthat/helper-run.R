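# The seeded default simulation and its pipeline run are shared across
# test files; both are computed once per session.
.run_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.run_cache$sim))
    .run_cache$sim <- termscape::simulate_dataset(seed = 1)
  .run_cache$sim
}

default_run <- function() {
  if (is.null(.run_cache$run)) {
    sim <- default_sim()
    .run_cache$run <- termscape::run_pipeline(
      sim$genome, sim$genes, sim$tss, sim$termseq, sim$rnaseq)
  }
  .run_cache$run
}
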