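# Shared large simulation used by several acceptance-level tests: a 1 Mb
# synthetic genome and 200,000 error-free 50 bp directional reads at the
# simulator defaults (p = 0.2, fragments 30-250 bp, mean 70). Built once
# per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

acceptance_run <- function() {
  if (is.null(.fixture_env$run)) {
    genome <- random_genome(1e6, gc = 0.55, seed = 20260930)
    cfg <- sim_config(n_reads = 2e5, seed = 4242)
    .fixture_env$run <- run_rrbs_pipeline(genome = genome, simulate = TRUE,
                                          sim = cfg)
  }
  .fixture_env$run
}
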