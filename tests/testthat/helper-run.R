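# One shared full-grid run at the published scale (1,000 cells x 100,000
# replicates, 10% true effects), computed on first use and reused by every
# test that asserts grid-level quantities. The seed is fixed so expected
# values are stable across sessions.
.run_cache <- new.env(parent = emptyenv())

full_grid_run <- function() {
  if (is.null(.run_cache$run)) {
    cfg <- run_config(profile = "paper", base_seed = 20260924L)
    out <- file.path(tempdir(), "posthocsim-grid-run")
    .run_cache$run <- run_experiment(cfg, out, quiet = TRUE)
  }
  .run_cache$run
}
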