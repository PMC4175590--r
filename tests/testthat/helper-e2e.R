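# One shared end-to-end run over the default synthetic cohort (20 tumour
# samples, 10 normals, full planted grid), reused across test files.

e2e_cache <- new.env(parent = emptyenv())

get_e2e <- function() {
  if (is.null(e2e_cache$run)) {
    d <- file.path(tempdir(), "kinfuse-e2e-fixture")
    out <- file.path(d, "out")
    sim <- simulate_cohort(sim_config(seed = 42), d)
    res <- run_fusion_pipeline(
      sim$sample_sheet, sim$annotation$gtf, sim$annotation$genome,
      sim$annotation$registry, expression = sim$expression,
      normals = dirname(sim$normals[[1]]), out_dir = out)
    e2e_cache$run <- list(sim = sim, res = res, dir = d, out = out)
  }
  e2e_cache$run
}

driver_pairs <- function(gt) {
  paste(gt$gene5[gt$role == "driver"], gt$gene3[gt$role == "driver"])
}
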