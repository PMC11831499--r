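# Session-level cache for the default synthetic fixture and pipeline runs,
# shared by the pipeline tests and the acceptance tests so the expensive
# steps run once.
.fixture_cache <- new.env(parent = emptyenv())

default_truth <- function() {
  if (is.null(.fixture_cache$truth)) {
    cfg <- sim_config(seed = 42)
    .fixture_cache$truth <- generate_truth(cfg)
  }
  .fixture_cache$truth
}

default_fixture_dir <- function() {
  if (is.null(.fixture_cache$dir)) {
    truth <- default_truth()
    sim <- simulate_counts(truth)
    dir <- file.path(tempdir(), "nodcerna-fixture-seed42")
    write_fixture(truth, sim, dir)
    .fixture_cache$sim <- sim
    .fixture_cache$dir <- dir
  }
  .fixture_cache$dir
}

default_sim <- function() {
  default_fixture_dir()
  .fixture_cache$sim
}

default_pipeline <- function() {
  if (is.null(.fixture_cache$run)) {
    outdir <- file.path(tempdir(), "nodcerna-out-seed42")
    .fixture_cache$run <- suppressMessages(
      run_pipeline(default_fixture_dir(), outdir))
    .fixture_cache$outdir <- outdir
  }
  .fixture_cache$run
}

default_pipeline_outdir <- function() {
  default_pipeline()
  .fixture_cache$outdir
}

# A small, fast configuration for structural generator tests.
small_config <- function(seed = 7) {
  sim_config(n_mrna = 30, n_lncrna = 25, n_mirna = 8, n_circrna = 4,
             n_planted_de = c(mRNA = 6, lncRNA = 4, miRNA = 2, circRNA = 2),
             n_planted_nark = c(mRNA = 4, lncRNA = 2, miRNA = 2, circRNA = 1),
             n_planted_triplets = 4, mirnas_per_pair = 2,
             n_planted_modules = 1, module_size = 10, seed = seed)
}
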