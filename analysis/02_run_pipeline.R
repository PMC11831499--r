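#!/usr/bin/env Rscript

# Run the full analysis on results/fixture: normalization, detectability,
# NR and NARK differential expression, lncRNA modules, NNR union, cis
# targets, MRE scanning, and ceRNA network assembly. Writes results/pipeline/.
#
# Usage: Rscript analysis/02_run_pipeline.R [--resume]

library(nodcerna)

args <- commandArgs(trailingOnly = TRUE)
fixture_dir <- file.path("results", "fixture")
if (!dir.exists(fixture_dir)) {
  stop("no fixture at ", fixture_dir,
       "; run analysis/01_simulate_fixture.R first")
}

res <- run_pipeline(fixture_dir, file.path("results", "pipeline"),
                    resume = "--resume" %in% args)

message(sprintf("soft power beta = %d (fallback: %s)",
                res$beta$beta, res$beta$warning))
message(sprintf("%d ceRNA triplets retained", nrow(res$triplets)))
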