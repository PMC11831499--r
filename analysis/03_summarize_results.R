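#!/usr/bin/env Rscript

# Compare the pipeline outputs in results/pipeline against the planted truth
# in results/fixture and write results/summary.json plus a console report.
#
# Usage: Rscript analysis/03_summarize_results.R

library(nodcerna)

fixture_dir <- file.path("results", "fixture")
pipe_dir <- file.path("results", "pipeline")
for (d in c(fixture_dir, pipe_dir)) {
  if (!dir.exists(d)) stop("missing ", d, "; run the earlier scripts first")
}

triplets <- utils::read.delim(file.path(pipe_dir, "cerna_triplets.tsv"),
                              stringsAsFactors = FALSE)
truth_triplets <- utils::read.delim(file.path(fixture_dir,
                                              "truth_triplets.tsv"),
                                    stringsAsFactors = FALSE)
truth_nr <- utils::read.delim(file.path(fixture_dir, "truth_planted_nr.tsv"),
                              stringsAsFactors = FALSE)
modules <- utils::read.delim(file.path(pipe_dir, "modules_lncrna.tsv"),
                             stringsAsFactors = FALSE)
truth_modules <- utils::read.delim(file.path(fixture_dir,
                                             "truth_modules.tsv"),
                                   stringsAsFactors = FALSE)

want <- with(truth_triplets, paste(lncrna, mirna, mrna))
got <- with(triplets, paste(lncrna, mirna, mrna))
precision <- if (length(got) > 0) {
  length(intersect(got, want)) / length(got)
} else NA_real_
recall <- length(intersect(got, want)) / length(want)

geno_members <- truth_modules$feature[truth_modules$module == 1]
found_members <- modules$feature[modules$module != 0]
module_recall <- length(intersect(found_members, geno_members)) /
  length(geno_members)

summary <- list(
  n_planted_triplets = length(want),
  n_recovered_triplets = length(got),
  cerna_precision = precision,
  cerna_recall = recall,
  n_planted_nr = nrow(truth_nr),
  n_genotype_module_members = length(geno_members),
  module_member_recall = module_recall)

jsonlite::write_json(summary, file.path("results", "summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message(paste(sprintf("%-26s %s", names(summary), unlist(summary)),
              collapse = "\n"))
message("wrote results/summary.json")
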