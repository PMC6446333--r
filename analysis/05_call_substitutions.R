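#!/usr/bin/env Rscript
# The decision step: for each line, is one chromosome's missingness the
# unique maximum, at least 0.40, at least 5x the median of the others,
# and depressed along the whole chromosome? Writes the cohort JSON report.

suppressPackageStartupMessages(library(chromsub))
G <- read_genotypes("results/cohort/genotypes.tsv")
map <- read_marker_map("results/cohort/marker_map.tsv")

samples <- c("WP1", "WP2", "Donor", "SubL1", "SubL2", "SubL3")
calls <- call_cohort(G, map, samples,
                     chromosome_lengths = wheat_chromosome_lengths())
write_calls_json(calls, "results/calls.json")

df <- as.data.frame(calls)
print(df[, c("sample", "verdict", "called_chromosome", "missing_ratio",
             "background_median", "fold")])
n_sub <- sum(df$verdict == "substitution")
message(sprintf("%d substitution call(s); concordant chromosome: %s",
                n_sub, paste(unique(stats::na.omit(df$called_chromosome)),
                             collapse = ", ")))
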