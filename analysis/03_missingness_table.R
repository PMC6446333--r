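#!/usr/bin/env Rscript
# Per-chromosome missing-call statistics for every sample, rendered as the
# familiar per-line table (mapped count, then missing count and one-decimal
# percentage per line), plus the genome-wide donor hybridization rate.

suppressPackageStartupMessages(library(chromsub))
G <- read_genotypes("results/cohort/genotypes.tsv")
map <- read_marker_map("results/cohort/marker_map.tsv")

samples <- c("SubL1", "SubL2", "SubL3")
summaries <- lapply(samples, function(s) summarize_missingness(G, map, s))
tab <- render_table1(summaries)
write_table1(tab, "results/missingness_table.tsv")

message("missingness table (substituted and parent-divergent rows):")
print(tab[tab$Chromosome %in% c("1A", "2D", "4B", "7B"), ])

rate <- hybridization_rate(G, "Donor")
message(sprintf("donor hybridization: %d of %d markers (%s)",
                sum(G[, "Donor"] != "NC"), nrow(G),
                percent_from_counts(sum(G[, "Donor"] != "NC"), nrow(G))))
stopifnot(abs(rate - 0.577) < 0.01)
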