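#!/usr/bin/env Rscript
# Sliding-window observed/expected marker ratio along chromosome 4B
# (10 Mb windows, 1 Mb step) for the three substitution lines: in a true
# whole-chromosome substitution the ratio is depressed along the entire
# chromosome, not in a segment. Writes one BED4 track and one step plot
# per line.

suppressPackageStartupMessages(library(chromsub))
G <- read_genotypes("results/cohort/genotypes.tsv")
map <- read_marker_map("results/cohort/marker_map.tsv")
dir.create("results/tracks", showWarnings = FALSE, recursive = TRUE)

len_4B <- wheat_chromosome_lengths()[["4B"]]
for (s in c("SubL1", "SubL2", "SubL3")) {
  trk <- scan_chromosome(G, map, s, "4B", window_spec(), len_4B)
  export_track(trk, sprintf("results/tracks/%s_4B.bed", s),
               plot_path = sprintf("results/tracks/%s_4B.png", s))
  cov <- coverage_fraction(trk, depressed_threshold = 0.7)
  message(sprintf(
    "%s: %d windows, mean ratio %.3f, %.1f%% of windows depressed (<= 0.7)",
    s, nrow(trk), mean(trk$ratio, na.rm = TRUE), 100 * cov))
}
message("a euploid parent for contrast:")
trk_wp <- scan_chromosome(G, map, "WP1", "4B", window_spec(), len_4B)
message(sprintf("WP1: mean ratio %.3f, %.1f%% depressed",
                mean(trk_wp$ratio, na.rm = TRUE),
                100 * coverage_fraction(trk_wp, 0.7)))
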