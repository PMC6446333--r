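#' Run the full simulation-to-call pipeline
#'
#' Simulates a marker map and genotype matrix under `config`, summarises
#' per-chromosome missingness for every sample, calls substitutions,
#' scans the called chromosomes, filters shared homozygous markers for
#' each called chromosome (across the lines called for it plus the first
#' alien donor in the cohort), and writes all primary outputs under
#' `out_dir`:
#'
#' * `marker_map.tsv`, `genotypes.tsv`, `truth.json` — the simulated data;
#' * `missingness_table.tsv` — the per-chromosome missingness table;
#' * `calls.json` — the cohort call report;
#' * `track_<sample>_<chrom>.bed` — window tracks of called chromosomes;
#' * `shared_<chrom>.tsv` — shared homozygous markers per called
#'   chromosome.
#'
#' Outputs are byte-identical across runs with the same config (the seed
#' lives in the config).
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param params a [caller_params()].
#' @param spec a [window_spec()].
#' @return invisibly, a list with the in-memory objects (`map`,
#'   `genotypes`, `truth`, `summaries`, `table1`, `calls`, `shared`) and
#'   the written `files`.
#' @export
run_pipeline <- function(config, out_dir, params = caller_params(),
                         spec = window_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  map <- simulate_marker_map(config)
  sim <- simulate_genotypes(map, config)
  G <- sim$genotypes

  files <- c(
    map = file.path(out_dir, "marker_map.tsv"),
    genotypes = file.path(out_dir, "genotypes.tsv"),
    truth = file.path(out_dir, "truth.json"),
    table1 = file.path(out_dir, "missingness_table.tsv"),
    calls = file.path(out_dir, "calls.json")
  )
  write_marker_map(map, files[["map"]])
  write_genotypes(G, files[["genotypes"]])
  write_truth(sim$truth, files[["truth"]])

  samples <- config$samples$sample
  summaries <- lapply(samples, function(s) summarize_missingness(G, map, s))
  names(summaries) <- samples
  table1 <- render_table1(summaries)
  write_table1(table1, files[["table1"]])

  lens <- config$chromosome_lengths
  calls <- call_cohort(G, map, samples, params, spec, lens)
  write_calls_json(calls, files[["calls"]])

  called <- as.data.frame(calls)
  called <- called[called$verdict == "substitution", , drop = FALSE]
  for (i in seq_len(nrow(called))) {
    smp <- called$sample[i]
    chrom <- called$called_chromosome[i]
    trk <- scan_chromosome(G, map, smp, chrom, spec, lens[[chrom]])
    f <- file.path(out_dir, sprintf("track_%s_%s.bed", smp, chrom))
    export_track(trk, f)
    files[[sprintf("track_%s_%s", smp, chrom)]] <- f
  }

  shared <- list()
  donors <- config$samples$sample[config$samples$role == "alien_donor"]
  if (length(donors) > 0 && nrow(called) > 0) {
    for (chrom in unique(called$called_chromosome)) {
      lines <- called$sample[called$called_chromosome == chrom]
      shared[[chrom]] <- filter_shared_homozygous(G, map, chrom, lines,
                                                  donors[1])
      f <- file.path(out_dir, sprintf("shared_%s.tsv", chrom))
      write_shared_markers(shared[[chrom]], f)
      files[[sprintf("shared_%s", chrom)]] <- f
    }
  }

  invisible(list(map = map, genotypes = G, truth = sim$truth,
                 summaries = summaries, table1 = table1, calls = calls,
                 shared = shared, files = files))
}
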