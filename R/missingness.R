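# Per-chromosome missing-call statistics: the machine form of the printed
# per-line missingness table, plus the genome-wide alien cross-hybridization
# rate.

#' Construct a per-chromosome missingness summary from counts
#'
#' Builds the summary object directly from (mapped, missing) count pairs,
#' e.g. when re-rendering a published table. Most users will call
#' [summarize_missingness()] on a genotype matrix instead.
#'
#' @param chromosome character vector of chromosome ids.
#' @param n_mapped mapped-marker counts per chromosome.
#' @param n_missing missing-call counts per chromosome.
#' @param sample sample id the counts belong to.
#' @return data.frame of class `missingness_summary` with columns
#'   `chromosome`, `n_mapped`, `n_missing`, `missing_ratio` (NA where
#'   `n_mapped == 0`).
#' @export
missingness_summary <- function(chromosome, n_mapped, n_missing, sample) {
  if (any(n_missing < 0) || any(n_missing > n_mapped))
    input_error("need 0 <= n_missing <= n_mapped")
  out <- data.frame(
    chromosome = as.character(chromosome),
    n_mapped = as.integer(n_mapped),
    n_missing = as.integer(n_missing),
    missing_ratio = ifelse(n_mapped > 0, n_missing / n_mapped, NA_real_),
    stringsAsFactors = FALSE
  )
  attr(out, "sample") <- sample
  class(out) <- c("missingness_summary", "data.frame")
  out
}

#' Per-chromosome missing-call counts and ratios for one sample
#'
#' For each chromosome, counts the mapped markers (markers of `map`
#' present in `G`) and those with an NC call in `sample`. "Missing" means
#' call state NC only — a heterozygous AB is a present call. Markers of
#' `map` absent from `G` are excluded from all counts and reported in the
#' `discrepancy` attribute.
#'
#' @param G genotype matrix (markers x samples, values AA/AB/BB/NC).
#' @param map marker map data.frame (`marker`, `chrom`, `pos`).
#' @param sample sample id (column of `G`).
#' @return a [missingness_summary()] with one row per chromosome (sorted
#'   by chromosome id); attribute `discrepancy` lists unmatched markers.
#' @examples
#' cfg <- simulation_config(chromosome_lengths = c(chr1 = 1e6, chr2 = 1e6),
#'                          n_markers = 200, seed = 3)
#' map <- simulate_marker_map(cfg)
#' sim <- simulate_genotypes(map, cfg)
#' summarize_missingness(sim$genotypes, map, "SubL1")
#' @export
summarize_missingness <- function(G, map, sample) {
  if (!sample %in% colnames(G)) lookup_error("sample", sample)
  if (nrow(map) == 0) input_error("marker map is empty")
  in_G <- map$marker %in% rownames(G)
  discrepancy <- map$marker[!in_G]
  map <- map[in_G, , drop = FALSE]
  calls <- G[map$marker, sample]
  chroms <- sort(unique(map$chrom))
  fac <- factor(map$chrom, levels = chroms)
  n_mapped <- as.integer(table(fac))
  n_missing <- as.integer(tapply(calls == "NC", fac, sum, default = 0L))
  out <- missingness_summary(chroms, n_mapped, n_missing, sample)
  attr(out, "discrepancy") <- discrepancy
  out
}

#' Genome-wide alien cross-hybridization rate
#'
#' Fraction of all markers in the genotype matrix — mapped or not — with a
#' non-NC call in the alien donor sample. This is the statistic behind
#' "x of y array features also hybridized with the donor".
#'
#' @param G genotype matrix.
#' @param alien_sample donor sample id.
#' @return fraction in \[0, 1\].
#' @export
hybridization_rate <- function(G, alien_sample) {
  if (!alien_sample %in% colnames(G)) lookup_error("sample", alien_sample)
  mean(G[, alien_sample] != "NC")
}

#' Render the per-chromosome missingness table
#'
#' One row per chromosome: the mapped-marker count (`Number`), then for
#' each sample its missing count and ratio as a one-decimal percentage
#' (round-half-even, computed exactly from the counts via
#' [percent_from_counts()]). All summaries must share one marker map,
#' i.e. identical chromosome sets and mapped counts.
#'
#' @param summaries list of [missingness_summary()] objects (one per
#'   sample).
#' @return data.frame with columns `Chromosome`, `Number`, then
#'   `<sample>_missing` and `<sample>_ratio` per sample.
#' @export
render_table1 <- function(summaries) {
  if (!is.list(summaries) || length(summaries) == 0)
    input_error("summaries must be a non-empty list")
  if (inherits(summaries, "missingness_summary")) summaries <- list(summaries)
  ref <- summaries[[1]]
  for (s in summaries[-1]) {
    if (!identical(s$chromosome, ref$chromosome) ||
        !identical(s$n_mapped, ref$n_mapped))
      consistency_error("summaries do not share one marker map")
  }
  out <- data.frame(Chromosome = ref$chromosome, Number = ref$n_mapped,
                    stringsAsFactors = FALSE)
  for (s in summaries) {
    id <- attr(s, "sample")
    out[[paste0(id, "_missing")]] <- s$n_missing
    out[[paste0(id, "_ratio")]] <- percent_from_counts(s$n_missing, s$n_mapped)
  }
  out
}

#' Write the rendered missingness table as TSV
#'
#' @param table1 output of [render_table1()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table1 <- function(table1, path) {
  utils::write.table(table1, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
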