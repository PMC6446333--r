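# Markers on the substituted chromosome that cross-hybridize with the
# alien homoeolog: present, homozygous, and allele-identical in every
# substitution line and the alien donor.

#' Filter shared homozygous markers on a chromosome
#'
#' Tests every mapped marker on `chromosome` across the given substitution
#' lines and the alien donor. A marker is included iff its call is
#' homozygous (`AA` or `BB`) in every queried sample and all calls are
#' identical. Exclusion reasons are assigned with fixed precedence
#' `missing_in_some` > `heterozygous_in_some` > `allele_discordant`, so
#' reason counts are deterministic.
#'
#' @param G genotype matrix.
#' @param map marker map.
#' @param chromosome chromosome id.
#' @param lines character vector of substitution-line sample ids (>= 1).
#' @param alien alien donor sample id (distinct from `lines`).
#' @return list of class `shared_marker_set`: `chromosome`, `markers`
#'   (data.frame `marker`, `pos`, `allele`, sorted by position),
#'   `n_tested`, and `excluded` (named counts per reason).
#' @export
filter_shared_homozygous <- function(G, map, chromosome, lines, alien) {
  if (length(lines) < 1) input_error("need at least one substitution line")
  if (alien %in% lines)
    input_error("alien donor must be distinct from the substitution lines")
  for (smp in c(lines, alien))
    if (!smp %in% colnames(G)) lookup_error("sample", smp)
  if (!chromosome %in% map$chrom) lookup_error("chromosome", chromosome)
  mk <- map[map$chrom == chromosome & map$marker %in% rownames(G), ,
            drop = FALSE]
  calls <- G[mk$marker, c(lines, alien), drop = FALSE]

  any_nc <- apply(calls == "NC", 1, any)
  any_ab <- apply(calls == "AB", 1, any)
  concordant <- apply(calls, 1, function(x) length(unique(x)) == 1)
  reason <- rep(NA_character_, nrow(mk))
  reason[!any_nc & !any_ab & !concordant] <- "allele_discordant"
  reason[any_ab & !any_nc] <- "heterozygous_in_some"
  reason[any_nc] <- "missing_in_some"
  included <- is.na(reason)

  markers <- data.frame(marker = mk$marker[included],
                        pos = mk$pos[included],
                        allele = calls[included, 1],
                        stringsAsFactors = FALSE)
  markers <- markers[order(markers$pos), , drop = FALSE]
  rownames(markers) <- NULL
  excluded <- c(
    missing_in_some = sum(reason == "missing_in_some", na.rm = TRUE),
    heterozygous_in_some = sum(reason == "heterozygous_in_some", na.rm = TRUE),
    allele_discordant = sum(reason == "allele_discordant", na.rm = TRUE)
  )
  structure(list(chromosome = chromosome, markers = markers,
                 n_tested = nrow(mk), excluded = excluded),
            class = "shared_marker_set")
}

#' @export
print.shared_marker_set <- function(x, ...) {
  cat(sprintf(
    "%d shared homozygous markers on %s (of %d tested; excluded: %d missing, %d heterozygous, %d discordant)\n",
    nrow(x$markers), x$chromosome, x$n_tested,
    x$excluded[["missing_in_some"]], x$excluded[["heterozygous_in_some"]],
    x$excluded[["allele_discordant"]]))
  invisible(x)
}

#' Per-window counts of shared markers along the chromosome
#'
#' Bins the shared markers into non-overlapping windows of
#' `spec$window_size` and flags windows containing none — a quick check
#' that the shared set covers the whole chromosome rather than a segment.
#'
#' @param set a [filter_shared_homozygous()] result.
#' @param chromosome_length chromosome length in bp.
#' @param spec a [window_spec()] (only `window_size` is used; bins are
#'   non-overlapping).
#' @return data.frame with columns `start`, `end`, `n_shared`, `empty`.
#' @export
coverage_report <- function(set, chromosome_length, spec = window_spec()) {
  if (chromosome_length <= 0) input_error("chromosome_length must be > 0")
  starts <- (seq_len(ceiling(chromosome_length / spec$window_size)) - 1) *
    spec$window_size
  ends <- starts + spec$window_size
  p <- sort(set$markers$pos)
  n <- findInterval(ends, p) - findInterval(starts, p)
  data.frame(start = starts, end = ends, n_shared = as.integer(n),
             empty = n == 0)
}

#' Write a shared-marker set as TSV
#'
#' Columns `marker`, `chrom`, `pos`, `allele` — the layout of a
#' supplementary shared-marker table.
#'
#' @param set a [filter_shared_homozygous()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_shared_markers <- function(set, path) {
  out <- data.frame(marker = set$markers$marker, chrom = set$chromosome,
                    pos = set$markers$pos, allele = set$markers$allele,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
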