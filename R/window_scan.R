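# Sliding-window observed/expected marker ratio along a chromosome.
# Windows are 0-based half-open [start, start + window_size) at steps of
# `step`; marker positions are 1-based, and a marker at position p falls
# in a window iff start < p <= end (see marker_in_window()).

#' Sliding-window specification
#'
#' @param window_size window width in bp (default 10 Mb).
#' @param step step between window starts in bp (default 1 Mb).
#' @param min_expected windows with fewer mapped markers are flagged
#'   undefined rather than given an unstable ratio (default 5).
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(window_size = 1e7, step = 1e6, min_expected = 5) {
  if (window_size <= 0) config_error("window_size", "must be > 0")
  if (step <= 0) config_error("step", "must be > 0")
  if (step > window_size) config_error("step", "must be <= window_size")
  if (min_expected < 0) config_error("min_expected", "must be >= 0")
  structure(list(window_size = window_size, step = step,
                 min_expected = min_expected),
            class = "window_spec")
}

#' Observed/expected marker ratio in sliding windows
#'
#' For each window `[k*step, k*step + window_size)` with `k = 0, 1, ...`
#' while the start lies inside the chromosome, counts the mapped markers
#' in the window (`n_expected`) and those with a non-NC call in `sample`
#' (`n_observed`). The final partial windows at the chromosome end are
#' kept (their nominal end may exceed the chromosome length). Windows
#' with `n_expected < min_expected` have ratio `NA`.
#'
#' @param G genotype matrix.
#' @param map marker map data.frame.
#' @param sample sample id.
#' @param chromosome chromosome id.
#' @param spec a [window_spec()].
#' @param chromosome_length chromosome length in bp (>= max marker
#'   position).
#' @return data.frame of class `window_track` with columns `chrom`,
#'   `start`, `end`, `n_expected`, `n_observed`, `ratio`; attributes
#'   `sample`, `spec`, `chromosome_length`.
#' @export
scan_chromosome <- function(G, map, sample, chromosome,
                            spec = window_spec(), chromosome_length) {
  if (!sample %in% colnames(G)) lookup_error("sample", sample)
  if (!chromosome %in% map$chrom) lookup_error("chromosome", chromosome)
  mk <- map[map$chrom == chromosome & map$marker %in% rownames(G), ,
            drop = FALSE]
  if (nrow(mk) > 0 && chromosome_length < max(mk$pos))
    input_error("chromosome_length is smaller than the largest marker position")
  starts <- (seq_len(ceiling(chromosome_length / spec$step)) - 1) * spec$step
  ends <- starts + spec$window_size
  p_all <- sort(mk$pos)
  p_obs <- sort(mk$pos[G[mk$marker, sample] != "NC"])
  # count of positions p with start < p <= end, via sorted lookups
  n_exp <- findInterval(ends, p_all) - findInterval(starts, p_all)
  n_obs <- findInterval(ends, p_obs) - findInterval(starts, p_obs)
  ratio <- ifelse(n_exp >= spec$min_expected & n_exp > 0, n_obs / n_exp,
                  NA_real_)
  out <- data.frame(chrom = chromosome, start = starts, end = ends,
                    n_expected = as.integer(n_exp),
                    n_observed = as.integer(n_obs),
                    ratio = ratio, stringsAsFactors = FALSE)
  attr(out, "sample") <- sample
  attr(out, "spec") <- spec
  attr(out, "chromosome_length") <- chromosome_length
  class(out) <- c("window_track", "data.frame")
  out
}

#' Fraction of windows with a depressed marker ratio
#'
#' The "whole chromosome" test: the fraction of defined windows whose
#' observed/expected ratio is at or below `depressed_threshold`. A
#' substituted chromosome is depressed essentially everywhere; a segmental
#' introgression only locally.
#'
#' @param track a [scan_chromosome()] track.
#' @param depressed_threshold ratio threshold (default 0.7).
#' @return fraction in \[0, 1\].
#' @export
coverage_fraction <- function(track, depressed_threshold = 0.7) {
  defined <- !is.na(track$ratio)
  if (!any(defined))
    chromsub_error("track has no defined windows",
                   "chromsub_undefined_result_error")
  mean(track$ratio[defined] <= depressed_threshold)
}

#' Export a window track as BED4 (and optionally plot it)
#'
#' Writes one BED line per window (`chrom`, 0-based `start`, half-open
#' `end`, ratio to six decimals; `NA` for undefined windows). Overlapping
#' sliding windows serialize as overlapping intervals — no merging. A
#' round-trip through [read_track()] reproduces the ratios to six
#' decimals.
#'
#' @param track a [scan_chromosome()] track.
#' @param bed_path output BED path.
#' @param plot_path optional PNG/SVG path for a step plot of the track.
#' @return `bed_path`, invisibly.
#' @export
export_track <- function(track, bed_path, plot_path = NULL) {
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom,
                   as.integer(track$start), as.integer(track$end),
                   ifelse(is.na(track$ratio), "NA",
                          sprintf("%.6f", track$ratio)))
  ok <- tryCatch({
    writeLines(lines, bed_path); TRUE
  }, error = function(e) FALSE)
  if (!ok) chromsub_error(sprintf("cannot write '%s'", bed_path),
                          "chromsub_io_error")
  if (!is.null(plot_path)) {
    p <- plot_track(track)
    ggplot2::ggsave(plot_path, p, width = 8, height = 3, dpi = 150)
  }
  invisible(bed_path)
}

#' Read a BED4 window track written by [export_track()]
#'
#' @param bed_path BED path.
#' @return data.frame with columns `chrom`, `start`, `end`, `ratio`.
#' @export
read_track <- function(bed_path) {
  out <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "ratio"),
                           na.strings = "NA", stringsAsFactors = FALSE)
  out
}

#' Step plot of a window track
#'
#' @param track a [scan_chromosome()] track.
#' @return a ggplot object (windows at their midpoints, in Mb).
#' @export
plot_track <- function(track) {
  df <- track[!is.na(track$ratio), , drop = FALSE]
  df$mid_mb <- (df$start + df$end) / 2 / 1e6
  ggplot2::ggplot(df, ggplot2::aes(x = mid_mb, y = ratio)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = sprintf("%s position (Mb, window midpoint)", track$chrom[1]),
      y = "observed / expected markers",
      title = sprintf("%s — %s", attr(track, "sample"),
                      track$chrom[1])) +
    ggplot2::theme_minimal()
}
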