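# Decide which chromosome, if any, is replaced by an alien homoeolog in a
# line, from its per-chromosome missingness and the window track of the
# candidate chromosome.

#' Substitution-caller thresholds
#'
#' A chromosome is called substituted when (1) its missing ratio is the
#' unique maximum and at least `min_missing_ratio`, (2) it exceeds the
#' median missing ratio of all other chromosomes by a factor of at least
#' `min_fold_over_background` (the median is robust to a few
#' parent-divergent chromosomes with mildly elevated missingness), and
#' (3) its window track is depressed along the whole chromosome: at least
#' `min_coverage_fraction` of defined windows have ratio at or below
#' `depressed_threshold`. A line passing the ratio tests but failing
#' coverage is flagged ambiguous (segmental-introgression suspect), as is
#' a tie for the maximum or more than one chromosome above
#' `min_missing_ratio`.
#'
#' @param min_missing_ratio absolute missing-ratio gate (default 0.40).
#' @param min_fold_over_background fold over the median of the other
#'   chromosomes (default 5).
#' @param min_coverage_fraction required fraction of depressed windows
#'   (default 0.8).
#' @param depressed_threshold window ratio at or below which a window
#'   counts as depressed (default 0.7).
#' @return an object of class `caller_params`.
#' @export
caller_params <- function(min_missing_ratio = 0.40,
                          min_fold_over_background = 5,
                          min_coverage_fraction = 0.8,
                          depressed_threshold = 0.7) {
  for (p in c("min_missing_ratio", "min_coverage_fraction",
              "depressed_threshold")) {
    v <- get(p)
    if (v < 0 || v > 1) config_error(p, "must be in [0, 1]")
  }
  if (min_fold_over_background < 1)
    config_error("min_fold_over_background", "must be >= 1")
  structure(list(min_missing_ratio = min_missing_ratio,
                 min_fold_over_background = min_fold_over_background,
                 min_coverage_fraction = min_coverage_fraction,
                 depressed_threshold = depressed_threshold),
            class = "caller_params")
}

#' Call a whole-chromosome substitution for one sample
#'
#' The candidate is the chromosome with the maximum missing ratio; the
#' verdict follows the gates documented in [caller_params()]:
#' `substitution` when all pass, `ambiguous` when the ratio tests pass but
#' whole-chromosome coverage fails (or the candidate is not unique), else
#' `no_substitution`.
#'
#' @param summary a [summarize_missingness()] summary for the sample.
#' @param tracks named list of [scan_chromosome()] tracks; must contain at
#'   least the candidate chromosome when the ratio gates pass.
#' @param params a [caller_params()].
#' @return list of class `substitution_call`: `sample`, `verdict`
#'   (`substitution` / `no_substitution` / `ambiguous`),
#'   `called_chromosome` (NA unless substitution), `missing_ratio`,
#'   `background_median`, `fold`, `coverage_fraction`, `reason`, `params`.
#' @export
call_sample <- function(summary, tracks = list(), params = caller_params()) {
  ok <- !is.na(summary$missing_ratio)
  if (nrow(summary) == 0 || !any(ok))
    input_error("missingness summary is empty")
  s <- summary[ok, , drop = FALSE]
  r <- s$missing_ratio
  i <- which.max(r)
  cand <- s$chromosome[i]
  r_max <- r[i]
  bg_median <- stats::median(r[-i])
  fold <- if (length(r) == 1) Inf
          else if (bg_median == 0) (if (r_max > 0) Inf else 1)
          else r_max / bg_median

  res <- list(sample = attr(summary, "sample"),
              verdict = "no_substitution",
              called_chromosome = NA_character_,
              missing_ratio = r_max,
              background_median = bg_median,
              fold = fold,
              coverage_fraction = NA_real_,
              reason = NA_character_,
              params = params)
  class(res) <- "substitution_call"

  tie <- sum(r == r_max) > 1
  multi <- sum(r >= params$min_missing_ratio) > 1
  ratio_pass <- r_max >= params$min_missing_ratio &&
    fold >= params$min_fold_over_background
  if (!ratio_pass) {
    res$reason <- "below_ratio_gates"
    return(res)
  }
  if (tie || multi) {
    res$verdict <- "ambiguous"
    res$reason <- if (tie) "tied_maximum" else "multiple_candidates"
    return(res)
  }
  if (is.null(tracks[[cand]]))
    input_error(sprintf("no window track supplied for candidate chromosome '%s'",
                        cand))
  cov <- coverage_fraction(tracks[[cand]], params$depressed_threshold)
  res$coverage_fraction <- cov
  if (cov >= params$min_coverage_fraction) {
    res$verdict <- "substitution"
    res$called_chromosome <- cand
    res$reason <- "all_gates_passed"
  } else {
    res$verdict <- "ambiguous"
    res$reason <- "low_whole_chromosome_coverage"
  }
  res
}

#' @export
print.substitution_call <- function(x, ...) {
  cat(sprintf("sample %s: %s%s (missing ratio %.3f, background median %.3f, fold %.1f%s)\n",
              x$sample, x$verdict,
              if (!is.na(x$called_chromosome))
                sprintf(" of chromosome %s", x$called_chromosome) else "",
              x$missing_ratio, x$background_median, x$fold,
              if (!is.na(x$coverage_fraction))
                sprintf(", coverage %.2f", x$coverage_fraction) else ""))
  invisible(x)
}

#' Call substitutions for a cohort of samples
#'
#' Runs [summarize_missingness()] per sample, computes the window track
#' for the candidate chromosome (the coverage gate applies only to it),
#' and calls each sample. Chromosome lengths default to the map's largest
#' marker position per chromosome.
#'
#' @param G genotype matrix.
#' @param map marker map.
#' @param samples character vector of sample ids to call.
#' @param params a [caller_params()].
#' @param spec a [window_spec()] for the coverage test.
#' @param chromosome_lengths optional named vector of chromosome lengths.
#' @return list of class `substitution_cohort`: one `substitution_call`
#'   per sample, named by sample.
#' @export
call_cohort <- function(G, map, samples, params = caller_params(),
                        spec = window_spec(), chromosome_lengths = NULL) {
  if (is.null(chromosome_lengths))
    chromosome_lengths <- tapply(map$pos, map$chrom, max)
  calls <- lapply(samples, function(smp) {
    summ <- summarize_missingness(G, map, smp)
    r <- summ$missing_ratio
    cand <- summ$chromosome[which.max(r)]
    tracks <- list()
    if (max(r, na.rm = TRUE) >= params$min_missing_ratio) {
      tracks[[cand]] <- scan_chromosome(G, map, smp, cand, spec,
                                        chromosome_lengths[[cand]])
    }
    call_sample(summ, tracks, params)
  })
  names(calls) <- samples
  class(calls) <- "substitution_cohort"
  calls
}

#' Flatten cohort calls to a data.frame
#'
#' @param x a `substitution_cohort`.
#' @param row.names,optional,... ignored (S3 conformance).
#' @return data.frame with one row per sample.
#' @export
as.data.frame.substitution_cohort <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  do.call(rbind, lapply(unclass(x), function(cl) {
    data.frame(sample = cl$sample, verdict = cl$verdict,
               called_chromosome = cl$called_chromosome,
               missing_ratio = cl$missing_ratio,
               background_median = cl$background_median,
               fold = cl$fold,
               coverage_fraction = cl$coverage_fraction,
               reason = cl$reason, stringsAsFactors = FALSE)
  }))
}

#' Write a cohort call report as JSON
#'
#' Per-sample evidence (verdict, statistics, thresholds) plus the package
#' version, in a stable layout suitable for diffing.
#'
#' @param calls a `substitution_cohort`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_calls_json <- function(calls, path) {
  payload <- list(
    software = "chromsub",
    version = as.character(utils::packageVersion("chromsub")),
    any_ambiguous = any(vapply(unclass(calls),
                               function(cl) cl$verdict == "ambiguous",
                               logical(1))),
    calls = lapply(unclass(calls), function(cl) {
      cl$params <- unclass(cl$params)
      unclass(cl)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
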