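# a uniformly depressed (or flat) synthetic track for gate tests
flat_track <- function(chrom, ratio, n = 50) {
  structure(data.frame(chrom = chrom,
                       start = seq(0, by = 1e6, length.out = n),
                       end = seq(1e7, by = 1e6, length.out = n),
                       n_expected = 100L,
                       n_observed = as.integer(round(100 * ratio)),
                       ratio = ratio),
            class = c("window_track", "data.frame"))
}

test_that("a euploid line with background missingness only is not called", {
  cfg <- small_config(seed = 3)
  map <- simulate_marker_map(cfg)
  sim <- simulate_genotypes(map, cfg)
  summ <- summarize_missingness(sim$genotypes, map, "WP1")
  call <- call_sample(summ, params = caller_params())
  expect_equal(call$verdict, "no_substitution")
  expect_true(is.na(call$called_chromosome))
})

test_that("a published-style summary calls the substituted chromosome", {
  # substituted chromosome at 59.0% missing, every other chromosome at or
  # below 8.3%, with a uniformly depressed window track
  tab <- table1_fixture()
  summ <- missingness_summary(tab$chrom, tab$n_mapped, tab$miss_SubL1, "SubL1")
  tracks <- list("4B" = flat_track("4B", 0.41))
  call <- call_sample(summ, tracks, caller_params())
  expect_equal(call$verdict, "substitution")
  expect_equal(call$called_chromosome, "4B")
  expect_equal(call$missing_ratio, 1535 / 2601)
  expect_gt(call$fold, 5)
})

test_that("ties, rival candidates, and patchy coverage yield ambiguous", {
  summ2 <- missingness_summary(c("a", "b", "c", "d"),
                               rep(1000, 4), c(600, 600, 10, 12), "S")
  expect_equal(call_sample(summ2)$verdict, "ambiguous")
  expect_equal(call_sample(summ2)$reason, "tied_maximum")

  summ3 <- missingness_summary(c("a", "b", "c", "d"),
                               rep(1000, 4), c(600, 450, 10, 12), "S")
  expect_equal(call_sample(summ3)$reason, "multiple_candidates")

  # ratio gates pass but the depression is segmental, not whole-chromosome
  summ4 <- missingness_summary(c("a", "b", "c", "d"),
                               rep(1000, 4), c(600, 12, 10, 12), "S")
  patchy <- list(a = flat_track("a", c(rep(0.4, 20), rep(1, 30))))
  call <- call_sample(summ4, patchy)
  expect_equal(call$verdict, "ambiguous")
  expect_equal(call$reason, "low_whole_chromosome_coverage")

  expect_error(call_sample(missingness_summary(character(0), integer(0),
                                               integer(0), "S")),
               class = "chromsub_input_error")
})

test_that("raising the absolute ratio gate never creates a substitution call", {
  tab <- table1_fixture()
  summ <- missingness_summary(tab$chrom, tab$n_mapped, tab$miss_SubL2, "S")
  tracks <- list("4B" = flat_track("4B", 0.41))
  verdicts <- vapply(seq(0.1, 0.9, by = 0.1), function(th) {
    call_sample(summ, tracks, caller_params(min_missing_ratio = th))$verdict
  }, character(1))
  sub <- verdicts == "substitution"
  # once the gate passes the observed ratio, the verdict leaves and never
  # returns to "substitution"
  expect_true(all(diff(as.integer(sub)) <= 0))
})

test_that("cohort calls separate substitution lines from euploids", {
  lens <- stats::setNames(rep(5e7, 4), paste0("c", 1:4))
  samples <- data.frame(
    sample = c("Sub", "E1", "E2", "Donor"),
    role = c("substitution_line", "wheat_parent", "no_alien_derivative",
             "alien_donor"),
    substituted_chromosome = c("c3", NA, NA, NA),
    stringsAsFactors = FALSE)
  cfg <- simulation_config(chromosome_lengths = lens, n_markers = 4000,
                           samples = samples,
                           divergent_chromosomes = numeric(0), seed = 17)
  map <- simulate_marker_map(cfg)
  sim <- simulate_genotypes(map, cfg)
  calls <- call_cohort(sim$genotypes, map, c("Sub", "E1", "E2"),
                       chromosome_lengths = lens)
  df <- as.data.frame(calls)
  expect_equal(df$verdict, c("substitution", "no_substitution",
                             "no_substitution"))
  expect_equal(df$called_chromosome[1], "c3")
})

test_that("replicate substitution lines are called concordantly", {
  cfg <- cohort_config(markers_per_chrom = 300, seed = 23)
  map <- simulate_marker_map(cfg)
  sim <- simulate_genotypes(map, cfg)
  calls <- call_cohort(sim$genotypes, map, c("SubL1", "SubL2", "SubL3"),
                       chromosome_lengths = cfg$chromosome_lengths)
  df <- as.data.frame(calls)
  expect_equal(df$verdict, rep("substitution", 3))
  expect_equal(unique(df$called_chromosome), "4B")
})

test_that("the JSON report carries verdicts, evidence, and thresholds", {
  tab <- table1_fixture()
  summ <- missingness_summary(tab$chrom, tab$n_mapped, tab$miss_SubL3, "SubL3")
  calls <- structure(list(SubL3 = call_sample(summ,
                                              list("4B" = flat_track("4B", 0.4)))),
                     class = "substitution_cohort")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_calls_json(calls, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$calls$SubL3$verdict, "substitution")
  expect_equal(rep$calls$SubL3$called_chromosome, "4B")
  expect_equal(rep$calls$SubL3$params$min_missing_ratio, 0.4)
  expect_false(rep$any_ambiguous)
})
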