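#' Run the full homozygote-screening analysis
#'
#' Orchestrates the stages end to end: homozygote scan, optional
#' clinical-concordance QC with exclusion of clinically contradicted
#' calls, homozygote frequency table with Hardy-Weinberg expected
#' frequencies, per-haplotype MHC marker heterozygosity, and
#' population-coverage estimates (top-k and full cumulative curve).
#' Every stage exclusion is counted in the summary; nothing is filtered
#' silently.  Given identical inputs the run is deterministic.
#'
#' @param cohort An \linkS4class{HLACohort} or a path readable by
#'   [readCohort()].
#' @param reference Optional \linkS4class{HaplotypeFrequencySet} (or
#'   path) of registry haplotype frequencies; required for expected
#'   frequencies and coverage.
#' @param clinical Optional clinical typing table (or path) for
#'   concordance QC.
#' @param panel Locus panel to scan.
#' @param resolution Scan resolution.
#' @param ppThreshold Optional posterior-probability floor for the scan.
#' @param window Marker window for heterozygosity verification.
#' @param rankBy Coverage ranking key, as in [rankHaplotypes()].
#' @param topK Integer vector of prefix sizes to summarise coverage at.
#' @param outputDir Optional directory; when given, [renderReports()]
#'   writes the report files there.
#' @return List of class \code{hla_run}: \code{summary} (cohort size,
#'   homozygote count and percentage, exclusion log, coverage
#'   summaries), \code{calls}, \code{table}, \code{curve},
#'   \code{concordance}, \code{excluded}.
#' @examples
#' pool <- HaplotypeFrequencySet(c("A*01~B*08", "A*03~B*35"),
#'                               c(0.08, 0.10), resolution = "low")
#' sim <- simulateCohort(pool, 500, seed = 42)
#' res <- runPipeline(sim$cohort, reference = pool, panel = c("A", "B"),
#'                    resolution = "low")
#' res$summary$n_homozygotes
#' @export
runPipeline <- function(cohort, reference = NULL, clinical = NULL,
                        panel = c("A", "B", "C", "DRB1", "DQA1", "DQB1"),
                        resolution = c("high", "low"), ppThreshold = NULL,
                        window = "mhc_a_dqb1",
                        rankBy = "observed_n", topK = c(3L, 10L),
                        outputDir = NULL) {
  resolution <- match.arg(resolution)
  if (is.character(cohort)) cohort <- readCohort(cohort)
  if (is.character(reference)) {
    reference <- readHaplotypeFrequencies(reference,
                                          resolution = resolution)
  }
  if (is.character(clinical)) clinical <- readClinicalTypings(clinical)
  stopifnot(all(topK > 0))

  calls <- scanHomozygotes(cohort, panel, resolution,
                           ppThreshold = ppThreshold)
  size <- attr(calls, "cohort_size")
  nMissingLocus <- attr(calls, "n_missing_locus")
  nPPFiltered <- attr(calls, "n_pp_filtered")

  concordance <- NULL
  excluded <- calls[0, , drop = FALSE]
  nPreQC <- nrow(calls)
  if (!is.null(clinical)) {
    concordance <- compareTypings(cohort, clinical, resolution)
    split <- flagDiscordantHomozygotes(calls, clinical)
    excluded <- split$excluded
    calls <- structure(split$retained, panel = panel,
                       resolution = resolution, cohort_size = size)
  }

  tab <- homozygoteTable(calls, size, reference = reference)
  if (hasMarkers(cohort) && nrow(calls) > 0L) {
    het <- haplotypeMeanHet(calls, cohort, window)
    tab$mean_het_pct <- het$mean_het_pct[match(tab$haplotype,
                                               het$haplotype)]
  }

  curve <- NULL
  coverageSummary <- list()
  if (!is.null(reference) && nrow(tab) > 0L) {
    ranked <- rankHaplotypes(tab, by = rankBy)
    ref <- haploFrequencies(reference)
    p <- ref$frequency[match(ranked$haplotype, ref$haplotype)]
    known <- !is.na(p)
    curve <- cumulativeCoverage(p[known], ranked$haplotype[known])
    ks <- unique(c(topK[topK <= sum(known)], sum(known)))
    coverageSummary <- lapply(ks, function(k) {
      list(k = k,
           coverage_pct = roundHalfUp(
             100 * setCoverage(p[known][seq_len(k)])$coverage, 1))
    })
  }

  summary <- list(
    cohort_size = size,
    panel = panel,
    resolution = resolution,
    n_homozygotes = nrow(calls),
    n_haplotypes = nrow(tab),
    proportion_homozygous_pct = if (size > 0)
      roundHalfUp(100 * nrow(calls) / size, 1) else 0,
    exclusions = list(
      missing_locus = nMissingLocus,
      pp_filtered = nPPFiltered,
      clinically_discordant = nPreQC - nrow(calls)),
    coverage = coverageSummary)

  result <- structure(list(summary = summary, calls = calls, table = tab,
                           curve = curve, concordance = concordance,
                           excluded = excluded),
                      class = "hla_run")
  if (!is.null(outputDir)) renderReports(result, outputDir)
  result
}

#' @export
print.hla_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "HLA homozygote screen: %d of %d donors (%.1f%%) homozygous over %s (%s resolution)\n",
    s$n_homozygotes, s$cohort_size, s$proportion_homozygous_pct,
    paste(s$panel, collapse = "-"), s$resolution))
  cat("  distinct homozygous haplotypes:", s$n_haplotypes, "\n")
  for (cv in s$coverage) {
    cat(sprintf("  coverage, top %d: %.1f%%\n", cv$k, cv$coverage_pct))
  }
  invisible(x)
}

## fixed-precision decimal formatting for report files (round-half-even,
## as R's round); NA prints as empty
.fmt <- function(x, digits) {
  ifelse(is.na(x), "", formatC(round(x, digits), format = "f",
                               digits = digits))
}

#' Write pipeline reports to a directory
#'
#' Emits the stage outputs as plain-text reports with fixed column order
#' and rounding: the homozygote table (frequencies to 8 decimals at high
#' resolution, 6 at low; heterozygosity percentages to 2 decimals), the
#' cumulative coverage curve (percentages to 1 decimal), the per-locus
#' concordance table, and a JSON run summary.  Re-reading an emitted
#' table reproduces its values to the printed precision.
#'
#' @param result An \code{hla_run} from [runPipeline()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
renderReports <- function(result, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory ", dir)
  }
  paths <- character()
  freqDigits <- if (result$summary$resolution == "high") 8L else 6L

  tab <- result$table
  out <- data.frame(haplotype = tab$haplotype,
                    n_homozygotes = tab$n_homozygotes,
                    observed_frequency = .fmt(tab$observed_frequency,
                                              freqDigits),
                    expected_frequency = .fmt(tab$expected_frequency,
                                              freqDigits),
                    mean_het_pct = .fmt(tab$mean_het_pct, 2L),
                    stringsAsFactors = FALSE)
  p <- file.path(dir, "homozygote_table.tsv")
  write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  if (!is.null(result$curve)) {
    cu <- result$curve
    out <- data.frame(k = cu$k, haplotype = cu$haplotype,
                      frequency = .fmt(cu$frequency, freqDigits),
                      cumulative_coverage_pct =
                        .fmt(roundHalfUp(100 * cu$cumulative_coverage, 1),
                             1L),
                      stringsAsFactors = FALSE)
    p <- file.path(dir, "coverage_curve.tsv")
    write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }

  if (!is.null(result$concordance)) {
    pl <- result$concordance$per_locus
    pl$error_pct <- .fmt(pl$error_pct, 2L)
    p <- file.path(dir, "concordance.tsv")
    write.table(pl, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }

  p <- file.path(dir, "summary.json")
  jsonlite::write_json(result$summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
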