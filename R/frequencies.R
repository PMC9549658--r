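#' Homozygote frequency arithmetic
#'
#' Small, exact helpers behind the frequency tables: the observed
#' homozygote frequency is the homozygote count over the cohort size; the
#' Hardy-Weinberg expected homozygote frequency of a haplotype with
#' population frequency \eqn{p} is \eqn{p^2}; and the inverse
#' \eqn{\sqrt{e}} recovers a haplotype frequency from a published
#' expected homozygote frequency (the only route when the registry
#' frequencies themselves are unpublished).
#'
#' @param n Homozygote count(s).
#' @param cohortSize Number of donors screened (> 0).
#' @return \code{observedFrequency}: \code{n / cohortSize} at full
#'   precision.
#' @examples
#' observedFrequency(149, 20737)           # 0.00718522...
#' expectedHomozygoteFrequency(0.0831153)  # ~0.00690815
#' frequencyFromExpected(0.00690815)       # ~0.0831153
#' @export
observedFrequency <- function(n, cohortSize) {
  if (any(cohortSize <= 0)) stop("cohortSize must be positive")
  if (any(n < 0 | n > cohortSize)) stop("n must lie in [0, cohortSize]")
  n / cohortSize
}

#' @rdname observedFrequency
#' @param p Haplotype frequency in [0, 1].
#' @return \code{expectedHomozygoteFrequency}: \eqn{p^2}.
#' @export
expectedHomozygoteFrequency <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("haplotype frequency must lie in [0, 1]")
  }
  p^2
}

#' @rdname observedFrequency
#' @param e Expected homozygote frequency in [0, 1].
#' @return \code{frequencyFromExpected}: \eqn{\sqrt{e}}.
#' @export
frequencyFromExpected <- function(e) {
  if (any(is.na(e)) || any(e < 0 | e > 1)) {
    stop("expected homozygote frequency must lie in [0, 1]")
  }
  sqrt(e)
}

#' Build a homozygote frequency table
#'
#' Aggregates homozygote calls into the report-style table: one row per
#' homozygous haplotype with the donor count, the observed homozygote
#' frequency n / cohort size, and -- when a reference
#' \linkS4class{HaplotypeFrequencySet} is given -- the Hardy-Weinberg
#' expected frequency \eqn{p^2} from the reference (registry) frequency,
#' never from in-cohort estimates.  Haplotypes absent from the reference
#' get \code{NA}, not zero.
#'
#' Rows are ordered by descending homozygote count, ties by descending
#' expected frequency, then by haplotype string.
#'
#' @param calls Call table from [scanHomozygotes()].
#' @param cohortSize Number of donors screened; defaults to the scan's
#'   \code{cohort_size} attribute.
#' @param reference Optional \linkS4class{HaplotypeFrequencySet} of
#'   registry haplotype frequencies.
#' @return data.frame with columns \code{haplotype},
#'   \code{n_homozygotes}, \code{observed_frequency},
#'   \code{expected_frequency}, \code{mean_het_pct} (NA until filled by
#'   [haplotypeMeanHet()]).
#' @export
homozygoteTable <- function(calls, cohortSize = attr(calls, "cohort_size"),
                            reference = NULL) {
  if (is.null(cohortSize)) stop("cohortSize is required")
  if (nrow(calls) == 0L) {
    tab <- data.frame(haplotype = character(),
                      n_homozygotes = integer(),
                      observed_frequency = numeric(),
                      expected_frequency = numeric(),
                      mean_het_pct = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(tab, cohort_size = cohortSize))
  }
  counts <- table(calls$haplotype)
  tab <- data.frame(haplotype = names(counts),
                    n_homozygotes = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab$observed_frequency <- if (nrow(tab) > 0L)
    observedFrequency(tab$n_homozygotes, cohortSize) else numeric()
  tab$expected_frequency <- rep(NA_real_, nrow(tab))
  if (!is.null(reference) && nrow(tab) > 0L) {
    ref <- haploFrequencies(reference)
    p <- ref$frequency[match(tab$haplotype, ref$haplotype)]
    tab$expected_frequency <- ifelse(is.na(p), NA_real_, p^2)
  }
  tab$mean_het_pct <- rep(NA_real_, nrow(tab))
  o <- order(-tab$n_homozygotes,
             -ifelse(is.na(tab$expected_frequency), -Inf,
                     tab$expected_frequency),
             tab$haplotype)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, cohort_size = cohortSize)
}

#' Per-locus allele counts and frequencies
#'
#' Counts every allele occurrence at one locus (two per donor, so a
#' homozygote contributes two); frequencies are counts over 2 x the
#' number of donors typed at the locus and sum to one.  Donors missing
#' the locus are skipped and counted in the \code{n_skipped} attribute.
#'
#' @param cohort An \linkS4class{HLACohort}.
#' @param gene A single gene symbol.
#' @return data.frame with columns \code{gene}, \code{allele},
#'   \code{count}, \code{frequency}, ordered by descending count then
#'   allele.
#' @export
alleleFrequencies <- function(cohort, gene) {
  stopifnot(length(gene) == 1L)
  if (!gene %in% HLA_GENES) stop("unknown gene: ", gene)
  g <- hlaGenotypes(cohort)
  size <- length(unique(g$donor_id))
  g <- g[g$gene == gene, , drop = FALSE]
  if (nrow(g) == 0L) stop("no donors typed at locus ", gene)
  counts <- table(c(g$allele_1, g$allele_2))
  out <- data.frame(gene = gene, allele = names(counts),
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$frequency <- out$count / (2 * nrow(g))
  out <- out[order(-out$count, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_skipped = size - nrow(g))
}

#' Pearson correlation of observed vs reference allele frequencies
#'
#' Imputation QC: correlates in-cohort imputed allele frequencies with
#' an external reference set using Pearson's product-moment correlation.
#' Alleles on the exclusion list or lacking a reference value are removed
#' and reported, mirroring the standard practice of excluding alleles
#' with no reference frequency or unresolved low-resolution calls.
#'
#' @param observed data.frame with columns \code{allele},
#'   \code{frequency} (e.g. from [alleleFrequencies()]).
#' @param reference data.frame with columns \code{allele},
#'   \code{frequency}.
#' @param exclude Character vector of allele names to drop before
#'   correlating.
#' @return List with \code{r}, \code{n_pairs} and \code{excluded} (the
#'   alleles dropped, with the reason).
#' @export
correlateWithReference <- function(observed, reference,
                                   exclude = character()) {
  stopifnot(all(c("allele", "frequency") %in% names(observed)),
            all(c("allele", "frequency") %in% names(reference)))
  excluded <- data.frame(allele = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (length(exclude)) {
    excluded <- rbind(excluded,
                      data.frame(allele = intersect(observed$allele, exclude),
                                 reason = "excluded by request",
                                 stringsAsFactors = FALSE))
    observed <- observed[!observed$allele %in% exclude, , drop = FALSE]
  }
  m <- match(observed$allele, reference$allele)
  noRef <- observed$allele[is.na(m)]
  if (length(noRef)) {
    excluded <- rbind(excluded,
                      data.frame(allele = noRef,
                                 reason = "no reference frequency",
                                 stringsAsFactors = FALSE))
  }
  x <- observed$frequency[!is.na(m)]
  y <- reference$frequency[m[!is.na(m)]]
  if (length(x) < 3L) {
    stop("fewer than 3 shared alleles after exclusions")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a frequency vector; correlation undefined")
  }
  list(r = stats::cor(x, y, method = "pearson"), n_pairs = length(x),
       excluded = excluded)
}
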