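#' Is a locus genotype homozygous at a given resolution?
#'
#' A genotype is homozygous at a resolution when both alleles are equal
#' after truncation to that resolution, so e.g. B*15:01/B*15:02 is
#' homozygous at low but not at high resolution.
#'
#' @param allele1,allele2 Character vectors of allele strings (recycled
#'   pairwise).
#' @param level Resolution, \code{"high"} or \code{"low"}.
#' @return Logical vector.
#' @examples
#' isLocusHomozygous("B*15:01", "B*15:02", "low")   # TRUE
#' isLocusHomozygous("B*15:01", "B*15:02", "high")  # FALSE
#' @export
isLocusHomozygous <- function(allele1, allele2, level = c("high", "low")) {
  level <- match.arg(level)
  truncateAllele(allele1, level) == truncateAllele(allele2, level)
}

#' Scan a cohort for panel-wide HLA homozygotes
#'
#' The core screening step: finds every donor homozygous, at the
#' requested resolution, at every locus of the panel, and assembles the
#' (trivially phased) homozygous haplotype from the shared alleles.
#'
#' PP filtering is opt-in: by default the smallest per-panel posterior
#' probability is reported per call (\code{min_pp}) but no donor is
#' dropped, since the nominal 0.5 cutoff is descriptive rather than an
#' exclusion gate.  With \code{ppThreshold} set, donors with any panel
#' posterior probability below it are dropped before the scan and
#' counted.
#'
#' @param cohort An \linkS4class{HLACohort}.
#' @param panel Character vector of genes (subset of [HLA_GENES]),
#'   in serialisation order.
#' @param resolution \code{"high"} or \code{"low"}.
#' @param ppThreshold Optional posterior-probability floor.
#' @param missingLocusPolicy How to treat donors lacking a panel locus:
#'   \code{"exclude_donor"} drops them (counted in the
#'   \code{n_missing_locus} attribute); \code{"treat_as_heterozygous"}
#'   keeps them but they can never be called homozygous.  Either way no
#'   call is emitted for such donors.
#' @return data.frame of calls ordered by \code{donor_id}, with columns
#'   \code{donor_id}, \code{haplotype} (truncated to \code{resolution})
#'   and \code{min_pp} (NA when any panel PP is missing).  Attributes:
#'   \code{panel}, \code{resolution}, \code{cohort_size},
#'   \code{n_missing_locus}, \code{n_pp_filtered}.
#' @export
scanHomozygotes <- function(cohort, panel,
                            resolution = c("high", "low"),
                            ppThreshold = NULL,
                            missingLocusPolicy = c("exclude_donor",
                                                   "treat_as_heterozygous")) {
  resolution <- match.arg(resolution)
  missingLocusPolicy <- match.arg(missingLocusPolicy)
  if (length(panel) == 0L) stop("empty locus panel")
  if (anyDuplicated(panel)) stop("panel genes must be unique")
  if (!all(panel %in% HLA_GENES)) {
    stop("unknown gene in panel: ",
         paste(setdiff(panel, HLA_GENES), collapse = ", "))
  }
  g <- hlaGenotypes(cohort)
  size <- length(unique(g$donor_id))
  g <- g[g$gene %in% panel, , drop = FALSE]

  nLoci <- table(g$donor_id)
  complete <- names(nLoci)[nLoci == length(panel)]
  nMissing <- length(unique(hlaGenotypes(cohort)$donor_id)) -
    length(complete)
  g <- g[g$donor_id %in% complete, , drop = FALSE]

  nPPFiltered <- 0L
  if (!is.null(ppThreshold) && nrow(g) > 0L) {
    low <- !is.na(g$posterior_probability) &
      g$posterior_probability < ppThreshold
    dropIds <- unique(g$donor_id[low])
    nPPFiltered <- length(dropIds)
    g <- g[!g$donor_id %in% dropIds, , drop = FALSE]
  }

  empty <- data.frame(donor_id = character(), haplotype = character(),
                      min_pp = numeric(), stringsAsFactors = FALSE)
  calls <- empty
  if (nrow(g) > 0L) {
    hom <- isLocusHomozygous(g$allele_1, g$allele_2, resolution)
    homIds <- names(which(tapply(hom, g$donor_id, all)))
    if (length(homIds) > 0L) {
      h <- g[g$donor_id %in% homIds, , drop = FALSE]
      h$allele <- truncateAllele(h$allele_1, resolution)
      h <- h[order(h$donor_id, match(h$gene, panel)), , drop = FALSE]
      byDonor <- split(h, h$donor_id)
      calls <- data.frame(
        donor_id = names(byDonor),
        haplotype = vapply(byDonor, function(x)
          formatHaplotype(x$allele), character(1)),
        min_pp = vapply(byDonor, function(x) {
          pp <- x$posterior_probability
          if (anyNA(pp)) NA_real_ else min(pp)
        }, numeric(1)),
        stringsAsFactors = FALSE)
      calls <- calls[order(calls$donor_id), , drop = FALSE]
      rownames(calls) <- NULL
    }
  }
  structure(calls, panel = panel, resolution = resolution,
            cohort_size = size, n_missing_locus = nMissing,
            n_pp_filtered = nPPFiltered)
}

#' Count donors homozygous at a single locus
#'
#' Consistent with [scanHomozygotes()] over a one-gene panel.
#'
#' @inheritParams scanHomozygotes
#' @param gene A single gene symbol.
#' @return Integer count.
#' @export
countSingleLocusHomozygotes <- function(cohort, gene,
                                        resolution = c("high", "low")) {
  stopifnot(length(gene) == 1L)
  nrow(scanHomozygotes(cohort, gene, resolution))
}
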