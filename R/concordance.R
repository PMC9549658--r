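#' Concordance of imputed vs clinical-grade HLA typing
#'
#' Per-locus comparison of imputed genotypes against clinical typing
#' results for the donors present in both sources.  A comparison is one
#' (donor, locus) typing; by default an error is any genotype-level
#' mismatch -- the unordered allele pairs, truncated to the comparison
#' resolution, differ.  With \code{alleleLevel = TRUE} mismatched alleles
#' are counted individually (multiset difference, 0/1/2 per typing) and
#' rates are per allele call.
#'
#' @param cohort An \linkS4class{HLACohort} of imputed genotypes.
#' @param clinical Clinical typing data.frame (\code{donor_id},
#'   \code{gene}, \code{allele_1}, \code{allele_2}), e.g. from
#'   [readClinicalTypings()].
#' @param resolution Comparison resolution; clinical-grade typing is
#'   high-resolution, so \code{"high"} is the default.
#' @param alleleLevel Count allele-level rather than genotype-level
#'   errors.
#' @return List of class \code{concordance_report}: \code{per_locus}
#'   data.frame (\code{gene}, \code{n_typings}, \code{n_errors},
#'   \code{error_pct}), \code{overall_n} comparisons,
#'   \code{n_imputed_only} and \code{n_clinical_only} skipped (donor,
#'   locus) pairs, \code{resolution}, \code{allele_level}.
#' @export
compareTypings <- function(cohort, clinical,
                           resolution = c("high", "low"),
                           alleleLevel = FALSE) {
  resolution <- match.arg(resolution)
  if (anyDuplicated(clinical[c("donor_id", "gene")])) {
    stop("duplicate clinical rows for one (donor, gene)")
  }
  g <- hlaGenotypes(cohort)
  key <- function(d) paste(d$donor_id, d$gene, sep = "\r")
  shared <- intersect(key(g), key(clinical))
  imp <- g[key(g) %in% shared, , drop = FALSE]
  cli <- clinical[match(key(imp), key(clinical)), , drop = FALSE]

  mismatches <- integer(0)
  if (nrow(imp) > 0L) {
    ia1 <- truncateAllele(imp$allele_1, resolution)
    ia2 <- truncateAllele(imp$allele_2, resolution)
    ca1 <- truncateAllele(cli$allele_1, resolution)
    ca2 <- truncateAllele(cli$allele_2, resolution)
    ip <- orderAllelePair(ia1, ia2)
    cp <- orderAllelePair(ca1, ca2)
    mismatches <- .pairMismatch(ip$allele_1, ip$allele_2,
                                cp$allele_1, cp$allele_2)
  }
  geneLevels <- intersect(HLA_GENES, unique(imp$gene))
  geneF <- factor(imp$gene, levels = geneLevels)
  if (alleleLevel) {
    nTyp <- 2L * as.integer(table(geneF))
    nErr <- as.integer(tapply(mismatches, geneF, sum, default = 0L))
  } else {
    nTyp <- as.integer(table(geneF))
    nErr <- as.integer(tapply(mismatches > 0L, geneF, sum, default = 0L))
  }
  perLocus <- data.frame(gene = geneLevels, n_typings = nTyp,
                         n_errors = nErr,
                         error_pct = ifelse(nTyp > 0, 100 * nErr / nTyp,
                                            NA_real_),
                         stringsAsFactors = FALSE)
  structure(list(per_locus = perLocus,
                 overall_n = nrow(imp),
                 n_imputed_only = nrow(g) - nrow(imp),
                 n_clinical_only = nrow(clinical) - nrow(imp),
                 resolution = resolution,
                 allele_level = alleleLevel),
            class = "concordance_report")
}

## number of allele mismatches between two unordered, canonically
## ordered pairs: 0 (identical), 1 (one shared allele) or 2 (disjoint)
.pairMismatch <- function(x1, x2, y1, y2) {
  same <- x1 == y1 & x2 == y2
  oneShared <- !same & (x1 == y1 | x1 == y2 | x2 == y1 | x2 == y2)
  ifelse(same, 0L, ifelse(oneShared, 1L, 2L))
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Imputation concordance over", x$overall_n, "typings at",
      x$resolution, "resolution",
      if (x$allele_level) "(allele-level errors)" else
        "(genotype-level errors)", "\n")
  print(x$per_locus, row.names = FALSE)
  invisible(x)
}

#' Exclude homozygote calls contradicted by clinical typing
#'
#' A homozygote call whose donor is clinically heterozygous, at the
#' comparison resolution, at any locus of the scanned panel is excluded
#' (with the discordant locus recorded): the clinical result overrides
#' the imputed homozygosity.  Calls with no clinical data at any panel
#' locus are retained but flagged unverified.  Retained and excluded
#' always partition the input.
#'
#' @param calls Call table from [scanHomozygotes()].
#' @param clinical Clinical typing data.frame as in [compareTypings()].
#' @param panel Panel genes of the scan; defaults to the calls'
#'   \code{panel} attribute.
#' @param resolution Comparison resolution; defaults to the calls'
#'   \code{resolution} attribute.
#' @return List with \code{retained} (the calls plus a
#'   \code{verification} column: \code{"concordant"} or
#'   \code{"unverified"}) and \code{excluded} (the calls plus
#'   \code{discordant_locus}).
#' @export
flagDiscordantHomozygotes <- function(calls, clinical,
                                      panel = attr(calls, "panel"),
                                      resolution = attr(calls,
                                                        "resolution")) {
  if (is.null(panel) || is.null(resolution)) {
    stop("panel and resolution are required (or scan attributes missing)")
  }
  cli <- clinical[clinical$gene %in% panel &
                    clinical$donor_id %in% calls$donor_id, , drop = FALSE]
  discordantLocus <- rep(NA_character_, nrow(calls))
  verified <- logical(nrow(calls))
  if (nrow(cli) > 0L) {
    het <- !isLocusHomozygous(cli$allele_1, cli$allele_2, resolution)
    verified <- calls$donor_id %in% cli$donor_id
    hetByDonor <- split(cli$gene[het], cli$donor_id[het])
    loci <- hetByDonor[calls$donor_id]
    has <- !vapply(loci, is.null, logical(1))
    discordantLocus[has] <- vapply(loci[has], paste, character(1),
                                   collapse = ",")
  }
  drop <- !is.na(discordantLocus)
  retained <- calls[!drop, , drop = FALSE]
  retained$verification <- ifelse(verified[!drop], "concordant",
                                  "unverified")
  excluded <- calls[drop, , drop = FALSE]
  excluded$discordant_locus <- discordantLocus[drop]
  rownames(retained) <- rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded)
}
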