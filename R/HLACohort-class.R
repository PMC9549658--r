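#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges start end seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
NULL

#' Cohort of imputed HLA genotypes
#'
#' Central container for a donor cohort: a long-format genotype table (one
#' row per donor per locus, unordered allele pair plus the imputation
#' posterior probability) and, optionally, an MHC DNA-marker genotype
#' matrix with hg38 positions held as a \linkS4class{GRanges}.
#'
#' Imputation produces unphased per-locus genotypes, so the class never
#' stores phased haplotypes; haplotypes are only asserted downstream for
#' fully homozygous donors, where phase is trivial.
#'
#' @slot genotypes data.frame with columns \code{donor_id}, \code{gene},
#'   \code{allele_1}, \code{allele_2} (canonical strings, pair in
#'   canonical lexicographic order) and \code{posterior_probability}
#'   (numeric in [0,1], NA allowed).
#' @slot markers integer matrix, donors x markers, coded 0 = homozygous
#'   reference, 1 = heterozygous, 2 = homozygous alternate, NA = missing.
#' @slot markerRanges \linkS4class{GRanges} of marker positions (hg38,
#'   1-based), parallel to the marker matrix columns.
#'
#' @seealso [readCohort()], [simulateCohort()], [scanHomozygotes()]
#' @export
setClass("HLACohort",
  representation(genotypes = "data.frame",
                 markers = "matrix",
                 markerRanges = "GRanges"),
  prototype(genotypes = data.frame(donor_id = character(),
                                   gene = character(),
                                   allele_1 = character(),
                                   allele_2 = character(),
                                   posterior_probability = numeric(),
                                   stringsAsFactors = FALSE),
            markers = matrix(integer(), 0L, 0L),
            markerRanges = GenomicRanges::GRanges()))

setValidity("HLACohort", function(object) {
  g <- object@genotypes
  need <- c("donor_id", "gene", "allele_1", "allele_2",
            "posterior_probability")
  if (!all(need %in% names(g))) {
    return(paste("genotypes must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(g) > 0L) {
    if (!all(g$gene %in% HLA_GENES)) {
      return("genotypes contain an unknown HLA gene")
    }
    if (anyDuplicated(g[c("donor_id", "gene")])) {
      return("duplicate (donor_id, gene) rows in genotypes")
    }
    pp <- g$posterior_probability
    if (any(!is.na(pp) & (pp < 0 | pp > 1))) {
      return("posterior_probability outside [0, 1]")
    }
    if (any(g$allele_2 < g$allele_1)) {
      return("allele pairs not in canonical order")
    }
  }
  m <- object@markers
  if (ncol(m) != length(object@markerRanges)) {
    return("markerRanges length must equal the number of marker columns")
  }
  if (nrow(m) > 0L) {
    if (is.null(rownames(m))) return("marker matrix needs donor rownames")
    if (!all(rownames(m) %in% g$donor_id)) {
      return("marker matrix rows include unknown donors")
    }
    vals <- m[!is.na(m)]
    if (length(vals) && !all(vals %in% 0:2)) {
      return("marker genotypes must be coded 0/1/2/NA")
    }
  }
  TRUE
})

#' Construct an HLACohort
#'
#' Allele strings are canonicalised through the nomenclature parser and
#' each pair is put into canonical (lexicographic) order, so genotype
#' equality is order-insensitive.
#'
#' @param genotypes data.frame with columns \code{donor_id}, \code{gene},
#'   \code{allele_1}, \code{allele_2} and (optionally)
#'   \code{posterior_probability}.
#' @param markers Optional donor x position marker matrix coded 0/1/2/NA;
#'   column names give 1-based hg38 positions unless \code{markerRanges}
#'   is supplied.
#' @param markerRanges Optional \linkS4class{GRanges} for the marker
#'   columns.
#' @return An \linkS4class{HLACohort}.
#' @export
HLACohort <- function(genotypes, markers = NULL, markerRanges = NULL) {
  if (is.null(genotypes$posterior_probability)) {
    genotypes$posterior_probability <- rep(NA_real_, nrow(genotypes))
  }
  genotypes$donor_id <- as.character(genotypes$donor_id)
  genotypes$gene <- as.character(genotypes$gene)
  if (nrow(genotypes) > 0L) {
    a1 <- canonicalAllele(as.character(genotypes$allele_1), genotypes$gene)
    a2 <- canonicalAllele(as.character(genotypes$allele_2), genotypes$gene)
    p1 <- parseAllele(a1)
    p2 <- parseAllele(a2)
    if (!all(p1$gene == genotypes$gene) || !all(p2$gene == genotypes$gene)) {
      i <- which(p1$gene != genotypes$gene | p2$gene != genotypes$gene)[1L]
      stop("allele gene disagrees with the gene column in row ", i)
    }
    pair <- orderAllelePair(a1, a2)
    genotypes$allele_1 <- pair$allele_1
    genotypes$allele_2 <- pair$allele_2
  } else {
    genotypes$allele_1 <- as.character(genotypes$allele_1)
    genotypes$allele_2 <- as.character(genotypes$allele_2)
  }
  genotypes$posterior_probability <-
    as.numeric(genotypes$posterior_probability)
  rownames(genotypes) <- NULL
  genotypes <- genotypes[c("donor_id", "gene", "allele_1", "allele_2",
                           "posterior_probability")]

  if (is.null(markers)) {
    markers <- matrix(integer(), 0L, 0L)
    ranges <- GenomicRanges::GRanges()
  } else {
    storage.mode(markers) <- "integer"
    if (is.null(markerRanges)) {
      pos <- suppressWarnings(as.integer(colnames(markers)))
      if (anyNA(pos)) {
        stop("marker matrix column names must be integer positions ",
             "when markerRanges is not given")
      }
      ranges <- GenomicRanges::GRanges("chr6", IRanges::IRanges(pos, pos))
    } else {
      ranges <- markerRanges
    }
  }
  new("HLACohort", genotypes = genotypes, markers = markers,
      markerRanges = ranges)
}

#' @rdname HLACohort-accessors
#' @export
setGeneric("donorIds", function(x) standardGeneric("donorIds"))

#' @rdname HLACohort-accessors
#' @export
setGeneric("cohortSize", function(x) standardGeneric("cohortSize"))

#' @rdname HLACohort-accessors
#' @export
setGeneric("hlaGenotypes", function(x) standardGeneric("hlaGenotypes"))

#' @rdname HLACohort-accessors
#' @export
setGeneric("markerMatrix", function(x) standardGeneric("markerMatrix"))

#' @rdname HLACohort-accessors
#' @export
setGeneric("markerRanges", function(x) standardGeneric("markerRanges"))

#' @rdname HLACohort-accessors
#' @export
setGeneric("hasMarkers", function(x) standardGeneric("hasMarkers"))

#' Accessors for HLACohort objects
#'
#' @param x An \linkS4class{HLACohort}.
#' @name HLACohort-accessors
NULL

#' @rdname HLACohort-accessors
#' @export
setMethod("donorIds", "HLACohort", function(x) {
  sort(unique(x@genotypes$donor_id))
})

#' @rdname HLACohort-accessors
#' @export
setMethod("cohortSize", "HLACohort", function(x) {
  length(unique(x@genotypes$donor_id))
})

#' @rdname HLACohort-accessors
#' @export
setMethod("hlaGenotypes", "HLACohort", function(x) x@genotypes)

#' @rdname HLACohort-accessors
#' @export
setMethod("markerMatrix", "HLACohort", function(x) x@markers)

#' @rdname HLACohort-accessors
#' @export
setMethod("markerRanges", "HLACohort", function(x) x@markerRanges)

#' @rdname HLACohort-accessors
#' @export
setMethod("hasMarkers", "HLACohort", function(x) ncol(x@markers) > 0L)

setMethod("show", "HLACohort", function(object) {
  g <- object@genotypes
  cat("HLACohort with", length(unique(g$donor_id)), "donors,",
      length(unique(g$gene)), "HLA loci")
  if (ncol(object@markers) > 0L) {
    cat(",", ncol(object@markers), "MHC markers")
  }
  cat("\n")
  if (nrow(g) > 0L) {
    cat("  loci:", paste(intersect(HLA_GENES, unique(g$gene)),
                         collapse = ", "), "\n")
    pp <- g$posterior_probability
    if (any(!is.na(pp))) {
      cat(sprintf("  posterior probability: median %.3f, min %.3f\n",
                  stats::median(pp, na.rm = TRUE), min(pp, na.rm = TRUE)))
    }
  }
  invisible(NULL)
})

.readTable <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, stringsAsFactors = FALSE,
             colClasses = "character", check.names = FALSE)
}

#' Read an imputed-genotype cohort table
#'
#' Reads the tabular interchange format emitted by HLA imputation
#' post-processing (HIBAG-style): one row per donor per locus with columns
#' \code{donor_id}, \code{gene}, \code{allele_1}, \code{allele_2},
#' \code{posterior_probability}.  TSV by default; files ending in
#' \code{.csv} are read comma-separated.
#'
#' @param path Path to the table.
#' @return An \linkS4class{HLACohort}.
#' @export
readCohort <- function(path) {
  tab <- .readTable(path)
  need <- c("donor_id", "gene", "allele_1", "allele_2",
            "posterior_probability")
  if (!all(need %in% names(tab))) {
    stop("cohort file must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(tab) > 0L && anyDuplicated(tab[c("donor_id", "gene")])) {
    d <- tab[duplicated(tab[c("donor_id", "gene")]), , drop = FALSE]
    stop("duplicate rows for donor '", d$donor_id[1L], "', locus '",
         d$gene[1L], "'")
  }
  pp <- suppressWarnings(as.numeric(tab$posterior_probability))
  bad <- !is.na(tab$posterior_probability) &
    nzchar(tab$posterior_probability) & is.na(pp)
  if (any(bad)) {
    stop("non-numeric posterior probability '",
         tab$posterior_probability[which(bad)[1L]], "'")
  }
  if (any(!is.na(pp) & (pp < 0 | pp > 1))) {
    stop("posterior probability outside [0, 1]")
  }
  tab$posterior_probability <- pp
  HLACohort(tab)
}

#' Write a cohort genotype table
#'
#' Inverse of [readCohort()]; writing then re-reading a canonical cohort
#' reproduces it exactly.
#'
#' @param cohort An \linkS4class{HLACohort}.
#' @param path Output path (TSV).
#' @export
writeCohort <- function(cohort, path) {
  write.table(hlaGenotypes(cohort), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a donor-by-position marker genotype matrix
#'
#' First column \code{donor_id}; remaining column names are 1-based hg38
#' positions; cells coded \code{0} (hom ref), \code{1} (het), \code{2}
#' (hom alt) or \code{.} (missing).
#'
#' @param path Path to the TSV/CSV matrix.
#' @return Integer matrix with donor rownames and position colnames.
#' @export
readMarkerMatrix <- function(path) {
  tab <- .readTable(path)
  if (names(tab)[1L] != "donor_id") {
    stop("marker matrix must start with a donor_id column")
  }
  m <- as.matrix(tab[-1L])
  m[m == "."] <- NA
  storage.mode(m) <- "integer"
  rownames(m) <- tab$donor_id
  m
}

#' Read marker genotypes from a VCF
#'
#' Maps diploid GT fields to the 0/1/2 marker coding (0|0 -> 0, phased or
#' unphased het -> 1, 1|1 -> 2, missing -> NA).  Positions are taken from
#' the VCF POS column (1-based).  Requires the \pkg{vcfR} package.
#'
#' @param path Path to an (uncompressed or gzipped) VCF with sample
#'   columns named by donor.
#' @return Integer matrix, donors x positions, as [readMarkerMatrix()].
#' @export
readMarkerVCF <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("readMarkerVCF needs the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  pos <- as.integer(vcfR::getPOS(v))
  code <- function(x) {
    a <- strsplit(gsub("|", "/", x, fixed = TRUE), "/", fixed = TRUE)
    vapply(a, function(al) {
      if (length(al) != 2L || any(al == ".")) return(NA_integer_)
      sum(as.integer(al != "0"))
    }, integer(1))
  }
  m <- apply(gt, 2L, code)
  m <- t(matrix(m, nrow = nrow(gt), dimnames = list(NULL, colnames(gt))))
  colnames(m) <- pos
  m
}

#' Read a clinical-grade HLA typing table
#'
#' Columns \code{donor_id}, \code{gene}, \code{allele_1}, \code{allele_2};
#' used as the comparison arm for imputation concordance QC.
#'
#' @param path Path to the TSV/CSV table.
#' @return data.frame with canonicalised, pair-ordered allele columns.
#' @export
readClinicalTypings <- function(path) {
  tab <- .readTable(path)
  need <- c("donor_id", "gene", "allele_1", "allele_2")
  if (!all(need %in% names(tab))) {
    stop("clinical typing file must have columns: ",
         paste(need, collapse = ", "))
  }
  if (nrow(tab) > 0L && anyDuplicated(tab[c("donor_id", "gene")])) {
    stop("duplicate clinical typing rows for one (donor, locus)")
  }
  if (nrow(tab) > 0L) {
    a1 <- canonicalAllele(tab$allele_1, tab$gene)
    a2 <- canonicalAllele(tab$allele_2, tab$gene)
    pair <- orderAllelePair(a1, a2)
    tab$allele_1 <- pair$allele_1
    tab$allele_2 <- pair$allele_2
  }
  tab[need]
}
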