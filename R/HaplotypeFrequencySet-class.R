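#' Reference haplotype frequency table
#'
#' Registry-style table of multi-locus HLA haplotype frequencies for one
#' population.  These frequencies (the Hardy-Weinberg \eqn{p}) drive the
#' expected homozygote frequency \eqn{p^2} and the carrier/coverage
#' calculations.
#'
#' @slot panel Character vector of genes, in serialisation order.
#' @slot resolution \code{"high"} (two-field) or \code{"low"}
#'   (first-field) allele resolution of the table.
#' @slot data data.frame with columns \code{haplotype} (serialised as in
#'   [formatHaplotype()]) and \code{frequency}.
#' @slot population Free-text population label.
#' @export
setClass("HaplotypeFrequencySet",
  representation(panel = "character", resolution = "character",
                 data = "data.frame", population = "character"),
  prototype(panel = character(), resolution = "high",
            data = data.frame(haplotype = character(),
                              frequency = numeric(),
                              stringsAsFactors = FALSE),
            population = ""))

setValidity("HaplotypeFrequencySet", function(object) {
  d <- object@data
  if (!all(c("haplotype", "frequency") %in% names(d))) {
    return("data needs 'haplotype' and 'frequency' columns")
  }
  if (!object@resolution %in% c("high", "low")) {
    return("resolution must be 'high' or 'low'")
  }
  if (anyDuplicated(d$haplotype)) return("duplicate haplotypes")
  if (nrow(d) > 0L) {
    f <- d$frequency
    if (any(is.na(f)) || any(f < 0 | f > 1)) {
      return("frequencies must lie in [0, 1]")
    }
    if (sum(f) > 1 + 1e-9) return("frequencies sum to more than 1")
    parsed <- parseHaplotype(d$haplotype)
    if (!identical(parsed$panel, object@panel)) {
      return("haplotype loci do not match the panel")
    }
    nf <- vapply(strsplit(unlist(strsplit(d$haplotype, "~", fixed = TRUE)),
                          "\\*"),
                 function(x) length(strsplit(x[2L], ":", fixed = TRUE)[[1L]]),
                 integer(1))
    if (object@resolution == "low" && any(nf != 1L)) {
      return("low-resolution haplotypes must have single-field alleles")
    }
    if (object@resolution == "high" && any(nf > 2L)) {
      return("high-resolution haplotypes must have at most two fields")
    }
  }
  TRUE
})

#' Construct a HaplotypeFrequencySet
#'
#' @param haplotype Character vector of serialised haplotypes
#'   (\code{"A*03:01~B*35:01~..."}).
#' @param frequency Numeric vector of haplotype frequencies in [0, 1];
#'   the sum may be below 1 (the residual is the unmodelled remainder of
#'   the population's haplotype pool).
#' @param resolution Allele resolution of the table.
#' @param population Optional population label.
#' @return A \linkS4class{HaplotypeFrequencySet}.
#' @examples
#' HaplotypeFrequencySet(c("A*01~B*08", "A*03~B*35"), c(0.08, 0.095),
#'                       resolution = "low", population = "toy")
#' @export
HaplotypeFrequencySet <- function(haplotype, frequency,
                                  resolution = c("high", "low"),
                                  population = "") {
  resolution <- match.arg(resolution)
  haplotype <- as.character(haplotype)
  panel <- if (length(haplotype)) parseHaplotype(haplotype)$panel
           else character()
  d <- data.frame(haplotype = haplotype, frequency = as.numeric(frequency),
                  stringsAsFactors = FALSE)
  new("HaplotypeFrequencySet", panel = panel, resolution = resolution,
      data = d, population = population)
}

#' @rdname HaplotypeFrequencySet-accessors
#' @export
setGeneric("haploFrequencies", function(x) standardGeneric("haploFrequencies"))

#' @rdname HaplotypeFrequencySet-accessors
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @rdname HaplotypeFrequencySet-accessors
#' @export
setGeneric("hlaResolution", function(x) standardGeneric("hlaResolution"))

#' @rdname HaplotypeFrequencySet-accessors
#' @export
setGeneric("populationLabel", function(x) standardGeneric("populationLabel"))

#' Accessors for HaplotypeFrequencySet objects
#'
#' @param x A \linkS4class{HaplotypeFrequencySet}.
#' @name HaplotypeFrequencySet-accessors
NULL

#' @rdname HaplotypeFrequencySet-accessors
#' @export
setMethod("haploFrequencies", "HaplotypeFrequencySet", function(x) x@data)

#' @rdname HaplotypeFrequencySet-accessors
#' @export
setMethod("panelGenes", "HaplotypeFrequencySet", function(x) x@panel)

#' @rdname HaplotypeFrequencySet-accessors
#' @export
setMethod("hlaResolution", "HaplotypeFrequencySet", function(x) x@resolution)

#' @rdname HaplotypeFrequencySet-accessors
#' @export
setMethod("populationLabel", "HaplotypeFrequencySet",
          function(x) x@population)

setMethod("show", "HaplotypeFrequencySet", function(object) {
  cat("HaplotypeFrequencySet:", nrow(object@data), "haplotypes over",
      paste(object@panel, collapse = "-"),
      sprintf("(%s resolution)", object@resolution), "\n")
  if (nzchar(object@population)) {
    cat("  population:", object@population, "\n")
  }
  cat(sprintf("  total modelled frequency: %.4f\n", sum(object@data$frequency)))
  invisible(NULL)
})

#' Read / write haplotype frequency tables
#'
#' Interchange format: TSV/CSV with columns \code{haplotype} (serialised
#' gene-ordered \code{"~"}-joined alleles) and \code{frequency}; an
#' optional \code{population} column labels the table.
#'
#' @param path File path.
#' @param resolution Allele resolution of the table.
#' @param population Population label (overrides any file column).
#' @return [readHaplotypeFrequencies()]: a
#'   \linkS4class{HaplotypeFrequencySet}.
#' @export
readHaplotypeFrequencies <- function(path, resolution = c("high", "low"),
                                     population = NULL) {
  resolution <- match.arg(resolution)
  tab <- .readTable(path)
  if (!all(c("haplotype", "frequency") %in% names(tab))) {
    stop("frequency file must have 'haplotype' and 'frequency' columns")
  }
  pop <- population
  if (is.null(pop)) {
    pop <- if ("population" %in% names(tab) && nrow(tab) > 0L)
      tab$population[1L] else ""
  }
  HaplotypeFrequencySet(tab$haplotype, as.numeric(tab$frequency),
                        resolution = resolution, population = pop)
}

#' @rdname readHaplotypeFrequencies
#' @param x A \linkS4class{HaplotypeFrequencySet} to write.
#' @export
writeHaplotypeFrequencies <- function(x, path) {
  d <- haploFrequencies(x)
  d$population <- populationLabel(x)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published Finnish homozygote frequency tables
#'
#' Homozygote tables from a published screen of 20,737 genotyped Finnish
#' blood donors: per homozygous haplotype, the number of homozygous
#' donors, the observed homozygote frequency, and the Hardy-Weinberg
#' expected homozygote frequency \eqn{p^2} computed from (unpublished)
#' Finnish stem-cell-registry haplotype frequencies.  The registry
#' frequencies themselves are not public; [frequencyFromExpected()]
#' recovers them as \eqn{\sqrt{p^2}}.
#'
#' @param panel \code{"A-DQB1"}: 41 six-locus high-resolution haplotypes
#'   (A, B, C, DRB1, DQA1, DQB1; also carries the mean percentage of
#'   heterozygous MHC markers per haplotype, a FER flag for haplotypes
#'   enriched in Finland but rare elsewhere, and a flag for haplotypes
#'   whose homozygosity was confirmed by clinical typing).
#'   \code{"A-B"}: 49 two-locus low-resolution haplotypes.
#' @return data.frame, one row per haplotype, ranked by homozygote count.
#' @examples
#' tab <- finnishHomozygotes("A-DQB1")
#' sum(tab$n_homozygotes)  # 317
#' @export
finnishHomozygotes <- function(panel = c("A-DQB1", "A-B")) {
  panel <- match.arg(panel)
  file <- switch(panel,
                 "A-DQB1" = "finland_homozygotes_a_dqb1.tsv",
                 "A-B" = "finland_homozygotes_a_b.tsv")
  path <- system.file("extdata", file, package = "HLAbank",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab
}
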