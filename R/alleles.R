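#' @import methods
#' @importFrom stats cor rbeta rbinom runif setNames
#' @importFrom utils read.delim write.table
NULL

#' Classical HLA loci handled by the package
#'
#' The seven classical HLA genes that HLA imputation pipelines typically
#' call at high resolution and that homozygote screens are run over.
#'
#' @format Character vector of gene symbols in chromosomal (telomere to
#'   centromere) order: A, C, B, DRB1, DQA1, DQB1, DPB1 would be physical
#'   order; the conventional reporting order A, B, C, DRB1, DQA1, DQB1,
#'   DPB1 is used here.
#' @export
HLA_GENES <- c("A", "B", "C", "DRB1", "DQA1", "DQB1", "DPB1")

#' Parse HLA allele names
#'
#' Parses allele strings in standard colon-delimited nomenclature
#' (\code{"A*03:01"}, \code{"DQB1*05:01:01"}, or a bare field string such
#' as \code{"03:01"} when \code{gene} supplies the locus).  Expression
#' suffixes (N, L, S, Q, C, A) are accepted and retained separately; they
#' play no role in resolution-truncated matching.
#'
#' @param text Character vector of allele names.
#' @param gene Optional gene symbol(s) (recycled) used when \code{text}
#'   lacks the \code{GENE*} prefix.
#' @return A data.frame with one row per input: \code{gene},
#'   \code{fields} (list column of digit strings, leading zeros kept),
#'   \code{suffix} and \code{raw}.
#' @examples
#' parseAllele("A*03:01")
#' parseAllele("03", gene = "B")
#' @export
parseAllele <- function(text, gene = NULL) {
  stopifnot(is.character(text))
  if (length(text) == 0L) {
    return(data.frame(gene = character(), fields = I(list()),
                      suffix = character(), raw = character(),
                      stringsAsFactors = FALSE))
  }
  raw <- text
  text <- trimws(text)
  if (any(!nzchar(text))) {
    stop("empty allele string at position ",
         which(!nzchar(text))[1L])
  }
  hint <- if (is.null(gene)) rep(NA_character_, length(text)) else
    rep_len(as.character(gene), length(text))

  hasStar <- grepl("*", text, fixed = TRUE)
  geneTok <- ifelse(hasStar, sub("\\*.*$", "", text), hint)
  fieldTok <- ifelse(hasStar, sub("^[^*]*\\*", "", text), text)
  if (any(is.na(geneTok))) {
    stop("allele '", text[which(is.na(geneTok))[1L]],
         "' has no gene prefix and no 'gene' hint was given")
  }
  bad <- !(geneTok %in% HLA_GENES)
  if (any(bad)) {
    stop("unknown HLA gene '", geneTok[which(bad)[1L]], "' in allele '",
         raw[which(bad)[1L]], "'")
  }
  hasSuffix <- grepl("[NLSQCA]$", fieldTok)
  suffix <- ifelse(hasSuffix, substring(fieldTok, nchar(fieldTok)), "")
  core <- substr(fieldTok, 1L, nchar(fieldTok) - nchar(suffix))
  fields <- strsplit(core, ":", fixed = TRUE)
  okField <- vapply(fields, function(f) {
    length(f) >= 1L && length(f) <= 4L && all(grepl("^[0-9]+$", f))
  }, logical(1))
  if (any(!okField)) {
    stop("cannot parse allele fields in '", raw[which(!okField)[1L]], "'")
  }
  data.frame(gene = geneTok, fields = I(fields), suffix = suffix,
             raw = raw, stringsAsFactors = FALSE)
}

#' Format alleles back to canonical nomenclature strings
#'
#' @param gene Character vector of gene symbols.
#' @param fields List of character vectors of numeric fields (or a single
#'   character vector for one allele).
#' @param suffix Optional expression suffix vector.
#' @return Character vector like \code{"A*03:01"}.
#' @export
formatAllele <- function(gene, fields, suffix = "") {
  if (!is.list(fields)) fields <- list(fields)
  stopifnot(length(gene) == length(fields))
  suffix <- rep_len(suffix, length(gene))
  paste0(gene, "*",
         vapply(fields, paste, character(1), collapse = ":"),
         suffix)
}

#' Canonicalise allele strings
#'
#' Parse-and-reformat, so \code{" a*03:01 "}-style irregularities become
#' errors and canonical strings pass through unchanged.
#'
#' @inheritParams parseAllele
#' @return Character vector of canonical allele strings.
#' @export
canonicalAllele <- function(text, gene = NULL) {
  p <- parseAllele(text, gene)
  formatAllele(p$gene, p$fields, p$suffix)
}

#' Truncate alleles to a typing resolution
#'
#' Low resolution keeps the first nomenclature field (two-digit allele
#' family, the level used for HLA-matched thrombocytes); high resolution
#' keeps the first two fields (protein-level, four-digit).  Expression
#' suffixes are dropped on truncation since matching is field-based.
#'
#' @param allele Character vector of allele strings.
#' @param level \code{"high"} (two fields) or \code{"low"} (one field).
#' @param gene Optional gene hint for bare field strings.
#' @return Character vector of truncated canonical allele strings.
#'
#' Truncating a one-field allele to high resolution is an error
#' ("insufficient resolution"): the second field is unknown, not zero.
#' @examples
#' truncateAllele("A*03:01", "low")   # "A*03"
#' truncateAllele("A*03:01:02", "high")  # "A*03:01"
#' @export
truncateAllele <- function(allele, level = c("high", "low"), gene = NULL) {
  level <- match.arg(level)
  p <- parseAllele(allele, gene)
  keep <- if (level == "low") 1L else 2L
  short <- vapply(p$fields, length, integer(1)) < keep
  if (any(short)) {
    stop("insufficient resolution: allele '", p$raw[which(short)[1L]],
         "' has fewer than ", keep, " fields")
  }
  formatAllele(p$gene, lapply(p$fields, `[`, seq_len(keep)))
}

## canonical unordered-pair order: lexicographic on the serialized allele
## (equivalently on the field vector, since the gene part is shared)
orderAllelePair <- function(a1, a2) {
  swap <- a2 < a1
  list(allele_1 = ifelse(swap, a2, a1),
       allele_2 = ifelse(swap, a1, a2))
}

#' Serialise and parse multi-locus haplotypes
#'
#' A haplotype is written as the gene-ordered, \code{"~"}-joined allele
#' string, e.g.
#' \code{"A*03:01~B*35:01~C*04:01~DRB1*01:01~DQA1*01:01~DQB1*05:01"}.
#'
#' @param alleles Character vector of allele strings, one per panel gene,
#'   in panel order.
#' @return \code{formatHaplotype}: a single haplotype string.
#' @export
formatHaplotype <- function(alleles) {
  paste(alleles, collapse = "~")
}

#' @rdname formatHaplotype
#' @param haplotype Character vector of haplotype strings.
#' @return \code{parseHaplotype}: a list with \code{panel} (gene vector of
#'   the first haplotype) and \code{alleles} (matrix, one row per
#'   haplotype, one column per gene).
#' @export
parseHaplotype <- function(haplotype) {
  parts <- strsplit(haplotype, "~", fixed = TRUE)
  n <- lengths(parts)
  if (length(unique(n)) > 1L) {
    stop("haplotypes have differing numbers of loci")
  }
  flat <- parseAllele(unlist(parts))
  alleles <- matrix(formatAllele(flat$gene, flat$fields, flat$suffix),
                    nrow = length(haplotype), byrow = TRUE)
  genes <- matrix(flat$gene, nrow = length(haplotype), byrow = TRUE)
  panel <- genes[1L, , drop = TRUE]
  if (length(haplotype) > 1L && !all(t(genes) == panel)) {
    stop("haplotypes have inconsistent locus panels")
  }
  if (anyDuplicated(panel)) {
    stop("haplotype repeats a locus: ", haplotype[1L])
  }
  colnames(alleles) <- panel
  list(panel = panel, alleles = alleles)
}

#' Truncate every allele of a haplotype string
#'
#' @param haplotype Character vector of haplotype strings.
#' @param level Resolution, as in [truncateAllele()].
#' @return Character vector of truncated haplotype strings.
#' @export
truncateHaplotype <- function(haplotype, level = c("high", "low")) {
  level <- match.arg(level)
  if (length(haplotype) == 0L) return(character())
  parts <- strsplit(haplotype, "~", fixed = TRUE)
  vapply(parts, function(a) formatHaplotype(truncateAllele(a, level)),
         character(1))
}
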