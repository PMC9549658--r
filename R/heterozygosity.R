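#' Built-in MHC analysis windows
#'
#' Two hg38 chromosome-6 windows used for genomic verification of HLA
#' homozygosity: \code{mhc_a_dqb1} (29,942,470-32,666,689), the segment
#' spanning HLA-A to HLA-DQB1, and \code{mhc_extended}
#' (28,510,120-33,480,577), the extended MHC including HLA-DPB1.
#' Coordinates are 1-based and inclusive at both ends.
#'
#' @return A named \linkS4class{GRanges} of length 2.
#' @export
mhcWindows <- function() {
  gr <- GenomicRanges::GRanges(
    "chr6",
    IRanges::IRanges(start = c(29942470L, 28510120L),
                     end = c(32666689L, 33480577L)))
  names(gr) <- c("mhc_a_dqb1", "mhc_extended")
  gr
}

## accept a window as a built-in name, c(start, end), or a GRanges
resolveWindow <- function(window) {
  if (is.character(window) && length(window) == 1L) {
    wins <- mhcWindows()
    if (!window %in% names(wins)) {
      stop("unknown window '", window, "'; built-ins are: ",
           paste(names(wins), collapse = ", "))
    }
    return(wins[window])
  }
  if (is.numeric(window) && length(window) == 2L) {
    if (window[1L] <= 0 || window[1L] > window[2L]) {
      stop("window must satisfy 0 < start <= end")
    }
    return(GenomicRanges::GRanges(
      "chr6", IRanges::IRanges(as.integer(window[1L]),
                               as.integer(window[2L]))))
  }
  if (is(window, "GRanges") && length(window) == 1L) return(window)
  stop("window must be a built-in name, c(start, end), or a single GRanges")
}

#' Select markers inside a genomic window
#'
#' 1-based, inclusive at both boundaries, matching the segment notation
#' of the built-in windows.
#'
#' @param positions Integer vector of marker positions (1-based).
#' @param window A window accepted by [mhcWindows()] name, numeric
#'   \code{c(start, end)}, or \linkS4class{GRanges}.
#' @return Integer indices of the in-window positions.
#' @export
windowMarkers <- function(positions, window) {
  win <- resolveWindow(window)
  which(positions >= GenomicRanges::start(win) &
          positions <= GenomicRanges::end(win))
}

#' Per-donor marker heterozygosity within a window
#'
#' For every donor with marker data, the percentage of heterozygous
#' markers among the non-missing markers inside the window.  Missing
#' genotypes are excluded from the denominator (they carry no evidence
#' either way); a donor with zero non-missing in-window markers gets
#' \code{NA}, never a spurious 0.
#'
#' @param cohort An \linkS4class{HLACohort} with markers attached.
#' @param window Window specification (see [windowMarkers()]).
#' @return data.frame with one row per marker-bearing donor:
#'   \code{donor_id}, \code{n_markers_in_window}, \code{n_non_missing},
#'   \code{n_het}, \code{het_pct}.
#' @export
donorHetPct <- function(cohort, window = "mhc_a_dqb1") {
  if (!hasMarkers(cohort)) stop("cohort carries no marker data")
  m <- markerMatrix(cohort)
  idx <- windowMarkers(GenomicRanges::start(markerRanges(cohort)), window)
  sub <- m[, idx, drop = FALSE]
  nonMissing <- rowSums(!is.na(sub))
  nHet <- rowSums(sub == 1L, na.rm = TRUE)
  data.frame(donor_id = rownames(m),
             n_markers_in_window = length(idx),
             n_non_missing = as.integer(nonMissing),
             n_het = as.integer(nHet),
             het_pct = ifelse(nonMissing > 0L, 100 * nHet / nonMissing,
                              NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean marker heterozygosity per homozygous haplotype
#'
#' Groups homozygote calls by haplotype and averages the donors'
#' in-window heterozygosity percentages -- the per-haplotype verification
#' column of the homozygote report.  The default averages over donors
#' (each donor weighted equally); \code{pooled = TRUE} instead pools
#' markers across the group's donors (each marker comparison weighted
#' equally).
#'
#' @param calls Call table from [scanHomozygotes()].
#' @param cohort The \linkS4class{HLACohort} carrying the markers.
#' @param window Window specification (see [windowMarkers()]).
#' @param pooled Pool markers across donors instead of averaging
#'   per-donor percentages.
#' @return data.frame with columns \code{haplotype}, \code{n_donors}
#'   (marker-bearing donors in the group), \code{mean_het_pct} (NA for
#'   groups with no marker-bearing donor).
#' @export
haplotypeMeanHet <- function(calls, cohort, window = "mhc_a_dqb1",
                             pooled = FALSE) {
  het <- donorHetPct(cohort, window)
  merged <- merge(calls[c("donor_id", "haplotype")], het, by = "donor_id")
  groups <- split(merged, factor(merged$haplotype,
                                 levels = unique(calls$haplotype)))
  out <- data.frame(
    haplotype = names(groups),
    n_donors = vapply(groups, function(x) sum(!is.na(x$het_pct)),
                      integer(1)),
    mean_het_pct = vapply(groups, function(x) {
      if (pooled) {
        nm <- sum(x$n_non_missing)
        if (nm == 0L) NA_real_ else 100 * sum(x$n_het) / nm
      } else {
        v <- x$het_pct[!is.na(x$het_pct)]
        if (length(v) == 0L) NA_real_ else mean(v)
      }
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}
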