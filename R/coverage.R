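#' Carrier probability of a haplotype under Hardy-Weinberg
#'
#' The proportion of a random-mating population carrying at least one
#' copy of a haplotype of frequency \eqn{p}: \eqn{1-(1-p)^2 = 2p - p^2}.
#' A recipient is HLA-compatible with a homozygous donor exactly when
#' they carry the donor's haplotype, so this is also the single-donor
#' population coverage.
#'
#' @param p Haplotype frequency (vectorised), in [0, 1].
#' @return Numeric vector of carrier probabilities.
#' @examples
#' carrierProbability(0.5)  # 0.75
#' @export
carrierProbability <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("haplotype frequency must lie in [0, 1]")
  }
  1 - (1 - p)^2
}

#' Population coverage of a set of homozygous haplotypes
#'
#' The fraction of the population compatible with at least one haplotype
#' of the set.  Haplotypes are mutually exclusive on a chromosome, so a
#' random chromosome matches the set with probability \eqn{F = \sum_i
#' p_i} and a random diploid individual carries at least one matching
#' chromosome with probability \eqn{1-(1-F)^2}.  The subtraction of the
#' \eqn{(1-F)^2} term is what removes the double-counted overlap --
#' individuals compatible with more than one haplotype of the set --
#' relative to naively summing per-haplotype carrier probabilities.
#'
#' @param p Numeric vector of haplotype frequencies; all non-negative,
#'   summing to at most 1 (with 1e-9 slack for printed-value rounding).
#' @return List of class \code{coverage_result}: \code{n_haplotypes},
#'   \code{summed_frequency} (\eqn{F}), \code{coverage}
#'   (\eqn{1-(1-F)^2}) and \code{carrier_probabilities} (per-haplotype
#'   \eqn{2p_i - p_i^2}).
#' @examples
#' setCoverage(c(0.08, 0.05, 0.07))
#' @export
setCoverage <- function(p) {
  if (any(is.na(p)) || any(p < 0)) {
    stop("haplotype frequencies must be non-negative")
  }
  total <- sum(p)
  if (total > 1 + 1e-9) stop("haplotype frequencies sum to more than 1")
  structure(list(n_haplotypes = length(p),
                 summed_frequency = total,
                 coverage = 1 - (1 - total)^2,
                 carrier_probabilities = carrierProbability(pmin(p, 1))),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf(
    "Population coverage: %.1f%% (%d haplotypes, summed frequency %.4f)\n",
    roundHalfUp(100 * x$coverage, 1), x$n_haplotypes, x$summed_frequency))
  invisible(x)
}

#' Cumulative coverage curve over ranked haplotypes
#'
#' Prefix-wise [setCoverage()] over haplotypes in the given (rank) order;
#' the final point is the full-set coverage.  The curve is non-decreasing
#' because adding a haplotype can only increase the summed frequency.
#'
#' @param p Numeric vector of haplotype frequencies, already ordered by
#'   rank.
#' @param haplotype Optional labels, same length as \code{p}.
#' @return data.frame with columns \code{k}, \code{haplotype},
#'   \code{frequency}, \code{cumulative_frequency},
#'   \code{cumulative_coverage}.
#' @export
cumulativeCoverage <- function(p, haplotype = NULL) {
  if (any(is.na(p)) || any(p < 0)) {
    stop("haplotype frequencies must be non-negative")
  }
  if (sum(p) > 1 + 1e-9) stop("haplotype frequencies sum to more than 1")
  if (is.null(haplotype)) haplotype <- as.character(seq_along(p))
  cf <- cumsum(p)
  data.frame(k = seq_along(p), haplotype = haplotype, frequency = p,
             cumulative_frequency = cf,
             cumulative_coverage = 1 - (1 - cf)^2,
             stringsAsFactors = FALSE)
}

#' Rank a homozygote table and take the top k
#'
#' Stable descending sort by the chosen key (homozygote count or
#' reference-derived expected frequency), ties broken by the other key
#' and then by haplotype string, so ranking is fully deterministic.
#'
#' @param table A homozygote table ([homozygoteTable()]-style data.frame
#'   with columns \code{haplotype}, \code{n_homozygotes},
#'   \code{expected_frequency}).
#' @param by Ranking key: \code{"observed_n"} or
#'   \code{"reference_frequency"}.
#' @param k Optional prefix size; \code{k} larger than the table returns
#'   the whole table with a warning.
#' @return The reordered (sub)table.
#' @export
rankHaplotypes <- function(table, by = c("observed_n",
                                         "reference_frequency"),
                           k = NULL) {
  by <- match.arg(by)
  if (nrow(table) == 0L) stop("empty homozygote table")
  n <- table$n_homozygotes
  e <- ifelse(is.na(table$expected_frequency), -Inf,
              table$expected_frequency)
  o <- if (by == "observed_n") order(-n, -e, table$haplotype)
       else order(-e, -n, table$haplotype)
  out <- table[o, , drop = FALSE]
  if (!is.null(k)) {
    if (k > nrow(out)) {
      warning("k = ", k, " exceeds table size ", nrow(out),
              "; returning the full table")
      k <- nrow(out)
    }
    out <- out[seq_len(k), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

## round-half-up to `digits` decimals (printed coverage percentages use
## this; R's round() is half-even)
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
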