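## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched.  seed = NULL leaves the global stream in use.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

.singletonHaplotype <- function(panel, index) {
  ## unique synthetic haplotypes for the residual ("other") frequency
  ## mass: allele families 900+ are unused by real nomenclature, so
  ## singletons never collide with named haplotypes, and each index gets
  ## a distinct FIRST field so singletons stay distinct even after
  ## low-resolution truncation -- the residual pool can never produce a
  ## homozygote at either resolution.
  vapply(index, function(i) {
    formatHaplotype(paste0(panel, "*", 900L + i, ":01"))
  }, character(1))
}

#' Simulate a diploid cohort from a haplotype pool
#'
#' Draws, for every donor, two haplotypes independently from the
#' configured frequency distribution (random mating / Hardy-Weinberg), so
#' a haplotype of frequency \eqn{f} yields homozygotes at rate \eqn{f^2}
#' and carriers at \eqn{1-(1-f)^2}.  The frequency mass not covered by
#' the named pool is assigned to unique singleton haplotypes, which can
#' never produce spurious homozygotes.
#'
#' Posterior probabilities are left missing here; [applyImputationNoise()]
#' simulates the imputation step and assigns them.
#'
#' @param frequencies A \linkS4class{HaplotypeFrequencySet}; the named
#'   haplotype pool.
#' @param nDonors Number of donors to draw.
#' @param seed Optional integer; fixes the cohort exactly.
#' @return List with \code{cohort} (an \linkS4class{HLACohort}) and
#'   \code{truth}, a data.frame of each donor's two drawn haplotype
#'   labels (\code{hap1}, \code{hap2}) -- the phased ground truth the
#'   analysis itself never sees.
#' @examples
#' pool <- HaplotypeFrequencySet(c("A*01~B*08", "A*03~B*35"), c(0.1, 0.2),
#'                               resolution = "low")
#' sim <- simulateCohort(pool, 100, seed = 1)
#' cohortSize(sim$cohort)
#' @export
simulateCohort <- function(frequencies, nDonors, seed = NULL) {
  stopifnot(is(frequencies, "HaplotypeFrequencySet"), nDonors >= 0)
  d <- haploFrequencies(frequencies)
  panel <- panelGenes(frequencies)
  f <- d$frequency
  other <- 1 - sum(f)
  if (other < -1e-9) stop("haplotype frequencies sum to more than 1")
  other <- max(other, 0)

  donor <- sprintf("D%06d", seq_len(nDonors))
  if (nDonors == 0L) {
    empty <- data.frame(donor_id = character(), gene = character(),
                        allele_1 = character(), allele_2 = character(),
                        stringsAsFactors = FALSE)
    return(list(cohort = HLACohort(empty),
                truth = data.frame(donor_id = character(),
                                   hap1 = character(), hap2 = character(),
                                   stringsAsFactors = FALSE)))
  }

  withSeed(seed, {
    idx <- sample.int(nrow(d) + 1L, 2L * nDonors, replace = TRUE,
                      prob = c(f, other))
    lab <- character(2L * nDonors)
    named <- idx <= nrow(d)
    lab[named] <- d$haplotype[idx[named]]
    if (any(!named)) {
      lab[!named] <- .singletonHaplotype(panel, seq_len(sum(!named)))
    }
    hap1 <- lab[seq_len(nDonors)]
    hap2 <- lab[nDonors + seq_len(nDonors)]

    haps <- unique(c(hap1, hap2))
    alleleByHap <- parseHaplotype(haps)$alleles
    rownames(alleleByHap) <- haps

    geno <- do.call(rbind, lapply(seq_along(panel), function(j) {
      data.frame(donor_id = donor, gene = panel[j],
                 allele_1 = alleleByHap[hap1, j],
                 allele_2 = alleleByHap[hap2, j],
                 posterior_probability = NA_real_,
                 stringsAsFactors = FALSE)
    }))
    geno <- geno[order(geno$donor_id, match(geno$gene, panel)), ]
    list(cohort = HLACohort(geno),
         truth = data.frame(donor_id = donor, hap1 = hap1, hap2 = hap2,
                            stringsAsFactors = FALSE))
  })
}

#' Attach haplotype-linked MHC markers to a simulated cohort
#'
#' Each haplotype label carries a fixed random binary marker vector over
#' \code{nMarkers} distinct positions placed uniformly in the window; a
#' donor is heterozygous at a marker exactly where its two haplotypes'
#' vectors differ (perfect linkage), after which homozygous states are
#' flipped to heterozygous with probability \code{noiseRate} to emulate
#' residual within-haplotype variation.
#'
#' @param sim A \code{list(cohort, truth)} as returned by
#'   [simulateCohort()].
#' @param nMarkers Number of marker positions.
#' @param window Window name (\code{"mhc_a_dqb1"} or
#'   \code{"mhc_extended"}), a length-2 numeric \code{c(start, end)}, or
#'   a single \linkS4class{GRanges}; 1-based inclusive hg38 coordinates.
#' @param noiseRate Per-marker probability of flipping a homozygous state
#'   to heterozygous.
#' @param seed Optional integer seed.
#' @return The input list with \code{cohort} replaced by a cohort
#'   carrying the marker matrix.
#' @export
attachMarkers <- function(sim, nMarkers, window = "mhc_a_dqb1",
                          noiseRate = 0, seed = NULL) {
  stopifnot(nMarkers > 0L, noiseRate >= 0, noiseRate <= 1)
  win <- resolveWindow(window)
  start <- GenomicRanges::start(win)
  end <- GenomicRanges::end(win)
  width <- end - start + 1L
  if (width < nMarkers) {
    stop("window of width ", width, " cannot host ", nMarkers,
         " distinct marker positions")
  }
  truth <- sim$truth
  geno <- hlaGenotypes(sim$cohort)
  withSeed(seed, {
    pos <- start - 1L + sort(sample.int(width, nMarkers))
    haps <- unique(c(truth$hap1, truth$hap2))
    V <- matrix(stats::rbinom(length(haps) * nMarkers, 1L, 0.5),
                nrow = length(haps), dimnames = list(haps, NULL))
    states <- V[truth$hap1, , drop = FALSE] + V[truth$hap2, , drop = FALSE]
    if (noiseRate > 0) {
      flip <- matrix(stats::runif(length(states)) < noiseRate,
                     nrow = nrow(states)) & states != 1L
      states[flip] <- 1L
    }
    rownames(states) <- truth$donor_id
    colnames(states) <- pos
    list(cohort = HLACohort(geno, markers = states), truth = truth)
  })
}

#' Simulate imputation errors and posterior probabilities
#'
#' Each allele call is independently replaced, with probability
#' \code{errorRate}, by a different allele drawn uniformly from that
#' locus's observed allele universe.  Genotype posterior probabilities
#' are drawn from a high-confidence Beta for untouched genotypes
#' (\code{ppCorrect}, default mean 0.98) and a diffuse Beta around 0.5
#' for genotypes carrying an erroneous call (\code{ppError}), emulating
#' confident imputation with occasional near-threshold calls.  The
#' pre-noise genotype table is returned as the clinical truth for
#' concordance testing.
#'
#' A locus whose universe holds a single allele cannot host an error;
#' such calls are skipped and counted in the \code{n_skipped} attribute
#' of the returned cohort's genotype table.
#'
#' @param sim A \code{list(cohort, ...)} from [simulateCohort()], or an
#'   \linkS4class{HLACohort}.
#' @param errorRate Per-allele-call substitution probability in [0, 1].
#' @param ppCorrect,ppError Length-2 \code{c(shape1, shape2)} Beta
#'   parameters for the two posterior-probability families.
#' @param seed Optional integer seed.
#' @return List with \code{cohort} (noisy \linkS4class{HLACohort}),
#'   \code{truth} (clinical-style table: donor_id, gene, allele_1,
#'   allele_2 before noise), \code{n_errors} and \code{n_calls}.
#' @export
applyImputationNoise <- function(sim, errorRate, ppCorrect = c(49, 1),
                                 ppError = c(8, 8), seed = NULL) {
  stopifnot(errorRate >= 0, errorRate <= 1)
  cohort <- if (is(sim, "HLACohort")) sim else sim$cohort
  g <- hlaGenotypes(cohort)
  truth <- g[c("donor_id", "gene", "allele_1", "allele_2")]
  if (nrow(g) == 0L) {
    return(list(cohort = cohort, truth = truth, n_errors = 0L,
                n_calls = 0L))
  }
  withSeed(seed, {
    universe <- lapply(split(c(g$allele_1, g$allele_2),
                             c(g$gene, g$gene)), unique)
    nSkipped <- 0L
    nErrors <- 0L
    alleles <- cbind(g$allele_1, g$allele_2)
    hit <- matrix(stats::runif(length(alleles)) < errorRate,
                  nrow = nrow(alleles))
    for (col in 1:2) {
      rows <- which(hit[, col])
      for (i in rows) {
        u <- universe[[g$gene[i]]]
        if (length(u) < 2L) {
          nSkipped <- nSkipped + 1L
          next
        }
        cur <- alleles[i, col]
        alt <- u[u != cur]
        alleles[i, col] <- alt[sample.int(length(alt), 1L)]
        nErrors <- nErrors + 1L
      }
    }
    erroneous <- alleles[, 1L] != g$allele_1 | alleles[, 2L] != g$allele_2
    pp <- ifelse(erroneous,
                 stats::rbeta(nrow(g), ppError[1L], ppError[2L]),
                 stats::rbeta(nrow(g), ppCorrect[1L], ppCorrect[2L]))
    noisy <- data.frame(donor_id = g$donor_id, gene = g$gene,
                        allele_1 = alleles[, 1L], allele_2 = alleles[, 2L],
                        posterior_probability = pp,
                        stringsAsFactors = FALSE)
    out <- HLACohort(noisy,
                     markers = if (hasMarkers(cohort)) markerMatrix(cohort),
                     markerRanges = if (hasMarkers(cohort))
                       markerRanges(cohort))
    if (nSkipped > 0L) {
      warning(nSkipped,
              " error(s) skipped at loci with a single-allele universe")
    }
    list(cohort = out, truth = truth, n_errors = nErrors,
         n_calls = 2L * nrow(g), n_skipped = nSkipped)
  })
}
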