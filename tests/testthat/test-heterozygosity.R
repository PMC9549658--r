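test_that("window selection is 1-based and inclusive at both ends", {
  pos <- c(29942469L, 29942470L, 31000000L, 32666689L, 32666690L)
  idx <- windowMarkers(pos, "mhc_a_dqb1")
  expect_equal(idx, 2:4)
  expect_equal(windowMarkers(integer(), "mhc_a_dqb1"), integer())
  # extended window spans the narrow one
  expect_equal(windowMarkers(pos, "mhc_extended"), 1:5)
  expect_equal(windowMarkers(pos, c(29942470, 32666689)), 2:4)
  expect_error(windowMarkers(pos, "nonsense"), "unknown window")
  expect_error(windowMarkers(pos, c(10, 5)), "start <= end")

  wins <- mhcWindows()
  expect_equal(unname(GenomicRanges::start(wins)),
               c(29942470L, 28510120L))
  expect_equal(unname(GenomicRanges::end(wins)),
               c(32666689L, 33480577L))
})

test_that("per-donor heterozygosity excludes missing from the denominator", {
  g <- data.frame(donor_id = c("d1", "d2", "d3"), gene = "A",
                  allele_1 = "A*01:01", allele_2 = "A*01:01")
  m <- rbind(d1 = c(0L, 0L, 2L, 0L),
             d2 = c(1L, 0L, 2L, NA),
             d3 = c(NA, NA, NA, NA))
  colnames(m) <- c(29942470L, 30000000L, 31000000L, 32000000L)
  cohort <- HLACohort(g, markers = m)

  het <- donorHetPct(cohort, "mhc_a_dqb1")
  expect_equal(het$n_markers_in_window, rep(4L, 3))
  expect_equal(het$het_pct[het$donor_id == "d1"], 0)
  # 1 het of 3 non-missing
  expect_equal(het$het_pct[het$donor_id == "d2"], 100 / 3)
  # all-missing donor is flagged undefined, not zero
  expect_true(is.na(het$het_pct[het$donor_id == "d3"]))
  expect_equal(het$n_non_missing, c(4L, 3L, 0L))

  expect_error(donorHetPct(HLACohort(g)), "no marker data")
})

test_that("1 het of 4 non-missing gives 25 percent", {
  g <- data.frame(donor_id = "d1", gene = "A",
                  allele_1 = "A*01:01", allele_2 = "A*01:01")
  m <- matrix(c(1L, 0L, 0L, 2L), nrow = 1,
              dimnames = list("d1", c(29942470L, 29942471L,
                                      29942472L, 29942473L)))
  het <- donorHetPct(HLACohort(g, markers = m), "mhc_a_dqb1")
  expect_equal(het$het_pct, 25)
})

test_that("heterozygosity is invariant under marker permutation and
           commutes with window pre-filtering", {
  sim <- simulateCohort(toyPool(2), 150, seed = 601)
  sim <- attachMarkers(sim, nMarkers = 300, window = "mhc_extended",
                       noiseRate = 0.05, seed = 602)
  cohort <- sim$cohort
  base <- donorHetPct(cohort, "mhc_a_dqb1")

  # permute columns
  perm <- sample(ncol(markerMatrix(cohort)))
  permuted <- HLACohort(hlaGenotypes(cohort),
                        markers = markerMatrix(cohort)[, perm],
                        markerRanges = markerRanges(cohort)[perm])
  hetP <- donorHetPct(permuted, "mhc_a_dqb1")
  expect_equal(hetP[order(hetP$donor_id), ]$het_pct,
               base[order(base$donor_id), ]$het_pct)

  # pre-filter to the window, then compute over everything
  keep <- windowMarkers(GenomicRanges::start(markerRanges(cohort)),
                        "mhc_a_dqb1")
  narrowed <- HLACohort(hlaGenotypes(cohort),
                        markers = markerMatrix(cohort)[, keep],
                        markerRanges = markerRanges(cohort)[keep])
  hetN <- donorHetPct(narrowed, "mhc_extended")
  expect_equal(hetN$het_pct, base$het_pct)
  expect_equal(hetN$n_het, base$n_het)
})

test_that("noise-free homozygotes score exactly zero and mixed donors above", {
  sim <- simulateCohort(toyPool(3), 500, seed = 607)
  sim <- attachMarkers(sim, nMarkers = 250, noiseRate = 0, seed = 608)
  het <- donorHetPct(sim$cohort, "mhc_a_dqb1")
  truth <- sim$truth
  hom <- truth$donor_id[truth$hap1 == truth$hap2]
  mixed <- truth$donor_id[truth$hap1 != truth$hap2]
  expect_true(all(het$het_pct[het$donor_id %in% hom] == 0))
  # two distinct haplotype vectors virtually surely differ somewhere in
  # 250 fair-coin markers
  expect_true(all(het$het_pct[het$donor_id %in% mixed] > 0))
})

test_that("per-haplotype means aggregate donor percentages", {
  g <- data.frame(donor_id = c("d1", "d2", "d3"), gene = "A",
                  allele_1 = "A*01:01", allele_2 = "A*01:01")
  m <- rbind(d1 = c(0L, 0L, 0L, 0L),      # 0 %
             d2 = c(1L, 0L, 2L, 0L),      # 25 %... use 1% analogue below
             d3 = c(1L, 1L, 0L, 0L))
  colnames(m) <- c(29942470L, 29942471L, 29942472L, 29942473L)
  cohort <- HLACohort(g, markers = m)
  calls <- data.frame(donor_id = c("d1", "d2", "d3"),
                      haplotype = c("A*01:01", "A*01:01", "A*02:01"),
                      min_pp = 0.9)
  out <- haplotypeMeanHet(calls, cohort, "mhc_a_dqb1")
  expect_equal(out$mean_het_pct[out$haplotype == "A*01:01"],
               mean(c(0, 25)))
  # single-donor group equals that donor's value
  expect_equal(out$mean_het_pct[out$haplotype == "A*02:01"], 50)
  expect_equal(out$n_donors, c(2L, 1L))

  # pooled mode weights marker comparisons, not donors
  pooled <- haplotypeMeanHet(calls, cohort, "mhc_a_dqb1", pooled = TRUE)
  expect_equal(pooled$mean_het_pct[pooled$haplotype == "A*01:01"],
               100 * 1 / 8)
})

test_that("low marker noise surfaces as the configured mean percentage", {
  one <- HaplotypeFrequencySet(
    haploFrequencies(toyPool(1))$haplotype, 1, resolution = "high")
  sim <- simulateCohort(one, 300, seed = 613)
  sim <- attachMarkers(sim, nMarkers = 400, noiseRate = 0.001, seed = 614)
  calls <- scanHomozygotes(sim$cohort, SIX_LOCI, "high")
  out <- haplotypeMeanHet(calls, sim$cohort, "mhc_a_dqb1")
  nComparisons <- 300 * 400
  se <- 100 * sqrt(0.001 * 0.999 / nComparisons)
  expect_lt(abs(out$mean_het_pct - 0.1), 4 * se)
})
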