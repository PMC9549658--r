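test_that("degenerate simulation configurations behave exactly", {
  pool <- toyPool(2)
  empty <- simulateCohort(pool, 0, seed = 1)
  expect_equal(cohortSize(empty$cohort), 0L)
  expect_equal(nrow(empty$truth), 0L)

  # a single haplotype at frequency 1 makes every donor homozygous
  one <- HaplotypeFrequencySet(haploFrequencies(pool)$haplotype[1L], 1,
                               resolution = "high")
  sim <- simulateCohort(one, 100, seed = 2)
  g <- hlaGenotypes(sim$cohort)
  expect_true(all(g$allele_1 == g$allele_2))
  expect_equal(cohortSize(sim$cohort), 100L)
  expect_true(all(sim$truth$hap1 == sim$truth$hap2))
})

test_that("the same seed reproduces the cohort bit for bit", {
  pool <- toyPool(3)
  a <- simulateCohort(pool, 400, seed = 99)
  b <- simulateCohort(pool, 400, seed = 99)
  expect_identical(hlaGenotypes(a$cohort), hlaGenotypes(b$cohort))
  expect_identical(a$truth, b$truth)
  c <- simulateCohort(pool, 400, seed = 100)
  expect_false(identical(a$truth, c$truth))
})

test_that("homozygote counts follow the Hardy-Weinberg binomial", {
  # haplotype frequency recovered from the top published expected
  # homozygote frequency: f = sqrt(0.00690815), n = 20737 donors, so the
  # homozygote count is Binomial(n, f^2) with mean ~143.25
  f <- frequencyFromExpected(0.00690815)
  pool <- HaplotypeFrequencySet(
    "A*03:01~B*35:01~C*04:01~DRB1*01:01~DQA1*01:01~DQB1*05:01", f,
    resolution = "high")
  n <- 20737L
  sim <- simulateCohort(pool, n, seed = 17)
  hom <- sum(sim$truth$hap1 == sim$truth$hap2 &
               sim$truth$hap1 != "" &
               grepl("A\\*03:01", sim$truth$hap1))
  expected <- n * f^2
  sd <- sqrt(n * f^2 * (1 - f^2))
  expect_lt(abs(hom - expected), 4 * sd)
})

test_that("empirical haplotype frequencies converge to the configured f", {
  pool <- toyPool(3)
  cfg <- haploFrequencies(pool)
  n <- 50000L
  sim <- simulateCohort(pool, n, seed = 23)
  draws <- c(sim$truth$hap1, sim$truth$hap2)
  for (i in seq_len(nrow(cfg))) {
    fhat <- mean(draws == cfg$haplotype[i])
    sd <- sqrt(cfg$frequency[i] * (1 - cfg$frequency[i]) / (2 * n))
    expect_lt(abs(fhat - cfg$frequency[i]), 4 * sd)
  }
})

test_that("sqrt of the observed homozygote frequency recovers f", {
  pool <- toyPool(2)
  cfg <- haploFrequencies(pool)
  n <- 50000L
  sim <- simulateCohort(pool, n, seed = 31)
  hom <- sim$truth$hap1 == sim$truth$hap2
  for (i in seq_len(nrow(cfg))) {
    obs <- mean(hom & sim$truth$hap1 == cfg$haplotype[i])
    fhat <- frequencyFromExpected(obs)
    f <- cfg$frequency[i]
    # delta method: sd(sqrt(obs)) ~ sd(obs) / (2 f)
    sdObs <- sqrt(f^2 * (1 - f^2) / n)
    expect_lt(abs(fhat - f), 4 * sdObs / (2 * f))
  }
})

test_that("haplotype-linked markers encode identity-by-state exactly", {
  pool <- toyPool(2)
  sim <- simulateCohort(pool, 300, seed = 41)
  sim <- attachMarkers(sim, nMarkers = 120, window = "mhc_a_dqb1",
                       noiseRate = 0, seed = 42)
  m <- markerMatrix(sim$cohort)
  expect_equal(ncol(m), 120L)
  pos <- GenomicRanges::start(markerRanges(sim$cohort))
  expect_true(all(pos >= 29942470 & pos <= 32666689))
  expect_false(is.unsorted(pos))
  expect_equal(anyDuplicated(pos), 0L)

  # noise-free: a donor is heterozygous exactly where its two haplotype
  # vectors differ, so truth-homozygotes have zero het markers
  hom <- sim$truth$donor_id[sim$truth$hap1 == sim$truth$hap2]
  expect_true(all(m[hom, ] != 1L))
  # and two donors sharing an unordered haplotype pair share the pattern
  key <- paste(pmin(sim$truth$hap1, sim$truth$hap2),
               pmax(sim$truth$hap1, sim$truth$hap2))
  dupPair <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(dupPair) >= 2L) {
    i <- dupPair[key[dupPair] == key[dupPair][1L]][1:2]
    expect_identical(unname(m[sim$truth$donor_id[i[1L]], ] == 1L),
                     unname(m[sim$truth$donor_id[i[2L]], ] == 1L))
  }
})

test_that("marker noise raises homozygote heterozygosity by its rate", {
  one <- HaplotypeFrequencySet(
    haploFrequencies(toyPool(1))$haplotype, 1, resolution = "high")
  sim <- simulateCohort(one, 400, seed = 51)
  rate <- 0.02
  sim <- attachMarkers(sim, nMarkers = 500, noiseRate = rate, seed = 52)
  m <- markerMatrix(sim$cohort)
  hetFrac <- mean(m == 1L)
  nCells <- length(m)
  expect_lt(abs(hetFrac - rate), 4 * sqrt(rate * (1 - rate) / nCells))
})

test_that("marker windows too narrow for the marker count are refused", {
  sim <- simulateCohort(toyPool(1), 10, seed = 61)
  expect_error(attachMarkers(sim, nMarkers = 100, window = c(100, 150)),
               "cannot host")
})

test_that("imputation noise is absent at rate 0 and total at rate 1", {
  sim <- simulateCohort(toyPool(2), 200, seed = 71)
  clean <- applyImputationNoise(sim, 0, seed = 72)
  expect_identical(clean$truth[c("donor_id", "gene", "allele_1", "allele_2")],
                   hlaGenotypes(sim$cohort)[c("donor_id", "gene",
                                              "allele_1", "allele_2")])
  expect_equal(clean$n_errors, 0L)
  # posterior probabilities drawn from the high-confidence family
  pp <- hlaGenotypes(clean$cohort)$posterior_probability
  expect_true(all(pp > 0 & pp <= 1))
  expect_gt(mean(pp), 0.9)

  # rate 1 with a binary per-locus universe flips every call
  g <- data.frame(donor_id = rep(c("d1", "d2"), each = 1L),
                  gene = "A",
                  allele_1 = c("A*01:01", "A*02:01"),
                  allele_2 = c("A*01:01", "A*02:01"))
  flipped <- applyImputationNoise(HLACohort(g), 1, seed = 73)
  gf <- hlaGenotypes(flipped$cohort)
  expect_equal(gf$allele_1, c("A*02:01", "A*01:01"))
  expect_equal(gf$allele_2, c("A*02:01", "A*01:01"))
})

test_that("the injected error fraction is recovered at scale", {
  # 2299 donors x 6 loci = 13794 genotypes = 27588 allele calls at a
  # rate inside the published 0-4.6 percent per-locus error range
  rate <- 0.023
  sim <- simulateCohort(toyPool(3), 2299, seed = 81)
  noisy <- applyImputationNoise(sim, rate, seed = 82)
  expect_equal(noisy$n_calls, 27588L)
  sd <- sqrt(rate * (1 - rate) / noisy$n_calls)
  expect_lt(abs(noisy$n_errors / noisy$n_calls - rate), 3 * sd)

  # erroneous genotypes carry visibly degraded posterior probabilities
  g <- hlaGenotypes(noisy$cohort)
  truthPairs <- noisy$truth
  changed <- g$allele_1 != truthPairs$allele_1 |
    g$allele_2 != truthPairs$allele_2
  expect_gt(mean(g$posterior_probability[!changed]),
            mean(g$posterior_probability[changed]))
})
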