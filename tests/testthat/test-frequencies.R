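test_that("observed frequency is exact division with guards", {
  # published worked examples: counts over the 20,737-donor cohort
  expect_equal(round(observedFrequency(149, 20737), 8), 0.00718522)
  expect_equal(round(observedFrequency(48, 20737), 8), 0.00231470)
  expect_equal(observedFrequency(0, 20737), 0)
  expect_error(observedFrequency(1, 0), "positive")
  expect_error(observedFrequency(5, 4), "\\[0, cohortSize\\]")
})

test_that("expected homozygote frequency is p squared and inverts by sqrt", {
  expect_equal(expectedHomozygoteFrequency(0), 0)
  expect_equal(expectedHomozygoteFrequency(1), 1)
  expect_equal(expectedHomozygoteFrequency(0.5), 0.25)
  # the top published expected frequency and its square-root recovery
  expect_equal(expectedHomozygoteFrequency(0.0831153), 0.00690815,
               tolerance = 1e-6)
  expect_equal(frequencyFromExpected(0.00690815), 0.0831153,
               tolerance = 1e-6)
  expect_equal(frequencyFromExpected(0.25), 0.5)
  expect_equal(frequencyFromExpected(0), 0)
  expect_equal(frequencyFromExpected(1), 1)
  expect_error(expectedHomozygoteFrequency(1.1), "\\[0, 1\\]")
  expect_error(frequencyFromExpected(-0.1), "\\[0, 1\\]")
  # inversion identity over a grid
  p <- seq(0, 1, by = 0.05)
  expect_equal(frequencyFromExpected(expectedHomozygoteFrequency(p)), p)
})

test_that("homozygote tables count, normalise and sort deterministically", {
  pool <- toyPool(3)
  sim <- simulateCohort(pool, 5000, seed = 307)
  calls <- scanHomozygotes(sim$cohort, SIX_LOCI, "high")
  tab <- homozygoteTable(calls, reference = pool)

  expect_equal(sum(tab$n_homozygotes), nrow(calls))
  expect_equal(tab$observed_frequency, tab$n_homozygotes / 5000)
  # sum of observed frequencies equals total homozygote fraction exactly
  expect_equal(sum(tab$observed_frequency), nrow(calls) / 5000)
  # expected frequencies are reference p^2, never in-cohort estimates
  ref <- haploFrequencies(pool)
  m <- match(tab$haplotype, ref$haplotype)
  expect_equal(tab$expected_frequency, ref$frequency[m]^2)
  # descending count order with deterministic ties
  expect_true(all(diff(tab$n_homozygotes) <= 0))

  # a haplotype missing from the reference gets NA, not zero
  calls2 <- data.frame(donor_id = "x1",
                       haplotype = "A*80:01~B*82:01~C*18:01~DRB1*16:02~DQA1*06:01~DQB1*06:01",
                       min_pp = 0.9)
  tab2 <- homozygoteTable(calls2, cohortSize = 100, reference = pool)
  expect_true(is.na(tab2$expected_frequency))
})

test_that("allele frequencies count two calls per donor and sum to one", {
  cohort <- allHomCohort(2)  # both donors A*03:01/A*03:01
  af <- alleleFrequencies(cohort, "A")
  expect_equal(af$count, 4L)
  expect_equal(af$frequency, 1)

  g <- data.frame(donor_id = "d9", gene = "A",
                  allele_1 = "A*01:01", allele_2 = "A*02:01")
  af <- alleleFrequencies(HLACohort(g), "A")
  expect_equal(nrow(af), 2L)
  expect_equal(af$frequency, c(0.5, 0.5))

  sim <- simulateCohort(toyPool(3), 4000, seed = 311)
  af <- alleleFrequencies(sim$cohort, "B")
  expect_equal(sum(af$frequency), 1)
  # marginal check against the configured pool: allele B*35:01 occurs on
  # haplotype 1 only, so its frequency estimates f1
  f1 <- haploFrequencies(toyPool(3))$frequency[1L]
  fhat <- af$frequency[af$allele == "B*35:01"]
  expect_lt(abs(fhat - f1), 4 * sqrt(f1 * (1 - f1) / 8000))
})

test_that("reference correlation reproduces the product-moment formula", {
  obs <- data.frame(allele = paste0("A*", sprintf("%02d", 1:10), ":01"),
                    frequency = seq(0.01, 0.10, by = 0.01))
  expect_equal(correlateWithReference(obs, obs)$r, 1)

  rev <- obs
  rev$frequency <- rev(rev$frequency)
  expect_equal(correlateWithReference(obs, rev)$r, -1)

  set.seed(401)
  x <- runif(20, 0, 0.05)
  y <- x + rnorm(20, 0, 0.01)
  o <- data.frame(allele = paste0("B*", sprintf("%02d", 1:20), ":01"),
                  frequency = x)
  r <- data.frame(allele = o$allele, frequency = y)
  got <- correlateWithReference(o, r)$r
  # independent oracle: the product-moment formula written out
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got, manual, tolerance = 1e-12)

  # exclusions: by request and for missing reference values, reported
  res <- correlateWithReference(o, r[1:18, ],
                                exclude = o$allele[1L])
  expect_equal(res$n_pairs, 17L)
  expect_setequal(res$excluded$allele, c(o$allele[1L], o$allele[19:20]))
  expect_error(correlateWithReference(o[1:2, ], r), "fewer than 3")
  o0 <- o; o0$frequency <- 0.01
  expect_error(correlateWithReference(o0, r), "zero variance")
})

test_that("observed homozygote counts fit Hardy-Weinberg expectations", {
  pool <- publishedPool(5)
  cfg <- haploFrequencies(pool)
  n <- 50000L
  sim <- simulateCohort(pool, n, seed = 419)
  calls <- scanHomozygotes(sim$cohort, SIX_LOCI, "high")
  counts <- table(factor(calls$haplotype, levels = cfg$haplotype))
  probs <- cfg$frequency^2
  # multinomial over: homozygous for each pool haplotype, or anything else
  gof <- suppressWarnings(
    stats::chisq.test(c(as.integer(counts), n - sum(counts)),
                      p = c(probs, 1 - sum(probs))))
  expect_gt(gof$p.value, 0.001)
})
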