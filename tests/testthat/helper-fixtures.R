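# shared fixtures: everything is built in code at test time

SIX_LOCI <- c("A", "B", "C", "DRB1", "DQA1", "DQB1")

# small high-resolution haplotype pool with realistic Finnish-style
# frequencies (most frequent six-locus homozygous haplotypes)
toyPool <- function(k = 3) {
  haps <- c(
    "A*03:01~B*35:01~C*04:01~DRB1*01:01~DQA1*01:01~DQB1*05:01",
    "A*01:01~B*08:01~C*07:01~DRB1*03:01~DQA1*05:01~DQB1*02:01",
    "A*03:01~B*07:02~C*07:02~DRB1*15:01~DQA1*01:02~DQB1*06:02",
    "A*02:01~B*13:02~C*06:02~DRB1*07:01~DQA1*02:01~DQB1*02:02",
    "A*02:01~B*15:01~C*03:04~DRB1*04:01~DQA1*03:01~DQB1*03:02")
  f <- c(0.0831, 0.0492, 0.0337, 0.0199, 0.0173)
  HaplotypeFrequencySet(haps[seq_len(k)], f[seq_len(k)],
                        resolution = "high", population = "toy")
}

# pool built from the published expected homozygote frequencies
# (square-root recovery); rows containing a single-field allele are
# dropped so the pool is fully usable at high resolution
publishedPool <- function(k = 10) {
  tab <- finnishHomozygotes("A-DQB1")
  twoField <- vapply(strsplit(tab$haplotype, "~", fixed = TRUE),
                     function(a) all(grepl(":", a, fixed = TRUE)),
                     logical(1))
  tab <- tab[twoField, , drop = FALSE][seq_len(k), , drop = FALSE]
  HaplotypeFrequencySet(tab$haplotype,
                        frequencyFromExpected(tab$expected_frequency),
                        resolution = "high", population = "Finland")
}

# cohort of n donors all homozygous for the first pool haplotype
allHomCohort <- function(n, pool = toyPool(1)) {
  hap <- haploFrequencies(pool)$haplotype[1L]
  al <- parseHaplotype(hap)
  geno <- do.call(rbind, lapply(seq_along(al$panel), function(j) {
    data.frame(donor_id = sprintf("H%03d", seq_len(n)),
               gene = al$panel[j],
               allele_1 = unname(al$alleles[1L, j]),
               allele_2 = unname(al$alleles[1L, j]),
               posterior_probability = 0.99,
               stringsAsFactors = FALSE)
  }))
  HLACohort(geno)
}

# write a cohort table to a temp file and return the path
tmpCohortFile <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Monte-Carlo coverage oracle: simulate nDraws diploid individuals by two
# independent chromosome draws from the full haplotype distribution and
# count those carrying at least one set member
mcCoverage <- function(p, nDraws = 1e5) {
  k <- length(p)
  idx1 <- sample.int(k + 1L, nDraws, replace = TRUE, prob = c(p, 1 - sum(p)))
  idx2 <- sample.int(k + 1L, nDraws, replace = TRUE, prob = c(p, 1 - sum(p)))
  mean(idx1 <= k | idx2 <= k)
}
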