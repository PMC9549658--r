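# HLAbank

Identification and population-coverage analysis of HLA-homozygous donors
from imputed HLA genotypes.

## The problem

Allogeneic therapeutic cells (iPS-derived lines, mesenchymal stromal
cells, HLA-typed thrombocytes) are rejected when they display HLA alleles
the recipient does not carry.  A donor homozygous for one HLA haplotype
displays only that haplotype's antigens, so their cells are compatible
with everyone who carries *at least one copy* of the haplotype.  Large
genotyped blood-donor biobanks plus statistical HLA imputation make it
cheap to screen tens of thousands of donors for such homozygotes.

`HLAbank` implements that screen and the statistics around it for
cohorts of imputed genotypes (HIBAG-style output: per-donor, per-locus
allele pairs with posterior probabilities):

- **Homozygote scan** over a configurable locus panel (e.g. A–DQB1 at
  high/4-digit resolution, or A–B at low/2-digit resolution for
  platelet matching), with opt-in posterior-probability filtering.
- **Frequency tables**: observed homozygote frequency `n / N` and the
  Hardy–Weinberg expected frequency `p²` from registry haplotype
  frequencies.
- **Population coverage** of a haplotype set S with overlap correction:
  under random mating a random chromosome matches S with probability
  `F = Σᵢ pᵢ`, so the fraction of the population compatible with at
  least one haplotype of S is `1 − (1 − F)²`; naively summing the
  per-haplotype carrier probabilities `2pᵢ − pᵢ²` would double-count
  people compatible with several haplotypes.
- **Genomic verification**: percentage of heterozygous DNA markers per
  donor within MHC windows (hg38 chr6 29,942,470–32,666,689 and
  28,510,120–33,480,577) — a true HLA homozygote should be nearly
  marker-homozygous across the MHC.
- **Concordance QC** of imputed calls against clinical-grade typing,
  with exclusion of homozygote calls contradicted by a clinical
  heterozygote.
- A **synthetic-cohort generator** (Hardy–Weinberg diploid sampling
  from a haplotype pool, haplotype-linked markers, imputation noise
  with degraded posteriors) so the whole pipeline is testable without
  access to restricted biobank data.

The package ships the published homozygote frequency tables for a
screen of 20,737 Finnish blood donors (41 six-locus haplotypes, 49
low-resolution A–B haplotypes) as worked-example inputs; see
`?finnishHomozygotes`.

## Worked example

```r
library(HLAbank)

pool <- HaplotypeFrequencySet(
  c("A*03:01~B*35:01~C*04:01~DRB1*01:01~DQA1*01:01~DQB1*05:01",
    "A*01:01~B*08:01~C*07:01~DRB1*03:01~DQA1*05:01~DQB1*02:01",
    "A*03:01~B*07:02~C*07:02~DRB1*15:01~DQA1*01:02~DQB1*06:02"),
  c(0.0831, 0.0492, 0.0337), resolution = "high",
  population = "Finland-like")

sim   <- simulateCohort(pool, 20737, seed = 42)
sim   <- attachMarkers(sim, nMarkers = 500, noiseRate = 0.002, seed = 42)
noisy <- applyImputationNoise(sim, errorRate = 0.005, seed = 42)

res <- runPipeline(noisy$cohort, reference = pool, clinical = noisy$truth)
res
#> HLA homozygote screen: 208 of 20737 donors (1.0%) homozygous over A-B-C-DRB1-DQA1-DQB1 (high resolution)
#>   distinct homozygous haplotypes: 3
#>   coverage, top 3: 30.4%

res$table[, 1:5]
#>                                                  haplotype n_homozygotes observed_frequency expected_frequency mean_het_pct
#> 1 A*03:01~B*35:01~C*04:01~DRB1*01:01~DQA1*01:01~DQB1*05:01           129            0.00622            0.00691        0.209
#> 2 A*01:01~B*08:01~C*07:01~DRB1*03:01~DQA1*05:01~DQB1*02:01            56            0.00270            0.00242        0.171
#> 3 A*03:01~B*07:02~C*07:02~DRB1*15:01~DQA1*01:02~DQB1*06:02            23            0.00111            0.00114        0.157
```

Each row: a haplotype every one of whose carriers is compatible with
that row's homozygous donors; `n_homozygotes` of 20,737 simulated donors
were called homozygous for it (about `20737 · p²` each, as Hardy–Weinberg
predicts); `mean_het_pct` is the average percentage of heterozygous MHC
markers among those donors — near the 0.2 % marker-noise floor, i.e. the
calls are genomically homozygous.

Coverage from the shipped published tables (registry frequencies
recovered as `√(expected homozygote frequency)`):

```r
tab <- finnishHomozygotes("A-DQB1")
p   <- frequencyFromExpected(tab$expected_frequency)
setCoverage(sort(p, decreasing = TRUE)[1:3])
#> Population coverage: 30.4% (3 haplotypes, summed frequency 0.1660)
setCoverage(p)
#> Population coverage: 69.3% (41 haplotypes, summed frequency 0.4461)
```

So the three most frequent six-locus homozygous haplotypes already cover
30.4 % of the population, and all 41 found in the 20,737-donor screen
cover 69.3 %.

## Documentation

The methods vignette (`vignettes/hla-homozygote-screening.Rmd`) describes
the model, the synthetic-data generator and its limits, numerical
conventions (rounding, tie-breaks, degenerate inputs) and the design
decisions; function-level documentation is in the roxygen comments.
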