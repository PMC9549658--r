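---
title: "Screening imputed genotypes for HLA-homozygous donors: methods and design"
author: "HLAbank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening imputed genotypes for HLA-homozygous donors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HLAbank)
```

## The model

A donor homozygous for an HLA haplotype *h* (identical alleles at every
panel locus, hence both chromosomes carrying *h*) displays only *h*'s
antigens, so their cells are HLA-compatible with every recipient who
carries at least one copy of *h*.  Three quantities follow from
Hardy–Weinberg (random-mating) assumptions applied to haplotype
frequency *p*:

* expected homozygote frequency: $p^2$;
* carrier probability (single-donor coverage): $1-(1-p)^2 = 2p - p^2$;
* population coverage of a haplotype set $S$ with
  $F = \sum_{h \in S} p_h$: $1-(1-F)^2$.

The set-coverage form is exact because haplotypes are mutually exclusive
on one chromosome: a random chromosome matches $S$ with probability $F$,
and a diploid individual fails to match only if both chromosomes miss,
$(1-F)^2$.  Expanding shows the "overlap" explicitly,
$\sum_h (2p_h - p_h^2) - \text{coverage} \ge 0$: summing per-haplotype
carrier probabilities double-counts individuals compatible with more
than one haplotype in the set, and the squared term removes exactly that
overlap.  `setCoverage()` implements this and the test suite checks it
against a Monte-Carlo diploid-sampling oracle.

Because registry haplotype frequencies are often unpublished while the
*expected homozygote frequencies* $p^2$ are printed in reports,
`frequencyFromExpected()` recovers $p = \sqrt{p^2}$; this inversion is
what lets the shipped Finnish tables drive the coverage worked examples
(`finnishHomozygotes()`).

### Assumptions and when they break

* Hardy–Weinberg at the haplotype level (random mating, no inbreeding).
  Population substructure or consanguinity raises homozygote counts
  above $Np^2$; the package reports both observed and expected columns
  precisely so such deviation is visible, and the goodness-of-fit test
  used on synthetic cohorts (chi-square over per-haplotype homozygote
  counts) is the appropriate check on real data too.
* Frequencies refer to the same population as the cohort.  Expected
  frequencies always come from the reference table, never from
  in-cohort estimates, so a mismatched reference shows up as
  observed/expected discrepancy rather than being silently absorbed.
* Compatibility is defined as carriage of the full donor haplotype; no
  permissive-mismatch or single-locus-mismatch models are included.

## The screen

`scanHomozygotes()` calls a donor homozygous when, at every locus of the
panel, the two alleles are equal after truncation to the requested
resolution.  Two resolutions are supported: *high* keeps the first two
nomenclature fields (protein level, "4-digit"), *low* keeps the first
field (allele family, "2-digit", the level used for HLA-matched
thrombocytes).  Truncating a one-field allele to high resolution is an
error, not a guess — the second field is unknown.  Imputation output is
unphased, but a panel-wide homozygote's phase is trivial, which is the
only point where the package ever asserts a haplotype.

Two useful monotonicity facts are enforced by construction and tested
on random cohorts: extending the panel can only shrink the homozygote
set, and high-resolution homozygotes are a subset of low-resolution
ones.

### Posterior probabilities

Imputation posterior probabilities (PP) are carried through and the
smallest per-panel PP is reported per call (`min_pp`), but no donor is
dropped by default: the conventional 0.5 cutoff is descriptive, and
near-threshold calls are exactly the ones a haplobank would resolve by
confirmatory clinical typing rather than discard.  Filtering is opt-in
via `ppThreshold`, and filtered donors are counted, never silently
removed.  The same logging convention holds everywhere (missing-locus
donors, clinically discordant calls, alleles excluded from
correlation).

### Clinical concordance

`compareTypings()` compares imputed and clinical genotypes per (donor,
locus) at high resolution by default, since clinical-grade typing is
high-resolution.  The default error unit is the genotype (any mismatch
of the unordered truncated pair); allele-level counting (0/1/2 wrong
alleles per typing, rates per allele call) is available via
`alleleLevel = TRUE` because published per-locus error ranges do not
always state their granularity — neither mode is privileged.
`flagDiscordantHomozygotes()` excludes a homozygote call only when the
clinical typing is *heterozygous* at a panel locus (the clinical result
refutes homozygosity); calls without clinical data are retained and
flagged unverified.

## MHC marker heterozygosity

True HLA homozygosity usually extends across the MHC, so the percentage
of heterozygous DNA markers inside an MHC window is an orthogonal,
genomic check on the imputed calls.  Two built-in hg38 windows are
provided: `mhc_a_dqb1` (chr6:29,942,470–32,666,689, the HLA-A-to-DQB1
segment) and `mhc_extended` (chr6:28,510,120–33,480,577, including
DPB1).  Coordinates are 1-based and inclusive at both ends; half-open
(BED-style) inputs must be converted by the caller — the readers take
explicit positions precisely to avoid silent convention clashes.  One
published mention of the extended window truncates the end coordinate
to 3,480,577; the full methods-level value 33,480,577 is treated as
canonical.

Missing marker genotypes are excluded from the denominator rather than
counted as homozygous (counting them would deflate heterozygosity,
i.e. bias the verification toward passing), and a donor with zero
informative markers in the window gets `NA`, never 0.  Per-haplotype
summaries average donor percentages by default; whether published
per-haplotype figures average donors or pool markers is typically
unstated, so a pooled mode (`pooled = TRUE`, weighting marker
comparisons instead of donors) is provided.  The two differ only when
group members have unequal missingness.

## The synthetic-cohort generator

Restricted biobank genotypes cannot ship with an analysis package, so
the generator produces cohorts with exactly the statistical structure
the analysis assumes:

* **Diploid sampling** (`simulateCohort()`): each donor is two
  independent haplotype draws from the configured frequency
  distribution — the Hardy–Weinberg mechanism itself, so homozygote
  rates are $p^2$ by construction and parameter-recovery tests close
  the loop by re-estimating $p$ as the square root of the observed
  homozygote fraction.
* **Residual mass** ($1-\sum f$) is assigned to unique singleton
  haplotypes with unique first-field alleles, so the unmodelled pool
  can never generate a spurious homozygote at either resolution — a
  deliberately conservative null.
* **Markers** (`attachMarkers()`): every haplotype label carries a
  fixed random binary vector at positions placed uniformly in the
  window; a donor is heterozygous exactly where its two vectors differ
  (perfect linkage), then homozygous states flip to heterozygous with
  `noiseRate`, emulating residual within-haplotype variation.
* **Imputation noise** (`applyImputationNoise()`): each allele call is
  independently replaced with probability `errorRate` by a different
  allele from the locus's observed universe.  Genotype PPs are drawn
  from Beta(49, 1) (mean 0.98) for untouched genotypes and Beta(8, 8)
  (mean 0.5, visible spread) for genotypes with an erroneous call —
  reproducing the qualitative picture of confident imputation with
  rare near-0.5 posteriors.  Default error magnitudes in the tests
  (0.5–2.3 % per call) sit inside the 0–4.6 % per-locus range reported
  for imputation-vs-clinical comparisons.

What the generator does **not** emulate: linkage-disequilibrium decay
and recombination (marker linkage is perfect within a haplotype),
allele-specific imputation error profiles (errors are uniform over the
locus universe), genotyping-array artefacts, and population
substructure.  Tests passing on synthetic data therefore validate the
*computational* pipeline — counting, frequency arithmetic, coverage,
window logic, concordance bookkeeping — not the biological fidelity of
HLA imputation itself.

Reproducibility: every stochastic function takes a `seed` and restores
the caller's RNG state afterwards.  A single seeded stream with fully
vectorised sampling is used (rather than per-donor sub-streams); one
seed fixes the whole cohort bit-for-bit, which is the guarantee the
test suite and the acceptance script rely on.

## Numerical conventions

* Frequencies are kept at full double precision internally; report
  files round half-even to 8 decimals (high-resolution tables) or 6
  (low-resolution tables), and heterozygosity percentages to 2.
* Summary percentages (proportion homozygous, coverage) round half-up
  to one decimal, matching the convention of published headline figures
  like "1.5 %" and "30.4 %".
* Frequency-set mass is validated as $\sum f \le 1 + 10^{-9}$; the
  slack absorbs accumulated rounding when frequencies are recovered
  from printed values.
* Allele pairs are stored in lexicographic order of the serialised
  allele, making genotype equality order-insensitive; ranking
  tie-breaks are: other key descending, then haplotype string — fully
  deterministic.
* Degenerate inputs are defined, not special-cased ad hoc: empty
  haplotype sets cover 0 %, empty cohorts produce empty reports and a
  zero summary, a donor with no informative markers is `NA`.

## Scale of the validation runs

The statistical tests use cohorts of 20,737–50,000 donors (matching
the scale at which $p^2$ expectations for frequencies around 0.01–0.08
give comfortably testable counts), 50 Monte-Carlo coverage comparisons
at $10^6$ simulated diploids each, and 1,000-case property sweeps for
the coverage inequalities.  Chi-square goodness-of-fit on per-haplotype
homozygote counts uses the pool haplotypes plus an "anything else"
category and is asserted at $p > 0.001$.

## Known limitations

* No IPD-IMGT/HLA database integration: allele names are validated
  syntactically (gene, digit fields, expression suffix), not against
  the registry; G/P ambiguity groups are out of scope.
* Low resolution is first-field truncation, not serological splits —
  adequate for modern two-digit reporting, wrong for legacy serology.
* Coverage treats compatibility as full-haplotype carriage; no DPB1
  TCE/permissive-mismatch modelling, no multi-population pooling.
* The concordance module compares genotypes, not NGS reads; typing
  ambiguity strings are not expanded.
* One shipped six-locus table row contains a single-field DQA1 allele
  exactly as printed in its source; it parses and serialises fine but
  cannot be truncated to high resolution, and no ground truth is
  asserted for it.
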