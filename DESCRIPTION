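Package: HLAbank
Title: Identification and Population Coverage of HLA-Homozygous Donors
    from Imputed Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens cohorts of imputed HLA genotypes for donors homozygous
    across a configurable locus panel, builds homozygote frequency tables
    with Hardy-Weinberg expected frequencies (haplotype frequency squared),
    estimates the fraction of a population HLA-compatible with a set of
    homozygous haplotypes using the overlap-corrected carrier formula
    1 - (1 - sum(p))^2, verifies homozygosity from MHC-region DNA marker
    heterozygosity, and quality-controls imputed calls against clinical-grade
    typing.  Includes a synthetic-cohort generator (Hardy-Weinberg diploid
    sampling from a haplotype pool, haplotype-linked markers, imputation
    noise) so the whole pipeline is testable without access to restricted
    biobank genotypes, and ships published homozygote frequency tables for
    the Finnish population as worked-example inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
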