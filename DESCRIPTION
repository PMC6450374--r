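Package: poollink
Title: Bulked-Segregant Linkage Mapping from Pooled Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the recombination frequency between a causal locus and
    transcript SNVs from bulked-segregant sequencing read counts via a
    beta-binomial generative likelihood (maximum-likelihood point estimate,
    profile-likelihood confidence interval, LOD score, and an exact-tail
    exclusion test for implausible allele ratios), filters called variants by
    quality, type, parental origin and coverage, computes exact two-point
    linkage statistics (recombination fraction, LOD, chi-square) on individual
    F2 genotype-by-phenotype tables, screens allele pairs for diagnostic
    restriction enzymes (CAPS markers), reports coding consequences of point
    variants, and simulates F2 populations, bulks and pooled read counts with
    the statistical structure the likelihood model assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
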