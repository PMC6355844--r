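Package: hetmap
Title: Sex-Linked Marker Classification, Heterogamety Inference and
    Linkage Mapping in Full-Sib Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects sex-linked variants and sex-specific transcripts in
    two-parent full-sib families under both female (ZW) and male (XY)
    heterogamety, infers which sex is heterogametic, builds two-point
    genetic maps for outbred full-sib (CP) families with phenotypic sex
    mapped as a testcross locus (Haldane distances, LOD grouping), and
    reconstructs the ancestral heterogamety state over a set of species
    trees with a three-state continuous-time Markov model, MCMC over
    hierarchically-priored rates, stepping-stone marginal likelihoods and
    Bayes-factor ranking of constrained ancestral-state scenarios.  A
    strict-clock converter turns synonymous-site divergence into
    divergence times.  A seeded simulator generates full-sib genotype
    tables (VCF 4.2 plus sample manifest), expression matrices and
    Mk-evolved characters with known truth labels for validation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
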