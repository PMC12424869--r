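Package: rdnavar
Title: Variant Frequencies, Rare-Variant Burden and Heritability for the
    Multi-Copy Human rDNA Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls rRNA variant frequencies from short reads mapped against a
    paralog-variant atlas of the 18S and 28S subunits of the 45S rDNA unit.
    Reads are assigned by exact (optionally base-quality-masked) matching to
    expansion-segment alleles carrying 150 bp reference flanks; allele-level
    counts are converted to single-nucleotide variant frequencies via
    per-region lookup tables. Includes a unique-mapper rare-variant burden
    algorithm with cohort-level allele collapsing, copy-number-scaled
    zeroing and a per-region major-allele-frequency statistic; monozygotic
    twin identification and per-variant twin-correlation heritability;
    covariate-adjusted linear and logistic trait association with Bonferroni
    control and QQ diagnostics; and a seeded synthetic-cohort simulator
    (multi-copy genomes, twins, somatic mutations, GC-biased reads) so the
    whole stack is testable without access to biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
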