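Package: pedpqtl
Title: Protein Quantitative Trait Locus Mapping for Pediatric Plasma Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for mapping genetic and
    demographic determinants of plasma protein levels in pediatric cohorts.
    Covers rank-based inverse normal transformation with Blom offset,
    downshifted-normal imputation of missing intensities, multiple-regression
    association of proteins with age, sex and BMI-SDS, genotype quality
    control, per-protein and per-peptide genome-wide association scans,
    LD-based clumping into primary pQTLs with cis/trans classification and
    conditional analysis, peptide-level elimination of artefactual pQTLs with
    confidence tiers, variance decomposition by sequential sums of squares,
    allelic fold-change effect sizes, protein-based age/BMI prediction,
    Wald-ratio Mendelian randomization, approximate-Bayes-factor
    colocalization, replication and novelty assessment. A synthetic-cohort
    generator with planted cis/trans effects and variant-spanning peptide
    artefacts makes every stage testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
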