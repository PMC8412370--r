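Package: breedload
Title: Derived-Allele Mutational Load, Differentiation Scans and
    Disease-Variant Association in Dog Breeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying between-population mutational load from
    outgroup-polarized genotypes using derived-allele sharing ratios (R and
    R-squared statistics) with weighted block-jackknife inference;
    per-site Weir-Cockerham F_ST and copy-number V_ST differentiation
    scans with conservation-stratified candidate-variant prioritization
    and selective-sweep window merging; and case-control association of
    candidate markers with late-onset disease including genotype-by-age
    interaction models, age-stratified subsampling, two-locus linkage
    disequilibrium by EM, and breed-incidence regression.  A
    seed-reproducible Wright-Fisher breed-panel and cohort simulator
    provides inputs with the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
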