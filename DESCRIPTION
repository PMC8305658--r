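Package: fpcseg
Title: Variant Prioritization and Pedigree Co-Segregation Analysis for
    Familial Pancreatic Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing rare germline variants in familial
    pancreatic cancer (FPC) pedigrees. Implements an additive five-predictor
    deleteriousness score (SIFT, PolyPhen-2, MutationTaster, PROVEAN, CADD),
    a three-tier candidate triage (high ensemble score, FPC risk genes with
    sub-threshold CADD, recurrence across families), per-family
    co-segregation verdicts with an incomplete-penetrance rule, and
    cohort-level carrier-family prevalence reporting. Includes an extended
    PED dialect for phenotype-rich pedigrees, VCF genotype ingestion, a
    Mendelian-consistency check, and a seeded synthetic cohort generator
    (gene-drop through multi-generation pedigrees with age-dependent
    penetrance) for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
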