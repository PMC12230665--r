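Package: oncotherapyr
Title: Variant Interpretation, Clinical Evidence Harmonization, and
    Protein Context for Precision Oncology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting somatic and germline variants in a
    molecular tumor board setting. Parses variant queries at DNA,
    transcript, and protein level (HGVS and shorthand notations) and
    variant files in VCF and MAF; harmonizes clinical evidence tables
    from heterogeneous knowledge-base dialects onto a common schema
    (AMP/ASCO/CAP evidence tiers, response types, OncoTree-style cancer
    main types, drug classes); matches therapies to biomarkers at five
    specificity levels and aggregates them into treatment tables and
    sunburst hierarchies; classifies variants into the five ACMG
    pathogenicity categories with a full derivation trace; and computes
    structural context features for a mutated protein site from a PDB
    structure (Shrake-Rupley solvent accessibility, relative surface
    area, alpha-carbon distance fields, three-state secondary structure,
    substitution physicochemistry, disulfide and salt-bridge candidates,
    spatial neighbors). Ships deterministic fixture generators so every
    component is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    vcfR,
    bio3d,
    generics,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
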