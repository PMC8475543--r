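Package: fawstrain
Title: Fall Armyworm Host-Strain Diagnostics from TaqMan qPCR, RFLP and SNP
    Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for differentiating the corn (C) and rice (R) host strains
    of the fall armyworm, Spodoptera frugiperda, and their interstrain
    hybrids. Implements allele-specific TaqMan genotype calling from FAM/VIC
    quantification-cycle (Cq) tables, in-silico PCR and restriction-fragment
    (RFLP) typing of the COI and Tpi markers, multi-marker consensus strain
    assignment with hybrid detection, discovery of strain-diagnostic SNPs
    from a multi-sample VCF via per-site Weir-Cockerham fixation indices,
    extraction of N-masked assay-design context sequences, and
    standard-curve (assay sensitivity) analysis. A seeded synthetic-data
    generator emulates Cq distributions, dilution series and two-strain
    genotype matrices so the full workflow is testable without external
    sequence downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
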