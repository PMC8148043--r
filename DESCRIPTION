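Package: pwsasdx
Title: Streamlined Molecular Diagnostics for Prader-Willi and Angelman
    Syndromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a streamlined molecular-diagnostic workflow for
    Prader-Willi and Angelman syndromes (PWS/AS) from exome sequencing and
    methylation-sensitive MLPA data on GRCh37. Components: an
    absence-of-heterozygosity detector that segments same-zygosity variant
    runs from a VCF and applies the 15q11 critical-region rule; an
    exon-level read-depth CNV caller using doubly normalized coverage
    Z scores against batch comparators with Stouffer-combined group scores
    and deletion-extent typing (type I / type II / atypical / SNRPN-only);
    an MS-MLPA interpreter for copy-number and methylation probes; and an
    integrated classifier mapping the joint evidence to the molecular
    mechanism class (deletion subtypes, segmental or total isodisomy 15,
    heterodisomy or imprinting-center epimutation, imprinting-center
    microdeletion, point mutation). A seed-reproducible synthetic-specimen
    generator emits class-consistent VCF, coverage and MLPA bundles for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
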