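Package: assnp
Title: Allele-Specific Transcription-Factor Binding from ChIP-seq Allelic Read Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and annotates SNPs with allele-specific transcription-factor
    binding (AS-SNPs) from per-allele ChIP-seq read counts at heterozygous sites.
    Implements exact two-sided binomial tests against copy-number-adjusted null
    proportions, Benjamini-Hochberg false-discovery-rate control, gap/blacklist/CNV
    region filtering with a removal audit trail, common/rare allele-frequency
    classification, allele-specific effect statistics, linkage-disequilibrium-based
    GWAS and eQTL catalog integration with matched-random-set permutation
    enrichment, and closed-form Hardy-Weinberg heterozygote-discovery power
    calculations. Ships a truth-labelled synthetic-data generator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
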