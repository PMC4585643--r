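Package: mulekit
Title: Multi-Caller Variant Consensus, Trio Mendelian Error and Genome
    Binning Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Standalone toolkit for the bespoke computational stages of
    multi-caller variant-calling pipelines: indel normalization
    (left-align and trim), merging of per-caller VCFs with provenance
    tracking, M-out-of-N consensus extraction, trio Mendelian error
    statistics (allele drop-in, allele drop-out, identity-by-state
    tallies), multi-set variant concordance with Venn partition counts,
    variant summary statistics (Ti/Tv, het/hom, MAF filtering), a
    cluster-free genome binning and rotation-scheduling core with
    resumable task-graph execution, and seeded synthetic-data generators
    for caller VCF sets and family trios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
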