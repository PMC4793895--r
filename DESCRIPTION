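Package: VariantSieve
Title: Metadata-Driven Mining and Sequential Filtering of VCF Variants
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A scriptable engine for mining annotated variants in Variant
    Call Format (VCF) files. Parses INFO and FORMAT fields into typed
    documents driven entirely by the header metadata, classifies genotype
    zygosity for arbitrary ploidy by counting alternate alleles, and
    normalizes multi-allelic records to one allele per row. Variants are
    held in an indexed in-memory document store and trimmed by chains of
    typed filters applied consecutively, each reporting its surviving
    variant count. Sample groups support quantified genotype queries
    (any/all/fraction, require/exclude, minimum alternate-read depth) for
    case-control and family designs; BED files and pasted genomic ranges
    become boolean annotations; trio inheritance-pattern and
    compound-heterozygote annotations are computed and filterable like any
    INFO field. Surviving variants export as tab-delimited tables, and
    filter strategies save to versioned JSON for reuse across datasets. A
    deterministic synthetic-fixture generator and a command-line interface
    make every workflow reproducible in batch.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
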