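Package: capdmr
Title: Differential Methylation Region Calling and Genomic Context
    Annotation for MethylCap-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide differential-methylation analysis of
    methyl-CpG capture sequencing (methylCap-seq) enrichment data.
    Implements a dual-threshold screen that extracts condition-specific
    hypermethylated regions from confidence-scored peak sets by
    common-peak subtraction, hierarchical genomic-context classification
    of the resulting regions (TSS/intragenic/intergenic; CpG island
    versus island shore; orphan versus gene-associated islands;
    CGI-containing versus CGI-free promoters), TSS metaprofiles, summary
    reports with contingency statistics and gene-set enrichment, a
    seeded synthetic-data generator with planted regions and spike-in
    controls for end-to-end validation, and small calculators for
    bisulfite-clone, MSRE-qPCR and delta-delta-Ct quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
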