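Package: ampliphase
Title: Full-Length Haplotype Reconstruction from Tiled Long-Read Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs full-length diploid haplotypes of a ~77 kb locus from
    four overlapping long-range PCR amplicons sequenced with long reads.
    Reads are clustered into the two alleles of each amplicon via heterozygous
    sites, per-allele consensus sequences are chained across amplicon overlaps
    into phased haplotypes, and haplotypes are diffed against the reference to
    produce HGVS-named small-variant calls. A contiguous amplicon-dropout
    signature flags cryptic structural variants, which a split-read junction
    caller resolves to exact breakpoints with an inserted-sequence consensus.
    An in-silico multiplex gap-PCR screens donor cohorts for deletion carriers.
    Ships a fully seeded synthetic-data generator emulating a CD36-deficiency
    study design (amplicon panel, diploid genotype cohort, nanopore- and
    HiFi-like reads, 600-donor screening cohort) for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    IRanges,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    VariantAnnotation,
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: minimap2
Config/testthat/edition: 3
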