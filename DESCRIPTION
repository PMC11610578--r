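Package: drrscan
Title: Differential Reference Regions and Inversion Breakpoint Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares reference genome assemblies through pairwise whole-genome
    alignment coverage to call differential reference regions (DRRs), i.e.
    segments larger than 10 kbp present in one assembly and missing from
    another. Annotates DRRs with repeat composition and genomic context
    (centromere proximity, segmental-duplication overlap), classifies their
    presence in a sequenced population from read depth, and characterizes
    inversion breakpoint junctions (microhomology, insertions, junction
    indels, span) to infer the likely double-strand-break repair mechanism
    (NHEJ, MMEJ, MMBIR, NAHR). Includes a seeded simulator that generates
    template/query genome pairs, depth panels and junction sequences with
    matching truth files for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
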