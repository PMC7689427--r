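Package: panhap
Title: Haplotype Block Discovery Across Pangenome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls identical-by-state haplotype blocks between crop genome
    assemblies from whole-chromosome alignment tables (binned median identity
    with error-tolerant bin stitching) and from gene-anchored BLAST alignments
    (trimmed-mean sliding windows), combines the two call sets, lifts intervals
    between assemblies using shared gene projections as anchors, quantifies
    haplotype sharing and conservation across cultivars, designs
    haplotype-informed SNP marker panels, and assigns genotyped germplasm to
    haplotype groups. Ships a seeded synthetic pangenome generator that plants
    identical-by-descent blocks, near-identical background divergence,
    introgression-like segments and N runs, emitting every downstream input
    with ground truth so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    dada2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
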