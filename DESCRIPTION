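Package: introtrace
Title: Tracing Donor Introgressions and Designing Selection Markers in Rice Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for marker-assisted tracing of a herbicide-tolerance allele
    through rice breeding programs: genotype calling from KASP (Kompetitive
    Allele-Specific PCR) endpoint fluorescence, trio-based classification of an
    improved line's SNPs into donor / receptor-parent / heterozygous / unknown
    origin, detection of donor introgression blocks from windowed SNP density,
    and design of codominant InDel, CAPS and KASP markers with in-silico PCR
    and restriction digestion. Includes a synthetic-data generator producing
    trio genomes with planted introgressions, fluorescence plates and amplicon
    pairs with exact ground truth, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    cluster,
    stats,
    utils,
    grDevices,
    graphics,
    methods
Suggests: testthat (>= 3.0.0), withr, seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
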