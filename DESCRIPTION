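Package: ruminet
Title: Genome-Resolved Carbohydrate Trophic Networks for Rumen Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects SusCD-anchored polysaccharide utilization loci (PULs)
    in annotated metagenome-assembled genomes, classifies their target
    substrate with a configurable CAZy-family rulebook, and gates every
    call with metaproteomic evidence (two or more unique peptides mapped
    uniquely to one genome). Reconstructs genomic potential for sugar
    utilization and fermentation with pathway-completeness thresholds,
    normalizes carbohydrate microarray (CoMPP) polymer signals, and
    assembles a bipartite genome-substrate trophic network with hub and
    tier annotation. Links viral contigs to microbial hosts by
    tetranucleotide-frequency similarity and CRISPR protospacer matching.
    Ships a synthetic-community generator with planted ground truth so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    S4Vectors,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
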