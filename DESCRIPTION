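Package: nmseq
Title: Calling and snoRNA Assignment of RNA 2'-O-Methylation from 3'-End
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of ribose 2'-O-methylation (Nm)
    mapping experiments. Generates synthetic references, box C/D snoRNAs
    and ground-truth modification sites; simulates oxidation-based 3'-end
    sequencing (RibOxi-seq-style) with unique molecular identifiers and
    alkaline-fragmentation end profiles (RiboMeth-seq-style); calls Nm
    sites from deduplicated single-nucleotide 3'-end coverage; computes
    MethScores with flanking-window normalization; predicts canonical
    box C/D snoRNA targets via the D+5 rule; and classifies differential
    sites across isogenic wild-type/deletion conditions to assign orphan
    snoRNA targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
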