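Package: onsenscan
Title: Detection and Chromosomal Landscape Analysis of Heat-Induced LTR
    Retrotransposon Neo-Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects new insertions of a heat-stress-activated Ty1/copia
    LTR retrotransposon (Onsen/ATCOPIA78 of Arabidopsis thaliana) from
    paired-end whole-genome sequencing, using discordant read pairs against
    a TE-masked reference together with LTR junction reads trimmed and
    remapped to resolve target-site duplications. Characterizes the
    chromosomal landscape of the calls: an H3K9me2-based euchromatin and
    heterochromatin partition, insertion densities, genic category tables,
    Fisher and hypergeometric enrichment tests, a matched-random-locus
    permutation test of window-count variance with gamma tail fitting, and
    expression-impact summaries from RNA-seq count tables. Includes a
    synthetic-data generator (genomes, planted insertions with target-site
    duplications, alignments, chromatin tracks, count tables) so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
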