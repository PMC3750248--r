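Package: pairplasma
Title: Whole-Genome Relatedness, Synteny and Genomic-Island Screening for
    Prokaryotic Genome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative genomics of closely related prokaryotic (especially
    archaeal) genomes at desk scale. Calls orthologs between two proteomes by
    reciprocal best hit over Smith-Waterman alignments or ingested BLAST
    tabular hits, and derives whole-genome relatedness statistics: average
    amino acid identity (AAI), the normalized ortholog fraction, synteny
    conservation (fraction of orthologs in collinear blocks and mean block
    length), marker-gene genome completeness, tiered annotation confidence
    calls, diagnostic protein motif scans (including type I copper-binding
    sites of blue-copper proteins), and detection of lineage-specific gene
    clusters (candidate horizontally transferred islands) with GC-composition
    deviation. Ships a genome-pair evolver that simulates descent from a
    common ancestor under substitution, gene gain/loss, rearrangement and
    island insertion, emitting full ground truth so every statistic can be
    validated against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
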