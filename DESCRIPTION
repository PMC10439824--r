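Package: annoqc
Title: Quality Assessment and Evidence-Based Refinement of Structural Genome Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks predicted gene models against the structural expectations
    of well-annotated eukaryotic (especially plant) genomes and refines them with
    structural and functional-evidence filters. Computes gFACs-style summary
    statistics (mono-exonic to multi-exonic ratio, gene and CDS lengths, CDS N50,
    ORF completeness), validates canonical splice sites, applies a two-round
    refinement protocol (protein-domain certification of single-exon models,
    ortholog-or-similarity certification of multi-exon models), measures a
    reciprocal-coverage annotation rate, and scores predictions against a
    reference annotation at nucleotide, transcript, and gene level using exact
    coding intron-chain matching. Includes a deterministic planted-genome
    simulator (soft-masked LTR-like repeats, controllable corruption and
    evidence false-negative rates) so every stage can be tested at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    rtracklayer,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
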