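Package: gffx
Type: Package
Title: Transcript Annotation Parsing, Comparison and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for transcript-level genome annotation in GFF3, GTF and
    BED formats: a hierarchical gene/transcript/exon data model with
    order-tolerant parsers and column-exact writers; genome-backed spliced
    sequence extraction, CDS validation, translation and splice-site
    consensus checks; filtering, locus clustering and redundancy removal;
    classification of query transcripts against a reference annotation with
    a 15-code overlap scheme; accuracy metrics at six levels (base, exon,
    intron, intron chain, transcript, locus) with tracking, refmap and tmap
    reports; and a streaming interval-tree classifier for large query sets.
    Includes a deterministic synthetic-data generator producing genomes,
    reference annotations and perturbed query sets with known expected
    classifications.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
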