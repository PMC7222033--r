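# gffx

Transcript annotations move through every RNA-seq and genome-annotation
pipeline as GFF3, GTF or BED files, and two recurring jobs dominate their
handling: cleaning/converting/filtering an annotation (and pulling
transcript sequences out of a genome), and judging how well a set of
assembled or predicted transcripts agrees with a reference annotation.
`gffx` is an R toolkit for both, aimed at people building or evaluating
transcriptome assemblies and at anyone who needs scriptable, tested
GFF/GTF/BED manipulation inside R.

What it provides:

* **A hierarchical data model** (gene / transcript / exon / CDS) with
  order-tolerant parsers for GFF3, GTF and BED12, column-exact writers,
  per-seqid coordinate-sorted indexes and fast overlap queries. All
  internal coordinates are 1-based inclusive; BED is converted at the I/O
  boundary only.
* **Genome-backed sequence operations**: samtools-compatible FASTA
  indexing (`.fai`), spliced exon/CDS extraction with strand handling and
  soft-mask (case) preservation, translation, CDS completeness checking
  (START/STOP presence, in-frame stops) and GT-AG/GC-AG/AT-AC splice-site
  consensus validation.
* **Transform operations** in the style of `gffread`: filtering by length,
  intron size, range, coding status, pseudogene annotation and splice
  consensus; clustering transcripts into same-strand exon-overlap loci;
  redundancy removal at three stringencies; close-exon merging; CDS-only
  exon synthesis; attribute tables.
* **Classification and accuracy metrics** in the style of `gffcompare`:
  every query transcript is assigned one of 15 single-character class
  codes describing its relationship to the closest reference transcript
  (`=`, `c`, `k`, `m`, `n`, `j`, `e`, `o`, `s`, `x`, `i`, `y`, `p`, `r`,
  `u`, in decreasing priority), and accuracy is reported at six levels --
  base, exon, intron, intron chain, transcript, locus -- as

  ```
  Sensitivity = TP / (TP + FN)        Precision = TP / (TP + FP)
  ```

  together with novel/missed exon, intron and locus counts, super-locus
  (`XLOC`) construction, TSS grouping (`tss_id`), multi-sample merging of
  structurally equivalent transfrags (identical intron chains; >80% mutual
  overlap for single-exon transcripts) and the `.stats`, `.tracking`,
  `.refmap` and `.tmap` report files.
* **A streaming classifier** (`trmap`-style): the reference is loaded into
  an interval tree and arbitrarily many query transcripts are classified
  one at a time, reporting *all* overlapping references per query in a
  pseudo-FASTA format.
* **A deterministic fixture generator** producing genomes, reference
  annotations with canonical splice sites and valid CDS, and perturbed
  query sets whose expected class codes are known by construction -- every
  test in the package runs on generated data.

## Worked example

Generate a small fixture (3 genes, 2 isoforms each), perturb three
transcripts in known ways, and compare them against the reference:

```r
library(gffx)

fx  <- make_fixture(seed = 42, n_genes = 3, isoforms_per_gene = 2)
qry <- make_query(list(set = fx$reference, genome = fx$genome,
                       territories = fx$territories),
                  specs = list(
                    list(op = "exact_copy",         expected_code = "="),
                    list(op = "drop_terminal_exon", expected_code = "c"),
                    list(op = "shift_intron",       expected_code = "j")),
                  seed = 5)

compute_stats(qry$set, fx$reference)
```

```
# gffx transcript accuracy report
#
#= Sample q1: 3 query transfrags (3 multi-exon)
#  Reference: 6 transcripts (6 multi-exon)
                       Sensitivity | Precision
Base level                   89.9% |      99.4%
Exon level                   75.0% |      81.8%
Intron level                 58.3% |      87.5%
Intron chain level           16.7% |      33.3%
Transcript level             16.7% |      33.3%
Locus level                  33.3% |      33.3%
  Missed exons:         1/12
  Novel exons:          0/11
  Missed introns:       1/12
  Novel introns:        0/8
  Missed loci:          0/3
  Novel loci:           0/3
```

Reading the report: the exact copy is the only full transcript-level match
(1 of 3 queries, so transcript precision is 33.3%; 1 of 6 reference
transcripts, so sensitivity is 16.7%). The truncated copy still matches at
the exon and intron levels it retains; the shifted intron costs one intron
and two exon matches but nearly all bases still align (base precision
99.4%). Per-transcript detail comes from the annotator:

```r
ann <- annotate_transcripts(qry$set, fx$reference)
vapply(ann$transcripts, function(t) t$attributes$class_code, "")
#>   Q_001 Q_002 Q_003
#>     "="   "c"   "j"
```

Shell-style entry points wrapping the same functions live in
`inst/scripts/` (`gffread.R`, `gffcompare.R`, `trmap.R`,
`gffx-fixtures.R`), e.g.

```sh
Rscript inst/scripts/gffcompare.R -r reference.gff3 -o cmp transcripts.gtf
```

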