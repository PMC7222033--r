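---
title: "Models and methods: transcript structure, classification and accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: transcript structure, classification and accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gffx)
```

This vignette is the package's own account of its methods: the data model,
the classification scheme, the accuracy metrics, the parameters that
matter, and the choices we made where the design was genuinely open. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

## The data model

A *transcript* is an ordered chain of non-overlapping exons on one
reference sequence and strand, optionally carrying CDS segments (each with
a frame phase) and free-form attributes. The transcript span is defined by
the exon chain; for CDS-only records (legal in GTF) the CDS chain stands
in until exons are synthesized explicitly with `force_exons()`. All
coordinates are 1-based inclusive; BED's 0-based half-open convention is
converted at the I/O boundary only, so every internal comparison works in
one coordinate system.

The *intron chain* -- the ordered list of intron `(start, end)` pairs --
is the unit of structural identity throughout the package: two multi-exon
transcripts are structurally equivalent iff their chains are identical,
which deliberately leaves the lengths of the first and last exons free
(assemblers rarely recover transcript ends exactly). Two single-exon
transcripts are equivalent when their overlap exceeds 80% of the *longer*
one. Measuring against the longer transcript is the stricter reading of
the rule and is used consistently (equivalence, redundancy, merging,
transcript-level accuracy); a single-exon and a multi-exon transcript
never match, because the 80% rule is defined for single-exon pairs only.

Parsers hold all records in memory until end of input and then link the
hierarchy, so features may arrive in any order. Duplicate GFF3 container
IDs are renamed with a numeric discriminator (a warning is raised;
segments attach to the first occurrence); in GTF, lines sharing a
`transcript_id` merge by dialect. Exons with an unknown `Parent`, lines
with malformed coordinates, and transcripts whose exons disagree on strand
are skipped/rejected with per-line diagnostics, collected on the returned
set; `strict = TRUE` turns the coordinate diagnostics fatal. Unknown
feature types under a transcript are retained as opaque children and
dropped in transcript-only output.

Overlap queries run through per-seqid coordinate-sorted indexes backed by
`IRanges::findOverlaps`; the test suite checks them against literal
brute-force scans.

## Classification codes

`classify_pair()` evaluates the 15-code scheme in strictly decreasing
priority (`=`, `c`, `k`, `m`, `n`, `j`, `e`, `o`, `s`, `x`, `i`, `y`; plus
`p`, `r`, `u` for queries overlapping no reference) and returns the first
code whose definition holds, so a pair satisfying several definitions gets
the highest-priority one. Where the wording of a code leaves room, we fixed
the semantics as follows and test against constructed pairs:

* **`=`** requires the exact intron chain match only. The terminal-end
  tolerance does *not* participate here; it applies at the transcript
  accuracy level (below). Single-exon pairs use the 80%-of-the-longer
  rule.
* **`c`/`k`** (containment either way) require the contained transcript's
  chain to be a *contiguous* sub-chain of the container's, boundary
  containment, and intron compatibility: no exonic base of the contained
  transcript may fall in a container intron. A single exon inside a
  reference exon is `c`.
* **`m` vs `n`**: `m` requires every reference intron to be either exactly
  matched or fully spanned by a single query exon, with no novel query
  introns; any other configuration in which a reference intron is fully
  spanned by a query exon is `n`.
* **`j`** needs the same strand and at least one shared splice-site
  coordinate (donor with donor, acceptor with acceptor).
* **`e`** (single exon partially covering an intron) uses an intrusion
  threshold: the exon must reach more than 10 bases into a reference
  intron without spanning it. The threshold is ours (configurable
  `e_intrusion`); no canonical value exists.
* **`s`** requires at least one exact intron match on the opposite strand.
  One matching intron suffices -- the code flags a likely mapping error,
  and a single anti-sense intron match is already diagnostic.
* **`p`** (possible run-on) uses a 2000-base default for "close to the
  reference but not overlapping", same strand, configurable
  (`runon_max_distance`); again no canonical value exists.
* **`r`** (repeat) requires at least 50% of the query's *exonic* bases to
  be soft-masked (lower case) in the supplied genome.
* Degenerate span-only overlaps (no exonic overlap, no intron containment
  either way) fall back to `o`/`x` by strand; they cannot arise from the
  fixture generator and are tie-handling, not a claim about biology.

`best_reference()` scores a query against every span-overlapping
reference and keeps the highest-priority code, breaking ties by larger
exonic overlap, then lexicographically smaller reference id.

Super-loci (`XLOC_*`) are connected components of exon overlap pooled
over all samples *and* the reference, merged across strands: the
opposite-strand codes `s`/`x` are assessed between members of one locus,
so a locus must be able to span both strands. Within-sample loci used by
the accuracy metrics (`cluster_loci()`) are same-strand by definition,
and strand-`.` transcripts form their own stratum there -- "." is evidence
of neither strand. TSS groups are strand-aware single linkage on the 5'
start site (genomic start on `+`, genomic end on `-`) with a 100-base
default distance; `.`-strand transcripts get no `tss_id`.

## Accuracy metrics

Six levels, each reporting sensitivity `TP/(TP+FN)` and precision
`TP/(TP+FP)`:

1. **base** -- exon bases at identical coordinates, strand-aware, per
   reference sequence;
2. **exon** -- de-duplicated exon intervals; boundaries must match
   exactly, except that the *free* outer boundaries of terminal exons may
   differ by up to the end tolerance (default 100 bases). An exon interval
   shared by several transcripts is free at an end if it is terminal in
   any of them;
3. **intron** -- de-duplicated intron intervals, exact coordinates only;
4. **intron chain** -- multi-exon transcripts whose complete chain matches
   a reference chain exactly (single-exon transcripts are excluded by
   construction);
5. **transcript** -- full exon chain match with terminal ends within the
   tolerance, plus the single-exon 80% rule;
6. **locus** -- exon-overlap clusters containing at least one
   transcript-level match.

Matching is many-to-many, so the number of *reference* features confirmed
(the sensitivity numerator) can differ from the number of *query* features
confirmed (the precision numerator). Both sides are carried in the result
(`sn_tp/sn_total`, `pr_tp/pr_total`); the conventional `TP`/`FP` columns
are defined on the query side, so `TP + FP` always equals the query
feature total, and `FN` on the reference side. Novel/missed counts use
plain overlap (a query exon is *novel* if it overlaps no reference exon
at all), which is deliberately weaker than boundary matching.

Pipeline order per sample: close-exon pre-merge on the query transfrags
(introns shorter than 5 bases are fused; `no_merge` disables), optional
single-exon dropping (`-M`/`-N` analogues), reference chain
de-duplication mirroring `-D` (so duplicated reference entries do not
double-count false negatives), then the optional `-R`/`-Q` restrictions
(reference restricted to query-overlapped transcripts and vice versa).

Multi-sample merging collapses structurally equivalent transfrags across
samples to one consensus record -- the representative with the longest
span; ties go to the earlier start, then the smaller id. Single-exon
equivalence is not transitive, so clusters are built by single linkage;
the consensus id (`TCONS_` + 8-digit counter) and `XLOC_` + 6-digit
counter are assigned in genomic order. The redundancy modes operationalize
the containment options: `C` discards contained intron-redundant
transfrags whose exonic bases stay within the container's exons; `A`
exempts those whose strand-aware 5' terminal exon does not overlap any
container exon (an alternate TSS, typically starting inside a container
intron); `X` also discards transfrags whose terminal ends stick into the
container's introns. FPKM/TPM/cov are pass-through attributes
(case-insensitive keys), formatted with six decimals, `0.000000` when
absent.

## Sequence operations

FASTA indexing is faidx-compatible (`name, length, offset, linebases,
linewidth`; the test suite checks byte equality against `samtools
faidx`), with seek-based fetches. Ragged records cannot be seek-indexed
and fall back to an in-memory copy with a warning. Case is preserved
end-to-end because soft-masking carries meaning (the repeat code).

Translation uses the standard genetic code built in code; a stop codon
renders as `"."` and terminates the output, ambiguous codons give `"X"`,
and a trailing partial codon is ignored. The CDS phase of the 5'-most
segment (transcription order) seeds the frame; a missing frame column is
treated as phase 0 with a warning. CDS extraction includes the terminal
stop codon when the segments include it -- no silent trimming. CDS status
labels are `complete` / `missing_start` / `missing_stop` / `missing_both`
with `,inframe_stop` appended when internal stops exist; the vocabulary is
ours, the conditions are the standard ones. Splice sites are read on the
transcript strand and are canonical iff the donor-acceptor pair is GT-AG,
GC-AG or AT-AC, case-insensitively (a masked splice site is still a splice
site).

Close-exon merging (`merge_close_exons`) fuses exons separated by introns
shorter than the threshold, left to right: 4 bases for the gffread-style
`-Z` transform, 5 for the comparison pre-merge. It runs before CDS
validation so that validation sees the final exon chain.

## The synthetic-data generator

`make_genome` / `make_reference` / `make_query` exist so that every
behavior above is testable without downloads. The generator emulates the
*structural* properties the methods depend on: non-overlapping gene
territories (each gene centered in its slot with 1200-base free margins,
laid out over the first 70% of each sequence, the tail kept intergenic),
multi-exon transcripts with exons of 140--240 bases and introns of
80--300 bases, planted canonical splice dinucleotides, and a complete CDS
(ATG, no in-frame stops, TAA) written through the exon boundaries so
frame bookkeeping is exercised across introns. Each perturbation op
produces a query whose class code is known by construction; the defining
property -- `best_reference` returns exactly the expected code, for all
15 codes, across seeds -- *is* the test.

What the generator does not emulate: realistic expression levels, read
noise, alternative splicing complexity beyond exon skipping, overlapping
gene territories, pseudogene annotation, or chimeric transcripts. Passing
tests therefore demonstrate the correctness of the structural logic, not
robustness to every pathology of real annotation files; the parser-level
diagnostics (orphans, mixed strands, duplicate ids, ragged FASTA) are
tested separately with hand-written degenerate inputs.

Every generator call seeds its own RNG stream explicitly and restores the
caller's state, so fixtures are reproducible and independent of test
order.

## Numerical and policy choices

* Tie-breaks are total and documented: redundancy survivor = longer
  spliced length, then earlier start, then smaller id; best reference =
  priority, then overlap, then id; trmap hits ordered by reference start,
  then id.
* Interval arithmetic is integer throughout; "overlap" always means at
  least one shared base, and book-ended intervals (gap 0) do not overlap.
* `@exons`-style interval lists render as `start-end,start-end` in
  genomic order, and the same convention is used in trmap records.
* The `.stats` layout carries the standard quantities in a documented
  format; byte-compatibility with other tools' stats files is not
  claimed. The `.tracking`/`.refmap`/`.tmap` cell formats, by contrast,
  are byte-tested.
* Problem sizes in the test suite were chosen to keep the whole suite in
  the low minutes on a laptop: fixture genomes of 30 kb with 2--6 genes,
  randomized property tests with 20--40 transcripts (500 for the interval
  tree oracle), 1000 random CDSs for the translation oracle, and sweeps of
  at most 201 points per threshold in `scripts/acceptance.R`.

## Known limitations

* Only the standard genetic code; no selenocysteine; ambiguity handling
  is N-to-X only.
* GFF3 features with multiple `Parent`s are duplicated per parent rather
  than shared.
* Reference-name remapping is a plain two-column rename; no alias
  database.
* Expression values are never estimated, only passed through.
* The streaming classifier indexes transcript *spans*; a query lying
  entirely within an intron of a reference still enumerates that
  reference (and is classified `i`), which matches the classification
  semantics but means span overlap, not exonic overlap, drives record
  emission.
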