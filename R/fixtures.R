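# Deterministic synthetic-data generators: genomes, reference annotations
# with canonical splice sites and valid CDS, and perturbed query sets with
# known expected classification codes. Every generator draws from its own
# explicitly seeded RNG stream and leaves the caller's RNG untouched.

dna_bases <- c("A", "C", "G", "T")

#' Generate a random genome
#'
#' Uppercase A/C/G/T sequences, reproducible for a fixed seed. Soft-masked
#' tracts and canonical splice dinucleotides are planted afterwards by
#' [make_reference()] / [make_query()] (see [plant_bases()]).
#'
#' @param seed Integer seed.
#' @param n_seqs Number of sequences.
#' @param lengths Integer vector of sequence lengths (recycled).
#' @param names Sequence names (default `chr1`, `chr2`, ...).
#' @return Named character vector of sequences.
#' @export
make_genome <- function(seed, n_seqs = 1L, lengths = 30000L, names = NULL) {
  lengths <- rep_len(as.integer(lengths), n_seqs)
  if (is.null(names)) names <- paste0("chr", seq_len(n_seqs))
  with_seed(seed, {
    seqs <- vapply(lengths, function(L)
      paste(sample(dna_bases, L, replace = TRUE), collapse = ""), "")
    stats::setNames(seqs, names)
  })
}

#' Overwrite genome bases at a position
#'
#' @param genome Named character vector from [make_genome()].
#' @param seqid Sequence name.
#' @param start 1-based position of the first replaced base.
#' @param replacement Replacement string.
#' @return The modified genome.
#' @export
plant_bases <- function(genome, seqid, start, replacement) {
  s <- genome[[seqid]]
  stopifnot(start >= 1L, start + nchar(replacement) - 1L <= nchar(s))
  substr(s, start, start + nchar(replacement) - 1L) <- replacement
  genome[[seqid]] <- s
  genome
}

plant_intron_sites <- function(genome, seqid, strand, intron) {
  if (strand == "-") {
    genome <- plant_bases(genome, seqid, intron[1L], "CT")
    plant_bases(genome, seqid, intron[2L] - 1L, "AC")
  } else {
    genome <- plant_bases(genome, seqid, intron[1L], "GT")
    plant_bases(genome, seqid, intron[2L] - 1L, "AG")
  }
}

complement_str <- function(s) chartr("ACGTacgt", "TGCAtgca", s)

nonstop_codons <- local({
  b <- c("T", "C", "A", "G")
  all3 <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

# margin (bases) kept free on each side of a gene inside its territory slot
territory_margin <- 1200L

#' Generate a reference annotation over a genome
#'
#' Lays out non-overlapping gene territories in the first 70\% of each
#' sequence (the remaining tail stays intergenic), builds multi-exon
#' transcripts with planted canonical GT-AG splice sites and, when
#' requested, a complete valid CDS (ATG start, no in-frame stops, TAA
#' stop) written through the exon boundaries. Additional isoforms skip one
#' internal exon each and share the gene's strand. Deterministic for a
#' fixed seed.
#'
#' @param genome Named character vector from [make_genome()].
#' @param n_genes Total number of genes (distributed round-robin over
#'   sequences).
#' @param isoforms_per_gene Isoforms per gene (extra isoforms are
#'   non-coding).
#' @param seed Integer seed.
#' @param with_cds Give the first isoform of each gene a complete CDS.
#' @param exons_per_tx Exon count of the primary isoform (>= 2; at least 4
#'   is needed by the full perturbation vocabulary of [make_query()]).
#' @return List with `set` (the [annotation_set()]), `genome` (with planted
#'   bases) and `territories` (data.frame of gene slots).
#' @export
make_reference <- function(genome, n_genes = 4L, isoforms_per_gene = 1L,
                           seed = 1L, with_cds = TRUE, exons_per_tx = 4L) {
  stopifnot(exons_per_tx >= 2L)
  seq_names <- names(genome)
  seq_of_gene <- rep_len(seq_names, n_genes)
  with_seed(seed, {
    txs <- list(); genes <- list()
    terr <- data.frame(gene_id = character(0), seqid = character(0),
                       strand = character(0), slot_start = integer(0),
                       slot_end = integer(0), primary_tx = character(0),
                       stringsAsFactors = FALSE)
    for (sq in seq_names) {
      g_here <- which(seq_of_gene == sq)
      if (!length(g_here)) next
      zone <- floor(0.7 * nchar(genome[[sq]]))
      W <- zone %/% length(g_here)
      for (j in seq_along(g_here)) {
        gi <- g_here[j]
        slot_start <- (j - 1L) * W + 1L
        slot_end <- j * W
        k <- exons_per_tx
        exon_len <- sample(140:240, k, replace = TRUE)
        intron_len <- if (k > 1L) sample(80:300, k - 1L, replace = TRUE)
          else integer(0)
        span <- sum(exon_len) + sum(intron_len)
        if (span + 2L * territory_margin > W)
          stop("gene territories do not fit on ", sq,
               "; enlarge the genome or reduce n_genes")
        strand <- if (gi %% 2L == 0L) "-" else "+"
        gstart <- slot_start + territory_margin
        ex <- matrix(0L, nrow = k, ncol = 2L)
        pos <- gstart
        for (e in seq_len(k)) {
          ex[e, ] <- c(pos, pos + exon_len[e] - 1L)
          pos <- pos + exon_len[e] + (if (e < k) intron_len[e] else 0L)
        }
        introns <- if (k > 1L)
          cbind(ex[-k, 2L] + 1L, ex[-1L, 1L] - 1L) else empty_ivmat()
        for (ii in seq_len(nrow(introns)))
          genome <- plant_intron_sites(genome, sq, strand, introns[ii, ])
        gid <- sprintf("G%03d", gi)
        cds <- NULL
        if (with_cds) {
          pl <- plant_cds(genome, sq, strand, ex)
          genome <- pl$genome
          cds <- pl$cds
        }
        tid0 <- sprintf("T%03d.1", gi)
        txs[[tid0]] <- transcript(
          tid0, sq, strand, exons = ex, cds = cds, gene_id = gid,
          gene_name = sprintf("GENE%d", gi), source = "gffx_sim",
          feature_type = "mRNA")
        iso_ids <- tid0
        if (isoforms_per_gene > 1L && k >= 3L) {
          for (iso in 2:isoforms_per_gene) {
            skip <- 1L + ((iso - 2L) %% (k - 2L)) + 1L   # internal exon
            tid <- sprintf("T%03d.%d", gi, iso)
            txs[[tid]] <- transcript(
              tid, sq, strand, exons = ex[-skip, , drop = FALSE],
              gene_id = gid, gene_name = sprintf("GENE%d", gi),
              source = "gffx_sim", feature_type = "mRNA")
            iso_ids <- c(iso_ids, tid)
          }
        }
        genes[[gid]] <- gene(gid, sq, strand, gstart,
                             max(ex[, 2L]), name = sprintf("GENE%d", gi),
                             transcript_ids = iso_ids, source = "gffx_sim")
        terr <- rbind(terr, data.frame(
          gene_id = gid, seqid = sq, strand = strand,
          slot_start = slot_start, slot_end = slot_end,
          primary_tx = tid0, stringsAsFactors = FALSE))
      }
    }
    list(set = annotation_set(unname(txs), unname(genes),
                              seqid_order = seq_names),
         genome = genome, territories = terr)
  })
}

# Write a valid coding sequence (ATG + non-stop codons + TAA) through the
# spliced exon positions of a transcript, leaving a 30-base UTR on each end.
plant_cds <- function(genome, seqid, strand, ex) {
  gpos <- unlist(lapply(seq_len(nrow(ex)), function(i)
    seq.int(ex[i, 1L], ex[i, 2L])))
  Lsp <- length(gpos)
  sp_start <- 31L
  usable <- Lsp - 60L
  n_codons <- usable %/% 3L
  stopifnot(n_codons >= 3L)
  sp_end <- sp_start + 3L * n_codons - 1L
  coding <- paste0("ATG",
                   paste(sample(nonstop_codons, n_codons - 2L,
                                replace = TRUE), collapse = ""),
                   "TAA")
  if (strand == "-") {
    # transcript position i maps to genomic position gpos[Lsp - i + 1]
    gsel <- gpos[seq.int(Lsp - sp_end + 1L, Lsp - sp_start + 1L)]
    bases <- rev(strsplit(complement_str(coding), "")[[1L]])
  } else {
    gsel <- gpos[seq.int(sp_start, sp_end)]
    bases <- strsplit(coding, "")[[1L]]
  }
  s <- genome[[seqid]]
  for (i in seq_along(gsel)) substr(s, gsel[i], gsel[i]) <- bases[i]
  genome[[seqid]] <- s
  gmin <- min(gsel); gmax <- max(gsel)
  cds <- do.call(rbind, Filter(Negate(is.null),
    lapply(seq_len(nrow(ex)), function(i) {
      s0 <- max(ex[i, 1L], gmin); e0 <- min(ex[i, 2L], gmax)
      if (e0 >= s0) c(s0, e0) else NULL
    })))
  list(genome = genome, cds = cds)
}

#' The full perturbation vocabulary, one spec per class code
#'
#' Operations applied to a reference transcript so that the resulting query
#' classifies with a known code: exact_copy/trim_ends/extend_ends (`=`),
#' drop_terminal_exon and containment_fragment (`c`), contain_reference
#' (`k`), retain_intron (`m`), retain_intron_partial (`n`), shift_intron
#' (`j`), shift_into_intron (`e`), overlap_shift (`o`), strand_flip (`s`),
#' opposite_exon (`x`), within_intron (`i`), bridge_reference (`y`),
#' downstream_offset (`p`), softmask_repeat (`r`), intergenic (`u`).
#'
#' @return List of `list(op, expected_code)` specs covering all 15 codes.
#' @export
all_code_specs <- function() {
  list(
    list(op = "exact_copy", expected_code = "="),
    list(op = "trim_ends", expected_code = "="),
    list(op = "extend_ends", expected_code = "="),
    list(op = "drop_terminal_exon", expected_code = "c"),
    list(op = "containment_fragment", expected_code = "c"),
    list(op = "contain_reference", expected_code = "k"),
    list(op = "retain_intron", expected_code = "m"),
    list(op = "retain_intron_partial", expected_code = "n"),
    list(op = "shift_intron", expected_code = "j"),
    list(op = "shift_into_intron", expected_code = "e"),
    list(op = "overlap_shift", expected_code = "o"),
    list(op = "strand_flip", expected_code = "s"),
    list(op = "opposite_exon", expected_code = "x"),
    list(op = "within_intron", expected_code = "i"),
    list(op = "bridge_reference", expected_code = "y"),
    list(op = "downstream_offset", expected_code = "p"),
    list(op = "softmask_repeat", expected_code = "r"),
    list(op = "intergenic", expected_code = "u")
  )
}

flip <- function(strand) if (strand == "+") "-" else "+"

#' Generate perturbed query transcripts with known expected codes
#'
#' Applies each perturbation spec to a reference transcript (cycling
#' through the genes) and records the expected classification code; the
#' defining property of the generator is that [best_reference()] on each
#' query returns exactly the expected code. Specs inapplicable to the
#' chosen transcript (too few exons, no room in the territory) are skipped
#' with a diagnostic.
#'
#' @param reference The list returned by [make_reference()] (`set`,
#'   `genome`, `territories`).
#' @param specs List of `list(op, expected_code)`; default
#'   [all_code_specs()].
#' @param seed Integer seed.
#' @param prefix Query id prefix.
#' @return List with `set` (query [annotation_set()]), `ledger`
#'   (data.frame id/op/expected_code/ref_id) and `genome` (soft-mask ops
#'   modify it).
#' @export
make_query <- function(reference, specs = all_code_specs(), seed = 1L,
                       prefix = "Q") {
  ref_set <- reference$set
  genome <- reference$genome
  terr <- reference$territories
  with_seed(seed, {
    txs <- list()
    ledger <- data.frame(id = character(0), op = character(0),
                         expected_code = character(0), ref_id = character(0),
                         stringsAsFactors = FALSE)
    for (si in seq_along(specs)) {
      sp <- specs[[si]]
      row <- terr[1L + (si - 1L) %% nrow(terr), ]
      t <- ref_set$transcripts[[row$primary_tx]]
      qid <- sprintf("%s_%03d", prefix, si)
      built <- build_perturbation(sp$op, t, row, genome, qid)
      if (is.null(built)) {
        warning("spec '", sp$op, "' not applicable to ", t$id, "; skipped")
        next
      }
      genome <- built$genome
      q <- built$tx
      q$gene_id <- paste0(prefix, "G_", row$gene_id)
      txs[[qid]] <- q
      ledger <- rbind(ledger, data.frame(
        id = qid, op = sp$op, expected_code = sp$expected_code,
        ref_id = t$id, stringsAsFactors = FALSE))
    }
    list(set = annotation_set(unname(txs),
                              seqid_order = ref_set$seqid_order),
         ledger = ledger, genome = genome)
  })
}

build_perturbation <- function(op, t, terr_row, genome, qid) {
  ex <- t$exons
  k <- nrow(ex)
  ii <- tx_introns(t)
  sq <- t$seqid
  L <- nchar(genome[[sq]])
  mk <- function(exons, strand = t$strand) {
    list(genome = genome,
         tx = transcript(qid, sq, strand, exons = exons,
                         source = "gffx_sim"))
  }
  switch(op,
    exact_copy = mk(ex),
    trim_ends = {
      ex2 <- ex
      ex2[1L, 1L] <- ex2[1L, 1L] + 40L
      ex2[k, 2L] <- ex2[k, 2L] - 40L
      if (ex2[1L, 1L] >= ex2[1L, 2L] || ex2[k, 1L] >= ex2[k, 2L])
        return(NULL)
      mk(ex2)
    },
    extend_ends = {
      ex2 <- ex
      ex2[1L, 1L] <- ex2[1L, 1L] - 100L
      ex2[k, 2L] <- ex2[k, 2L] + 100L
      if (ex2[1L, 1L] < terr_row$slot_start) return(NULL)
      mk(ex2)
    },
    drop_terminal_exon = if (k < 3L) NULL else
      mk(ex[-k, , drop = FALSE]),
    containment_fragment = if (k < 4L) NULL else
      mk(ex[2:(k - 1L), , drop = FALSE]),
    contain_reference = {
      a <- c(ex[1L, 1L] - 400L, ex[1L, 1L] - 301L)
      b <- c(ex[k, 2L] + 301L, ex[k, 2L] + 400L)
      if (a[1L] < terr_row$slot_start || b[2L] > terr_row$slot_end)
        return(NULL)
      mk(rbind(a, ex, b))
    },
    retain_intron = if (k < 3L) NULL else {
      fused <- rbind(ex[1L, ], c(ex[2L, 1L], ex[3L, 2L]))
      if (k > 3L) fused <- rbind(fused, ex[4:k, , drop = FALSE])
      mk(fused)
    },
    retain_intron_partial = if (k < 4L) NULL else {
      ex2 <- rbind(c(ex[1L, 1L], ex[1L, 2L] + 12L),
                   c(ex[2L, 1L] + 12L, ex[3L, 2L]),
                   ex[4:k, , drop = FALSE])
      mk(ex2)
    },
    shift_intron = if (k < 3L) NULL else {
      ex2 <- ex
      ex2[1L, 2L] <- ex2[1L, 2L] + 12L
      ex2[2L, 1L] <- ex2[2L, 1L] + 12L
      mk(ex2)
    },
    shift_into_intron = if (k < 3L) NULL else {
      intr <- ii[2L, ]
      if (intr[2L] - intr[1L] + 1L < 60L) return(NULL)
      mk(c(ex[2L, 1L], ex[2L, 2L] + 40L))
    },
    overlap_shift = {
      s0 <- ex[1L, 1L] - 200L
      if (s0 < terr_row$slot_start) return(NULL)
      mk(c(s0, ex[1L, 1L] + 50L))
    },
    strand_flip = if (k < 2L) NULL else mk(ex, strand = flip(t$strand)),
    opposite_exon = mk(c(ex[2L, 1L] + 10L, ex[2L, 2L] - 10L),
                       strand = flip(t$strand)),
    within_intron = {
      intr <- ii[1L, ]
      if (intr[2L] - intr[1L] + 1L < 70L) return(NULL)
      mk(c(intr[1L] + 20L, intr[1L] + 60L))
    },
    bridge_reference = {
      a <- c(ex[1L, 1L] - 400L, ex[1L, 1L] - 301L)
      b <- c(ex[k, 2L] + 301L, ex[k, 2L] + 400L)
      if (a[1L] < terr_row$slot_start || b[2L] > terr_row$slot_end)
        return(NULL)
      mk(rbind(a, b))
    },
    downstream_offset = {
      s0 <- ex[k, 2L] + 501L
      if (s0 + 299L > terr_row$slot_end) return(NULL)
      mk(c(s0, s0 + 299L))
    },
    softmask_repeat = {
      s0 <- L - 2000L
      seg <- c(s0, s0 + 299L)
      masked <- tolower(substr(genome[[sq]], seg[1L], seg[2L]))
      genome <- plant_bases(genome, sq, seg[1L], masked)
      mk(seg)
    },
    intergenic = {
      s0 <- L - 3000L
      mk(c(s0, s0 + 299L))
    },
    stop("unknown perturbation op '", op, "'")
  )
}

#' One-call fixture bundle
#'
#' Convenience wrapper generating a genome, a reference annotation and a
#' perturbed query set in one deterministic step.
#'
#' @param seed Integer seed.
#' @param n_seqs,lengths Passed to [make_genome()].
#' @param n_genes,isoforms_per_gene,with_cds Passed to [make_reference()].
#' @param specs Passed to [make_query()].
#' @return List with `genome`, `reference` (set), `territories`, `query`
#'   (set), `ledger`.
#' @export
make_fixture <- function(seed = 1L, n_seqs = 1L, lengths = 30000L,
                         n_genes = 4L, isoforms_per_gene = 1L,
                         with_cds = TRUE, specs = all_code_specs()) {
  genome <- make_genome(seed, n_seqs, lengths)
  ref <- make_reference(genome, n_genes = n_genes,
                        isoforms_per_gene = isoforms_per_gene,
                        seed = seed + 1L, with_cds = with_cds)
  qry <- make_query(ref, specs = specs, seed = seed + 2L)
  list(genome = qry$genome, reference = ref$set,
       territories = ref$territories, query = qry$set, ledger = qry$ledger)
}
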