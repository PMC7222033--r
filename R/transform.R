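#' Build a transcript filter specification
#'
#' Collects the gffread-style filtering predicates. A transcript survives
#' [filter_transcripts()] iff it passes every enabled predicate. Transcript
#' length is the sum of exon lengths (spliced length), not the genomic span.
#'
#' @param max_intron Discard transcripts with any intron longer than this
#'   many bases.
#' @param min_len Discard transcripts with spliced length below this.
#' @param range List or vector `(seqid, start, end[, strand])`: keep only
#'   transcripts overlapping this range (and on the strand, if given).
#' @param range_contained Require full containment within `range` instead of
#'   overlap.
#' @param drop_single_exon Discard single-exon transcripts.
#' @param coding_only Keep only transcripts with CDS features.
#' @param noncoding_only Keep only transcripts without CDS features
#'   (mutually exclusive with `coding_only`).
#' @param drop_inframe_stop Discard coding transcripts whose CDS contains an
#'   in-frame stop codon (requires a genome).
#' @param canonical_splice_only Discard multi-exon transcripts having any
#'   intron without a GT-AG / GC-AG / AT-AC splice consensus (requires a
#'   genome).
#' @param complete_cds_only Keep only transcripts with a complete valid CDS:
#'   START and STOP present, no in-frame stops, frame-consistent length
#'   (requires a genome).
#' @param drop_pseudo Discard pseudogenes and their transcripts (see
#'   [is_pseudogene()]).
#' @return A list of class `gffx_filter`.
#' @export
filter_spec <- function(max_intron = NULL, min_len = NULL, range = NULL,
                        range_contained = FALSE, drop_single_exon = FALSE,
                        coding_only = FALSE, noncoding_only = FALSE,
                        drop_inframe_stop = FALSE,
                        canonical_splice_only = FALSE,
                        complete_cds_only = FALSE, drop_pseudo = FALSE) {
  if (coding_only && noncoding_only)
    stop("coding_only and noncoding_only are mutually exclusive")
  if (!is.null(range)) {
    range <- as.list(range)
    if (length(range) < 3L) stop("range needs (seqid, start, end[, strand])")
    range <- list(seqid = as.character(range[[1L]]),
                  start = as.integer(range[[2L]]),
                  end = as.integer(range[[3L]]),
                  strand = if (length(range) >= 4L)
                    as.character(range[[4L]]) else NULL)
  }
  structure(list(max_intron = max_intron, min_len = min_len, range = range,
                 range_contained = range_contained,
                 drop_single_exon = drop_single_exon,
                 coding_only = coding_only, noncoding_only = noncoding_only,
                 drop_inframe_stop = drop_inframe_stop,
                 canonical_splice_only = canonical_splice_only,
                 complete_cds_only = complete_cds_only,
                 drop_pseudo = drop_pseudo), class = "gffx_filter")
}

#' Filter transcripts of an annotation set
#'
#' @param set A [annotation_set()].
#' @param spec A [filter_spec()].
#' @param genome Optional `gffx_faidx`; required by the sequence-based
#'   predicates (`drop_inframe_stop`, `canonical_splice_only`,
#'   `complete_cds_only`). Supplying those without a genome is a
#'   configuration error raised before any work.
#' @return The filtered set.
#' @export
filter_transcripts <- function(set, spec = filter_spec(), genome = NULL) {
  needs_genome <- spec$drop_inframe_stop || spec$canonical_splice_only ||
    spec$complete_cds_only
  if (needs_genome && is.null(genome))
    stop("this filter configuration requires a genome (see -g)")
  keep <- vapply(set$transcripts, function(t) {
    tx_passes(t, spec, genome, set$genes)
  }, NA)
  set_subset(set, names(set$transcripts)[keep])
}

tx_passes <- function(t, spec, genome, genes) {
  if (!is.null(spec$min_len) && tx_exonic_length(t) < spec$min_len)
    return(FALSE)
  if (!is.null(spec$max_intron)) {
    ii <- tx_introns(t)
    if (nrow(ii) && any(ii[, 2L] - ii[, 1L] + 1L > spec$max_intron))
      return(FALSE)
  }
  if (!is.null(spec$range)) {
    r <- spec$range
    if (t$seqid != r$seqid) return(FALSE)
    if (spec$range_contained) {
      if (t$start < r$start || t$end > r$end) return(FALSE)
    } else {
      if (t$end < r$start || t$start > r$end) return(FALSE)
    }
    if (!is.null(r$strand) && nzchar(r$strand) && r$strand != "." &&
        t$strand != r$strand) return(FALSE)
  }
  if (spec$drop_single_exon && tx_num_exons(t) < 2L) return(FALSE)
  has_cds <- nrow(t$cds) > 0L
  if (spec$coding_only && !has_cds) return(FALSE)
  if (spec$noncoding_only && has_cds) return(FALSE)
  if (spec$drop_pseudo) {
    g <- if (!is.na(t$gene_id)) genes[[t$gene_id]] else NULL
    if (is_pseudogene(t, g)) return(FALSE)
  }
  if (spec$drop_inframe_stop && has_cds) {
    st <- validate_cds(t, genome)
    if (length(st$inframe_stop_positions)) return(FALSE)
  }
  if (spec$complete_cds_only) {
    if (!has_cds) return(FALSE)
    st <- validate_cds(t, genome)
    if (!st$has_start || !st$has_stop ||
        length(st$inframe_stop_positions) || !st$frame_consistent)
      return(FALSE)
  }
  if (spec$canonical_splice_only && nrow(t$exons) > 1L) {
    ss <- splice_sites(t, genome)
    if (any(!ss$canonical | is.na(ss$canonical))) return(FALSE)
  }
  TRUE
}

pseudo_attr_keys <- c("biotype", "gene_biotype", "transcript_biotype",
                      "gene_type", "transcript_type", "pseudo")

#' Is a transcript (or its gene) annotated as a pseudogene?
#'
#' True iff the feature type contains "pseudogene" (case-insensitive), or
#' any of the attributes `biotype`, `gene_biotype`, `transcript_biotype`,
#' `gene_type`, `transcript_type` has a value containing "pseudogene", or
#' the attribute `pseudo` equals "true" -- on the transcript or its parent
#' gene.
#'
#' @param t A [transcript()].
#' @param parent_gene Optional [gene()].
#' @export
is_pseudogene <- function(t, parent_gene = NULL) {
  check <- function(feature_type, attributes) {
    if (grepl("pseudogene", feature_type, ignore.case = TRUE)) return(TRUE)
    for (k in pseudo_attr_keys) {
      hit <- which(tolower(names(attributes)) == k)
      if (!length(hit)) next
      v <- tolower(as.character(attributes[[hit[1L]]]))
      if (k == "pseudo" && v == "true") return(TRUE)
      if (grepl("pseudogene", v)) return(TRUE)
    }
    FALSE
  }
  if (check(t$feature_type, t$attributes)) return(TRUE)
  if (!is.null(parent_gene) &&
      check(parent_gene$feature_type, parent_gene$attributes)) return(TRUE)
  FALSE
}

#' Cluster transcripts into loci by exon overlap
#'
#' A locus is a connected component of the graph whose edges join
#' same-strand transcripts sharing at least one exonic base. Strand "."
#' transcripts form their own stratum (they cluster only with each other):
#' loci are same-strand by definition and "." is evidence of neither strand.
#'
#' @param set A [annotation_set()].
#' @return List of locus records (`id`, `seqid`, `strand`, `start`, `end`,
#'   `transcript_ids`, `gene_ids`), ordered genomically; ids are
#'   `LOC_` + zero-padded counter.
#' @export
cluster_loci <- function(set) {
  txs <- set$transcripts
  if (!length(txs)) return(list())
  strata <- paste(vapply(txs, function(t) t$seqid, ""),
                  vapply(txs, function(t) t$strand, ""))
  loci <- list()
  for (st in unique(strata)) {
    members <- which(strata == st)
    comp <- exon_overlap_components(txs[members])
    for (ci in unique(comp)) {
      ids <- names(txs[members])[comp == ci]
      t1 <- txs[[ids[1L]]]
      gids <- unique(stats::na.omit(vapply(txs[ids],
                                           function(t) t$gene_id, "")))
      loci[[length(loci) + 1L]] <- list(
        seqid = t1$seqid, strand = t1$strand,
        start = min(vapply(txs[ids], function(t) t$start, 1L)),
        end = max(vapply(txs[ids], function(t) t$end, 1L)),
        transcript_ids = ids, gene_ids = as.character(gids))
    }
  }
  order_key <- order(match(vapply(loci, `[[`, "", "seqid"), set$seqid_order),
                     vapply(loci, `[[`, 1L, "start"),
                     vapply(loci, `[[`, 1L, "end"))
  loci <- loci[order_key]
  for (i in seq_along(loci)) loci[[i]]$id <- sprintf("LOC_%06d", i)
  loci
}

# component labels for a list of transcripts joined by >=1 shared exonic base
exon_overlap_components <- function(txs) {
  n <- length(txs)
  if (n <= 1L) return(rep(1L, n))
  ex <- do.call(rbind, lapply(seq_len(n), function(i) {
    m <- tx_segments(txs[[i]])
    cbind(tx = i, m)
  }))
  h <- iv_hits(ex[, 2L], ex[, 3L], ex[, 2L], ex[, 3L])
  edges <- cbind(ex[h$q, 1L], ex[h$s, 1L])
  edges <- edges[edges[, 1L] < edges[, 2L], , drop = FALSE]
  components_from_edges(n, unique(edges))
}

#' Are two transcripts structurally matching?
#'
#' Matching (structural equivalence) means: multi-exon pairs share all
#' their introns (identical chains, terminal exon lengths free to differ);
#' single-exon pairs overlap by more than `se_overlap` of the longer
#' transcript's length. A single-exon vs multi-exon pair never matches.
#'
#' @param a,b Transcripts on the same seqid and strand.
#' @param se_overlap Single-exon overlap fraction threshold (default 0.8).
#' @export
transcripts_match <- function(a, b, se_overlap = 0.8) {
  if (a$seqid != b$seqid || a$strand != b$strand) return(FALSE)
  na <- tx_num_exons(a); nb <- tx_num_exons(b)
  if (na > 1L && nb > 1L)
    return(identical(tx_chain_key(a), tx_chain_key(b)))
  if (na == 1L && nb == 1L) {
    ov <- tx_exonic_overlap(a, b)
    longer <- max(tx_exonic_length(a), tx_exonic_length(b))
    return(ov > se_overlap * longer)
  }
  FALSE
}

# is `small` a contiguous sub-chain of `big`? (both intron matrices)
is_subchain <- function(small, big) {
  ns <- nrow(small); nb <- nrow(big)
  if (ns == 0L || ns > nb) return(FALSE)
  for (off in 0:(nb - ns)) {
    if (all(small[, 1L] == big[off + seq_len(ns), 1L]) &&
        all(small[, 2L] == big[off + seq_len(ns), 2L]))
      return(TRUE)
  }
  FALSE
}

#' Remove redundant transcripts
#'
#' Clusters the set into loci and discards duplicated transcripts within
#' each locus, at three levels of stringency:
#' \describe{
#'   \item{merge}{discard a transcript when another transcript has an
#'     identical intron chain and its boundaries are contained in (or equal
#'     to) the other's; single-exon transcripts contained in another
#'     single-exon transcript are likewise discarded.}
#'   \item{contain}{additionally discard shorter transcripts whose intron
#'     chain matches a contiguous part of a container's chain and whose
#'     boundaries are fully contained; contained single-exon transcripts
#'     whose exon lies within one exon of a container are also discarded.}
#'   \item{relaxed}{drop the boundary-containment requirement: an
#'     intron-chain (sub-)match suffices for multi-exon transcripts, and
#'     >80\% overlap of the longer for single-exon ones.}
#' }
#' The survivor among equals is the longer (spliced length) transcript,
#' then the earlier start, then the lexicographically smaller id.
#'
#' @param set A [annotation_set()].
#' @param mode `"merge"` (gffread -M), `"contain"` (-M -K) or `"relaxed"`
#'   (-M -K -Q).
#' @param se_overlap Single-exon overlap threshold for relaxed mode.
#' @return The reduced set.
#' @export
remove_redundant <- function(set, mode = c("merge", "contain", "relaxed"),
                             se_overlap = 0.8) {
  mode <- match.arg(mode)
  loci <- cluster_loci(set)
  keep_ids <- character(0)
  for (lc in loci) {
    txs <- set$transcripts[lc$transcript_ids]
    lens <- vapply(txs, tx_exonic_length, 1L)
    starts <- vapply(txs, function(t) t$start, 1L)
    ord <- order(-lens, starts, names(txs))
    kept <- list()
    for (i in ord) {
      t <- txs[[i]]
      dead <- FALSE
      for (u in kept) {
        if (redundant_in(u, t, mode, se_overlap)) { dead <- TRUE; break }
      }
      if (!dead) kept[[length(kept) + 1L]] <- t
    }
    keep_ids <- c(keep_ids, vapply(kept, function(t) t$id, ""))
  }
  set_subset(set, keep_ids)
}

# is t discarded as redundant against container u?
redundant_in <- function(u, t, mode, se_overlap = 0.8) {
  nt <- tx_num_exons(t); nu <- tx_num_exons(u)
  contained <- t$start >= u$start && t$end <= u$end
  if (nt > 1L && nu > 1L) {
    ti <- tx_introns(t); ui <- tx_introns(u)
    same <- nrow(ti) == nrow(ui) && is_subchain(ti, ui)
    sub <- is_subchain(ti, ui)
    return(switch(mode,
                  merge = same && contained,
                  contain = sub && contained,
                  relaxed = sub))
  }
  if (nt == 1L && nu == 1L) {
    if (mode == "relaxed") {
      ov <- tx_exonic_overlap(t, u)
      longer <- max(tx_exonic_length(t), tx_exonic_length(u))
      return(ov > se_overlap * longer)
    }
    return(contained)
  }
  if (nt == 1L && nu > 1L) {
    if (mode == "merge") return(FALSE)
    if (mode == "contain") {
      ex <- tx_segments(t)
      uex <- tx_segments(u)
      return(any(uex[, 1L] <= ex[1L, 1L] & uex[, 2L] >= ex[1L, 2L]))
    }
    return(tx_exonic_overlap(t, u) > se_overlap * tx_exonic_length(t))
  }
  FALSE
}

#' Merge very close exons
#'
#' Consecutive exons separated by an intron shorter than `min_kept_intron`
#' are fused into a single exon, iterating left to right (gffread's -Z uses
#' the default of 4; the comparison pipeline's pre-processing uses 5). CDS
#' segments are left untouched: the micro-introns this removes lie outside
#' annotated CDS in well-formed input.
#'
#' @param t A [transcript()].
#' @param min_kept_intron Smallest intron length (bases) that is preserved.
#' @return The transcript with fused exons.
#' @examples
#' t <- transcript("t", "chr1", "+", list(c(100, 200), c(204, 300)))
#' merge_close_exons(t)$exons   # one exon 100-300 (intron length 3 < 4)
#' @export
merge_close_exons <- function(t, min_kept_intron = 4L) {
  ex <- t$exons
  if (nrow(ex) < 2L) return(t)
  ks <- ex[1L, 1L]; ke <- ex[1L, 2L]
  out <- NULL
  for (i in 2:nrow(ex)) {
    gap <- ex[i, 1L] - ke - 1L
    if (gap < min_kept_intron) {
      ke <- max(ke, ex[i, 2L])
    } else {
      out <- rbind(out, c(ks, ke))
      ks <- ex[i, 1L]; ke <- ex[i, 2L]
    }
  }
  out <- rbind(out, c(ks, ke))
  t$exons <- as_ivmat(out)
  t$start <- min(t$exons[, 1L]); t$end <- max(t$exons[, 2L])
  t
}

#' Ensure a transcript has exon features
#'
#' A CDS-only transcript gains exons equal to its CDS segments; transcripts
#' that already have exons are returned unchanged.
#'
#' @param t A [transcript()].
#' @export
force_exons <- function(t) {
  if (nrow(t$exons)) return(t)
  t$exons <- t$cds
  t
}

#' Promote a childless gene to a single-exon transcript
#'
#' For single-line genes not parenting any transcripts: builds a transcript
#' with one exon spanning the entire gene.
#'
#' @param g A [gene()].
#' @export
gene_to_exon <- function(g) {
  transcript(g$id, g$seqid, g$strand, exons = c(g$start, g$end),
             gene_id = g$id, gene_name = g$name, source = g$source,
             feature_type = "transcript", attributes = g$attributes)
}
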