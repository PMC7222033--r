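#' Transcript classification codes
#'
#' The 15 single-character codes describing how a query transcript relates
#' to a reference transcript, in decreasing order of priority:
#' \tabular{ll}{
#' `=` \tab complete, exact intron chain match \cr
#' `c` \tab contained in reference (intron compatible) \cr
#' `k` \tab contains reference (reverse containment) \cr
#' `m` \tab retained intron(s), full intron chain match otherwise \cr
#' `n` \tab completely overlaps a reference intron, partial/no chain match \cr
#' `j` \tab multi-exon with at least one junction match \cr
#' `e` \tab single exon partially covering a reference intron \cr
#' `o` \tab other same-strand exonic overlap \cr
#' `s` \tab intron match on the opposite strand (likely mapping error) \cr
#' `x` \tab exonic overlap on the opposite strand \cr
#' `i` \tab fully contained within a reference intron \cr
#' `y` \tab contains a reference within its intron(s) \cr
#' `p` \tab possible polymerase run-on (close to reference, no overlap) \cr
#' `r` \tab repeat (at least 50\% of bases soft-masked) \cr
#' `u` \tab none of the above (unknown, intergenic) \cr
#' }
#' @export
class_codes <- c("=", "c", "k", "m", "n", "j", "e", "o", "s", "x", "i", "y",
                 "p", "r", "u")

#' Priority rank of a class code (1 = highest)
#' @param code Character vector of class codes.
#' @export
class_priority <- function(code) match(code, class_codes)

#' Classify a query transcript against one overlapping reference
#'
#' Returns the highest-priority code whose definition the pair satisfies,
#' evaluated in priority order. The terminal-end tolerance participates only
#' in transcript-level accuracy counting (see [compute_stats()]), not here:
#' `=` requires only the exact intron chain match (or the single-exon
#' overlap rule).
#'
#' @param q,r Query and reference transcripts sharing a seqid.
#' @param se_overlap Single-exon match threshold: shared exonic bases must
#'   exceed this fraction of the longer transcript (default 0.8).
#' @param e_intrusion Bases a single exon must extend past a reference exon
#'   boundary into an intron for code `e` (default 10).
#' @return A single class code.
#' @examples
#' r <- transcript("r", "chr1", "+", list(c(100, 200), c(300, 400)))
#' q <- transcript("q", "chr1", "+", list(c(150, 200), c(300, 360)))
#' classify_pair(q, r)   # "="
#' @export
classify_pair <- function(q, r, se_overlap = 0.8, e_intrusion = 10L) {
  if (q$seqid != r$seqid)
    stop("classify_pair requires transcripts on the same seqid")
  qi <- tx_introns(q); ri <- tx_introns(r)
  qn <- tx_num_exons(q); rn <- tx_num_exons(r)
  qex <- tx_segments(q); rex <- tx_segments(r)
  opposite <- q$strand %in% c("+", "-") && r$strand %in% c("+", "-") &&
    q$strand != r$strand
  compat <- !opposite
  ovl <- iv_intersect_width(qex, rex)
  len_q <- iv_width(qex); len_r <- iv_width(rex)

  # "=": exact intron chain match / reciprocal single-exon overlap
  if (compat) {
    if (qn > 1L && rn > 1L && nrow(qi) == nrow(ri) &&
        all(qi == ri)) return("=")
    if (qn == 1L && rn == 1L && ovl > se_overlap * max(len_q, len_r))
      return("=")
  }
  # "c": contained in reference, intron compatible
  if (compat && ovl > 0L && q$start >= r$start && q$end <= r$end &&
      iv_contains(rex, qex) &&
      (qn == 1L || is_subchain(qi, ri)))
    return("c")
  # "k": contains reference (reverse containment)
  if (compat && ovl > 0L && r$start >= q$start && r$end <= q$end &&
      iv_contains(qex, rex) &&
      (rn == 1L || is_subchain(ri, qi)))
    return("k")
  # introns of one fully covered by an exon of the other
  r_intron_in_q_exon <- if (nrow(ri)) vapply(seq_len(nrow(ri)), function(i)
    any(qex[, 1L] <= ri[i, 1L] & qex[, 2L] >= ri[i, 2L]), NA) else logical(0)
  # "m": every reference intron exactly matched or retained (spanned by one
  # query exon); no novel query introns
  if (compat && rn > 1L && any(r_intron_in_q_exon)) {
    ri_key <- paste0(ri[, 1L], "-", ri[, 2L])
    qi_key <- if (nrow(qi)) paste0(qi[, 1L], "-", qi[, 2L]) else character(0)
    matched <- ri_key %in% qi_key
    if (all(matched | r_intron_in_q_exon) && all(qi_key %in% ri_key) &&
        ovl > 0L)
      return("m")
    # "n": a reference intron is retained but the chains otherwise disagree
    if (ovl > 0L) return("n")
  }
  # "j": shares at least one splice junction, same strand
  if (compat && qn > 1L && rn > 1L &&
      (length(intersect(qi[, 1L], ri[, 1L])) ||
       length(intersect(qi[, 2L], ri[, 2L]))))
    return("j")
  # "e": single exon partially covering a reference intron
  if (compat && qn == 1L && rn > 1L && ovl > 0L && nrow(ri)) {
    intr_ov <- vapply(seq_len(nrow(ri)), function(i) {
      s <- max(qex[1L, 1L], ri[i, 1L]); e <- min(qex[1L, 2L], ri[i, 2L])
      max(0L, e - s + 1L)
    }, 1L)
    partial <- intr_ov > e_intrusion &
      !(qex[1L, 1L] <= ri[, 1L] & qex[1L, 2L] >= ri[, 2L])
    if (any(partial)) return("e")
  }
  # "o": any other same-strand exonic overlap
  if (compat && ovl > 0L) return("o")
  # "s": opposite-strand exact intron match
  if (opposite && nrow(qi) && nrow(ri)) {
    qi_key <- paste0(qi[, 1L], "-", qi[, 2L])
    ri_key <- paste0(ri[, 1L], "-", ri[, 2L])
    if (any(qi_key %in% ri_key)) return("s")
  }
  # "x": opposite-strand exonic overlap
  if (opposite && ovl > 0L) return("x")
  # "i": query fully inside one reference intron
  if (nrow(ri) && any(ri[, 1L] <= q$start & ri[, 2L] >= q$end))
    return("i")
  # "y": reference fully inside one query intron
  if (nrow(qi) && any(qi[, 1L] <= r$start & qi[, 2L] >= r$end))
    return("y")
  # degenerate span-only overlaps (no exonic overlap, no containment):
  # fall back on the generic overlap codes
  if (opposite) "x" else "o"
}

#' Classify a query transcript that overlaps no reference transcript
#'
#' Order of evaluation: repeat (`r`) when a genome is supplied and at least
#' `repeat_fraction_min` of the query's exonic bases are soft-masked
#' (lower-case); else run-on (`p`) when the nearest same-strand reference on
#' the seqid lies within `runon_max_distance`; else intergenic (`u`).
#'
#' @param q Query transcript.
#' @param reference A [annotation_set()] of reference transcripts.
#' @param genome Optional `gffx_faidx` for the soft-mask test.
#' @param repeat_fraction_min Minimum soft-masked fraction for code `r`.
#' @param runon_max_distance Maximum distance (bases) for code `p`.
#' @return `"r"`, `"p"` or `"u"`.
#' @export
classify_unmatched <- function(q, reference, genome = NULL,
                               repeat_fraction_min = 0.5,
                               runon_max_distance = 2000L) {
  if (!is.null(genome)) {
    s <- spliced_sequence(q, genome, "exons")
    n_low <- sum(utf8ToInt(s) >= utf8ToInt("a"))
    if (nchar(s) > 0L && n_low / nchar(s) >= repeat_fraction_min)
      return("r")
  }
  idx <- reference$index[[q$seqid]]
  if (!is.null(idx) && nrow(idx)) {
    strands <- vapply(reference$transcripts[idx$id],
                      function(t) t$strand, "")
    same <- strands == q$strand
    if (any(same)) {
      d <- pmax(idx$start[same] - q$end, q$start - idx$end[same], 0L)
      if (min(d) > 0L && min(d) <= runon_max_distance) return("p")
    }
  }
  "u"
}

#' Best matching reference for a query transcript
#'
#' Evaluates [classify_pair()] against every reference transcript whose
#' span overlaps the query and returns the highest-priority result; ties
#' break by larger exonic overlap in bases, then lexicographically smaller
#' reference id. Queries with no overlapping reference are routed to
#' [classify_unmatched()].
#'
#' @param q Query transcript.
#' @param reference A [annotation_set()].
#' @param genome Optional `gffx_faidx` (repeat test for unmatched queries).
#' @param ... Passed to [classify_pair()] / [classify_unmatched()].
#' @return List with `code` and `ref` (a transcript, or `NULL` for
#'   p/r/u).
#' @export
best_reference <- function(q, reference, genome = NULL, ...) {
  dots <- list(...)
  pair_args <- dots[names(dots) %in% c("se_overlap", "e_intrusion")]
  un_args <- dots[names(dots) %in% c("repeat_fraction_min",
                                     "runon_max_distance")]
  cands <- overlap_candidates(reference, q$seqid, q$start, q$end)
  if (!length(cands)) {
    code <- do.call(classify_unmatched,
                    c(list(q, reference, genome), un_args))
    return(list(code = code, ref = NULL))
  }
  codes <- vapply(cands, function(r)
    do.call(classify_pair, c(list(q, r), pair_args)), "")
  ovl <- vapply(cands, function(r) tx_exonic_overlap(q, r), 1L)
  ids <- vapply(cands, function(r) r$id, "")
  best <- order(class_priority(codes), -ovl, ids)[1L]
  list(code = unname(codes[best]), ref = cands[[best]])
}

#' Cluster queries and reference into super-loci
#'
#' A super-locus is a connected component of exon overlap over the union of
#' all query samples and the reference annotation. The merging is
#' strand-agnostic (a plus-strand query and a minus-strand reference
#' overlapping exonically share a super-locus), since the opposite-strand
#' codes s/x are assessed within a locus. Ids are `XLOC_` + zero-padded
#' counter in genomic order.
#'
#' @param queries A single [annotation_set()] or a list of them (one per
#'   sample).
#' @param reference A [annotation_set()] (may be empty).
#' @return List of super-locus records: `xloc_id`, `seqid`, `start`, `end`,
#'   `q_members` (data.frame sample/id), `ref_ids`.
#' @export
build_superloci <- function(queries, reference = NULL) {
  if (inherits(queries, "gffx_set")) queries <- list(queries)
  pool <- list(); meta <- list()
  for (si in seq_along(queries)) {
    for (t in queries[[si]]$transcripts) {
      pool[[length(pool) + 1L]] <- t
      meta[[length(meta) + 1L]] <- c(sample = si, id = t$id)
    }
  }
  n_q <- length(pool)
  if (!is.null(reference)) {
    for (t in reference$transcripts) {
      pool[[length(pool) + 1L]] <- t
      meta[[length(meta) + 1L]] <- c(sample = 0L, id = t$id)
    }
  }
  if (!length(pool)) return(list())
  seqids <- vapply(pool, function(t) t$seqid, "")
  seq_order <- unique(seqids)
  loci <- list()
  for (sq in seq_order) {
    members <- which(seqids == sq)
    comp <- exon_overlap_components(pool[members])
    for (ci in unique(comp)) {
      sel <- members[comp == ci]
      q_sel <- sel[sel <= n_q]
      r_sel <- sel[sel > n_q]
      loci[[length(loci) + 1L]] <- list(
        seqid = sq,
        start = min(vapply(pool[sel], function(t) t$start, 1L)),
        end = max(vapply(pool[sel], function(t) t$end, 1L)),
        q_members = data.frame(
          sample = vapply(meta[q_sel], function(m) as.integer(m["sample"]),
                          1L),
          id = vapply(meta[q_sel], function(m) m[["id"]], ""),
          stringsAsFactors = FALSE),
        ref_ids = vapply(meta[r_sel], function(m) m[["id"]], ""))
    }
  }
  ord <- order(match(vapply(loci, `[[`, "", "seqid"), seq_order),
               vapply(loci, `[[`, 1L, "start"),
               vapply(loci, `[[`, 1L, "end"))
  loci <- loci[ord]
  for (i in seq_along(loci)) loci[[i]]$xloc_id <- sprintf("XLOC_%06d", i)
  loci
}

#' Group transcripts by transcription start site
#'
#' The strand-aware start site is the genomic start on "+" and the genomic
#' end on "-". Within each strand, transcripts chain into one group by
#' single linkage: successive sorted starts differing by at most `d` bases
#' join the same group. Strand "." transcripts receive no group
#' (`NA`).
#'
#' @param txs List of transcripts (typically the members of one
#'   super-locus).
#' @param d Maximum start-site distance for grouping (default 100).
#' @return Integer vector of local group numbers, named by transcript id
#'   (`NA` for strand ".").
#' @export
assign_tss <- function(txs, d = 100L) {
  ids <- vapply(txs, function(t) t$id, "")
  strand <- vapply(txs, function(t) t$strand, "")
  tss <- ifelse(strand == "+",
                vapply(txs, function(t) t$start, 1L),
                vapply(txs, function(t) t$end, 1L))
  out <- stats::setNames(rep(NA_integer_, length(txs)), ids)
  grp <- 0L
  for (st in c("+", "-")) {
    sel <- which(strand == st)
    if (!length(sel)) next
    ord <- sel[order(tss[sel])]
    prev <- NULL
    for (i in ord) {
      if (is.null(prev) || tss[i] - tss[prev] > d) grp <- grp + 1L
      out[ids[i]] <- grp
      prev <- i
    }
  }
  out
}
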