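#' Options for the comparison pipeline
#'
#' @param restrict_ref Consider only reference transcripts that overlap any
#'   query transfrag (sensitivity correction, gffcompare -R).
#' @param restrict_query Consider only query transcripts overlapping the
#'   reference (precision correction, -Q).
#' @param drop_single_exon Ignore single-exon transfrags and reference
#'   transcripts (-M).
#' @param drop_single_exon_ref Ignore single-exon reference transcripts
#'   (-N).
#' @param end_tolerance Maximum distance (bases) allowed from the free ends
#'   of terminal exons when assessing exon and transcript accuracy
#'   (default 100, -e).
#' @param tss_distance Maximum distance for grouping transcription start
#'   sites (default 100, -d).
#' @param no_merge Disable close-exon merging; by default query exons
#'   separated by introns shorter than `merge_min_intron` bases are fused
#'   before comparison.
#' @param merge_min_intron Smallest intron preserved by the close-exon
#'   pre-merge (default 5).
#' @param se_overlap Single-exon transcript-match threshold as a fraction
#'   of the longer transcript (default 0.8).
#' @return List of class `gffx_cmp_opts`.
#' @export
compare_opts <- function(restrict_ref = FALSE, restrict_query = FALSE,
                         drop_single_exon = FALSE,
                         drop_single_exon_ref = FALSE,
                         end_tolerance = 100L, tss_distance = 100L,
                         no_merge = FALSE, merge_min_intron = 5L,
                         se_overlap = 0.8) {
  structure(list(restrict_ref = restrict_ref,
                 restrict_query = restrict_query,
                 drop_single_exon = drop_single_exon,
                 drop_single_exon_ref = drop_single_exon_ref,
                 end_tolerance = as.integer(end_tolerance),
                 tss_distance = as.integer(tss_distance),
                 no_merge = no_merge,
                 merge_min_intron = as.integer(merge_min_intron),
                 se_overlap = se_overlap), class = "gffx_cmp_opts")
}

#' Transcript-level match test
#'
#' A full exon chain match: all introns identical and the outer boundaries
#' of the terminal exons within `end_tolerance` bases of the reference; or,
#' for two single-exon transcripts, exonic overlap above `se_overlap` of
#' the longer one.
#'
#' @param q,r Transcripts.
#' @param end_tolerance Terminal free-end slack in bases (default 100).
#' @param se_overlap Single-exon overlap fraction threshold (default 0.8).
#' @export
tx_level_match <- function(q, r, end_tolerance = 100L, se_overlap = 0.8) {
  if (q$seqid != r$seqid) return(FALSE)
  if (q$strand %in% c("+", "-") && r$strand %in% c("+", "-") &&
      q$strand != r$strand) return(FALSE)
  qn <- tx_num_exons(q); rn <- tx_num_exons(r)
  if (qn > 1L && rn > 1L) {
    qi <- tx_introns(q); ri <- tx_introns(r)
    return(nrow(qi) == nrow(ri) && all(qi == ri) &&
             abs(q$start - r$start) <= end_tolerance &&
             abs(q$end - r$end) <= end_tolerance)
  }
  if (qn == 1L && rn == 1L) {
    ov <- tx_exonic_overlap(q, r)
    return(ov > se_overlap * max(tx_exonic_length(q), tx_exonic_length(r)))
  }
  FALSE
}

# ---- feature collection helpers ------------------------------------------

# distinct exons with terminal free-end flags (ORed over transcripts)
collect_exons <- function(set) {
  if (!length(set$transcripts))
    return(data.frame(seqid = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      start_free = logical(0), end_free = logical(0)))
  rows <- lapply(set$transcripts, function(t) {
    ex <- tx_segments(t)
    n <- nrow(ex)
    data.frame(seqid = t$seqid, strand = t$strand,
               start = ex[, 1L], end = ex[, 2L],
               start_free = seq_len(n) == 1L,
               end_free = seq_len(n) == n,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) return(data.frame())
  key <- paste(df$seqid, df$strand, df$start, df$end)
  agg_sf <- tapply(df$start_free, key, any)
  agg_ef <- tapply(df$end_free, key, any)
  out <- df[!duplicated(key), c("seqid", "strand", "start", "end")]
  k2 <- paste(out$seqid, out$strand, out$start, out$end)
  out$start_free <- as.logical(agg_sf[k2])
  out$end_free <- as.logical(agg_ef[k2])
  rownames(out) <- NULL
  out
}

collect_introns <- function(set) {
  rows <- lapply(set$transcripts, function(t) {
    ii <- tx_introns(t)
    if (!nrow(ii)) return(NULL)
    data.frame(seqid = t$seqid, strand = t$strand,
               start = ii[, 1L], end = ii[, 2L], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(df))
    return(data.frame(seqid = character(0), strand = character(0),
                      start = integer(0), end = integer(0)))
  df <- df[!duplicated(paste(df$seqid, df$strand, df$start, df$end)), ]
  rownames(df) <- NULL
  df
}

# exon-level boundary rule: starts/ends equal, or both free and within e
exon_feature_match <- function(qdf, rdf, e) {
  matched_q <- logical(nrow(qdf))
  matched_r <- logical(nrow(rdf))
  novel_q <- rep(TRUE, nrow(qdf))
  missed_r <- rep(TRUE, nrow(rdf))
  if (!nrow(qdf) || !nrow(rdf))
    return(list(matched_q = matched_q, matched_r = matched_r,
                novel_q = novel_q, missed_r = missed_r))
  strata <- unique(rbind(qdf[c("seqid", "strand")], rdf[c("seqid", "strand")]))
  for (i in seq_len(nrow(strata))) {
    qs <- which(qdf$seqid == strata$seqid[i] & qdf$strand == strata$strand[i])
    rs <- which(rdf$seqid == strata$seqid[i] & rdf$strand == strata$strand[i])
    if (!length(qs) || !length(rs)) next
    h <- iv_hits(qdf$start[qs], qdf$end[qs], rdf$start[rs], rdf$end[rs],
                 maxgap = e)
    for (k in seq_len(nrow(h))) {
      qi <- qs[h$q[k]]; ri <- rs[h$s[k]]
      s_ok <- qdf$start[qi] == rdf$start[ri] ||
        (qdf$start_free[qi] && rdf$start_free[ri] &&
           abs(qdf$start[qi] - rdf$start[ri]) <= e)
      e_ok <- qdf$end[qi] == rdf$end[ri] ||
        (qdf$end_free[qi] && rdf$end_free[ri] &&
           abs(qdf$end[qi] - rdf$end[ri]) <= e)
      if (s_ok && e_ok) {
        matched_q[qi] <- TRUE
        matched_r[ri] <- TRUE
      }
      if (qdf$end[qi] >= rdf$start[ri] && qdf$start[qi] <= rdf$end[ri]) {
        novel_q[qi] <- FALSE
        missed_r[ri] <- FALSE
      }
    }
  }
  list(matched_q = matched_q, matched_r = matched_r,
       novel_q = novel_q, missed_r = missed_r)
}

level_row <- function(level, sn_tp, sn_total, pr_tp, pr_total) {
  data.frame(level = level, sn_tp = sn_tp, sn_total = sn_total,
             pr_tp = pr_tp, pr_total = pr_total,
             TP = pr_tp, FN = sn_total - sn_tp, FP = pr_total - pr_tp,
             sensitivity = if (sn_total > 0L) sn_tp / sn_total else NA_real_,
             precision = if (pr_total > 0L) pr_tp / pr_total else NA_real_,
             stringsAsFactors = FALSE)
}

# reference-side deduplication mirroring query -D: one survivor (longest
# span) per distinct multi-exon intron chain
dedup_chains <- function(set) {
  txs <- set$transcripts
  keys <- vapply(txs, function(t)
    paste(t$seqid, t$strand, tx_chain_key(t)), "")
  multi <- vapply(txs, function(t) tx_num_exons(t) > 1L, NA)
  drop <- character(0)
  for (k in unique(keys[multi])) {
    grp <- names(txs)[multi & keys == k]
    if (length(grp) < 2L) next
    spans <- vapply(txs[grp], function(t) t$end - t$start + 1L, 1L)
    starts <- vapply(txs[grp], function(t) t$start, 1L)
    surv <- grp[order(-spans, starts, grp)][1L]
    drop <- c(drop, setdiff(grp, surv))
  }
  if (!length(drop)) set else set_subset(set, setdiff(names(txs), drop))
}

span_overlaps_set <- function(t, other) {
  idx <- other$index[[t$seqid]]
  !is.null(idx) && nrow(idx) &&
    any(idx$start <= t$end & idx$end >= t$start)
}

# ---- the six-level statistics --------------------------------------------

#' Compute six-level accuracy statistics
#'
#' Compares one or more query samples against a reference annotation and
#' reports sensitivity `TP/(TP+FN)` and precision `TP/(TP+FP)` at the base,
#' exon, intron, intron-chain, transcript and locus levels, plus novel and
#' missed exon/intron/locus counts. Matching is many-to-many, so the TP for
#' the sensitivity side (reference features confirmed) can differ from the
#' TP on the precision side (query features confirmed); both are reported.
#'
#' Levels: base counts exon bases at identical coordinates (strand-aware);
#' exon and intron levels compare de-duplicated interval sets (exact
#' boundaries for introns, terminal free ends within `end_tolerance` for
#' exons); intron-chain counts multi-exon transcripts whose full chain
#' exactly matches a reference chain; transcript additionally constrains
#' terminal ends to `end_tolerance` and admits single-exon matches above
#' `se_overlap` of the longer transcript; locus counts exon-overlap
#' clusters with at least one transcript-level match.
#'
#' @param queries A [annotation_set()] or list of them (one per sample).
#' @param reference Reference [annotation_set()].
#' @param opts A [compare_opts()].
#' @return Object of class `gffx_stats`: per-sample level tables and
#'   novel/missed counts.
#' @export
compute_stats <- function(queries, reference, opts = compare_opts()) {
  if (inherits(queries, "gffx_set")) queries <- list(queries)
  if (is.null(names(queries)) || any(!nzchar(names(queries))))
    names(queries) <- sprintf("q%d", seq_along(queries))
  samples <- lapply(names(queries), function(nm) {
    one_sample_stats(queries[[nm]], reference, opts, nm)
  })
  names(samples) <- names(queries)
  structure(list(samples = samples, opts = opts), class = "gffx_stats")
}

one_sample_stats <- function(query, reference, opts, name) {
  # close-exon pre-merge on the query transfrags
  if (!opts$no_merge) {
    query <- annotation_set(
      lapply(query$transcripts, merge_close_exons,
             min_kept_intron = opts$merge_min_intron),
      query$genes, seqid_order = query$seqid_order)
  }
  ref <- reference
  if (opts$drop_single_exon) {
    query <- set_subset(query, names(which(vapply(
      query$transcripts, function(t) tx_num_exons(t) > 1L, NA))))
    ref <- set_subset(ref, names(which(vapply(
      ref$transcripts, function(t) tx_num_exons(t) > 1L, NA))))
  }
  if (opts$drop_single_exon_ref) {
    ref <- set_subset(ref, names(which(vapply(
      ref$transcripts, function(t) tx_num_exons(t) > 1L, NA))))
  }
  ref <- dedup_chains(ref)
  if (opts$restrict_ref) {
    keep <- vapply(ref$transcripts, span_overlaps_set, NA, other = query)
    ref <- set_subset(ref, names(ref$transcripts)[keep])
  }
  if (opts$restrict_query) {
    keep <- vapply(query$transcripts, span_overlaps_set, NA, other = ref)
    query <- set_subset(query, names(query$transcripts)[keep])
  }

  lv <- list()

  # base level: strand-aware per-coordinate exon coverage
  qex_all <- collect_exons(query)
  rex_all <- collect_exons(ref)
  strata <- unique(rbind(qex_all[c("seqid", "strand")],
                         rex_all[c("seqid", "strand")]))
  tp_b <- 0L; q_b <- 0L; r_b <- 0L
  for (i in seq_len(nrow(strata))) {
    qm <- qex_all[qex_all$seqid == strata$seqid[i] &
                    qex_all$strand == strata$strand[i], ]
    rm_ <- rex_all[rex_all$seqid == strata$seqid[i] &
                     rex_all$strand == strata$strand[i], ]
    qiv <- iv_reduce(as_ivmat(qm[c("start", "end")]))
    riv <- iv_reduce(as_ivmat(rm_[c("start", "end")]))
    tp_b <- tp_b + iv_intersect_width(qiv, riv)
    q_b <- q_b + iv_width(qiv)
    r_b <- r_b + iv_width(riv)
  }
  lv$base <- level_row("base", tp_b, r_b, tp_b, q_b)

  # exon level
  em <- exon_feature_match(qex_all, rex_all, opts$end_tolerance)
  lv$exon <- level_row("exon", sum(em$matched_r), nrow(rex_all),
                       sum(em$matched_q), nrow(qex_all))
  novel_exons <- sum(em$novel_q)
  missed_exons <- sum(em$missed_r)

  # intron level (exact boundaries)
  qin <- collect_introns(query)
  rin <- collect_introns(ref)
  qkey <- paste(qin$seqid, qin$strand, qin$start, qin$end)
  rkey <- paste(rin$seqid, rin$strand, rin$start, rin$end)
  lv$intron <- level_row("intron", sum(rkey %in% qkey), nrow(rin),
                         sum(qkey %in% rkey), nrow(qin))
  ih <- intron_overlap_flags(qin, rin)
  novel_introns <- sum(ih$novel_q)
  missed_introns <- sum(ih$missed_r)

  # intron chain level (multi-exon transcripts only)
  qmulti <- Filter(function(t) tx_num_exons(t) > 1L, query$transcripts)
  rmulti <- Filter(function(t) tx_num_exons(t) > 1L, ref$transcripts)
  qchain <- vapply(qmulti, function(t)
    paste(t$seqid, t$strand, tx_chain_key(t)), "")
  rchain <- vapply(rmulti, function(t)
    paste(t$seqid, t$strand, tx_chain_key(t)), "")
  lv$intron_chain <- level_row("intron_chain",
                               sum(rchain %in% qchain), length(rmulti),
                               sum(qchain %in% rchain), length(qmulti))

  # transcript level
  q_matched <- vapply(query$transcripts, function(t) {
    any(vapply(overlap_candidates(ref, t$seqid, t$start, t$end),
               function(r) tx_level_match(t, r, opts$end_tolerance,
                                          opts$se_overlap), NA))
  }, NA)
  r_matched <- vapply(ref$transcripts, function(t) {
    any(vapply(overlap_candidates(query, t$seqid, t$start, t$end),
               function(r) tx_level_match(r, t, opts$end_tolerance,
                                          opts$se_overlap), NA))
  }, NA)
  lv$transcript <- level_row("transcript", sum(r_matched),
                             length(r_matched), sum(q_matched),
                             length(q_matched))

  # locus level
  q_loci <- cluster_loci(query)
  r_loci <- cluster_loci(ref)
  q_hit <- vapply(q_loci, function(l) any(q_matched[l$transcript_ids]), NA)
  r_hit <- vapply(r_loci, function(l) any(r_matched[l$transcript_ids]), NA)
  lv$locus <- level_row("locus", sum(r_hit), length(r_loci),
                        sum(q_hit), length(q_loci))
  novel_loci <- sum(vapply(q_loci, function(l) {
    !any(vapply(query$transcripts[l$transcript_ids], function(t)
      locus_exonic_overlap(t, ref), NA))
  }, NA))
  missed_loci <- sum(vapply(r_loci, function(l) {
    !any(vapply(ref$transcripts[l$transcript_ids], function(t)
      locus_exonic_overlap(t, query), NA))
  }, NA))

  list(name = name,
       n_query = length(query$transcripts),
       n_query_multi = length(qmulti),
       n_ref = length(ref$transcripts),
       n_ref_multi = length(rmulti),
       levels = do.call(rbind, c(unname(lv), list(make.row.names = FALSE))),
       novel_exons = novel_exons, missed_exons = missed_exons,
       novel_introns = novel_introns, missed_introns = missed_introns,
       novel_loci = novel_loci, missed_loci = missed_loci)
}

intron_overlap_flags <- function(qin, rin) {
  novel_q <- rep(TRUE, nrow(qin))
  missed_r <- rep(TRUE, nrow(rin))
  if (nrow(qin) && nrow(rin)) {
    strata <- unique(rbind(qin[c("seqid", "strand")],
                           rin[c("seqid", "strand")]))
    for (i in seq_len(nrow(strata))) {
      qs <- which(qin$seqid == strata$seqid[i] &
                    qin$strand == strata$strand[i])
      rs <- which(rin$seqid == strata$seqid[i] &
                    rin$strand == strata$strand[i])
      if (!length(qs) || !length(rs)) next
      h <- iv_hits(qin$start[qs], qin$end[qs], rin$start[rs], rin$end[rs])
      novel_q[qs[unique(h$q)]] <- FALSE
      missed_r[rs[unique(h$s)]] <- FALSE
    }
  }
  list(novel_q = novel_q, missed_r = missed_r)
}

# does any same-strand transcript of `other` share an exonic base with t?
locus_exonic_overlap <- function(t, other) {
  cands <- overlap_candidates(other, t$seqid, t$start, t$end)
  for (o in cands) {
    if (o$strand == t$strand && tx_exonic_overlap(t, o) > 0L) return(TRUE)
  }
  FALSE
}

#' @export
print.gffx_stats <- function(x, ...) {
  writeLines(format_stats_text(x))
  invisible(x)
}

format_stats_text <- function(x) {
  out <- c("# gffx transcript accuracy report", "#")
  for (s in x$samples) {
    out <- c(out,
             sprintf("#= Sample %s: %d query transfrags (%d multi-exon)",
                     s$name, s$n_query, s$n_query_multi),
             sprintf("#  Reference: %d transcripts (%d multi-exon)",
                     s$n_ref, s$n_ref_multi),
             sprintf("%-22s %11s | %s", "", "Sensitivity", "Precision"))
    labels <- c(base = "Base level", exon = "Exon level",
                intron = "Intron level", intron_chain = "Intron chain level",
                transcript = "Transcript level", locus = "Locus level")
    for (i in seq_len(nrow(s$levels))) {
      r <- s$levels[i, ]
      out <- c(out, sprintf("%-22s %10.1f%% | %9.1f%%",
                            labels[[r$level]],
                            100 * (r$sensitivity %||% NA_real_),
                            100 * (r$precision %||% NA_real_)))
    }
    out <- c(out,
             sprintf("  Missed exons:   %7d/%d", s$missed_exons,
                     max(s$levels$sn_total[s$levels$level == "exon"], 0L)),
             sprintf("  Novel exons:    %7d/%d", s$novel_exons,
                     max(s$levels$pr_total[s$levels$level == "exon"], 0L)),
             sprintf("  Missed introns: %7d/%d", s$missed_introns,
                     max(s$levels$sn_total[s$levels$level == "intron"], 0L)),
             sprintf("  Novel introns:  %7d/%d", s$novel_introns,
                     max(s$levels$pr_total[s$levels$level == "intron"], 0L)),
             sprintf("  Missed loci:    %7d/%d", s$missed_loci,
                     max(s$levels$sn_total[s$levels$level == "locus"], 0L)),
             sprintf("  Novel loci:     %7d/%d", s$novel_loci,
                     max(s$levels$pr_total[s$levels$level == "locus"], 0L)),
             "#")
  }
  out
}

#' Write the accuracy report to a .stats file
#' @param stats A `gffx_stats` from [compute_stats()].
#' @param file Output path.
#' @export
write_stats <- function(stats, file) {
  writeLines(format_stats_text(stats), file)
  invisible(file)
}

#' Discard duplicate query transfrags within a sample
#'
#' Mode `"D"` keeps one survivor (the longest span) per distinct multi-exon
#' intron chain. Mode `"S"` is stricter about what counts as duplicated: a
#' transfrag is discarded only when a same-chain transfrag exists whose
#' boundaries fully contain it (larger or identical).
#'
#' @param set A [annotation_set()].
#' @param mode `"D"` or `"S"`.
#' @return The de-duplicated set.
#' @export
dedup_queries <- function(set, mode = c("D", "S")) {
  mode <- match.arg(mode)
  if (mode == "D") return(dedup_chains(set))
  txs <- set$transcripts
  keys <- vapply(txs, function(t)
    paste(t$seqid, t$strand, tx_chain_key(t)), "")
  multi <- vapply(txs, function(t) tx_num_exons(t) > 1L, NA)
  drop <- character(0)
  for (k in unique(keys[multi])) {
    grp <- names(txs)[multi & keys == k]
    if (length(grp) < 2L) next
    for (a in grp) for (b in grp) {
      if (a == b || a %in% drop) next
      ta <- txs[[a]]; tb <- txs[[b]]
      contained <- ta$start >= tb$start && ta$end <= tb$end
      bigger <- (tb$end - tb$start) > (ta$end - ta$start) ||
        ((tb$end - tb$start) == (ta$end - ta$start) && b < a)
      if (contained && bigger && !(b %in% drop)) drop <- c(drop, a)
    }
  }
  if (!length(drop)) set else set_subset(set, setdiff(names(txs), drop))
}
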