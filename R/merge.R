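# strand-aware 5' terminal exon
five_prime_exon <- function(t) {
  ex <- tx_segments(t)
  if (t$strand == "-") ex[nrow(ex), , drop = FALSE] else ex[1L, , drop = FALSE]
}

fmt_expr <- function(t, key) {
  v <- suppressWarnings(as.numeric(get_attr(t, key)))
  sprintf("%.6f", if (is.na(v)) 0 else v)
}

#' Merge structurally equivalent transfrags across samples
#'
#' Builds the union of all transfrags: transfrags with the same exact
#' intron chain (or, for single-exon transfrags, overlapping by more than
#' `se_overlap` of the longer) collapse to one consensus record -- the
#' representative with the longest span -- with a fresh consensus id.
#' Redundancy modes tighten the union further:
#' \describe{
#'   \item{union}{collapse equivalent transfrags only.}
#'   \item{C}{also discard matching and contained transfrags (intron chain
#'     matching a contiguous part of the container, boundaries and exonic
#'     bases contained).}
#'   \item{A}{like C but keeps contained transfrags whose strand-aware 5'
#'     terminal exon does not overlap a container exon (alternate TSS).}
#'   \item{X}{like C but also discards contained transfrags whose terminal
#'     ends stick out within the container's introns.}
#' }
#' With `keep_ref_matches` a redundant transfrag structurally matching a
#' reference transcript is never discarded.
#'
#' @param queries List of [annotation_set()] (one per sample), optionally
#'   named.
#' @param reference Optional reference [annotation_set()] (class codes and
#'   the `keep_ref_matches` guard need it).
#' @param mode `"union"`, `"C"`, `"A"` or `"X"`.
#' @param keep_ref_matches Protect transfrags matching a reference.
#' @param tcons_prefix Consensus id prefix (default `"TCONS"`).
#' @param se_overlap Single-exon equivalence threshold.
#' @param genome Optional `gffx_faidx` for p/r/u classification.
#' @return List with `combined` (consensus [annotation_set()]) and
#'   `tracking` (data.frame, one row per structurally distinct transfrag).
#' @export
merge_samples <- function(queries, reference = NULL,
                          mode = c("union", "C", "A", "X"),
                          keep_ref_matches = FALSE, tcons_prefix = "TCONS",
                          se_overlap = 0.8, genome = NULL) {
  mode <- match.arg(mode)
  if (inherits(queries, "gffx_set")) queries <- list(queries)
  if (is.null(names(queries)) || any(!nzchar(names(queries))))
    names(queries) <- sprintf("q%d", seq_along(queries))
  pool <- list(); sample_of <- integer(0)
  for (si in seq_along(queries)) {
    for (t in queries[[si]]$transcripts) {
      pool[[length(pool) + 1L]] <- t
      sample_of <- c(sample_of, si)
    }
  }
  n <- length(pool)
  if (!n)
    return(list(combined = annotation_set(),
                tracking = empty_tracking(length(queries))))

  # equivalence clusters: exact chain groups + single-linkage single-exon
  strata <- vapply(pool, function(t) paste(t$seqid, t$strand), "")
  chains <- vapply(pool, function(t) tx_chain_key(t) %||% NA_character_, "")
  edges <- NULL
  for (st in unique(strata)) {
    sel <- which(strata == st)
    multi <- sel[!is.na(chains[sel])]
    if (length(multi) > 1L) {
      for (grp in split(multi, chains[multi])) {
        if (length(grp) > 1L)
          edges <- rbind(edges, cbind(grp[-length(grp)], grp[-1L]))
      }
    }
    single <- sel[is.na(chains[sel])]
    if (length(single) > 1L) {
      sm <- do.call(rbind, lapply(pool[single], function(t)
        c(t$start, t$end)))
      h <- iv_hits(sm[, 1L], sm[, 2L], sm[, 1L], sm[, 2L])
      h <- h[h$q < h$s, , drop = FALSE]
      for (k in seq_len(nrow(h))) {
        a <- pool[[single[h$q[k]]]]; b <- pool[[single[h$s[k]]]]
        ov <- tx_exonic_overlap(a, b)
        if (ov > se_overlap * max(tx_exonic_length(a), tx_exonic_length(b)))
          edges <- rbind(edges, cbind(single[h$q[k]], single[h$s[k]]))
      }
    }
  }
  comp <- components_from_edges(n, if (is.null(edges))
    matrix(integer(0), ncol = 2L) else edges)

  # consensus representative per cluster: longest span, earlier start, id
  reps <- vapply(split(seq_len(n), comp), function(members) {
    spans <- vapply(pool[members], function(t) t$end - t$start + 1L, 1L)
    starts <- vapply(pool[members], function(t) t$start, 1L)
    ids <- vapply(pool[members], function(t) t$id, "")
    members[order(-spans, starts, ids)][1L]
  }, 1L)

  matches_ref <- function(t) {
    !is.null(reference) && length(overlap_candidates(
      reference, t$seqid, t$start, t$end)) &&
      any(vapply(overlap_candidates(reference, t$seqid, t$start, t$end),
                 function(r) transcripts_match(t, r, se_overlap), NA))
  }

  keep_rep <- rep(TRUE, length(reps))
  if (mode != "union") {
    rep_tx <- pool[reps]
    ord <- order(-vapply(rep_tx, function(t) t$end - t$start + 1L, 1L))
    for (oi in seq_along(ord)) {
      i <- ord[oi]
      t <- rep_tx[[i]]
      if (!keep_rep[i]) next
      for (oj in seq_len(oi - 1L)) {
        j <- ord[oj]
        if (!keep_rep[j]) next
        u <- rep_tx[[j]]
        if (u$seqid != t$seqid || u$strand != t$strand) next
        if (contained_redundant(t, u, mode)) {
          if (keep_ref_matches && matches_ref(t)) next
          keep_rep[i] <- FALSE
          break
        }
      }
    }
  }

  clusters <- split(seq_len(n), comp)[keep_rep]
  reps <- reps[keep_rep]

  # consensus ids in genomic order
  seq_first <- unique(vapply(pool, function(t) t$seqid, ""))
  ordc <- order(match(vapply(pool[reps], function(t) t$seqid, ""),
                      seq_first),
                vapply(pool[reps], function(t) t$start, 1L),
                vapply(pool[reps], function(t) t$end, 1L))
  clusters <- clusters[ordc]
  reps <- reps[ordc]

  combined_tx <- list()
  for (ci in seq_along(reps)) {
    t <- pool[[reps[ci]]]
    tid <- sprintf("%s_%08d", tcons_prefix, ci)
    t2 <- t
    t2$id <- tid
    t2$attributes <- list()
    combined_tx[[length(combined_tx) + 1L]] <- t2
  }
  combined <- annotation_set(combined_tx, seqid_order = seq_first)

  loci <- build_superloci(list(combined), reference)
  xloc_of <- character(0)
  for (lc in loci) {
    members <- lc$q_members$id
    xloc_of[members] <- lc$xloc_id
  }

  rows <- lapply(seq_along(reps), function(ci) {
    t <- pool[[reps[ci]]]
    tid <- sprintf("%s_%08d", tcons_prefix, ci)
    if (!is.null(reference)) {
      br <- best_reference(t, reference, genome)
      refcell <- if (!is.null(br$ref))
        paste0(br$ref$gene_name %||% br$ref$gene_id %||% "-", "|",
               br$ref$id) else "-"
      code <- br$code
    } else {
      refcell <- "-"; code <- "-"
    }
    cells <- vapply(seq_along(queries), function(si) {
      members <- clusters[[ci]][sample_of[clusters[[ci]]] == si]
      if (!length(members)) return("-")
      spans <- vapply(pool[members], function(x) x$end - x$start + 1L, 1L)
      m <- pool[[members[order(-spans)][1L]]]
      sprintf("q%d:%s|%s|%d|%s|%s|%s|%d", si,
              m$gene_id %||% m$id, m$id, tx_num_exons(m),
              fmt_expr(m, "FPKM"), fmt_expr(m, "TPM"), fmt_expr(m, "cov"),
              tx_exonic_length(m))
    }, "")
    c(tcons_id = tid, xloc_id = xloc_of[tid] %||% "-", ref = refcell,
      class_code = code, cells)
  })
  tracking <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tracking) <- c("tcons_id", "xloc_id", "ref", "class_code",
                       names(queries))
  list(combined = combined, tracking = tracking)
}

empty_tracking <- function(n_samples) {
  df <- data.frame(tcons_id = character(0), xloc_id = character(0),
                   ref = character(0), class_code = character(0),
                   stringsAsFactors = FALSE)
  for (i in seq_len(n_samples)) df[[sprintf("q%d", i)]] <- character(0)
  df
}

# is t a contained intron-redundant transfrag of container u (merge modes)?
contained_redundant <- function(t, u, mode) {
  if (!(t$start >= u$start && t$end <= u$end)) return(FALSE)
  nt <- tx_num_exons(t); nu <- tx_num_exons(u)
  tex <- tx_segments(t); uex <- tx_segments(u)
  if (nt == 1L) {
    contained_in_exon <- any(uex[, 1L] <= tex[1L, 1L] &
                               uex[, 2L] >= tex[1L, 2L])
    if (mode == "X") return(iv_intersect_width(tex, uex) > 0L)
    if (!contained_in_exon) return(FALSE)
    if (mode == "A") return(TRUE)  # its only exon overlaps a container exon
    return(TRUE)
  }
  if (nu == 1L) return(FALSE)
  ti <- tx_introns(t); ui <- tx_introns(u)
  if (!is_subchain(ti, ui)) return(FALSE)
  compat <- iv_contains(uex, tex)   # no ends sticking into container introns
  ok <- switch(mode,
               C = compat,
               A = compat,
               X = TRUE)
  if (!ok) return(FALSE)
  if (mode == "A") {
    fp <- five_prime_exon(t)
    shares_5p <- any(uex[, 2L] >= fp[1L, 1L] & uex[, 1L] <= fp[1L, 2L])
    if (!shares_5p) return(FALSE)  # alternate TSS: keep
  }
  TRUE
}

#' Annotate query transcripts against a reference
#'
#' Every input transcript is retained (no de-duplication) and gains four
#' attributes: `xloc` (super-locus id), `tss_id` (transcription start
#' group), `cmp_ref` (closest reference transcript, omitted for
#' non-overlapping queries) and `class_code` (see [class_codes]).
#'
#' @param query A [annotation_set()].
#' @param reference Reference [annotation_set()].
#' @param genome Optional `gffx_faidx` (enables the repeat code).
#' @param d TSS grouping distance (default 100).
#' @param ... Passed to [best_reference()].
#' @return The annotated query set.
#' @export
annotate_transcripts <- function(query, reference, genome = NULL, d = 100L,
                                 ...) {
  loci <- build_superloci(list(query), reference)
  txs <- query$transcripts
  tss_counter <- 0L
  for (lc in loci) {
    member_ids <- lc$q_members$id
    if (!length(member_ids)) next
    tss <- assign_tss(txs[member_ids], d = d)
    local_ids <- sort(unique(tss[!is.na(tss)]))
    for (id in member_ids) {
      txs[[id]]$attributes$xloc <- lc$xloc_id
      g <- tss[[id]]
      if (!is.na(g))
        txs[[id]]$attributes$tss_id <-
          sprintf("TSS%d", tss_counter + match(g, local_ids))
    }
    tss_counter <- tss_counter + length(local_ids)
  }
  for (id in names(txs)) {
    br <- best_reference(txs[[id]], reference, genome, ...)
    if (!is.null(br$ref)) txs[[id]]$attributes$cmp_ref <- br$ref$id
    txs[[id]]$attributes$class_code <- br$code
  }
  annotation_set(unname(txs), query$genes, seqid_order = query$seqid_order)
}

#' Write a .tracking file
#'
#' One row per structurally distinct transfrag: consensus id, super-locus,
#' `gene|transcript` of the closest reference (or `-`), class code, then
#' one `qN:gene|tx|num_exons|FPKM|TPM|cov|len` cell per sample (`-` when
#' the sample lacks the transfrag).
#'
#' @param tracking Tracking data.frame from [merge_samples()].
#' @param file Output path.
#' @export
write_tracking <- function(tracking, file) {
  lines <- apply(tracking, 1L, paste, collapse = "\t")
  writeLines(as.character(lines), file)
  invisible(file)
}

#' Write a .refmap file for one sample
#'
#' One row per reference transcript fully (`=`) or partially (`c`) matched
#' by at least one query transcript of the sample, with a comma-separated
#' `gene|transcript` list of the matching queries.
#'
#' @param query Sample [annotation_set()].
#' @param reference Reference [annotation_set()].
#' @param file Output path.
#' @param ... Passed to [best_reference()].
#' @return Invisibly, the refmap data.frame.
#' @export
write_refmap <- function(query, reference, file, ...) {
  hits <- list()
  for (t in query$transcripts) {
    br <- best_reference(t, reference, ...)
    if (is.null(br$ref) || !(br$code %in% c("=", "c"))) next
    rid <- br$ref$id
    hits[[rid]] <- c(hits[[rid]],
                     stats::setNames(br$code,
                                     paste0(t$gene_id %||% t$id, "|", t$id)))
  }
  rows <- lapply(names(hits), function(rid) {
    r <- reference$transcripts[[rid]]
    codes <- hits[[rid]]
    data.frame(ref_gene = r$gene_name %||% r$gene_id %||% "-",
               ref_id = rid,
               class_code = if (any(codes == "=")) "=" else "c",
               matches = paste(names(codes), collapse = ","),
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ref_gene = character(0), ref_id = character(0),
               class_code = character(0), matches = character(0))
  ord <- match(df$ref_id, names(reference$transcripts))
  df <- df[order(ord), , drop = FALSE]
  writeLines(c("ref_gene\tref_id\tclass_code\tqry_id_list",
               apply(df, 1L, paste, collapse = "\t")), file)
  invisible(df)
}

#' Write a .tmap file for one sample
#'
#' One row per query transcript describing its most closely matching
#' reference transcript: reference gene name and id, class code, query gene
#' and transcript ids, exon count, FPKM/TPM/coverage (pass-through from
#' input attributes, else 0.000000), length, the query id of the gene's
#' major isoform (highest FPKM, ties to the longest), and the length of the
#' longest exonic overlap with a reference (`-` when there is none).
#'
#' @param query Sample [annotation_set()].
#' @param reference Reference [annotation_set()].
#' @param file Output path.
#' @param genome Optional `gffx_faidx` for p/r/u classification.
#' @param ... Passed to [best_reference()].
#' @return Invisibly, the tmap data.frame.
#' @export
write_tmap <- function(query, reference, file, genome = NULL, ...) {
  txs <- query$transcripts
  gene_of <- vapply(txs, function(t) t$gene_id %||% t$id, "")
  fpkm <- vapply(txs, function(t) {
    v <- suppressWarnings(as.numeric(get_attr(t, "FPKM")))
    if (is.na(v)) 0 else v
  }, 1)
  lens <- vapply(txs, tx_exonic_length, 1L)
  major <- vapply(names(txs), function(id) {
    sib <- names(txs)[gene_of == gene_of[[id]]]
    sib[order(-fpkm[sib], -lens[sib], sib)][1L]
  }, "")
  rows <- vapply(names(txs), function(id) {
    t <- txs[[id]]
    br <- best_reference(t, reference, genome, ...)
    cands <- overlap_candidates(reference, t$seqid, t$start, t$end)
    ovl <- if (length(cands))
      max(vapply(cands, function(r) tx_exonic_overlap(t, r), 1L)) else 0L
    paste(
      if (!is.null(br$ref)) br$ref$gene_name %||% br$ref$gene_id %||% "-"
        else "-",
      if (!is.null(br$ref)) br$ref$id else "-",
      br$code, gene_of[[id]], id, tx_num_exons(t),
      fmt_expr(t, "FPKM"), fmt_expr(t, "TPM"), fmt_expr(t, "cov"),
      tx_exonic_length(t), major[[id]],
      if (ovl > 0L) ovl else "-",
      sep = "\t")
  }, "")
  writeLines(c(paste("ref_gene_id", "ref_id", "class_code", "qry_gene_id",
                     "qry_id", "num_exons", "FPKM", "TPM", "cov", "len",
                     "major_iso_id", "ref_match_len", sep = "\t"),
               unname(rows)), file)
  invisible(rows)
}

#' Run the full comparison pipeline and write its report files
#'
#' Orchestrates per-sample de-duplication, six-level statistics, merging
#' and annotation, writing `<prefix>.stats`, `<prefix>.tracking`,
#' `<prefix>.combined.gtf` (multi-sample or redundancy-collapsing runs) or
#' `<prefix>.annotated.gtf` (plain single-sample runs), and per-sample
#' `<prefix>.<sample>.refmap` / `.tmap` files.
#'
#' @param queries Named list of sample [annotation_set()] objects.
#' @param reference Reference [annotation_set()].
#' @param out_prefix Output path prefix (default `"gffcmp"`).
#' @param opts A [compare_opts()].
#' @param dedup `NULL`, `"D"` or `"S"` per-sample duplicate removal.
#' @param merge_mode `NULL` (plain union) or `"C"`, `"A"`, `"X"`.
#' @param keep_ref_matches Protect reference-matching transfrags from
#'   redundancy discarding (-K).
#' @param genome Optional `gffx_faidx`.
#' @param tcons_prefix Consensus id prefix.
#' @param write_maps Write per-sample refmap/tmap files (disable for -T).
#' @return Invisibly, a list with `stats`, `combined`/`annotated` and
#'   `tracking`.
#' @export
gffcompare_run <- function(queries, reference, out_prefix = "gffcmp",
                           opts = compare_opts(), dedup = NULL,
                           merge_mode = NULL, keep_ref_matches = FALSE,
                           genome = NULL, tcons_prefix = "TCONS",
                           write_maps = TRUE) {
  if (inherits(queries, "gffx_set")) queries <- list(queries)
  if (is.null(names(queries)) || any(!nzchar(names(queries))))
    names(queries) <- sprintf("q%d", seq_along(queries))
  if (!is.null(dedup))
    queries <- lapply(queries, dedup_queries, mode = dedup)
  stats <- compute_stats(queries, reference, opts)
  write_stats(stats, paste0(out_prefix, ".stats"))
  mg <- merge_samples(queries, reference,
                      mode = merge_mode %||% "union",
                      keep_ref_matches = keep_ref_matches,
                      tcons_prefix = tcons_prefix,
                      se_overlap = opts$se_overlap, genome = genome)
  write_tracking(mg$tracking, paste0(out_prefix, ".tracking"))
  annotated <- NULL
  if (length(queries) > 1L || !is.null(merge_mode)) {
    write_annotation(mg$combined, "gtf",
                     file = paste0(out_prefix, ".combined.gtf"))
  } else {
    annotated <- annotate_transcripts(queries[[1L]], reference, genome,
                                      d = opts$tss_distance)
    write_annotation(annotated, "gtf", keep_attrs = TRUE,
                     file = paste0(out_prefix, ".annotated.gtf"))
  }
  if (write_maps) {
    for (nm in names(queries)) {
      write_refmap(queries[[nm]], reference,
                   paste0(out_prefix, ".", nm, ".refmap"))
      write_tmap(queries[[nm]], reference,
                 paste0(out_prefix, ".", nm, ".tmap"), genome = genome)
    }
  }
  invisible(list(stats = stats, combined = mg$combined,
                 tracking = mg$tracking, annotated = annotated))
}
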