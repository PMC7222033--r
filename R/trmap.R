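#' Build an interval tree over a reference annotation
#'
#' Loads every reference transcript into a per-seqid interval index keyed
#' by transcript span, supporting overlap enumeration for streaming
#' queries. Memory is proportional to the reference only; queries are
#' processed one at a time.
#'
#' @param reference A [annotation_set()].
#' @return Object of class `gffx_tree`.
#' @export
build_tree <- function(reference) {
  per_seq <- list()
  for (sq in names(reference$index)) {
    idx <- reference$index[[sq]]
    per_seq[[sq]] <- list(
      ranges = IRanges(idx$start, idx$end),
      ids = idx$id
    )
  }
  structure(list(per_seq = per_seq, reference = reference),
            class = "gffx_tree")
}

#' @export
print.gffx_tree <- function(x, ...) {
  cat(sprintf("<reference interval tree: %d transcript(s), %d seqid(s)>\n",
              length(x$reference$transcripts), length(x$per_seq)))
  invisible(x)
}

tree_overlaps <- function(tree, seqid, start, end) {
  node <- tree$per_seq[[seqid]]
  if (is.null(node)) return(character(0))
  h <- findOverlaps(IRanges(start, end), node$ranges)
  node$ids[sort(subjectHits(h))]
}

#' Stream-classify query transcripts against a reference tree
#'
#' For each query transcript with at least one reference overlap, reports
#' every overlapping reference transcript with its classification code
#' (codes p/r/u are reserved for non-overlapping transcripts and never
#' emitted here: queries with no overlap produce no record). Queries are
#' handled one at a time; only the tree and the current query are held.
#'
#' @param tree A `gffx_tree` from [build_tree()].
#' @param queries A [annotation_set()], file path, or character vector of
#'   annotation lines (any supported format).
#' @param simple Report only overlap percentages (one line per query)
#'   instead of classification records.
#' @param out Optional connection or path; records are written as they are
#'   produced.
#' @param ... Passed to [classify_pair()].
#' @return Invisibly, the character vector of output lines.
#' @export
stream_classify <- function(tree, queries, simple = FALSE, out = NULL, ...) {
  if (!inherits(queries, "gffx_set"))
    queries <- parse_annotation(queries)
  con <- NULL
  if (!is.null(out)) {
    con <- if (inherits(out, "connection")) out else file(out, "w")
    if (!inherits(out, "connection")) on.exit(close(con))
  }
  all_lines <- character(0)
  ord <- unlist(lapply(queries$seqid_order,
                       function(sq) queries$index[[sq]]$id),
                use.names = FALSE)
  for (id in ord) {
    q <- queries$transcripts[[id]]
    hit_ids <- tree_overlaps(tree, q$seqid, q$start, q$end)
    if (!length(hit_ids)) next
    refs <- tree$reference$transcripts[hit_ids]
    # hit ordering: by reference start, then id
    refs <- refs[order(vapply(refs, function(r) r$start, 1L),
                       vapply(refs, function(r) r$id, ""))]
    lines <- if (simple) {
      pct <- vapply(refs, function(r)
        100 * tx_exonic_overlap(q, r) / tx_exonic_length(q), 1)
      paste0(q$id, "\t",
             paste(sprintf("%s:%.1f", vapply(refs, function(r) r$id, ""),
                           pct), collapse = ","))
    } else {
      codes <- vapply(refs, function(r) classify_pair(q, r, ...), "")
      format_record(q, Map(function(code, r) list(code = code, ref = r),
                           codes, refs))
    }
    if (!is.null(con)) writeLines(lines, con)
    all_lines <- c(all_lines, lines)
  }
  invisible(all_lines)
}

#' Format one trmap pseudo-FASTA record
#'
#' A `">"` header with the query id, genomic location and strand, followed
#' by one tab-delimited line per overlapping reference: class code,
#' chromosome, strand, start, end, reference transcript id, and the exon
#' list as comma-delimited `start-end` intervals. All coordinates are
#' 1-based regardless of the input format.
#'
#' @param query Query transcript.
#' @param hits List of `list(code, ref)` pairs.
#' @return Character vector of record lines.
#' @export
format_record <- function(query, hits) {
  hdr <- sprintf(">%s %s:%d-%d %s %s", query$id, query$seqid, query$start,
                 query$end, query$strand, render_ivls(tx_segments(query)))
  body <- vapply(hits, function(h) {
    r <- h$ref
    paste(h$code, r$seqid, r$strand, r$start, r$end, r$id,
          render_ivls(tx_segments(r)), sep = "\t")
  }, "")
  c(hdr, unname(body))
}

#' Classify a query annotation file against a reference file
#'
#' Convenience wrapper: loads the reference into an interval tree and
#' streams the query file through [stream_classify()].
#'
#' @param ref Reference annotation: path, lines or [annotation_set()].
#' @param query Query annotation: path, lines or [annotation_set()].
#' @param out Optional output path.
#' @param simple Overlap percentages only.
#' @param ... Passed to [classify_pair()].
#' @return Invisibly, the output lines.
#' @export
trmap <- function(ref, query, out = NULL, simple = FALSE, ...) {
  if (!inherits(ref, "gffx_set")) ref <- parse_annotation(ref)
  stream_classify(build_tree(ref), query, simple = simple, out = out, ...)
}
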