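#' Construct an annotation set
#'
#' A collection of transcripts (and optional gene records) with a per-seqid
#' coordinate-sorted index used for overlap queries and ordered output.
#' Reference sequences are remembered in first-encountered order, mirroring
#' the default output ordering of the converters.
#'
#' @param transcripts List of [transcript()] objects.
#' @param genes List of [gene()] objects.
#' @param seqid_order Character vector fixing the reference-sequence block
#'   order; derived from the transcripts/genes when `NULL`.
#' @param diagnostics Character vector of parser/builder diagnostics.
#' @return An object of class `gffx_set`.
#' @export
annotation_set <- function(transcripts = list(), genes = list(),
                           seqid_order = NULL, diagnostics = character(0)) {
  ids <- vapply(transcripts, function(t) t$id, "")
  if (anyDuplicated(ids))
    stop("duplicate transcript ids in annotation set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(transcripts) <- ids
  gids <- vapply(genes, function(g) g$id, "")
  names(genes) <- gids
  if (is.null(seqid_order)) {
    seqs <- c(vapply(transcripts, function(t) t$seqid, ""),
              vapply(genes, function(g) g$seqid, ""))
    seqid_order <- unique(seqs)
  }
  set <- structure(list(
    transcripts = transcripts, genes = genes,
    seqid_order = seqid_order, diagnostics = diagnostics
  ), class = "gffx_set")
  set$index <- build_set_index(set)
  set
}

# per-seqid data.frame(start, end, id) sorted by (start, end)
build_set_index <- function(set) {
  if (!length(set$transcripts)) return(list())
  df <- data.frame(
    seqid = vapply(set$transcripts, function(t) t$seqid, ""),
    start = vapply(set$transcripts, function(t) t$start, 1L),
    end = vapply(set$transcripts, function(t) t$end, 1L),
    id = names(set$transcripts), stringsAsFactors = FALSE
  )
  lapply(split(df[c("start", "end", "id")], df$seqid), function(b) {
    b[order(b$start, b$end), , drop = FALSE]
  })
}

#' Number of transcripts in a set
#' @param set A `gffx_set`.
#' @export
n_transcripts <- function(set) length(set$transcripts)

#' Transcript ids of a set
#' @param set A `gffx_set`.
#' @export
tx_ids <- function(set) names(set$transcripts)

# Rebuild a set keeping only the given transcript ids; gene records are
# pruned to surviving members (childless genes are retained).
set_subset <- function(set, keep_ids) {
  tx <- set$transcripts[names(set$transcripts) %in% keep_ids]
  genes <- lapply(set$genes, function(g) {
    g$transcript_ids <- intersect(g$transcript_ids, keep_ids)
    g
  })
  genes <- Filter(function(g) length(g$transcript_ids) > 0L ||
                    !g$id %in% unlist(lapply(set$transcripts,
                                             function(t) t$gene_id)),
                  genes)
  annotation_set(tx, genes, seqid_order = set$seqid_order,
                 diagnostics = set$diagnostics)
}

#' Sort an annotation set
#'
#' Transcripts are always kept coordinate-sorted within each reference
#' sequence; this operation controls the order of the reference-sequence
#' blocks themselves.
#'
#' @param set A `gffx_set`.
#' @param mode `"default"` (first-encountered order), `"alpha"`
#'   (lexicographic), or `"by_list"` (order given in `list`).
#' @param list Character vector of seqid names for `mode = "by_list"`.
#' @return The set with `seqid_order` updated.
#' @export
sort_annotation <- function(set, mode = c("default", "alpha", "by_list"),
                            list = NULL) {
  mode <- match.arg(mode)
  ord <- set$seqid_order
  if (mode == "alpha") {
    ord <- sort(ord)
  } else if (mode == "by_list") {
    if (is.null(list)) stop("mode 'by_list' requires a seqid list")
    missing <- setdiff(ord, list)
    if (length(missing))
      warning("seqids absent from sort list placed last: ",
              paste(missing, collapse = ", "))
    ord <- c(intersect(list, ord), missing)
  }
  set$seqid_order <- ord
  set
}

#' Transcripts overlapping an interval
#'
#' Returns exactly the transcripts whose span shares at least one base with
#' the query interval, found through the coordinate-sorted index.
#'
#' @param set A `gffx_set`.
#' @param seqid Reference sequence name (unknown names yield an empty list).
#' @param start,end Query interval, 1-based inclusive.
#' @return List of `gffx_tx` objects, ordered by (start, end).
#' @export
overlap_candidates <- function(set, seqid, start, end) {
  idx <- set$index[[seqid]]
  if (is.null(idx) || !nrow(idx)) return(list())
  h <- iv_hits(start, end, idx$start, idx$end)
  set$transcripts[idx$id[sort(h$s)]]
}

#' @export
print.gffx_set <- function(x, ...) {
  cat(sprintf("<annotation set: %d transcript(s), %d gene(s), %d seqid(s)>\n",
              length(x$transcripts), length(x$genes), length(x$seqid_order)))
  if (length(x$diagnostics))
    cat(sprintf("  %d parser diagnostic(s); see $diagnostics\n",
                length(x$diagnostics)))
  invisible(x)
}
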