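#' Write an annotation set as GFF3, GTF or BED
#'
#' Default output is transcripts only with the basic attributes (ID, Parent
#' for children, geneID and gene_name when present). Writers are
#' column-exact: 9 tab-separated fields for GFF3/GTF with "." for missing
#' score/frame, and BED12 with the 0-based half-open conversion applied at
#' this boundary only. A round trip `parse_annotation(write_annotation(x))`
#' preserves every transcript's seqid, strand, exon chain and CDS chain.
#'
#' @param set A [annotation_set()]. Block order follows `set$seqid_order`
#'   (see [sort_annotation()]); transcripts are coordinate-sorted within
#'   each block.
#' @param format `"gff3"`, `"gtf"` or `"bed"`.
#' @param file Optional path; when given, lines are written there.
#' @param keep_attrs Preserve all original transcript attributes
#'   (gffread's `-F`).
#' @param keep_genes Also emit gene records (transcript-only mode otherwise).
#' @param loci Optional list of loci from [cluster_loci()]; each is written
#'   as a `locus` feature listing member transcript and gene ids.
#' @return Character vector of output lines, invisibly when `file` is given.
#' @export
write_annotation <- function(set, format = c("gff3", "gtf", "bed"),
                             file = NULL, keep_attrs = FALSE,
                             keep_genes = FALSE, loci = NULL) {
  format <- match.arg(format)
  out <- character(0)
  if (format == "gff3") out <- "##gff-version 3"
  for (sq in set$seqid_order) {
    idx <- set$index[[sq]]
    txs <- if (is.null(idx)) list() else set$transcripts[idx$id]
    genes_here <- Filter(function(g) g$seqid == sq, set$genes)
    if (length(loci)) {
      for (lc in Filter(function(l) l$seqid == sq, loci))
        out <- c(out, locus_line(lc, format))
    }
    if (keep_genes && format != "bed" && length(genes_here)) {
      gstart <- vapply(genes_here, function(g) g$start, 1L)
      genes_here <- genes_here[order(gstart)]
      for (g in genes_here) out <- c(out, gene_lines(g, format))
    }
    for (t in txs) {
      out <- c(out, switch(format,
                           gff3 = tx_gff3_lines(t, keep_attrs, keep_genes),
                           gtf = tx_gtf_lines(t, keep_attrs),
                           bed = tx_bed_line(t)))
    }
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

gff3_attr_string <- function(pairs) {
  keep <- !vapply(pairs, function(v) is.null(v) ||
                    (length(v) == 1L && is.na(v)), NA)
  pairs <- pairs[keep]
  paste(vapply(names(pairs), function(k)
    paste0(k, "=", pct_encode(as.character(pairs[[k]]))), ""),
    collapse = ";")
}

gtf_attr_string <- function(pairs) {
  keep <- !vapply(pairs, function(v) is.null(v) ||
                    (length(v) == 1L && is.na(v)), NA)
  pairs <- pairs[keep]
  paste0(paste(vapply(names(pairs), function(k)
    sprintf('%s "%s"', k, as.character(pairs[[k]])), ""),
    collapse = "; "), ";")
}

gff_row <- function(seqid, source, type, start, end, score, strand, phase,
                    attrs) {
  paste(seqid, source, type, start, end, dot_or(score), strand,
        dot_or(phase), attrs, sep = "\t")
}

tx_gff3_lines <- function(t, keep_attrs = FALSE, keep_genes = FALSE) {
  at <- list(ID = t$id)
  if (keep_genes && !is.na(t$gene_id)) at$Parent <- t$gene_id
  at$geneID <- t$gene_id
  at$gene_name <- t$gene_name
  if (keep_attrs) for (k in names(t$attributes))
    if (is.null(at[[k]])) at[[k]] <- t$attributes[[k]]
  lines <- gff_row(t$seqid, t$source, t$feature_type, t$start, t$end,
                   t$score, t$strand, NA, gff3_attr_string(at))
  for (i in seq_len(nrow(t$exons)))
    lines <- c(lines, gff_row(t$seqid, t$source, "exon",
                              t$exons[i, 1L], t$exons[i, 2L], NA, t$strand,
                              NA, paste0("Parent=", pct_encode(t$id))))
  for (i in seq_len(nrow(t$cds)))
    lines <- c(lines, gff_row(t$seqid, t$source, "CDS",
                              t$cds[i, 1L], t$cds[i, 2L], NA, t$strand,
                              t$cds_phase[i],
                              paste0("Parent=", pct_encode(t$id))))
  lines
}

tx_gtf_lines <- function(t, keep_attrs = FALSE) {
  gid <- if (is.na(t$gene_id)) t$id else t$gene_id
  base <- list(gene_id = gid, transcript_id = t$id, gene_name = t$gene_name)
  if (keep_attrs) for (k in names(t$attributes))
    if (is.null(base[[k]])) base[[k]] <- t$attributes[[k]]
  attrs <- gtf_attr_string(base)
  lines <- gff_row(t$seqid, t$source, "transcript", t$start, t$end, t$score,
                   t$strand, NA, attrs)
  core <- gtf_attr_string(list(gene_id = gid, transcript_id = t$id))
  for (i in seq_len(nrow(t$exons)))
    lines <- c(lines, gff_row(t$seqid, t$source, "exon",
                              t$exons[i, 1L], t$exons[i, 2L], NA, t$strand,
                              NA, core))
  for (i in seq_len(nrow(t$cds)))
    lines <- c(lines, gff_row(t$seqid, t$source, "CDS",
                              t$cds[i, 1L], t$cds[i, 2L], NA, t$strand,
                              t$cds_phase[i], core))
  lines
}

tx_bed_line <- function(t) {
  ex <- tx_segments(t)
  cstart <- t$start - 1L
  if (nrow(t$cds)) {
    thick_s <- min(t$cds[, 1L]) - 1L
    thick_e <- max(t$cds[, 2L])
  } else {
    thick_s <- cstart
    thick_e <- cstart
  }
  paste(t$seqid, cstart, t$end, t$id,
        if (is.na(t$score)) 0 else t$score, t$strand, thick_s, thick_e, "0",
        nrow(ex), paste0(paste(ex[, 2L] - ex[, 1L] + 1L, collapse = ","), ","),
        paste0(paste(ex[, 1L] - 1L - cstart, collapse = ","), ","),
        sep = "\t")
}

gene_lines <- function(g, format) {
  if (format == "gtf") {
    gff_row(g$seqid, g$source, "gene", g$start, g$end, NA, g$strand, NA,
            gtf_attr_string(list(gene_id = g$id, gene_name = g$name)))
  } else {
    gff_row(g$seqid, g$source, g$feature_type, g$start, g$end, NA, g$strand,
            NA, gff3_attr_string(list(ID = g$id, Name = g$name)))
  }
}

locus_line <- function(lc, format) {
  if (format == "gtf") {
    gff_row(lc$seqid, "gffx", "locus", lc$start, lc$end, NA, lc$strand, NA,
            gtf_attr_string(list(
              locus_id = lc$id,
              transcripts = paste(lc$transcript_ids, collapse = ","),
              genes = if (length(lc$gene_ids))
                paste(lc$gene_ids, collapse = ",") else NULL)))
  } else {
    attrs <- list(ID = lc$id,
                  transcripts = paste(lc$transcript_ids, collapse = ","))
    if (length(lc$gene_ids)) attrs$genes <- paste(lc$gene_ids, collapse = ",")
    gff_row(lc$seqid, "gffx", "locus", lc$start, lc$end, NA, lc$strand, NA,
            gff3_attr_string(attrs))
  }
}

#' Tabulate transcripts into a simple attribute table
#'
#' One row per transcript. Pseudo-attributes prefixed with `@` expose
#' structural fields: `@id`, `@geneid`, `@chr`, `@start`, `@end`, `@strand`,
#' `@numexons`, `@exons`, `@cds`, `@covlen` (sum of exon lengths) and
#' `@cdslen` (sum of CDS lengths). Any other name is looked up among the
#' transcript's attributes (then `gene_name`); a missing value renders as
#' `"."`. Interval lists render as `"start-end,start-end"` in genomic order.
#'
#' @param set A [annotation_set()].
#' @param attrlist Character vector of column names.
#' @return A data.frame with one column per requested name (all character).
#' @export
to_table <- function(set, attrlist) {
  ord <- unlist(lapply(set$seqid_order,
                       function(sq) set$index[[sq]]$id), use.names = FALSE)
  txs <- set$transcripts[ord]
  cols <- lapply(attrlist, function(a) {
    vapply(txs, function(t) table_field(t, a), "")
  })
  df <- as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
  names(df) <- attrlist
  rownames(df) <- NULL
  df
}

render_ivls <- function(m) {
  if (!nrow(m)) return(".")
  paste(paste0(m[, 1L], "-", m[, 2L]), collapse = ",")
}

table_field <- function(t, a) {
  switch(a,
         "@id" = t$id,
         "@geneid" = dot_or(t$gene_id),
         "@chr" = t$seqid,
         "@start" = as.character(t$start),
         "@end" = as.character(t$end),
         "@strand" = t$strand,
         "@numexons" = as.character(tx_num_exons(t)),
         "@exons" = render_ivls(tx_segments(t)),
         "@cds" = render_ivls(t$cds),
         "@covlen" = as.character(tx_exonic_length(t)),
         "@cdslen" = as.character(tx_cds_length(t)),
         {
           v <- get_attr(t, a)
           if (is.na(v) && a == "gene_name") v <- t$gene_name
           dot_or(v)
         })
}
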