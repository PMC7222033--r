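#' Construct a transcript
#'
#' The central record of the package: one transcript with its exon chain,
#' optional CDS segments, strand and attributes. Coordinates are 1-based
#' inclusive throughout (GFF native); BED input is converted at the I/O
#' boundary only.
#'
#' Exons are sorted by start and must not overlap; exact duplicate segments
#' are collapsed. The transcript span is derived from the exon chain (or from
#' the CDS chain for CDS-only transcripts).
#'
#' @param id Unique transcript identifier.
#' @param seqid Reference sequence (chromosome/contig) name.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @param exons Exon intervals: a two-column matrix, data.frame, or list of
#'   `c(start, end)` pairs. May be empty for CDS-only transcripts.
#' @param cds CDS intervals in the same formats, or `NULL`.
#' @param cds_phase Integer phase (0/1/2) per CDS segment in genomic order;
#'   computed assuming a 5'-phase of 0 when `NULL`.
#' @param gene_id,gene_name Optional parent gene identifier / display name.
#' @param score Optional numeric score (`NA` prints as ".").
#' @param source GFF source column.
#' @param feature_type GFF feature type of the transcript record.
#' @param attributes Named list of additional attributes (order preserved).
#' @param children Opaque child feature records retained from parsing.
#' @return An object of class `gffx_tx`.
#' @examples
#' t1 <- transcript("t1", "chr1", "+", exons = list(c(100, 200), c(300, 500)))
#' tx_introns(t1)
#' @export
transcript <- function(id, seqid, strand = ".", exons = NULL, cds = NULL,
                       cds_phase = NULL, gene_id = NA_character_,
                       gene_name = NA_character_, score = NA_real_,
                       source = ".", feature_type = "transcript",
                       attributes = list(), children = list()) {
  exons <- as_ivmat(exons)
  cds <- as_ivmat(cds)
  exons <- unique(exons)
  cds_keep <- !duplicated(cds)
  if (!is.null(cds_phase)) cds_phase <- cds_phase[cds_keep]
  cds <- cds[cds_keep, , drop = FALSE]
  if (!nrow(exons) && !nrow(cds))
    stop("transcript '", id, "' has neither exons nor CDS segments")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("transcript '", id, "' has overlapping exons")
  if (!(strand %in% c("+", "-", ".")))
    stop("invalid strand '", strand, "'")
  span_src <- if (nrow(exons)) exons else cds
  if (nrow(exons) && nrow(cds) && !iv_contains(exons, cds))
    stop("transcript '", id, "' has CDS segments outside its exons")
  if (nrow(cds)) {
    if (is.null(cds_phase) || all(is.na(cds_phase))) {
      cds_phase <- default_cds_phase(cds, strand)
    } else {
      cds_phase <- as.integer(cds_phase)
      na <- is.na(cds_phase)
      if (any(na)) cds_phase[na] <- default_cds_phase(cds, strand)[na]
    }
  } else {
    cds_phase <- integer(0)
  }
  structure(list(
    id = as.character(id), seqid = as.character(seqid), strand = strand,
    start = min(span_src[, 1L]), end = max(span_src[, 2L]),
    exons = exons, cds = cds, cds_phase = cds_phase,
    gene_id = as.character(gene_id), gene_name = as.character(gene_name),
    score = score, source = source, feature_type = feature_type,
    attributes = attributes, children = children
  ), class = "gffx_tx")
}

# Phase of each CDS segment in genomic order assuming the 5'-most segment
# (transcription order) starts in frame.
default_cds_phase <- function(cds, strand) {
  n <- nrow(cds)
  lens <- cds[, 2L] - cds[, 1L] + 1L
  ord <- if (strand == "-") rev(seq_len(n)) else seq_len(n)
  ph <- integer(n)
  cum <- 0L
  for (i in ord) {
    ph[i] <- (3L - cum %% 3L) %% 3L
    cum <- cum + lens[i]
  }
  ph
}

#' Construct a gene record
#'
#' @param id Gene identifier.
#' @param seqid,strand Location.
#' @param start,end Gene span (1-based inclusive).
#' @param name Optional display name.
#' @param transcript_ids Character vector of child transcript ids.
#' @param source,feature_type,attributes As for [transcript()].
#' @return An object of class `gffx_gene`.
#' @export
gene <- function(id, seqid, strand = ".", start, end, name = NA_character_,
                 transcript_ids = character(0), source = ".",
                 feature_type = "gene", attributes = list()) {
  stopifnot(end >= start, start >= 1)
  structure(list(
    id = as.character(id), seqid = as.character(seqid), strand = strand,
    start = as.integer(start), end = as.integer(end),
    name = as.character(name), transcript_ids = transcript_ids,
    source = source, feature_type = feature_type, attributes = attributes
  ), class = "gffx_gene")
}

#' Introns of a transcript
#'
#' @param t A `gffx_tx`.
#' @return Two-column integer matrix of intron intervals in genomic order
#'   (zero rows for single-exon or CDS-only transcripts).
#' @export
tx_introns <- function(t) {
  ex <- tx_segments(t)
  if (nrow(ex) < 2L) return(empty_ivmat())
  cbind(start = ex[-nrow(ex), 2L] + 1L, end = ex[-1L, 1L] - 1L)
}

#' Spliced (exonic) length of a transcript in bases
#' @param t A `gffx_tx`.
#' @export
tx_exonic_length <- function(t) {
  iv_width(if (nrow(t$exons)) t$exons else t$cds)
}

#' Total CDS length of a transcript in bases
#' @param t A `gffx_tx`.
#' @export
tx_cds_length <- function(t) iv_width(t$cds)

#' Number of exons (CDS segments for CDS-only transcripts)
#' @param t A `gffx_tx`.
#' @export
tx_num_exons <- function(t) {
  if (nrow(t$exons)) nrow(t$exons) else nrow(t$cds)
}

# Effective segment matrix: exons when present, else CDS.
tx_segments <- function(t) if (nrow(t$exons)) t$exons else t$cds

# Shared exonic bases between two transcripts (0 if different seqid).
tx_exonic_overlap <- function(a, b) {
  if (a$seqid != b$seqid) return(0L)
  iv_intersect_width(tx_segments(a), tx_segments(b))
}

# key identifying an intron chain (within a seqid/strand stratum)
tx_chain_key <- function(t) {
  ii <- tx_introns(t)
  if (!nrow(ii)) return(NA_character_)
  paste(paste0(ii[, 1L], "-", ii[, 2L]), collapse = ",")
}

get_attr <- function(t, keys, default = NA_character_) {
  nm <- names(t$attributes)
  for (k in keys) {
    hit <- which(tolower(nm) == tolower(k))
    if (length(hit)) return(as.character(t$attributes[[hit[1L]]]))
  }
  default
}

#' @export
print.gffx_tx <- function(x, ...) {
  cat(sprintf("<transcript %s %s:%d-%d(%s) %d exon(s)%s>\n", x$id, x$seqid,
              x$start, x$end, x$strand, tx_num_exons(x),
              if (nrow(x$cds)) sprintf(", CDS %dbp", tx_cds_length(x)) else ""))
  invisible(x)
}

#' @export
print.gffx_gene <- function(x, ...) {
  cat(sprintf("<gene %s %s:%d-%d(%s) %d transcript(s)>\n", x$id, x$seqid,
              x$start, x$end, x$strand, length(x$transcript_ids)))
  invisible(x)
}
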