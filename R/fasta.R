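#' Read a FASTA file preserving case
#'
#' Case matters here: soft-masked (lower-case) bases drive the repeat class
#' code, so sequences are kept exactly as written.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  nm <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (ends[i] < starts[i]) "" else
      paste(lines[starts[i]:ends[i]], collapse = "")
  }, "")
  stats::setNames(seqs, nm)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 60 columns).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Index a genome FASTA for random access
#'
#' Builds (or reads) a samtools-faidx-compatible sidecar index
#' (`<path>.fai`: name, length, offset, linebases, linewidth) and returns a
#' handle supporting random subsequence retrieval without loading the whole
#' genome. Records with ragged line widths cannot be seek-indexed; the whole
#' file is then loaded into memory with a warning and fetches are served
#' from the in-memory copy.
#'
#' @param path Genome FASTA path (soft-masked lower-case allowed).
#' @param write_fai Persist the index next to the genome when absent.
#' @return An object of class `gffx_faidx`.
#' @export
index_fasta <- function(path, write_fai = TRUE) {
  fai_path <- paste0(path, ".fai")
  if (file.exists(fai_path)) {
    fai <- utils::read.table(fai_path, sep = "\t", stringsAsFactors = FALSE,
                             col.names = c("name", "length", "offset",
                                           "linebases", "linewidth"))
    return(structure(list(path = path, fai = fai, seqs = NULL),
                     class = "gffx_faidx"))
  }
  lines <- readLines(path, warn = FALSE)
  sizes <- file.info(path)$size
  # detect line terminator width from the file size vs character count
  eol <- if (sum(nchar(lines, type = "bytes")) + 2L * length(lines) == sizes)
    2L else 1L
  offs <- cumsum(c(0L, nchar(lines, type = "bytes") + eol))
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  names_ <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  ragged <- FALSE
  rows <- lapply(seq_along(hdr), function(i) {
    if (ends[i] < starts[i])
      return(list(length = 0L, offset = offs[starts[i]],
                  linebases = 0L, linewidth = eol))
    widths <- nchar(lines[starts[i]:ends[i]], type = "bytes")
    if (length(widths) > 1L &&
        (any(widths[-length(widths)] != widths[1L]) ||
         widths[length(widths)] > widths[1L]))
      ragged <<- TRUE
    list(length = sum(widths), offset = offs[starts[i]],
         linebases = widths[1L], linewidth = widths[1L] + eol)
  })
  fai <- data.frame(
    name = names_,
    length = vapply(rows, `[[`, 0L, "length"),
    offset = vapply(rows, `[[`, 0L, "offset"),
    linebases = vapply(rows, `[[`, 0L, "linebases"),
    linewidth = vapply(rows, `[[`, 0L, "linewidth"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(fai$name))
    stop("duplicate sequence names in ", path)
  seqs <- NULL
  if (ragged) {
    warning("ragged line widths in ", path,
            "; falling back to in-memory sequences")
    seqs <- read_fasta(path)
  } else if (write_fai) {
    ok <- tryCatch({
      utils::write.table(fai, fai_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) seqs <- read_fasta(path)
  }
  structure(list(path = path, fai = fai, seqs = seqs), class = "gffx_faidx")
}

#' @export
print.gffx_faidx <- function(x, ...) {
  cat(sprintf("<faidx %s: %d sequence(s), %s bases%s>\n", x$path,
              nrow(x$fai), format(sum(x$fai$length), big.mark = ","),
              if (!is.null(x$seqs)) ", in-memory" else ""))
  invisible(x)
}

#' Sequence lengths known to an index
#' @param idx A `gffx_faidx`.
#' @return Named integer vector.
#' @export
fa_lengths <- function(idx) stats::setNames(idx$fai$length, idx$fai$name)

#' Fetch a genomic subsequence
#'
#' Random access through the faidx byte offsets (or the in-memory fallback);
#' equals the corresponding slice of the full sequence, case preserved.
#'
#' @param idx A `gffx_faidx` from [index_fasta()].
#' @param seqid Sequence name.
#' @param start,end 1-based inclusive coordinates.
#' @return Character scalar.
#' @export
fa_fetch <- function(idx, seqid, start, end) {
  row <- match(seqid, idx$fai$name)
  if (is.na(row)) stop("sequence '", seqid, "' not in FASTA index")
  if (start < 1L || end < start || end > idx$fai$length[row])
    stop(sprintf("range %d-%d outside sequence '%s' (length %d)",
                 start, end, seqid, idx$fai$length[row]))
  if (!is.null(idx$seqs)) return(substr(idx$seqs[[seqid]], start, end))
  lb <- idx$fai$linebases[row]
  lw <- idx$fai$linewidth[row]
  byte0 <- idx$fai$offset[row] + ((start - 1L) %/% lb) * lw +
    (start - 1L) %% lb
  n_bases <- end - start + 1L
  n_breaks <- (end - 1L) %/% lb - (start - 1L) %/% lb
  con <- file(idx$path, "rb")
  on.exit(close(con))
  seek(con, byte0)
  raw <- readChar(con, n_bases + n_breaks * (lw - lb), useBytes = TRUE)
  gsub("[\r\n]", "", raw)
}

#' Reverse complement of DNA strings (case preserved)
#' @param s Character vector of DNA sequences.
#' @export
revcomp <- function(s) {
  s <- chartr("ACGTUacgtuRYKMrykmBDHVbdhv", "TGCAAtgcaaYRMKyrmkVHDBvhdb", s)
  vapply(s, function(x) intToUtf8(rev(utf8ToInt(x))), "",
         USE.NAMES = FALSE)
}

#' Spliced transcript or CDS sequence
#'
#' Concatenates the segment subsequences in genomic order and, for minus
#' strand transcripts, returns the reverse complement of that concatenation.
#' Soft-masking (case) is preserved from the genome.
#'
#' @param t A [transcript()].
#' @param genome A `gffx_faidx` from [index_fasta()].
#' @param segments `"exons"` or `"cds"`.
#' @return DNA string, or `NULL` (with a warning) for `segments = "cds"` on
#'   a transcript without CDS.
#' @examples
#' \dontrun{
#' spliced_sequence(t1, genome, "exons")
#' }
#' @export
spliced_sequence <- function(t, genome, segments = c("exons", "cds")) {
  segments <- match.arg(segments)
  m <- if (segments == "cds") t$cds else tx_segments(t)
  if (!nrow(m)) {
    warning("transcript '", t$id, "' has no ", segments, " segments; skipped")
    return(NULL)
  }
  pieces <- vapply(seq_len(nrow(m)), function(i) {
    tryCatch(fa_fetch(genome, t$seqid, m[i, 1L], m[i, 2L]),
             error = function(e)
               stop("transcript '", t$id, "', segment ", m[i, 1L], "-",
                    m[i, 2L], ": ", conditionMessage(e), call. = FALSE))
  }, "")
  s <- paste(pieces, collapse = "")
  if (t$strand == "-") revcomp(s) else s
}

# standard genetic code, codons ordered T/C/A/G by position
codon_table <- local({
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L),
                   rep(b, 16L))
  aa <- strsplit(paste0("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
                        "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1L]]
  stats::setNames(aa, codons)
})

#' Translate a coding sequence
#'
#' Standard genetic code. Translation starts after trimming `phase` bases;
#' a stop codon is rendered as `"."` and terminates the output; a trailing
#' incomplete codon is ignored; codons containing ambiguous bases yield
#' `"X"`.
#'
#' @param cds_dna DNA string (spliced CDS on the coding strand).
#' @param phase Frame offset in 0/1/2.
#' @return Protein string (empty, with a warning, for inputs shorter than
#'   one codon after the phase trim).
#' @examples
#' translate_cds("ATGAAATAG")   # "MK."
#' @export
translate_cds <- function(cds_dna, phase = 0L) {
  s <- toupper(substr(cds_dna, phase + 1L, nchar(cds_dna)))
  s <- chartr("U", "T", s)
  n_codons <- nchar(s) %/% 3L
  if (n_codons == 0L) {
    warning("coding sequence shorter than one codon after phase trim")
    return("")
  }
  out <- character(n_codons)
  for (i in seq_len(n_codons)) {
    codon <- substr(s, 3L * i - 2L, 3L * i)
    aa <- unname(codon_table[codon])
    if (is.na(aa)) aa <- "X"
    if (aa == "*") {
      out[i] <- "."
      return(paste(out[seq_len(i)], collapse = ""))
    }
    out[i] <- aa
  }
  paste(out, collapse = "")
}

stop_codons <- c("TAA", "TAG", "TGA")

# phase of the 5'-most CDS segment on the coding strand
tx_cds_phase5 <- function(t) {
  if (!nrow(t$cds)) return(0L)
  i <- if (t$strand == "-") nrow(t$cds) else 1L
  p <- t$cds_phase[i]
  if (is.na(p)) {
    warning("transcript '", t$id, "': missing frame; assuming phase 0")
    p <- 0L
  }
  p
}

#' Validate the CDS of a coding transcript
#'
#' Splices the CDS from the genome on the coding strand and reports whether
#' the first codon is a START (ATG), whether the terminal codon is a STOP
#' (TAA/TAG/TGA), and any in-frame STOP codons strictly before the terminal
#' codon. The partialness label summarizes the findings for annotation
#' output: `"complete"`, `"missing_start"`, `"missing_stop"` or
#' `"missing_both"`, with `",inframe_stop"` appended when internal stops
#' exist.
#'
#' @param t A coding [transcript()].
#' @param genome A `gffx_faidx`.
#' @return A list of class `gffx_cds_status` with fields `has_start`,
#'   `has_stop`, `inframe_stop_positions` (0-based codon indices),
#'   `frame_consistent` and `partialness_label`.
#' @export
validate_cds <- function(t, genome) {
  if (!nrow(t$cds)) stop("transcript '", t$id, "' has no CDS segments")
  dna <- spliced_sequence(t, genome, "cds")
  phase <- tx_cds_phase5(t)
  s <- toupper(substr(dna, phase + 1L, nchar(dna)))
  n_codons <- nchar(s) %/% 3L
  frame_ok <- nchar(s) %% 3L == 0L
  codons <- substring(s, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  has_start <- n_codons >= 1L && codons[1L] == "ATG"
  has_stop <- n_codons >= 1L && codons[n_codons] %in% stop_codons
  internal <- which(codons[-n_codons] %in% stop_codons) - 1L
  label <- if (has_start && has_stop) "complete"
    else if (!has_start && !has_stop) "missing_both"
    else if (!has_start) "missing_start"
    else "missing_stop"
  if (length(internal)) label <- paste0(label, ",inframe_stop")
  structure(list(
    has_start = has_start, has_stop = has_stop,
    inframe_stop_positions = as.integer(internal),
    frame_consistent = frame_ok, partialness_label = label
  ), class = "gffx_cds_status")
}

#' @export
print.gffx_cds_status <- function(x, ...) {
  cat(sprintf("<CDS status: %s%s>\n", x$partialness_label,
              if (!x$frame_consistent) ", frame-inconsistent" else ""))
  invisible(x)
}

canonical_splice_pairs <- c("GT-AG", "GC-AG", "AT-AC")

#' Splice-site dinucleotides of a transcript's introns
#'
#' One entry per intron, read on the transcript's strand: the donor is the
#' first intron dinucleotide, the acceptor the last, both 5' to 3' on the
#' coding strand. Canonical means GT-AG, GC-AG or AT-AC (case-insensitive,
#' so soft-masked sites still validate). For strand "." the introns are
#' reported non-assessable (`canonical = NA`).
#'
#' @param t A multi-exon [transcript()].
#' @param genome A `gffx_faidx`.
#' @return data.frame with columns `intron_start`, `intron_end`, `donor`,
#'   `acceptor`, `canonical`, in transcript (5' to 3') order.
#' @export
splice_sites <- function(t, genome) {
  ii <- tx_introns(t)
  if (!nrow(ii))
    return(data.frame(intron_start = integer(0), intron_end = integer(0),
                      donor = character(0), acceptor = character(0),
                      canonical = logical(0)))
  left <- vapply(seq_len(nrow(ii)), function(i)
    fa_fetch(genome, t$seqid, ii[i, 1L], ii[i, 1L] + 1L), "")
  right <- vapply(seq_len(nrow(ii)), function(i)
    fa_fetch(genome, t$seqid, ii[i, 2L] - 1L, ii[i, 2L]), "")
  if (t$strand == "-") {
    donor <- revcomp(right)
    acceptor <- revcomp(left)
    ord <- rev(seq_len(nrow(ii)))
  } else {
    donor <- left
    acceptor <- right
    ord <- seq_len(nrow(ii))
  }
  canonical <- if (t$strand == ".") rep(NA, nrow(ii)) else
    paste0(toupper(donor), "-", toupper(acceptor)) %in% canonical_splice_pairs
  data.frame(intron_start = ii[ord, 1L], intron_end = ii[ord, 2L],
             donor = donor[ord], acceptor = acceptor[ord],
             canonical = canonical[ord], stringsAsFactors = FALSE)
}

#' Write transcript sequences extracted from a genome
#'
#' FASTA output helper behind the `-w`/`-x`/`-y` style outputs: spliced
#' exon sequences, spliced CDS, or CDS translations, wrapped at 60 columns.
#' Transcripts without CDS are skipped with a diagnostic for the CDS-based
#' modes. Extra defline fields from [to_table()] columns can be appended.
#'
#' @param set A [annotation_set()].
#' @param genome A `gffx_faidx`.
#' @param what `"exons"`, `"cds"` or `"protein"`.
#' @param file Optional output path.
#' @param defline_attrs Optional attribute list appended to deflines
#'   (rendered as in [to_table()], excluding `@id`).
#' @return Named character vector of sequences (invisibly when writing).
#' @export
extract_sequences <- function(set, genome,
                              what = c("exons", "cds", "protein"),
                              file = NULL, defline_attrs = NULL) {
  what <- match.arg(what)
  ord <- unlist(lapply(set$seqid_order,
                       function(sq) set$index[[sq]]$id), use.names = FALSE)
  out <- character(0)
  for (id in ord) {
    t <- set$transcripts[[id]]
    if (what != "exons" && !nrow(t$cds)) {
      warning("transcript '", id, "' has no CDS; skipped from ", what,
              " output")
      next
    }
    s <- spliced_sequence(t, genome, if (what == "exons") "exons" else "cds")
    if (what == "protein") s <- translate_cds(s, tx_cds_phase5(t))
    nm <- id
    if (!is.null(defline_attrs)) {
      extra <- vapply(setdiff(defline_attrs, "@id"),
                      function(a) table_field(t, a), "")
      if (length(extra)) nm <- paste(c(id, extra), collapse = " ")
    }
    out[nm] <- s
  }
  if (!is.null(file)) {
    write_fasta(out, file)
    return(invisible(out))
  }
  out
}
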