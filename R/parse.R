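#' Parse a GFF3, GTF or BED annotation stream
#'
#' Order-tolerant parser building a fully linked gene/transcript/exon
#' hierarchy. Features may arrive in any order: all records are held until
#' the end of input and linked through GFF3 `ID`/`Parent`, GTF
#' `transcript_id`, or BED block structure. Transcripts lacking explicit
#' exon features but carrying CDS segments are recorded as CDS-only (exon
#' synthesis is a separate transform, see [force_exons()]).
#'
#' Malformed lines are skipped with a diagnostic (fatal under
#' `strict = TRUE`); exons whose `Parent` never appears are reported as
#' orphans; transcripts whose exons disagree on strand are rejected. A second
#' GFF3 record reusing a transcript `ID` is renamed with a numeric
#' discriminator and a warning (in GTF, lines sharing a `transcript_id`
#' merge by dialect).
#'
#' @param x File path, connection, single string with embedded newlines, or
#'   character vector of lines.
#' @param format `"auto"` (content sniffing), `"gff3"`, `"gtf"` or `"bed"`.
#' @param strict Abort on malformed lines instead of skipping them.
#' @param verbose Emit diagnostics as messages as they occur (they are always
#'   collected in `$diagnostics` on the returned set).
#' @return A [annotation_set()].
#' @examples
#' set <- parse_annotation(c(
#'   "chr1\t.\texon\t100\t200\t.\t+\t.\tParent=t1",
#'   "chr1\t.\tmRNA\t100\t500\t.\t+\t.\tID=t1"), format = "gff3")
#' tx_ids(set)
#' @export
parse_annotation <- function(x, format = c("auto", "gff3", "gtf", "bed"),
                             strict = FALSE, verbose = FALSE) {
  format <- match.arg(format)
  lines <- read_input_lines(x)
  if (format == "auto") format <- sniff_format(lines)
  switch(format,
         gff3 = parse_gff3(lines, strict = strict, verbose = verbose),
         gtf = parse_gtf(lines, strict = strict, verbose = verbose),
         bed = parse_bed(lines, strict = strict, verbose = verbose))
}

read_input_lines <- function(x) {
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  if (is.character(x) && length(x) == 1L && !grepl("\n", x, fixed = TRUE) &&
      file.exists(x))
    return(readLines(x, warn = FALSE))
  if (is.character(x) && length(x) == 1L && grepl("\n", x, fixed = TRUE))
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  if (is.character(x)) return(x)
  stop("cannot read annotation input")
}

num_like <- function(x) grepl("^[0-9]+$", x)

#' Guess the annotation format of a set of input lines
#' @param lines Character vector of raw lines.
#' @return One of `"gff3"`, `"gtf"`, `"bed"`.
#' @export
sniff_format <- function(lines) {
  for (ln in lines) {
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) >= 9L && num_like(f[4L]) && num_like(f[5L])) {
      if (grepl('(transcript_id|gene_id)\\s+"', f[9L])) return("gtf")
      return("gff3")
    }
    if (length(f) >= 3L && num_like(f[2L]) && num_like(f[3L])) return("bed")
    stop("cannot determine annotation format from input")
  }
  stop("no data lines in annotation input")
}

# ---- attribute codecs ----------------------------------------------------

pct_decode <- function(x) {
  if (!grepl("%", x, fixed = TRUE)) return(x)
  utils::URLdecode(x)
}

pct_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  gsub("\n", "%0A", x, fixed = TRUE)
}

parse_gff3_attrs <- function(s) {
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 1L) next
    key <- substr(p, 1L, eq - 1L)
    out[[key]] <- pct_decode(substr(p, eq + 1L, nchar(p)))
  }
  out
}

parse_gtf_attrs <- function(s) {
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  out <- list()
  for (p in parts) {
    sp <- regexpr("[ \t]", p)
    if (sp < 1L) next
    key <- substr(p, 1L, sp - 1L)
    val <- trimws(substr(p, sp + 1L, nchar(p)))
    val <- sub('^"', "", val)
    val <- sub('"$', "", val)
    out[[key]] <- val
  }
  out
}

# ---- shared 9-column record reader ---------------------------------------

read_gff_records <- function(lines, attr_fun, strict, diag) {
  recs <- vector("list", length(lines))
  n <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      if (startsWith(ln, "##FASTA")) break
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L) {
      diag(sprintf("line %d: expected 9 tab-separated fields, got %d; skipped",
                   i, length(f)), fatal = strict)
      next
    }
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end) || start < 1L || end < start) {
      diag(sprintf("line %d: malformed coordinates '%s'..'%s'; skipped",
                   i, f[4L], f[5L]), fatal = strict)
      next
    }
    n <- n + 1L
    recs[[n]] <- list(
      seqid = f[1L], source = f[2L], type = f[3L], start = start, end = end,
      score = if (f[6L] == ".") NA_real_ else suppressWarnings(as.numeric(f[6L])),
      strand = if (f[7L] %in% c("+", "-")) f[7L] else ".",
      phase = if (f[8L] %in% c("0", "1", "2")) as.integer(f[8L]) else NA_integer_,
      attrs = attr_fun(f[9L]), line = i
    )
  }
  recs[seq_len(n)]
}

make_diag <- function(verbose) {
  msgs <- character(0)
  list(
    note = function(msg, fatal = FALSE) {
      if (fatal) stop(msg, call. = FALSE)
      msgs <<- c(msgs, msg)
      if (verbose) message(msg)
    },
    all = function() msgs
  )
}

is_segment_type <- function(type) {
  tolower(type) %in% c("exon", "cds", "pseudogenic_exon")
}

is_transcriptish_type <- function(type) {
  grepl("rna|transcript", tolower(type))
}

is_geneish_type <- function(type) {
  grepl("(^gene$)|(_gene$)", tolower(type))
}

# ---- GFF3 ----------------------------------------------------------------

parse_gff3 <- function(lines, strict = FALSE, verbose = FALSE) {
  dg <- make_diag(verbose)
  recs <- read_gff_records(lines, parse_gff3_attrs, strict, dg$note)
  nrec <- length(recs)
  seqid_order <- unique(vapply(recs, function(r) r$seqid, ""))

  seg <- vapply(recs, function(r) is_segment_type(r$type), NA)
  ids <- vapply(recs, function(r) r$attrs$ID %||% NA_character_, "")
  parents <- lapply(recs, function(r) {
    p <- r$attrs$Parent
    if (is.null(p)) character(0) else strsplit(p, ",", fixed = TRUE)[[1L]]
  })

  # map container id -> record indices (first record with that ID wins;
  # later duplicates of container ids get a discriminator)
  id_first <- new.env(parent = emptyenv())
  rename <- character(0)
  for (i in seq_len(nrec)) {
    if (seg[i] || is.na(ids[i])) next
    id <- ids[i]
    if (!is.null(id_first[[id]])) {
      k <- 1L
      repeat {
        cand <- paste0(id, "_", k)
        if (is.null(id_first[[cand]]) ) break
        k <- k + 1L
      }
      warning("duplicate feature ID '", id, "' renamed to '", cand, "'")
      rename[as.character(i)] <- cand
      ids[i] <- cand
      id_first[[cand]] <- i
    } else {
      id_first[[id]] <- i
    }
  }

  children_of <- new.env(parent = emptyenv())
  for (i in seq_len(nrec)) {
    n_known <- 0L
    for (p in parents[[i]]) {
      if (is.null(id_first[[p]])) next
      n_known <- n_known + 1L
      pid <- as.character(id_first[[p]])
      children_of[[pid]] <- c(children_of[[pid]], i)
    }
    if (length(parents[[i]]) && n_known == 0L) {
      dg$note(sprintf("line %d: feature of type '%s' has unknown Parent '%s'",
                      recs[[i]]$line, recs[[i]]$type,
                      paste(parents[[i]], collapse = ",")))
    }
  }
  kids <- function(i) children_of[[as.character(i)]] %||% integer(0)

  transcriptish <- vapply(seq_len(nrec), function(i) {
    if (seg[i]) return(FALSE)
    if (any(seg[kids(i)])) return(TRUE)
    is_transcriptish_type(recs[[i]]$type) ||
      (!is_geneish_type(recs[[i]]$type) && length(kids(i)) == 0L &&
         length(parents[[i]]) == 0L && !is.na(ids[i]) &&
         !is_known_nontx_type(recs[[i]]$type))
  }, NA)
  geneish <- vapply(seq_len(nrec), function(i) {
    if (seg[i] || transcriptish[i]) return(FALSE)
    if (any(transcriptish[kids(i)])) return(TRUE)
    is_geneish_type(recs[[i]]$type)
  }, NA)
  # a pseudogene-like container that directly parents exons is a transcript
  transcriptish <- transcriptish & !geneish

  txs <- list()
  for (i in which(transcriptish)) {
    r <- recs[[i]]
    id <- ids[i]
    if (is.na(id)) {
      id <- sprintf("tx_line%d", r$line)
      dg$note(sprintf("line %d: transcript record lacks ID; assigned '%s'",
                      r$line, id))
    }
    segs <- kids(i)[seg[kids(i)]]
    ex <- list(); cd <- list(); ph <- integer(0); opaque <- list()
    strands <- character(0)
    for (k in kids(i)) {
      rk <- recs[[k]]
      if (seg[k]) {
        strands <- c(strands, rk$strand)
        if (tolower(rk$type) == "cds") {
          cd[[length(cd) + 1L]] <- c(rk$start, rk$end)
          ph <- c(ph, rk$phase)
        } else {
          ex[[length(ex) + 1L]] <- c(rk$start, rk$end)
        }
      } else if (!transcriptish[k] && !geneish[k]) {
        opaque[[length(opaque) + 1L]] <- rk
      }
    }
    known <- setdiff(unique(strands), ".")
    if (length(known) > 1L) {
      dg$note(sprintf(
        "transcript '%s' rejected: exons on mixed strands (%s)",
        id, paste(known, collapse = "/")))
      next
    }
    strand <- if (r$strand != ".") r$strand
      else if (length(known)) known else "."
    # re-attach phase in genomic order of CDS rows
    if (length(cd)) {
      cdm <- do.call(rbind, cd)
      ord <- order(cdm[, 1L], cdm[, 2L])
      cdm <- cdm[ord, , drop = FALSE]
      ph <- ph[ord]
    } else {
      cdm <- NULL; ph <- NULL
    }
    if (!length(ex) && is.null(cdm)) {
      # span-only record: treat as a single exon covering the span
      ex <- list(c(r$start, r$end))
      dg$note(sprintf(
        "transcript '%s' has no exon or CDS children; using its span", id))
    }
    pgene <- NULL
    for (p in parents[[i]]) {
      pi <- id_first[[p]]
      if (!is.null(pi) && geneish[pi]) { pgene <- pi; break }
    }
    gene_id <- if (!is.null(pgene)) ids[pgene] else
      (r$attrs$geneID %||% r$attrs$gene_id %||% NA_character_)
    gene_name <- r$attrs$gene_name %||%
      (if (!is.null(pgene))
        recs[[pgene]]$attrs$gene_name %||% recs[[pgene]]$attrs$Name %||%
         NA_character_ else NA_character_)
    at <- r$attrs
    at$ID <- NULL; at$Parent <- NULL
    tx <- tryCatch(
      transcript(id, r$seqid, strand, exons = ex, cds = cdm, cds_phase = ph,
                 gene_id = gene_id, gene_name = gene_name, score = r$score,
                 source = r$source, feature_type = r$type, attributes = at,
                 children = opaque),
      error = function(e) {
        dg$note(sprintf("transcript '%s' rejected: %s", id,
                        conditionMessage(e)))
        NULL
      })
    if (!is.null(tx)) txs[[id]] <- tx
  }

  genes <- list()
  for (i in which(geneish)) {
    r <- recs[[i]]
    id <- ids[i]
    if (is.na(id)) next
    child_tx <- ids[kids(i)[transcriptish[kids(i)]]]
    child_tx <- child_tx[child_tx %in% names(txs)]
    at <- r$attrs; at$ID <- NULL; at$Parent <- NULL
    genes[[id]] <- gene(id, r$seqid, r$strand, r$start, r$end,
                        name = r$attrs$Name %||% r$attrs$gene_name %||%
                          NA_character_,
                        transcript_ids = child_tx, source = r$source,
                        feature_type = r$type, attributes = at)
  }

  annotation_set(unname(txs), unname(genes), seqid_order = seqid_order,
                 diagnostics = dg$all())
}

is_known_nontx_type <- function(type) {
  tolower(type) %in% c("region", "chromosome", "contig", "scaffold",
                       "biological_region", "match", "cdna_match")
}

# ---- GTF -----------------------------------------------------------------

parse_gtf <- function(lines, strict = FALSE, verbose = FALSE) {
  dg <- make_diag(verbose)
  recs <- read_gff_records(lines, parse_gtf_attrs, strict, dg$note)
  seqid_order <- unique(vapply(recs, function(r) r$seqid, ""))

  tx_env <- new.env(parent = emptyenv())
  tid_order <- character(0)
  gene_recs <- list()
  for (r in recs) {
    tid <- r$attrs$transcript_id
    type <- tolower(r$type)
    if (is.null(tid)) {
      if (type == "gene" && !is.null(r$attrs$gene_id)) {
        gene_recs[[r$attrs$gene_id]] <- r
      } else {
        dg$note(sprintf("line %d: '%s' record without transcript_id; skipped",
                        r$line, r$type))
      }
      next
    }
    e <- tx_env[[tid]]
    if (is.null(e)) {
      e <- list(exons = list(), cds = list(), phase = integer(0),
                container = NULL, opaque = list(), first = r)
      tid_order <- c(tid_order, tid)
    }
    if (type == "exon") {
      e$exons[[length(e$exons) + 1L]] <- r
    } else if (type == "cds") {
      e$cds[[length(e$cds) + 1L]] <- r
      e$phase <- c(e$phase, r$phase)
    } else if (type == "transcript" || is_transcriptish_type(r$type)) {
      e$container <- r
    } else {
      e$opaque[[length(e$opaque) + 1L]] <- r
    }
    tx_env[[tid]] <- e
  }

  txs <- list()
  for (tid in tid_order) {
    e <- tx_env[[tid]]
    main <- e$container %||% e$first
    strands <- vapply(c(e$exons, e$cds), function(r) r$strand, "")
    known <- setdiff(unique(strands), ".")
    if (length(known) > 1L) {
      dg$note(sprintf("transcript '%s' rejected: exons on mixed strands", tid))
      next
    }
    strand <- if (length(known)) known else main$strand
    ex <- lapply(e$exons, function(r) c(r$start, r$end))
    cd <- lapply(e$cds, function(r) c(r$start, r$end))
    ph <- e$phase
    if (length(cd)) {
      cdm <- do.call(rbind, cd)
      ord <- order(cdm[, 1L], cdm[, 2L])
      cdm <- cdm[ord, , drop = FALSE]
      ph <- ph[ord]
    } else {
      cdm <- NULL; ph <- NULL
    }
    if (!length(ex) && is.null(cdm)) {
      ex <- list(c(main$start, main$end))
      dg$note(sprintf(
        "transcript '%s' has no exon or CDS lines; using its span", tid))
    }
    at <- main$attrs
    at$transcript_id <- NULL; at$gene_id <- NULL
    tx <- tryCatch(
      transcript(tid, main$seqid, strand, exons = ex, cds = cdm,
                 cds_phase = ph,
                 gene_id = main$attrs$gene_id %||% NA_character_,
                 gene_name = main$attrs$gene_name %||% NA_character_,
                 score = main$score, source = main$source,
                 feature_type = if (!is.null(e$container)) e$container$type
                   else "transcript",
                 attributes = at, children = e$opaque),
      error = function(err) {
        dg$note(sprintf("transcript '%s' rejected: %s", tid,
                        conditionMessage(err)))
        NULL
      })
    if (!is.null(tx)) txs[[tid]] <- tx
  }

  # genes: explicit gene lines plus synthesized groupings by gene_id
  genes <- list()
  by_gene <- split(names(txs), vapply(txs, function(t) t$gene_id, ""))
  by_gene[["NA"]] <- NULL
  for (gid in names(by_gene)) {
    members <- by_gene[[gid]]
    spans <- do.call(rbind, lapply(txs[members],
                                   function(t) c(t$start, t$end)))
    r <- gene_recs[[gid]]
    t1 <- txs[[members[1L]]]
    genes[[gid]] <- gene(
      gid, t1$seqid, t1$strand,
      start = min(spans[, 1L], if (!is.null(r)) r$start),
      end = max(spans[, 2L], if (!is.null(r)) r$end),
      name = if (!is.null(r)) r$attrs$gene_name %||% NA_character_
        else t1$gene_name,
      transcript_ids = members,
      source = t1$source,
      attributes = if (!is.null(r)) r$attrs else list())
  }
  for (gid in setdiff(names(gene_recs), names(genes))) {
    r <- gene_recs[[gid]]
    at <- r$attrs; at$gene_id <- NULL
    genes[[gid]] <- gene(gid, r$seqid, r$strand, r$start, r$end,
                         name = r$attrs$gene_name %||% NA_character_,
                         source = r$source, attributes = at)
  }

  annotation_set(unname(txs), unname(genes), seqid_order = seqid_order,
                 diagnostics = dg$all())
}

# ---- BED -----------------------------------------------------------------

parse_bed <- function(lines, strict = FALSE, verbose = FALSE) {
  dg <- make_diag(verbose)
  txs <- list()
  seqid_order <- character(0)
  n_anon <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "track") ||
        startsWith(ln, "browser")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L || !num_like(f[2L]) || !num_like(f[3L])) {
      dg$note(sprintf("line %d: malformed BED line; skipped", i),
              fatal = strict)
      next
    }
    cstart <- as.integer(f[2L]); cend <- as.integer(f[3L])
    if (cend <= cstart) {
      dg$note(sprintf("line %d: empty/negative BED interval; skipped", i),
              fatal = strict)
      next
    }
    name <- if (length(f) >= 4L && nzchar(f[4L])) f[4L] else {
      n_anon <- n_anon + 1L
      sprintf("bed_%d", n_anon)
    }
    score <- if (length(f) >= 5L && f[5L] != ".")
      suppressWarnings(as.numeric(f[5L])) else NA_real_
    strand <- if (length(f) >= 6L && f[6L] %in% c("+", "-")) f[6L] else "."
    span_start <- cstart + 1L   # 0-based half-open -> 1-based inclusive
    span_end <- cend
    if (length(f) >= 12L) {
      nblocks <- as.integer(f[10L])
      sizes <- as.integer(strsplit(f[11L], ",", fixed = TRUE)[[1L]])
      starts <- as.integer(strsplit(f[12L], ",", fixed = TRUE)[[1L]])
      if (length(sizes) < nblocks || length(starts) < nblocks) {
        dg$note(sprintf("line %d: inconsistent BED block lists; skipped", i),
                fatal = strict)
        next
      }
      ex_start <- span_start + starts[seq_len(nblocks)]
      ex_end <- ex_start + sizes[seq_len(nblocks)] - 1L
      ex <- cbind(ex_start, ex_end)
    } else {
      ex <- cbind(span_start, span_end)
    }
    cds <- NULL
    if (length(f) >= 8L && num_like(f[7L]) && num_like(f[8L])) {
      ts <- as.integer(f[7L]); te <- as.integer(f[8L])
      if (te > ts) {
        thick <- c(ts + 1L, te)
        pieces <- lapply(seq_len(nrow(ex)), function(k) {
          s <- max(ex[k, 1L], thick[1L]); e <- min(ex[k, 2L], thick[2L])
          if (e >= s) c(s, e) else NULL
        })
        pieces <- Filter(Negate(is.null), pieces)
        if (length(pieces)) cds <- do.call(rbind, pieces)
      }
    }
    if (anyDuplicated(name) || !is.null(txs[[name]])) {
      k <- 1L
      repeat {
        cand <- paste0(name, "_", k)
        if (is.null(txs[[cand]])) break
        k <- k + 1L
      }
      warning("duplicate BED name '", name, "' renamed to '", cand, "'")
      name <- cand
    }
    tx <- tryCatch(
      transcript(name, f[1L], strand, exons = ex, cds = cds, score = score,
                 source = "bed", feature_type = "transcript"),
      error = function(e) {
        dg$note(sprintf("line %d: %s", i, conditionMessage(e)))
        NULL
      })
    if (is.null(tx)) next
    txs[[name]] <- tx
    if (!f[1L] %in% seqid_order) seqid_order <- c(seqid_order, f[1L])
  }
  annotation_set(unname(txs), seqid_order = seqid_order,
                 diagnostics = dg$all())
}
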