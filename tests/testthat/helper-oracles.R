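# Shared test fixtures and independent brute-force oracles. The oracles
# deliberately avoid the package's interval/index machinery: plain loops
# and integer-set arithmetic only.

mk_tx <- function(id, exons, seqid = "chr1", strand = "+", ...) {
  transcript(id, seqid, strand, exons = exons, ...)
}

mk_set <- function(...) annotation_set(list(...))

# random annotation set with integer coordinates; gaps >= 10 so the default
# close-exon pre-merge is the identity on these sets
rand_set <- function(seed, n = 30, seqids = c("chr1", "chr2"),
                     max_start = 5000, prefix = "t") {
  withr::with_seed(seed, {
    txs <- lapply(seq_len(n), function(i) {
      k <- sample(1:4, 1)
      start <- sample(seq_len(max_start), 1)
      lens <- sample(30:200, k, replace = TRUE)
      gaps <- if (k > 1) sample(10:300, k - 1, replace = TRUE) else integer(0)
      ex <- matrix(0L, k, 2)
      pos <- start
      for (e in seq_len(k)) {
        ex[e, ] <- c(pos, pos + lens[e] - 1L)
        pos <- pos + lens[e] + (if (e < k) gaps[e] else 0L)
      }
      transcript(sprintf("%s%03d", prefix, i), sample(seqids, 1),
                 sample(c("+", "-"), 1), exons = ex)
    })
    annotation_set(txs)
  })
}

# ---- brute-force oracles -------------------------------------------------

brute_overlap_scan <- function(set, seqid, start, end) {
  hits <- Filter(function(t) t$seqid == seqid && t$start <= end &&
                   t$end >= start, set$transcripts)
  unname(sort(vapply(hits, function(t) t$id, "")))
}

# exonic base set of a transcript as "strand:pos" keys
.base_keys <- function(t) {
  ex <- t$exons
  pos <- unlist(lapply(seq_len(nrow(ex)), function(i) ex[i, 1]:ex[i, 2]))
  paste(t$seqid, t$strand, pos)
}

brute_components <- function(txs, same_strand = TRUE) {
  n <- length(txs)
  lab <- seq_len(n)
  exon_ov <- function(a, b) {
    if (a$seqid != b$seqid) return(FALSE)
    if (same_strand && a$strand != b$strand) return(FALSE)
    for (i in seq_len(nrow(a$exons))) for (j in seq_len(nrow(b$exons))) {
      if (a$exons[i, 1] <= b$exons[j, 2] && a$exons[i, 2] >= b$exons[j, 1])
        return(TRUE)
    }
    FALSE
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (lab[i] != lab[j] && exon_ov(txs[[i]], txs[[j]])) {
        lab[lab == lab[j]] <- lab[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# naive six-level TP/FN/FP recomputation from first principles
naive_stats <- function(query, ref, e = 100, se = 0.8) {
  qt <- query$transcripts
  # mirror the pipeline's reference chain de-duplication
  rt <- ref$transcripts
  keys <- vapply(rt, function(t) paste(t$seqid, t$strand,
                                       paste(tx_introns(t), collapse = ",")),
                 "")
  multi <- vapply(rt, function(t) nrow(t$exons) > 1, NA)
  drop <- character(0)
  for (k in unique(keys[multi])) {
    grp <- names(rt)[multi & keys == k]
    if (length(grp) < 2) next
    spans <- vapply(rt[grp], function(t) t$end - t$start + 1L, 1L)
    starts <- vapply(rt[grp], function(t) t$start, 1L)
    drop <- c(drop, setdiff(grp, grp[order(-spans, starts, grp)][1]))
  }
  rt <- rt[setdiff(names(rt), drop)]

  out <- list()
  # base
  qb <- unique(unlist(lapply(qt, .base_keys)))
  rb <- unique(unlist(lapply(rt, .base_keys)))
  out$base <- c(sn_tp = length(intersect(rb, qb)), sn_total = length(rb),
                pr_tp = length(intersect(qb, rb)), pr_total = length(qb))
  # exon: distinct exons with ORed free flags
  ex_tab <- function(txs) {
    rows <- list()
    for (t in txs) for (i in seq_len(nrow(t$exons))) {
      key <- paste(t$seqid, t$strand, t$exons[i, 1], t$exons[i, 2])
      prev <- rows[[key]] %||% list(seqid = t$seqid, strand = t$strand,
                                    s = t$exons[i, 1], e2 = t$exons[i, 2],
                                    sf = FALSE, ef = FALSE)
      prev$sf <- prev$sf || i == 1
      prev$ef <- prev$ef || i == nrow(t$exons)
      rows[[key]] <- prev
    }
    rows
  }
  qe <- ex_tab(qt); re <- ex_tab(rt)
  exon_match <- function(a, b) {
    a$seqid == b$seqid && a$strand == b$strand &&
      (a$s == b$s || (a$sf && b$sf && abs(a$s - b$s) <= e)) &&
      (a$e2 == b$e2 || (a$ef && b$ef && abs(a$e2 - b$e2) <= e))
  }
  q_hit <- vapply(qe, function(a) any(vapply(re, exon_match, NA, a = a)), NA)
  r_hit <- vapply(re, function(b)
    any(vapply(qe, function(a) exon_match(a, b), NA)), NA)
  out$exon <- c(sn_tp = sum(r_hit), sn_total = length(re),
                pr_tp = sum(q_hit), pr_total = length(qe))
  # intron
  in_keys <- function(txs) {
    unique(unlist(lapply(txs, function(t) {
      ii <- tx_introns(t)
      if (!nrow(ii)) return(character(0))
      paste(t$seqid, t$strand, ii[, 1], ii[, 2])
    })))
  }
  qi <- in_keys(qt); ri <- in_keys(rt)
  out$intron <- c(sn_tp = length(intersect(ri, qi)), sn_total = length(ri),
                  pr_tp = length(intersect(qi, ri)), pr_total = length(qi))
  # intron chain
  ch <- function(txs) vapply(Filter(function(t) nrow(t$exons) > 1, txs),
                             function(t) paste(t$seqid, t$strand,
                                               paste(tx_introns(t),
                                                     collapse = ",")), "")
  qc <- ch(qt); rc <- ch(rt)
  out$intron_chain <- c(sn_tp = sum(rc %in% qc), sn_total = length(rc),
                        pr_tp = sum(qc %in% rc), pr_total = length(qc))
  # transcript
  naive_tmatch <- function(a, b) {
    if (a$seqid != b$seqid || a$strand != b$strand) return(FALSE)
    na <- nrow(a$exons); nb <- nrow(b$exons)
    if (na > 1 && nb > 1) {
      ia <- tx_introns(a); ib <- tx_introns(b)
      return(nrow(ia) == nrow(ib) && all(ia == ib) &&
               abs(a$start - b$start) <= e && abs(a$end - b$end) <= e)
    }
    if (na == 1 && nb == 1) {
      ov <- max(0, min(a$end, b$end) - max(a$start, b$start) + 1)
      return(ov > se * max(a$end - a$start + 1, b$end - b$start + 1))
    }
    FALSE
  }
  qm <- vapply(qt, function(a) any(vapply(rt, naive_tmatch, NA, a = a)), NA)
  rm_ <- vapply(rt, function(b)
    any(vapply(qt, function(a) naive_tmatch(a, b), NA)), NA)
  out$transcript <- c(sn_tp = sum(rm_), sn_total = length(rt),
                      pr_tp = sum(qm), pr_total = length(qt))
  # locus
  q_comp <- brute_components(qt)
  r_comp <- brute_components(rt)
  q_loci_hit <- vapply(unique(q_comp), function(ci) any(qm[q_comp == ci]), NA)
  r_loci_hit <- vapply(unique(r_comp), function(ci) any(rm_[r_comp == ci]), NA)
  out$locus <- c(sn_tp = sum(r_loci_hit), sn_total = length(unique(r_comp)),
                 pr_tp = sum(q_loci_hit), pr_total = length(unique(q_comp)))
  out
}

# write a small genome + index in a temp dir
tmp_genome <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  index_fasta(path)
}
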