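test_that("equivalent transfrags across samples collapse to one record", {
  s1 <- mk_set(transcript("A.1", "chr1", "+",
                          exons = list(c(100, 200), c(300, 400)),
                          gene_id = "A"))
  s2 <- mk_set(transcript("B.1", "chr1", "+",
                          exons = list(c(120, 200), c(300, 450)),
                          gene_id = "B"))
  mg <- merge_samples(list(s1 = s1, s2 = s2))
  expect_equal(n_transcripts(mg$combined), 1L)
  expect_equal(tx_ids(mg$combined), "TCONS_00000001")
  expect_equal(nrow(mg$tracking), 1L)
  expect_match(mg$tracking$s1, "^q1:A\\|A\\.1\\|2\\|")
  expect_match(mg$tracking$s2, "^q2:B\\|B\\.1\\|2\\|")
  # union output never contains two records with identical chains
  keys <- vapply(mg$combined$transcripts, function(t)
    paste(t$seqid, t$strand, paste(tx_introns(t), collapse = ",")), "")
  expect_false(anyDuplicated(keys[grepl(",", keys)]) > 0)
})

test_that("contained intron-redundant transfrags follow C / A / X semantics", {
  container <- transcript("big", "chr1", "+",
                          exons = list(c(100, 200), c(300, 400),
                                       c(500, 600), c(700, 800)))
  # sub-chain {i2,i3}, 5' exon inside a container exon (shared 5' exon)
  shared5 <- transcript("shared5", "chr1", "+",
                        exons = list(c(310, 400), c(500, 600), c(700, 780)))
  for (mode in c("C", "A", "X")) {
    mg <- merge_samples(list(mk_set(container), mk_set(shared5)),
                        mode = mode)
    expect_equal(n_transcripts(mg$combined), 1L, info = mode)
  }
  # same sub-chain but starting inside the container's first intron
  alt5 <- transcript("alt5", "chr1", "+",
                     exons = list(c(230, 400), c(500, 600), c(700, 780)))
  mg_c <- merge_samples(list(mk_set(container), mk_set(alt5)), mode = "C")
  expect_equal(n_transcripts(mg_c$combined), 2L)   # ends poke into intron
  mg_x <- merge_samples(list(mk_set(container), mk_set(alt5)), mode = "X")
  expect_equal(n_transcripts(mg_x$combined), 1L)   # X discards anyway
  mg_a <- merge_samples(list(mk_set(container), mk_set(alt5)), mode = "A")
  expect_equal(n_transcripts(mg_a$combined), 2L)   # alternate TSS kept
  # union keeps all structurally distinct transfrags
  mg_u <- merge_samples(list(mk_set(container), mk_set(shared5)),
                        mode = "union")
  expect_equal(n_transcripts(mg_u$combined), 2L)
})

test_that("-K protects reference-matching transfrags from discarding", {
  container <- transcript("big", "chr1", "+",
                          exons = list(c(100, 200), c(300, 400),
                                       c(500, 600), c(700, 800)))
  frag <- transcript("frag", "chr1", "+",
                     exons = list(c(310, 400), c(500, 600), c(700, 780)))
  ref <- mk_set(transcript("r", "chr1", "+",
                           exons = list(c(300, 400), c(500, 600),
                                        c(700, 800))))
  plain <- merge_samples(list(mk_set(container), mk_set(frag)),
                         reference = ref, mode = "C")
  expect_equal(n_transcripts(plain$combined), 1L)
  kept <- merge_samples(list(mk_set(container), mk_set(frag)),
                        reference = ref, mode = "C",
                        keep_ref_matches = TRUE)
  expect_equal(n_transcripts(kept$combined), 2L)
})

test_that("tracking rows reproduce the documented cell format byte for byte", {
  # 10 query exons totalling 2767 bases, sharing junctions with the
  # reference but not its full chain -> class j
  starts <- 1000 + (0:9) * 377
  ex <- cbind(starts, starts + c(rep(276, 9), 273))
  q <- transcript("STRG.377.2", "chr1", "+", exons = ex,
                  gene_id = "STRG.377",
                  attributes = list(FPKM = "0.304785", TPM = "0.760185",
                                    cov = "2.205239"))
  rex <- ex
  rex[1, 2] <- rex[1, 2] + 10   # shift the first junction
  rex[2, 1] <- rex[2, 1] + 10
  r <- transcript("rna-XM_006710864.2", "chr1", "+", exons = rex,
                  gene_id = "geneX", gene_name = "TCEA3")
  mg <- merge_samples(list(mk_set(q)), reference = mk_set(r))
  row <- unlist(mg$tracking[1, ])
  expect_equal(unname(row["tcons_id"]), "TCONS_00000001")
  expect_equal(unname(row["xloc_id"]), "XLOC_000001")
  expect_equal(unname(row["ref"]), "TCEA3|rna-XM_006710864.2")
  expect_equal(unname(row["class_code"]), "j")
  expect_equal(unname(row[5]),
               "q1:STRG.377|STRG.377.2|10|0.304785|0.760185|2.205239|2767")
  tf <- tempfile()
  write_tracking(mg$tracking, tf)
  expect_equal(readLines(tf),
               paste("TCONS_00000001", "XLOC_000001",
                     "TCEA3|rna-XM_006710864.2", "j",
                     "q1:STRG.377|STRG.377.2|10|0.304785|0.760185|2.205239|2767",
                     sep = "\t"))
})

test_that("refmap lists partial and full matches per reference transcript", {
  r <- transcript("uc007crl.1", "chr1", "+",
                  exons = list(c(100, 200), c(300, 400), c(500, 600)),
                  gene_id = "gMyog", gene_name = "Myog")
  q1 <- transcript("STRG.223.1", "chr1", "+",
                   exons = list(c(310, 400), c(500, 590)),
                   gene_id = "STRG.223")
  q2 <- transcript("STRG.224.1", "chr1", "+",
                   exons = list(c(320, 400), c(500, 580)),
                   gene_id = "STRG.224")
  tf <- tempfile()
  df <- write_refmap(annotation_set(list(q1, q2)), mk_set(r), tf)
  expect_equal(df$class_code, "c")
  expect_equal(df$matches, "STRG.223|STRG.223.1,STRG.224|STRG.224.1")
  expect_equal(readLines(tf)[2],
               "Myog\tuc007crl.1\tc\tSTRG.223|STRG.223.1,STRG.224|STRG.224.1")
  # a full match upgrades the row code to '='
  q3 <- transcript("STRG.225.1", "chr1", "+",
                   exons = list(c(110, 200), c(300, 400), c(500, 590)),
                   gene_id = "STRG.225")
  df2 <- write_refmap(annotation_set(list(q1, q3)), mk_set(r), tempfile())
  expect_equal(df2$class_code, "=")
})

test_that("tmap reports per-query best reference, major isoform and overlap", {
  r <- transcript("ref.1", "chr1", "+",
                  exons = list(c(100, 200), c(300, 400)),
                  gene_id = "gR", gene_name = "RGENE")
  iso1 <- transcript("g.1", "chr1", "+",
                     exons = list(c(100, 200), c(300, 400)),
                     gene_id = "g", attributes = list(FPKM = "5.0"))
  iso2 <- transcript("g.2", "chr1", "+", exons = list(c(100, 400)),
                     gene_id = "g", attributes = list(FPKM = "1.0"))
  lonely <- transcript("solo.1", "chr1", "+", exons = c(90000, 90500),
                       gene_id = "solo")
  tf <- tempfile()
  write_tmap(annotation_set(list(iso1, iso2, lonely)), mk_set(r), tf)
  lines <- readLines(tf)
  expect_equal(strsplit(lines[1], "\t")[[1]][c(1, 3, 6, 11, 12)],
               c("ref_gene_id", "class_code", "num_exons", "major_iso_id",
                 "ref_match_len"))
  f1 <- strsplit(lines[2], "\t")[[1]]
  expect_equal(f1[1:6], c("RGENE", "ref.1", "=", "g", "g.1", "2"))
  expect_equal(f1[7], "5.000000")
  expect_equal(f1[11], "g.1")               # highest FPKM isoform
  expect_equal(f1[12], "202")               # shared exonic bases
  f3 <- strsplit(lines[4], "\t")[[1]]
  expect_equal(f3[1:3], c("-", "-", "u"))   # no overlap at all
  expect_equal(f3[12], "-")
})

test_that("annotate_transcripts adds xloc, tss_id, cmp_ref and class_code", {
  fx <- make_fixture(23, n_genes = 3)
  ann <- annotate_transcripts(fx$query, fx$reference)
  ledger <- fx$ledger
  for (i in seq_len(nrow(ledger))) {
    t <- ann$transcripts[[ledger$id[i]]]
    expect_false(is.null(t$attributes$xloc))
    expect_false(is.null(t$attributes$class_code))
    if (!ledger$expected_code[i] %in% c("p", "r", "u")) {
      expect_equal(t$attributes$class_code, ledger$expected_code[i],
                   info = ledger$op[i])
      expect_equal(t$attributes$cmp_ref, ledger$ref_id[i],
                   info = ledger$op[i])
    } else {
      expect_null(t$attributes$cmp_ref)
    }
  }
  # same-strand transcripts starting within 100 bases share a tss_id
  q1 <- transcript("ta", "chr1", "+", exons = c(1000, 3000))
  q2 <- transcript("tb", "chr1", "+", exons = c(1080, 3100))
  q3 <- transcript("tc", "chr1", "+", exons = c(1400, 3200))
  ann2 <- annotate_transcripts(annotation_set(list(q1, q2, q3)),
                               annotation_set())
  expect_equal(ann2$transcripts$ta$attributes$tss_id,
               ann2$transcripts$tb$attributes$tss_id)
  expect_false(identical(ann2$transcripts$ta$attributes$tss_id,
                         ann2$transcripts$tc$attributes$tss_id))
})
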