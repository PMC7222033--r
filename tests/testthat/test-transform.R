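test_that("length and intron filters discard per the spliced-length rule", {
  set <- mk_set(
    transcript("long", "chr1", "+", exons = list(c(100, 199), c(300, 349))),
    transcript("mid", "chr1", "+", exons = c(1000, 1399)),
    transcript("short", "chr1", "+", exons = c(2000, 2089)))
  out <- filter_transcripts(set, filter_spec(min_len = 100))
  expect_setequal(tx_ids(out), c("long", "mid"))

  t_big <- transcript("big_intron", "chr1", "+",
                      exons = list(c(1, 100), c(1001, 1100),
                                   c(61101, 61200)))
  out2 <- filter_transcripts(mk_set(t_big), filter_spec(max_intron = 50000))
  expect_length(tx_ids(out2), 0)
  out3 <- filter_transcripts(mk_set(t_big), filter_spec(max_intron = 60000))
  expect_equal(tx_ids(out3), "big_intron")
})

test_that("range filtering distinguishes overlap from containment", {
  set <- mk_set(mk_tx("a", c(900, 1500)), mk_tx("b", c(1100, 1900)),
                mk_tx("c", c(2500, 2600)))
  ov <- filter_transcripts(set, filter_spec(range = list("chr1", 1000, 2000)))
  expect_setequal(tx_ids(ov), c("a", "b"))
  cont <- filter_transcripts(set, filter_spec(range = list("chr1", 1000, 2000),
                                              range_contained = TRUE))
  expect_equal(tx_ids(cont), "b")
  # strand-qualified range also requires strand equality
  strd <- filter_transcripts(set, filter_spec(
    range = list("chr1", 1000, 2000, "-")))
  expect_length(tx_ids(strd), 0)
})

test_that("an empty filter spec is the identity", {
  set <- rand_set(3, n = 20)
  out <- filter_transcripts(set, filter_spec())
  expect_setequal(tx_ids(out), tx_ids(set))
})

test_that("genome-requiring filters fail fast without a genome", {
  expect_error(filter_transcripts(rand_set(1, 3),
                                  filter_spec(complete_cds_only = TRUE)),
               "requires a genome")
})

test_that("pseudogene detection covers feature types and biotype attributes", {
  expect_true(is_pseudogene(transcript("p", "chr1", "+", exons = c(1, 10),
                                       feature_type = "pseudogene")))
  expect_true(is_pseudogene(transcript(
    "p2", "chr1", "+", exons = c(1, 10),
    attributes = list(gene_biotype = "processed_pseudogene"))))
  expect_false(is_pseudogene(transcript("m", "chr1", "+", exons = c(1, 10),
                                        feature_type = "mRNA")))
  g <- gene("g", "chr1", "+", 1, 100,
            attributes = list(biotype = "pseudogene"))
  expect_true(is_pseudogene(transcript("t", "chr1", "+", exons = c(1, 10)),
                            parent_gene = g))
  expect_true(is_pseudogene(transcript(
    "t2", "chr1", "+", exons = c(1, 10), attributes = list(pseudo = "true"))))
})

test_that("loci are connected components of same-strand exon overlap", {
  set <- mk_set(mk_tx("A", c(100, 200)), mk_tx("B", c(150, 250)),
                mk_tx("C", c(300, 400)))
  loci <- cluster_loci(set)
  members <- lapply(loci, `[[`, "transcript_ids")
  expect_setequal(lapply(members, sort), list(c("A", "B"), "C"))

  # strand difference separates loci
  set2 <- mk_set(mk_tx("A", c(100, 200)),
                 mk_tx("B", c(150, 250), strand = "-"))
  expect_length(cluster_loci(set2), 2)

  # transitivity joins chains of overlaps
  set3 <- mk_set(mk_tx("A", c(100, 200)), mk_tx("B", c(190, 300)),
                 mk_tx("C", c(290, 400)))
  expect_length(cluster_loci(set3), 1)

  # "." strand transcripts form their own stratum
  set4 <- mk_set(mk_tx("A", c(100, 200)),
                 mk_tx("B", c(150, 250), strand = "."))
  expect_length(cluster_loci(set4), 2)
})

test_that("cluster_loci partitions the set and matches brute-force components", {
  for (seed in c(5, 6)) {
    set <- rand_set(seed, n = 40, max_start = 2000)
    loci <- cluster_loci(set)
    all_members <- unlist(lapply(loci, `[[`, "transcript_ids"))
    expect_setequal(all_members, tx_ids(set))       # partition: all present
    expect_false(anyDuplicated(all_members) > 0)    # exactly once
    # same-strand strata equal brute-force connected components
    for (sq in c("chr1", "chr2")) for (st in c("+", "-")) {
      txs <- Filter(function(t) t$seqid == sq && t$strand == st,
                    set$transcripts)
      if (!length(txs)) next
      comp <- brute_components(txs)
      got <- Filter(function(l) l$seqid == sq && l$strand == st, loci)
      expect_equal(length(got), length(unique(comp)))
      brute_groups <- split(vapply(txs, function(t) t$id, ""), comp)
      got_groups <- lapply(got, `[[`, "transcript_ids")
      expect_setequal(lapply(brute_groups, function(x) unname(sort(x))),
                      lapply(got_groups, sort))
    }
  }
})

test_that("structural matching follows the intron-chain / 80 percent rules", {
  a <- mk_tx("a", list(c(100, 200), c(300, 400)))
  b <- mk_tx("b", list(c(150, 200), c(300, 560)))
  expect_true(transcripts_match(a, b))   # same introns, ends differ
  c_ <- mk_tx("c", list(c(100, 200), c(301, 400)))
  expect_false(transcripts_match(a, c_)) # intron (201,299) vs (201,300)
  s1 <- mk_tx("s1", c(100, 200))
  s2 <- mk_tx("s2", c(120, 220))         # overlap 81 of longer 101
  expect_true(transcripts_match(s1, s2))
  s3 <- mk_tx("s3", c(121, 220))         # overlap 80: not > 0.8 * 100
  expect_false(transcripts_match(mk_tx("s0", c(100, 199)), s3))
  expect_false(transcripts_match(a, s1)) # single vs multi never match
})

test_that("redundancy removal honors merge / contain / relaxed semantics", {
  container <- mk_tx("big", list(c(100, 200), c(300, 400), c(500, 600),
                                 c(700, 800)))
  dup <- mk_tx("dup", list(c(150, 200), c(300, 400), c(500, 600),
                           c(700, 750)))
  # identical chain, contained: merge discards the contained one
  out <- remove_redundant(mk_set(container, dup), "merge")
  expect_equal(tx_ids(out), "big")

  # 1-intron fragment matching the middle of the container
  frag <- mk_tx("frag", list(c(310, 400), c(500, 590)))
  expect_setequal(tx_ids(remove_redundant(mk_set(container, frag), "merge")),
                  c("big", "frag"))
  expect_equal(tx_ids(remove_redundant(mk_set(container, frag), "contain")),
               "big")

  # fragment poking past the container's end: contain keeps, relaxed drops
  poke <- mk_tx("poke", list(c(510, 600), c(700, 900)))
  expect_setequal(tx_ids(remove_redundant(mk_set(container, poke),
                                          "contain")), c("big", "poke"))
  expect_equal(tx_ids(remove_redundant(mk_set(container, poke), "relaxed")),
               "big")
})

test_that("remove_redundant is idempotent on random sets", {
  for (seed in c(21, 22)) {
    set <- rand_set(seed, n = 30, max_start = 1500)
    for (mode in c("merge", "contain", "relaxed")) {
      once <- remove_redundant(set, mode)
      twice <- remove_redundant(once, mode)
      expect_setequal(tx_ids(twice), tx_ids(once))
    }
  }
})

test_that("close-exon merging fuses introns below the threshold only", {
  t3 <- transcript("t", "chr1", "+", exons = list(c(100, 200), c(204, 300)))
  fused <- merge_close_exons(t3)                  # intron 201-203, length 3
  expect_equal(unname(fused$exons), rbind(c(100L, 300L)))
  t4 <- transcript("t", "chr1", "+", exons = list(c(100, 200), c(205, 300)))
  expect_equal(merge_close_exons(t4)$exons, t4$exons)  # length 4 kept
  single <- mk_tx("s", c(100, 200))
  expect_equal(merge_close_exons(single)$exons, single$exons)
  # iterative left-to-right fusion across several micro-introns
  t5 <- transcript("t", "chr1", "+",
                   exons = list(c(1, 10), c(12, 20), c(23, 30), c(40, 50)))
  expect_equal(unname(merge_close_exons(t5)$exons),
               rbind(c(1L, 30L), c(40L, 50L)))
})

test_that("close-exon merging outside the CDS never changes the translation", {
  fx <- make_fixture(9, n_genes = 2)
  idx <- tmp_genome(fx$genome)
  for (t in fx$reference$transcripts) {
    # append a micro-intron exon tail beyond the 3' UTR
    ex <- t$exons
    tail_exon <- c(t$end + 3L, t$end + 30L)
    t2 <- transcript(t$id, t$seqid, t$strand, exons = rbind(ex, tail_exon),
                     cds = t$cds, cds_phase = t$cds_phase)
    fused <- merge_close_exons(t2)
    expect_lt(nrow(fused$exons), nrow(t2$exons))
    expect_identical(
      translate_cds(spliced_sequence(fused, idx, "cds")),
      translate_cds(spliced_sequence(t, idx, "cds")))
  }
})

test_that("gene_to_exon spans the gene and force_exons is identity on exons", {
  g <- gene("g1", "chr1", "+", 500, 900)
  t <- gene_to_exon(g)
  expect_equal(unname(t$exons), rbind(c(500L, 900L)))
  t2 <- mk_tx("t", list(c(1, 10), c(20, 30)))
  expect_identical(force_exons(t2), t2)
})
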