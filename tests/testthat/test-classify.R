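test_that("classify_pair returns the documented codes on constructed pairs", {
  r <- mk_tx("r", list(c(100, 200), c(300, 400), c(500, 600)))
  # exact chain match despite different terminal ends
  q_eq <- mk_tx("q", list(c(150, 200), c(300, 400), c(500, 560)))
  expect_equal(classify_pair(q_eq, r), "=")
  # single exon inside a reference intron
  q_i <- mk_tx("qi", c(220, 280))
  expect_equal(classify_pair(q_i, r), "i")
  # opposite strand exonic overlap, no intron match
  q_x <- mk_tx("qx", c(150, 250), strand = "-")
  expect_equal(classify_pair(q_x, r), "x")
  # opposite strand with a matching intron
  q_s <- mk_tx("qs", list(c(150, 200), c(300, 400), c(500, 560)),
               strand = "-")
  expect_equal(classify_pair(q_s, r), "s")
  # one shared junction, chains otherwise different
  q_j <- mk_tx("qj", list(c(150, 200), c(320, 400), c(520, 560)))
  expect_equal(classify_pair(q_j, r), "j")
  # contained fragment, intron compatible
  q_c <- mk_tx("qc", list(c(310, 400), c(500, 590)))
  expect_equal(classify_pair(q_c, r), "c")
  expect_equal(classify_pair(r, q_c), "k")   # reverse containment
  # retained intron with full match elsewhere
  q_m <- mk_tx("qm", list(c(100, 200), c(300, 600)))
  expect_equal(classify_pair(q_m, r), "m")
  # retained intron plus a novel intron elsewhere
  q_n <- mk_tx("qn", list(c(100, 190), c(250, 600)))
  expect_equal(classify_pair(q_n, r), "n")
  # single exon intruding into an intron
  q_e <- mk_tx("qe", c(300, 450))
  expect_equal(classify_pair(q_e, r), "e")
  # plain same-strand exonic overlap
  q_o <- mk_tx("qo", c(50, 150))
  expect_equal(classify_pair(q_o, r), "o")
  # reference inside a query intron
  q_y <- mk_tx("qy", list(c(10, 50), c(700, 750)))
  expect_equal(classify_pair(q_y, r), "y")
})

test_that("classify_pair is reflexive and respects the priority order", {
  set <- rand_set(13, n = 30)
  for (t in set$transcripts) expect_equal(classify_pair(t, t), "=")
  # a pair satisfying both the c and j preconditions classifies c
  r <- mk_tx("r", list(c(100, 200), c(300, 400), c(500, 600)))
  q <- mk_tx("q", list(c(310, 400), c(500, 590)))  # shares junctions too
  expect_equal(classify_pair(q, r), "c")
})

test_that("c and k are mutual duals on random containment pairs", {
  withr::with_seed(40, {
    for (k in 1:20) {
      n <- sample(3:5, 1)
      starts <- cumsum(c(1000, rep(300, n - 1)))
      ex <- cbind(starts, starts + sample(80:200, n, TRUE))
      r <- transcript("r", "chr1", "+", exons = ex)
      keep <- sort(sample(2:(n - 1), min(2, n - 2)))
      q <- transcript("q", "chr1", "+",
                      exons = ex[min(keep):max(keep), , drop = FALSE])
      expect_equal(classify_pair(q, r), "c")
      expect_equal(classify_pair(r, q), "k")
    }
  })
})

test_that("single-exon equality follows the longer-transcript 80 percent rule", {
  r <- mk_tx("r", c(1000, 1999))          # length 1000
  expect_equal(classify_pair(mk_tx("q", c(1000, 1801)), r), "=")  # 802
  expect_equal(classify_pair(mk_tx("q", c(1000, 1799)), r), "c")  # 800
})

test_that("best_reference picks the highest-priority code, then overlap", {
  refs <- annotation_set(list(
    mk_tx("refA", list(c(100, 200), c(300, 400), c(500, 600))),
    mk_tx("refB", list(c(90, 200), c(320, 400), c(500, 610)))))
  q <- mk_tx("q", list(c(310, 400), c(500, 590)))
  # c against refA (sub-chain), j against refB
  got <- best_reference(q, refs)
  expect_equal(got$code, "c")
  expect_equal(got$ref$id, "refA")

  # two "=" refs: larger exonic overlap wins
  refs2 <- annotation_set(list(mk_tx("refL", c(1000, 1499)),
                               mk_tx("refS", c(1000, 1299))))
  q2 <- mk_tx("q2", c(1000, 1499))
  got2 <- best_reference(q2, refs2)
  expect_equal(got2$ref$id, "refL")

  # no overlap routes to the unmatched codes
  lonely <- mk_tx("solo", c(50000, 50100))
  expect_equal(best_reference(lonely, refs)$code, "u")
})

test_that("unmatched queries split into repeat, run-on and intergenic", {
  ref <- annotation_set(list(mk_tx("r", c(1000, 2000))))
  idx <- tmp_genome(c(chr1 = paste0(strrep("A", 3000),
                                    strrep("a", 400),
                                    strrep("A", 46600))))
  masked <- mk_tx("qmask", c(3001, 3400))     # 100% lower case
  expect_equal(classify_unmatched(masked, ref, idx), "r")
  runon <- mk_tx("qrun", c(2500, 2800))       # 500 bases downstream
  expect_equal(classify_unmatched(runon, ref, idx), "p")
  far <- mk_tx("qfar", c(30000, 30300))
  expect_equal(classify_unmatched(far, ref, idx), "u")
  # run-on requires the same strand
  runon_m <- mk_tx("qrm", c(2500, 2800), strand = "-")
  expect_equal(classify_unmatched(runon_m, ref, idx), "u")
})

test_that("super-loci merge across strands and equal brute-force components", {
  refA <- mk_tx("gA", list(c(100, 500)))
  refB <- mk_tx("gB", c(2000, 2500))
  q1 <- mk_tx("q1", c(300, 600))
  q2 <- mk_tx("q2", c(450, 2100))    # bridges gA and gB
  loci <- build_superloci(annotation_set(list(q1, q2)),
                          annotation_set(list(refA, refB)))
  expect_length(loci, 1)
  expect_setequal(loci[[1]]$ref_ids, c("gA", "gB"))
  expect_setequal(loci[[1]]$q_members$id, c("q1", "q2"))
  expect_equal(loci[[1]]$xloc_id, "XLOC_000001")

  # disjoint pairs give one super-locus each
  loci2 <- build_superloci(annotation_set(list(q1)),
                           annotation_set(list(refA, refB)))
  expect_length(loci2, 2)

  # randomized: partition matching strand-agnostic brute-force components
  set <- rand_set(55, n = 40, max_start = 3000)
  ref <- rand_set(56, n = 20, max_start = 3000, prefix = "r")
  loci3 <- build_superloci(set, ref)
  pool <- c(set$transcripts, ref$transcripts)
  for (sq in unique(vapply(pool, function(t) t$seqid, ""))) {
    txs <- Filter(function(t) t$seqid == sq, pool)
    comp <- brute_components(txs, same_strand = FALSE)
    here <- Filter(function(l) l$seqid == sq, loci3)
    expect_equal(length(here), length(unique(comp)))
  }
  all_ids <- unlist(lapply(loci3, function(l) c(l$q_members$id, l$ref_ids)))
  expect_setequal(all_ids, c(tx_ids(set), tx_ids(ref)))
  expect_false(anyDuplicated(all_ids) > 0)
})

test_that("TSS grouping is strand-aware single linkage", {
  txs <- list(mk_tx("a", c(1000, 5000)), mk_tx("b", c(1080, 5100)),
              mk_tx("c", c(1400, 5200)))
  g <- assign_tss(txs, d = 100)
  expect_equal(g[["a"]], g[["b"]])
  expect_false(g[["a"]] == g[["c"]])

  # chain transitivity: 1000,1100,1200 joins one group
  txs2 <- list(mk_tx("a", c(1000, 5000)), mk_tx("b", c(1100, 5100)),
               mk_tx("c", c(1200, 5200)))
  expect_length(unique(assign_tss(txs2, d = 100)), 1)

  # minus strand groups by genomic end
  txs3 <- list(mk_tx("a", c(1000, 5000), strand = "-"),
               mk_tx("b", c(2000, 5050), strand = "-"),
               mk_tx("c", c(1500, 5400), strand = "-"))
  g3 <- assign_tss(txs3, d = 100)
  expect_equal(g3[["a"]], g3[["b"]])
  expect_false(g3[["a"]] == g3[["c"]])

  # "." strand gets no group
  expect_true(is.na(assign_tss(list(mk_tx("d", c(1, 10), strand = ".")))))
})
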