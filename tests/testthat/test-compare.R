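lv <- function(stats, level, sample = 1) {
  s <- stats$samples[[sample]]
  s$levels[s$levels$level == level, ]
}

test_that("self-comparison yields 100 percent at every level", {
  for (seed in 1:3) {
    fx <- make_fixture(seed, n_genes = 4, isoforms_per_gene = 2)
    st <- compute_stats(fx$reference, fx$reference)
    expect_equal(st$samples$q1$levels$sensitivity, rep(1, 6))
    expect_equal(st$samples$q1$levels$precision, rep(1, 6))
    expect_equal(st$samples$q1$novel_loci, 0)
    expect_equal(st$samples$q1$missed_loci, 0)
  }
})

test_that("terminal-end slack applies to exon and transcript levels", {
  ref <- mk_set(transcript("r", "chr1", "+",
                           exons = list(c(100, 200), c(300, 400))))
  qry <- mk_set(transcript("q", "chr1", "+",
                           exons = list(c(150, 200), c(300, 350))))
  st <- compute_stats(qry, ref)
  expect_equal(lv(st, "intron")$sensitivity, 1)
  expect_equal(lv(st, "intron")$precision, 1)
  # both query exons differ only at free terminal ends, within 100 bases
  expect_equal(lv(st, "exon")$sensitivity, 1)
  expect_equal(lv(st, "exon")$precision, 1)
  expect_equal(lv(st, "transcript")$precision, 1)
  # base level counts only the shared coordinates
  expect_equal(lv(st, "base")$TP, 51L + 51L)
  expect_equal(lv(st, "base")$precision, 1)

  # beyond the slack the exon and transcript levels drop
  qry2 <- mk_set(transcript("q", "chr1", "+",
                            exons = list(c(150, 200), c(300, 510))))
  st2 <- compute_stats(qry2, ref)
  expect_equal(lv(st2, "transcript")$precision, 0)
  expect_lt(lv(st2, "exon")$precision, 1)
  # internal boundaries get no slack at all
  qry3 <- mk_set(transcript("q", "chr1", "+",
                            exons = list(c(150, 210), c(300, 350))))
  st3 <- compute_stats(qry3, ref)
  expect_equal(lv(st3, "intron")$precision, 0)
  expect_equal(lv(st3, "exon")$pr_tp, 1L)
})

test_that("locus level scores hit and missed reference loci", {
  ref <- mk_set(mk_tx("r1", list(c(100, 200), c(300, 400))),
                mk_tx("r2", c(5000, 5400)))
  qry <- mk_set(mk_tx("q1", list(c(100, 200), c(300, 400))))
  st <- compute_stats(qry, ref)
  expect_equal(lv(st, "locus")$sensitivity, 0.5)
  expect_equal(lv(st, "locus")$precision, 1)
  expect_equal(st$samples$q1$missed_loci, 1)
  expect_equal(st$samples$q1$novel_loci, 0)
})

test_that("all six levels match a brute-force recomputation on random sets", {
  for (seed in c(101, 102, 103)) {
    qry <- rand_set(seed, n = 25, max_start = 3000)
    ref <- rand_set(seed + 500, n = 20, max_start = 3000, prefix = "r")
    st <- compute_stats(qry, ref, compare_opts(no_merge = TRUE))
    oracle <- naive_stats(qry, ref)
    for (level in names(oracle)) {
      row <- lv(st, level)
      expect_equal(unname(row$sn_tp), unname(oracle[[level]]["sn_tp"]),
                   info = paste(seed, level))
      expect_equal(unname(row$sn_total), unname(oracle[[level]]["sn_total"]),
                   info = paste(seed, level))
      expect_equal(unname(row$pr_tp), unname(oracle[[level]]["pr_tp"]),
                   info = paste(seed, level))
      expect_equal(unname(row$pr_total), unname(oracle[[level]]["pr_total"]),
                   info = paste(seed, level))
    }
  }
})

test_that("FP + TP equals the query feature total at every level", {
  qry <- rand_set(31, n = 20)
  ref <- rand_set(32, n = 20, prefix = "r")
  st <- compute_stats(qry, ref)
  levels <- st$samples$q1$levels
  expect_equal(levels$FP + levels$TP, levels$pr_total)
  expect_true(all(levels$FN >= 0) && all(levels$FP >= 0))
})

test_that("unmatched additions cannot raise precision or sensitivity", {
  qry <- rand_set(61, n = 15, max_start = 2000)
  ref <- rand_set(62, n = 15, max_start = 2000, prefix = "r")
  base <- compute_stats(qry, ref)$samples$q1$levels
  # a far-away query transcript adds false positives only
  qry2 <- annotation_set(c(unname(qry$transcripts),
                           list(mk_tx("noise", c(900000, 900500)))))
  with_noise <- compute_stats(qry2, ref)$samples$q1$levels
  expect_true(all(with_noise$precision <= base$precision + 1e-12))
  # a far-away reference transcript adds false negatives only
  ref2 <- annotation_set(c(unname(ref$transcripts),
                           list(mk_tx("ghost", c(900000, 900500)))))
  with_ghost <- compute_stats(qry, ref2)$samples$q1$levels
  expect_true(all(with_ghost$sensitivity <= base$sensitivity + 1e-12))
})

test_that("-R never lowers sensitivity; -Q never lowers precision", {
  for (seed in c(71, 72)) {
    qry <- rand_set(seed, n = 20, max_start = 4000)
    ref <- rand_set(seed + 10, n = 20, max_start = 4000, prefix = "r")
    plain <- compute_stats(qry, ref)$samples$q1$levels
    rr <- compute_stats(qry, ref,
                        compare_opts(restrict_ref = TRUE))$samples$q1$levels
    qq <- compute_stats(qry, ref,
                        compare_opts(restrict_query = TRUE))$samples$q1$levels
    sn_ok <- is.na(plain$sensitivity) | is.na(rr$sensitivity) |
      rr$sensitivity >= plain$sensitivity - 1e-12
    pr_ok <- is.na(plain$precision) | is.na(qq$precision) |
      qq$precision >= plain$precision - 1e-12
    expect_true(all(sn_ok))
    expect_true(all(pr_ok))
  }
})

test_that("single-exon handling options drop the right transcripts", {
  ref <- mk_set(mk_tx("multi_r", list(c(100, 200), c(300, 400))),
                mk_tx("single_r", c(5000, 5200)))
  qry <- mk_set(mk_tx("multi_q", list(c(100, 200), c(300, 400))),
                mk_tx("single_q", c(5000, 5190)))
  st_m <- compute_stats(qry, ref, compare_opts(drop_single_exon = TRUE))
  expect_equal(lv(st_m, "transcript")$pr_total, 1L)
  expect_equal(lv(st_m, "transcript")$sn_total, 1L)
  st_n <- compute_stats(qry, ref,
                        compare_opts(drop_single_exon_ref = TRUE))
  expect_equal(lv(st_n, "transcript")$sn_total, 1L)
  expect_equal(lv(st_n, "transcript")$pr_total, 2L)
})

test_that("duplicate transfrag removal distinguishes -D and -S", {
  chain <- list(c(201, 299))
  t_big <- transcript("big", "chr1", "+",
                      exons = list(c(100, 200), c(300, 900)))
  t_in <- transcript("inner", "chr1", "+",
                     exons = list(c(150, 200), c(300, 800)))
  both <- annotation_set(list(t_big, t_in))
  expect_equal(tx_ids(dedup_queries(both, "D")), "big")
  expect_equal(tx_ids(dedup_queries(both, "S")), "big")  # contained

  t_a <- transcript("a", "chr1", "+", exons = list(c(100, 200), c(300, 800)))
  t_b <- transcript("b", "chr1", "+", exons = list(c(150, 200), c(300, 900)))
  crossed <- annotation_set(list(t_a, t_b))
  expect_length(tx_ids(dedup_queries(crossed, "D")), 1)   # same chain
  expect_setequal(tx_ids(dedup_queries(crossed, "S")), c("a", "b"))

  distinct <- rand_set(81, n = 10)
  expect_setequal(tx_ids(dedup_queries(distinct, "D")), tx_ids(distinct))
})

test_that("close-exon pre-merge is applied to queries by default", {
  # query micro-intron of 3 bases fuses, matching a single-exon reference
  ref <- mk_set(mk_tx("r", c(100, 300)))
  qry <- mk_set(transcript("q", "chr1", "+",
                           exons = list(c(100, 200), c(204, 300))))
  st <- compute_stats(qry, ref)
  expect_equal(lv(st, "transcript")$precision, 1)
  st_off <- compute_stats(qry, ref, compare_opts(no_merge = TRUE))
  expect_equal(lv(st_off, "transcript")$precision, 0)
})
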