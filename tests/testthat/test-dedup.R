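# Duplicate grouping, primary selection and base reconciliation.

test_that("pairs group by unclipped 5' coordinates and orientations", {
  p1 <- mk_pair("a", 1000L, 1100L, "76M", "76M")
  p2 <- mk_pair("b", 1000L, 1100L, "76M", "76M")
  p3 <- mk_pair("c", 1001L, 1100L, "76M", "76M")
  # clipped copy of p1: same unclipped coordinates, shifted pos
  p4 <- mk_pair("d", 1005L, 1100L, "5S71M", "76M")
  expect_identical(duplicate_key(p1), duplicate_key(p2))
  expect_false(duplicate_key(p1) == duplicate_key(p3))
  expect_identical(duplicate_key(p1), duplicate_key(p4))
  g <- group_duplicates(list(p1, p2, p3, p4), p1[0L, , drop = FALSE])
  expect_length(g, 2L)
  expect_identical(lengths(lapply(g, `[[`, "pairs")), c(3L, 1L))
})

test_that("a single at a paired group's start is absorbed and discarded", {
  pair <- mk_pair("p", 1000L, 1100L, "76M", "76M")
  hit <- mk_read("s_fwd", flag = 0L, pos = 1000L, cigar = "76M",
                 qual = qv(rep(40L, 76)))
  # same coordinate as the reverse mate's 5' end (1100 + 75), reverse strand
  hit_rev <- mk_read("s_rev", flag = 16L, pos = 1100L, cigar = "76M")
  miss <- mk_read("s_far", flag = 0L, pos = 2000L, cigar = "76M")
  dd <- dedup_reads(list(pair), dplyr::bind_rows(hit, hit_rev, miss))
  expect_length(dd$pairs, 1L)
  expect_identical(dd$singles$qname, "s_far")
  expect_identical(dd$n_discarded, 2L)
  # the discarded singles did not vote on the primary's bases
  expect_identical(dd$pairs[[1]]$qual, pair$qual)
})

test_that("the highest base-quality sum wins; ties break by position and name", {
  lo <- mk_pair("lo", 1000L, 1100L, qual1 = qv(rep(30L, 10)),
                qual2 = qv(rep(30L, 10)))
  hi <- mk_pair("hi", 1000L, 1100L, qual1 = qv(rep(35L, 10)),
                qual2 = qv(rep(35L, 10)))
  expect_identical(select_primary(list(lo, hi)), 2L)
  expect_identical(select_primary(list(hi, lo)), 1L)
  expect_identical(select_primary(list(lo)), 1L)
  # equal sums: the oracle is enumeration of both orders -> same winner
  tie_a <- mk_pair("aaa", 1000L, 1100L)
  tie_b <- mk_pair("bbb", 1000L, 1100L)
  w1 <- list(tie_a, tie_b)[[select_primary(list(tie_a, tie_b))]]
  w2 <- list(tie_b, tie_a)[[select_primary(list(tie_b, tie_a))]]
  expect_identical(w1$qname[1], "aaa")
  expect_identical(w2$qname[1], "aaa")
})

test_that("reconciliation follows the quality-10 branch rules", {
  prim <- mk_read("p", seq = "AAAAAAAAAA", qual = qv(rep(30L, 10)))
  # credible conflict (both >= 10): base kept, quality zeroed
  sec <- mk_read("p", seq = "ACAAAAAAAA", qual = qv(rep(35L, 10)))
  out <- reconcile_bases(prim, sec)
  expect_identical(out$seq, "AAAAAAAAAA")
  expect_identical(rnaprep:::qual_to_int(out$qual)[2], 0L)
  # low-quality conflict: the higher-quality base is substituted in
  prim2 <- mk_read("p", seq = "AAAAAAAAAA", qual = qv(c(5L, rep(30L, 9))))
  sec2 <- mk_read("p", seq = "GAAAAAAAAA", qual = qv(rep(30L, 10)))
  out2 <- reconcile_bases(prim2, sec2)
  expect_identical(substr(out2$seq, 1, 1), "G")
  expect_identical(rnaprep:::qual_to_int(out2$qual)[1], 30L)
  # agreement never changes anything
  sec3 <- mk_read("p", seq = "AAAAAAAAAA", qual = qv(rep(20L, 10)))
  expect_identical(reconcile_bases(prim, sec3)$qual, prim$qual)
  expect_identical(reconcile_bases(prim, sec3)$seq, prim$seq)
  # quality exactly 10 on both sides goes to the zeroing branch
  prim4 <- mk_read("p", seq = "AAAAAAAAAA", qual = qv(rep(10L, 10)))
  sec4 <- mk_read("p", seq = "TAAAAAAAAA", qual = qv(rep(10L, 10)))
  out4 <- reconcile_bases(prim4, sec4)
  expect_identical(substr(out4$seq, 1, 1), "A")
  expect_identical(rnaprep:::qual_to_int(out4$qual)[1], 0L)
})

test_that("a zeroed position stays zeroed across later duplicates", {
  prim <- mk_pair("p", 1000L, 1100L, seq1 = "AAAAAAAAAA",
                  qual1 = qv(rep(35L, 10)))
  s1 <- mk_pair("q", 1000L, 1100L, seq1 = "ATAAAAAAAA",
                qual1 = qv(rep(30L, 10)))
  # after zeroing, this copy (strong at position 2, weak overall so it can
  # never win the primary choice) must not resurrect the disputed base
  s2 <- mk_pair("r", 1000L, 1100L, seq1 = "ACAAAAAAAA",
                qual1 = qv(c(30L, 40L, rep(20L, 8))))
  dd <- dedup_reads(list(prim, s1, s2), prim[0L, , drop = FALSE])
  expect_length(dd$pairs, 1L)
  kept <- dd$pairs[[1]]
  expect_identical(substr(kept$seq[1], 2, 2), "A")
  expect_identical(rnaprep:::qual_to_int(kept$qual[1])[2], 0L)
})

test_that("reconciliation never touches placement, and members with other CIGARs are skipped", {
  prim <- mk_read("p", cigar = "10M", seq = "AAAAAAAAAA",
                  qual = qv(rep(30L, 10)))
  other <- mk_read("p", cigar = "2S8M", seq = "TTTTTTTTTT",
                   qual = qv(rep(40L, 10)))
  out <- reconcile_bases(prim, other)
  for (col in c("pos", "cigar", "seq", "qual")) {
    expect_identical(out[[col]], prim[[col]])
  }
})

test_that("dedup leaves at most one entity per key and selection is quality-monotone", {
  for (s in 1:8) {
    ri <- sim_random_input(s)
    qc <- qc_filter(ri$reads, ri$config)
    dd <- dedup_reads(qc$pairs, qc$singles)
    keys <- c(vapply(dd$pairs, duplicate_key, character(1)),
              vapply(seq_len(nrow(dd$singles)), function(i) {
                duplicate_key(dd$singles[i, , drop = FALSE])
              }, character(1)))
    expect_identical(anyDuplicated(keys), 0L)
    # the kept pair's pre-reconciliation quality sum is the group maximum
    in_keys <- vapply(qc$pairs, duplicate_key, character(1))
    for (gi in seq_along(dd$pairs)) {
      k <- duplicate_key(dd$pairs[[gi]])
      members <- qc$pairs[in_keys == k]
      best <- max(vapply(members, rnaprep:::entity_qual_sum, numeric(1)))
      orig <- members[[which(vapply(members, function(m) m$qname[1], character(1)) ==
                               dd$pairs[[gi]]$qname[1])]]
      expect_identical(rnaprep:::entity_qual_sum(orig), best)
    }
  }
})
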