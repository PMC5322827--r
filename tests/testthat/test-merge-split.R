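# Flank masking, overlap merging, exon consistency and intron splitting.

test_that("flank masking zeroes qualities in sequencing order", {
  cfg <- prep_config(min_flank_start = 3L)
  fwd <- mk_read(flag = 0L, cigar = "10M")
  expect_identical(rnaprep:::qual_to_int(mask_flanks(fwd, cfg)$qual),
                   c(0L, 0L, 0L, rep(30L, 7)))
  rev <- mk_read(flag = 16L, cigar = "10M")
  expect_identical(rnaprep:::qual_to_int(mask_flanks(rev, cfg)$qual),
                   c(rep(30L, 7), 0L, 0L, 0L))
  both <- prep_config(min_flank_start = 2L, min_flank_end = 3L)
  expect_identical(rnaprep:::qual_to_int(mask_flanks(fwd, both)$qual),
                   c(0L, 0L, rep(30L, 5), 0L, 0L, 0L))
  # defaults leave reads untouched
  expect_identical(mask_flanks(fwd, prep_config()), fwd)
})

test_that("soft-clip conditional masking touches only clipped reads", {
  cfg <- prep_config(soft_clips_exist = TRUE, min_flank_start = 3L)
  plain <- mk_read("plain", flag = 0L, cigar = "76M")
  clipped <- mk_read("clip", flag = 0L, cigar = "3S73M")
  out <- mask_flanks(dplyr::bind_rows(plain, clipped), cfg)
  expect_identical(out$qual[1], plain$qual)
  expect_identical(rnaprep:::qual_to_int(out$qual[2])[1:3], c(0L, 0L, 0L))
})

test_that("flanks covering the whole read zero every quality but keep the read", {
  cfg <- prep_config(min_flank_start = 8L, min_flank_end = 8L)
  r <- mk_read(flag = 0L, cigar = "10M")
  out <- mask_flanks(r, cfg)
  expect_identical(nrow(out), 1L)
  expect_identical(rnaprep:::qual_to_int(out$qual), rep(0L, 10))
})

test_that("overlap windows are reference-interval intersections", {
  expect_identical(overlap_window(mk_pair(pos1 = 1000L, pos2 = 1050L,
                                          cigar1 = "76M", cigar2 = "76M")),
                   c(1050L, 1075L))
  expect_identical(overlap_window(mk_pair(pos1 = 1000L, pos2 = 1200L,
                                          cigar1 = "76M", cigar2 = "76M")),
                   integer(0))
  expect_identical(overlap_window(mk_pair(pos1 = 1000L, pos2 = 1000L,
                                          cigar1 = "76M", cigar2 = "76M")),
                   c(1000L, 1075L))
})

test_that("exon consistency requires identical junctions inside the window", {
  # neither mate spliced in the window
  expect_true(exon_consistent(mk_pair(pos1 = 1000L, pos2 = 1050L,
                                      cigar1 = "76M", cigar2 = "76M")))
  # first mate skips inside the window, second does not
  expect_false(exon_consistent(mk_pair(pos1 = 1000L, pos2 = 1020L,
                                       cigar1 = "30M100N46M", cigar2 = "76M")))
  # both mates share the junction
  expect_true(exon_consistent(mk_pair(pos1 = 1000L, pos2 = 1020L,
                                      cigar1 = "30M100N46M",
                                      cigar2 = "10M100N66M")))
  # the junction sits outside the window
  expect_true(exon_consistent(mk_pair(pos1 = 1000L, pos2 = 1140L,
                                      cigar1 = "30M100N46M", cigar2 = "76M")))
})

test_that("merging resolves overlap bases by the quality rules", {
  agree <- mk_pair(pos1 = 1000L, pos2 = 1005L, cigar1 = "10M", cigar2 = "10M",
                   qual1 = qv(rep(30L, 10)), qual2 = qv(rep(36L, 10)))
  m <- merge_pair(agree, prep_config())
  expect_identical(nrow(m), 1L)
  expect_identical(m$cigar, "15M")
  expect_identical(m$flag, 0L)
  expect_identical(rnaprep:::qual_to_int(m$qual),
                   c(rep(30L, 5), rep(36L, 5), rep(36L, 5)))
  # disagreement discards under the default
  fight <- mk_pair(pos1 = 1000L, pos2 = 1005L, cigar1 = "10M", cigar2 = "10M",
                   seq1 = "AAAAAAAAAA", seq2 = "CAAAAAAAAA")
  expect_identical(nrow(merge_pair(fight, prep_config())), 0L)
  # keep_mismatches: credible conflict -> first-in-pair base at quality 0
  keep <- prep_config(keep_mismatches = TRUE)
  m2 <- merge_pair(fight, keep)
  expect_identical(nrow(m2), 1L)
  expect_identical(substr(m2$seq, 6, 6), "A")
  expect_identical(rnaprep:::qual_to_int(m2$qual)[6], 0L)
  # keep_mismatches: low-quality side loses to the better base
  weak <- mk_pair(pos1 = 1000L, pos2 = 1005L, cigar1 = "10M", cigar2 = "10M",
                  seq1 = "AAAAAATAAA", seq2 = "CAAAAAAAAA",
                  qual1 = qv(c(rep(30L, 6), 5L, 30L, 30L, 30L)),
                  qual2 = qv(rep(30L, 10)))
  m3 <- merge_pair(weak, keep)
  expect_identical(substr(m3$seq, 7, 7), "A")
  expect_identical(rnaprep:::qual_to_int(m3$qual)[7], 30L)
})

test_that("non-overlapping and exon-inconsistent pairs take their documented paths", {
  apart <- mk_pair(pos1 = 1000L, pos2 = 1200L, cigar1 = "10M", cigar2 = "10M",
                   mapq = 60L)
  m <- merge_pair(apart, prep_config(map_cutoff = 40L))
  expect_identical(nrow(m), 2L)
  expect_identical(m$pos, c(1000L, 1200L))
  expect_identical(m$mapq, c(60L, 60L))
  inc <- mk_pair(pos1 = 1000L, pos2 = 1020L, cigar1 = "30M100N46M",
                 cigar2 = "76M")
  expect_identical(nrow(merge_pair(inc, prep_config())), 0L)
})

test_that("merging handles deletions and insertions deterministically", {
  # a deletion in one mate's overlap: the other mate's base fills the column
  del <- mk_pair(pos1 = 1000L, pos2 = 1000L, cigar1 = "4M2D6M", cigar2 = "12M",
                 seq1 = "AAAAAAAAAA", seq2 = "AAAAGGAAAAAA",
                 qual1 = qv(rep(30L, 10)), qual2 = qv(rep(20L, 12)))
  m <- merge_pair(del, prep_config())
  expect_identical(m$cigar, "12M")
  expect_identical(substr(m$seq, 5, 6), "GG")
  expect_identical(rnaprep:::qual_to_int(m$qual)[5:6], c(20L, 20L))
  # an insertion in the first mate is carried through the merge
  ins <- mk_pair(pos1 = 1000L, pos2 = 1002L, cigar1 = "4M2I6M", cigar2 = "8M",
                 seq1 = "AAAACCAAAAAA", seq2 = "AAAAAAAA",
                 qual1 = qv(rep(30L, 12)), qual2 = qv(rep(30L, 8)))
  m2 <- merge_pair(ins, prep_config())
  expect_identical(m2$cigar, "4M2I6M")
  expect_identical(m2$seq, "AAAACCAAAAAA")
})

test_that("intron splitting follows CIGAR reference arithmetic", {
  one <- mk_read(pos = 1000L, cigar = "30M100N46M")
  out <- split_introns(one)
  expect_identical(out$pos, c(1000L, 1130L))
  expect_identical(out$cigar, c("30M", "46M"))
  expect_identical(out$qname, c("r1/1", "r1/2"))
  plain <- mk_read(pos = 1000L, cigar = "76M")
  expect_identical(split_introns(plain)$cigar, "76M")
  expect_identical(split_introns(plain)$qname, "r1")
  three <- mk_read(pos = 1000L, cigar = "20M50N30M60N26M")
  out3 <- split_introns(three)
  expect_identical(out3$pos, c(1000L, 1070L, 1160L))
  expect_identical(out3$cigar, c("20M", "30M", "26M"))
})

test_that("splitting attaches indels to fragments and drops insertion-only fragments", {
  # insertion right before the junction stays with the left fragment
  r <- mk_read(pos = 1000L, cigar = "10M2I50N10M")
  out <- split_introns(r)
  expect_identical(out$cigar, c("10M2I", "10M"))
  expect_identical(out$pos, c(1000L, 1060L))
  # insertion right after the junction anchors to the left fragment too
  r2 <- mk_read(pos = 1000L, cigar = "10M50N2I10M")
  out2 <- split_introns(r2)
  expect_identical(out2$cigar, c("10M2I", "10M"))
  # a deletion at a fragment edge is trimmed
  r3 <- mk_read(pos = 1000L, cigar = "10M3D50N10M")
  out3 <- split_introns(r3)
  expect_identical(out3$cigar, c("10M", "10M"))
  expect_identical(out3$pos, c(1000L, 1063L))
})

test_that("splitting conserves the aligned sequence", {
  withr::with_seed(11, {
    for (i in 1:15) {
      nseg <- sample(2:4, 1)
      segs <- paste0(sample(10:40, nseg, replace = TRUE), "M")
      gaps <- paste0(sample(50:200, nseg - 1, replace = TRUE), "N")
      cigar <- paste0(c(rbind(segs, c(gaps, ""))), collapse = "")
      n <- rnaprep:::query_consumed(rnaprep:::cigar_ops(cigar))
      seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   collapse = "")
      r <- mk_read(pos = 1000L, cigar = cigar, seq = seq,
                   qual = rnaprep:::int_to_qual(sample(0:40, n, replace = TRUE)))
      out <- split_introns(r)
      expect_identical(paste(out$seq, collapse = ""), seq)
      expect_identical(paste(out$qual, collapse = ""), r$qual)
      # reference span is conserved once skipped introns are added back
      skipped <- sum(as.integer(regmatches(cigar,
        gregexpr("[0-9]+(?=N)", cigar, perl = TRUE))[[1]]))
      expect_identical(sum(reference_span(out)) + skipped, reference_span(r))
    }
  })
})

test_that("no output of the full pipeline is spliced, paired, reverse or clipped", {
  for (s in c(3, 9, 17)) {
    ri <- sim_random_input(s)
    out <- prep_reads(ri$reads, ri$config)
    if (nrow(out) == 0L) next
    expect_false(any(grepl("[NS]", out$cigar)))
    expect_true(all(out$flag == 0L))
  }
})
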