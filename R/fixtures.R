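# Deterministic synthetic fixtures: a pseudo-random reference, ten golden
# alignment scenarios exercising every pipeline rule (each with its
# hand-derived expected output), a planted-rate profiler fixture and a
# randomized small-input generator for property tests. All randomness flows
# through an explicit seed.

#' Deterministic synthetic reference sequence
#'
#' @param n_contigs number of contigs (named `chr1`, `chr2`, ...).
#' @param contig_length length of each contig (>= 200).
#' @param seed integer seed; the same seed always yields the same sequence.
#' @return a `Biostrings::DNAStringSet`.
#' @export
sim_reference <- function(n_contigs = 1L, contig_length = 5000L, seed = 1L) {
  stopifnot(contig_length >= 200L, n_contigs >= 1L)
  seqs <- withr::with_seed(seed, vapply(seq_len(n_contigs), function(i) {
    paste(sample(c("A", "C", "G", "T"), contig_length, replace = TRUE),
          collapse = "")
  }, character(1)))
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- paste0("chr", seq_len(n_contigs))
  ref
}

#' Write a reference to an indexed FASTA file
#'
#' @param reference a `Biostrings::DNAStringSet`.
#' @param path destination `.fa` file.
#' @return `path`, invisibly (a `.fai` index is created alongside).
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

ref_chunk <- function(reference, rname, start, end) {
  substr(as.character(reference[[rname]]), start, end)
}

# deterministic substitute base, always different from the reference base
alt_base <- function(b) c(A = "C", C = "A", G = "T", T = "G", N = "A")[[toupper(b)]]

#' Build one synthetic record consistent with a reference.
#' M bases are copied from the reference; S and I bases use `fill`;
#' `sub` is an integer vector of query indices to substitute with a
#' non-reference base.
#' @noRd
sim_read <- function(reference, qname, rname, pos, cigar, reverse = FALSE,
                     paired = TRUE, first = TRUE, proper = TRUE,
                     mapq = 50L, qual = 35L, secondary = FALSE,
                     sub = integer(0), fill = "A", md = NA_character_) {
  ops <- cigar_ops(cigar)
  rpos <- pos - 1L
  chars <- character(0)
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]
    len <- ops$len[k]
    if (op == "M") {
      chars <- c(chars, strsplit(ref_chunk(reference, rname, rpos + 1L, rpos + len),
                                 "", fixed = TRUE)[[1]])
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      chars <- c(chars, rep(fill, len))
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + len
    }
  }
  for (i in sub) chars[i] <- alt_base(chars[i])
  qlen <- length(chars)
  q <- if (length(qual) == 1L) rep(as.integer(qual), qlen) else as.integer(qual)
  stopifnot(length(q) == qlen)
  flag <- FLAG_PAIRED * paired + FLAG_PROPER * (paired && proper) +
    FLAG_REVERSE * reverse + FLAG_FIRST * (paired && first) +
    FLAG_SECOND * (paired && !first) + FLAG_SECONDARY * secondary
  alignment_tibble(qname = qname, flag = as.integer(flag), rname = rname,
                   pos = pos, mapq = mapq, cigar = cigar,
                   seq = paste(chars, collapse = ""), qual = int_to_qual(q),
                   md = md)
}

#' Build a synthetic mate pair (first row = first-in-pair).
#' @noRd
sim_pair <- function(reference, qname, rname, pos1, cigar1, pos2, cigar2,
                     qual1 = 30L, qual2 = 30L, mapq = 50L, proper = TRUE,
                     reverse1 = FALSE, reverse2 = TRUE,
                     sub1 = integer(0), sub2 = integer(0),
                     rname2 = rname) {
  r1 <- sim_read(reference, qname, rname, pos1, cigar1, reverse = reverse1,
                 first = TRUE, proper = proper, mapq = mapq, qual = qual1,
                 sub = sub1)
  r2 <- sim_read(reference, qname, rname2, pos2, cigar2, reverse = reverse2,
                 first = FALSE, proper = proper, mapq = mapq, qual = qual2,
                 sub = sub2)
  r1$flag <- r1$flag + FLAG_MATE_REVERSE * reverse2
  r2$flag <- r2$flag + FLAG_MATE_REVERSE * reverse1
  r1$rnext <- rname2
  r1$pnext <- pos2
  r2$rnext <- rname
  r2$pnext <- pos1
  span2 <- ref_consumed(cigar_ops(cigar2))
  tl <- if (rname2 == rname) (pos2 + span2) - pos1 else 0L
  r1$tlen <- as.integer(tl)
  r2$tlen <- as.integer(-tl)
  dplyr::bind_rows(r1, r2)
}

#' One expected-output record (unpaired, forward, as the pipeline emits).
#' @noRd
expect_read <- function(qname, rname, pos, cigar, seq, qual, mapq = 50L) {
  alignment_tibble(qname = qname, flag = 0L, rname = rname, pos = pos,
                   mapq = mapq, cigar = cigar, seq = seq, qual = qual)
}

#' Names of the bundled golden scenarios
#'
#' @return character vector of scenario identifiers for [sim_scenario()].
#' @export
scenario_names <- function() {
  c("duplicate_cluster", "overlap_agree", "overlap_mismatch", "spliced_pair",
    "discordant_orientations", "cross_contig_pair", "soft_clipped",
    "mapq255", "single_vs_pair_dup", "exon_inconsistent_overlap")
}

#' Golden alignment scenarios with expected pipeline output
#'
#' Builds a small position-sorted set of synthetic records exercising one
#' pipeline rule, together with the configuration to run it under, the
#' hand-derived expected output records, and a per-read fate table. The
#' expected records are constructed literally in this generator (positions,
#' CIGARs, sequences and qualities written out by applying the documented
#' rules by hand), never by calling the pipeline.
#'
#' @param name one of [scenario_names()].
#' @param seed seed for the underlying reference sequence.
#' @return a list with elements `name`, `reference`, `reads` (alignment
#'   tibble, position-sorted, `"contigs"` attribute set), `config`
#'   ([prep_config()]), `expected` (alignment tibble of expected output)
#'   and `fates` (tibble `qname`, `fate`).
#' @export
sim_scenario <- function(name = scenario_names(), seed = 1L) {
  name <- match.arg(name)
  ref <- sim_reference(1L, 5000L, seed)
  config <- prep_config()
  fates <- NULL

  q0 <- function(...) int_to_qual(c(...))
  flat <- function(q, n) int_to_qual(rep(q, n))

  if (name == "duplicate_cluster") {
    # three pairs share the duplicate key (fwd 5' 1001, rev 5' 1156);
    # dupB has the highest base-quality sum and becomes primary. dupA
    # disagrees at first-mate base 10 with credible quality (30 vs 35):
    # the primary keeps its base but the quality is zeroed. dupC disagrees
    # at base 20 with quality 5 (< 10): the primary's higher-quality base
    # stands. The mates do not overlap, so the primary emits two fragments.
    qa <- rep(30L, 76)
    qc <- rep(32L, 76); qc[20] <- 5L
    reads <- dplyr::bind_rows(
      sim_pair(ref, "dupA", "chr1", 1001L, "76M", 1081L, "76M",
               qual1 = qa, qual2 = 30L, sub1 = 10L),
      sim_pair(ref, "dupB", "chr1", 1001L, "76M", 1081L, "76M",
               qual1 = 35L, qual2 = 35L),
      sim_pair(ref, "dupC", "chr1", 1001L, "76M", 1081L, "76M",
               qual1 = qc, qual2 = 32L, sub1 = 20L))
    qb <- rep(35L, 76); qb[10] <- 0L
    expected <- dplyr::bind_rows(
      expect_read("dupB/1", "chr1", 1001L, "76M",
                  ref_chunk(ref, "chr1", 1001, 1076), int_to_qual(qb)),
      expect_read("dupB/2", "chr1", 1081L, "76M",
                  ref_chunk(ref, "chr1", 1081, 1156), flat(35L, 76)))
    fates <- tibble::tibble(
      qname = c("dupA", "dupB", "dupC"),
      fate = c("discarded-duplicate", "primary-split-2", "discarded-duplicate"))

  } else if (name == "overlap_agree") {
    # one concordant pair overlapping by 26 bases; all bases agree, so the
    # merged read keeps the higher quality in the overlap.
    reads <- sim_pair(ref, "ovlA", "chr1", 1501L, "76M", 1551L, "76M",
                      qual1 = 30L, qual2 = 36L)
    expected <- expect_read("ovlA", "chr1", 1501L, "126M",
                            ref_chunk(ref, "chr1", 1501, 1626),
                            q0(rep(30L, 50), rep(36L, 76)))
    fates <- tibble::tibble(qname = "ovlA", fate = "merged-1")

  } else if (name == "overlap_mismatch") {
    # with keep_mismatches = FALSE (the default), any base disagreement in
    # the overlap discards the pair, whatever the qualities involved.
    qc2 <- rep(35L, 76); qc2[10] <- 5L
    reads <- dplyr::bind_rows(
      sim_pair(ref, "mmA", "chr1", 2001L, "76M", 2051L, "76M",
               qual1 = 30L, qual2 = 35L, sub2 = 5L),
      sim_pair(ref, "mmB", "chr1", 2501L, "76M", 2551L, "76M",
               qual1 = 33L, qual2 = 33L),
      sim_pair(ref, "mmC", "chr1", 3001L, "76M", 3051L, "76M",
               qual1 = 30L, qual2 = qc2, sub2 = 10L))
    expected <- expect_read("mmB", "chr1", 2501L, "126M",
                            ref_chunk(ref, "chr1", 2501, 2626), flat(33L, 126))
    fates <- tibble::tibble(
      qname = c("mmA", "mmB", "mmC"),
      fate = c("discarded-merge", "merged-1", "discarded-merge"))

  } else if (name == "spliced_pair") {
    # the first mate spans an intron (1031-1130); its second exon overlaps
    # the unspliced second mate, whose window holds no junction, so the
    # pair is consistent. Merging and splitting yield two fragments.
    reads <- sim_pair(ref, "splA", "chr1", 1001L, "30M100N46M", 1141L, "76M",
                      qual1 = 30L, qual2 = 35L)
    expected <- dplyr::bind_rows(
      expect_read("splA/1", "chr1", 1001L, "30M",
                  ref_chunk(ref, "chr1", 1001, 1030), flat(30L, 30)),
      expect_read("splA/2", "chr1", 1131L, "86M",
                  ref_chunk(ref, "chr1", 1131, 1216),
                  q0(rep(30L, 10), rep(35L, 76))))
    fates <- tibble::tibble(qname = "splA", fate = "merged-split-2")

  } else if (name == "discordant_orientations") {
    # mates on the same strand, and an outward-pointing pair (leftmost
    # mate reverse), are both discarded at QC; the inward control pair
    # survives as two fragments.
    reads <- dplyr::bind_rows(
      sim_pair(ref, "sameDir", "chr1", 1001L, "76M", 1101L, "76M",
               reverse1 = FALSE, reverse2 = FALSE),
      sim_pair(ref, "outward", "chr1", 1301L, "76M", 1401L, "76M",
               reverse1 = TRUE, reverse2 = FALSE),
      sim_pair(ref, "okPair", "chr1", 1601L, "76M", 1701L, "76M",
               qual1 = 30L, qual2 = 30L))
    expected <- dplyr::bind_rows(
      expect_read("okPair/1", "chr1", 1601L, "76M",
                  ref_chunk(ref, "chr1", 1601, 1676), flat(30L, 76)),
      expect_read("okPair/2", "chr1", 1701L, "76M",
                  ref_chunk(ref, "chr1", 1701, 1776), flat(30L, 76)))
    fates <- tibble::tibble(
      qname = c("sameDir", "outward", "okPair"),
      fate = c("discarded-qc", "discarded-qc", "merged-split-2"))

  } else if (name == "cross_contig_pair") {
    ref <- sim_reference(2L, 3000L, seed)
    # mates on different contigs are discarded even when flagged proper.
    reads <- dplyr::bind_rows(
      sim_pair(ref, "xchr", "chr1", 1001L, "76M", 1001L, "76M",
               rname2 = "chr2"),
      sim_pair(ref, "ctrl", "chr2", 1501L, "76M", 1551L, "76M",
               qual1 = 30L, qual2 = 30L))
    expected <- expect_read("ctrl", "chr2", 1501L, "126M",
                            ref_chunk(ref, "chr2", 1501, 1626), flat(30L, 126))
    fates <- tibble::tibble(qname = c("xchr", "ctrl"),
                            fate = c("discarded-qc", "merged-1"))

  } else if (name == "soft_clipped") {
    # with soft_clips_exist = TRUE, flank masking touches only reads whose
    # CIGAR holds soft clips; clipA's clipped first mate gets its first
    # three sequencing cycles zeroed (the trailing three fall in the clip,
    # which is then stripped). Unclipped mates pass unmasked. clipC's
    # clipped mate is on the reverse strand: its first sequencing cycles
    # are the rightmost stored bases.
    config <- prep_config(soft_clips_exist = TRUE,
                          min_flank_start = 3L, min_flank_end = 3L)
    reads <- dplyr::bind_rows(
      sim_pair(ref, "clipA", "chr1", 1001L, "73M3S", 1101L, "76M",
               qual1 = 30L, qual2 = 30L),
      sim_pair(ref, "clipB", "chr1", 2001L, "76M", 2101L, "76M",
               qual1 = 28L, qual2 = 28L),
      sim_pair(ref, "clipC", "chr1", 2401L, "76M", 2501L, "3S73M",
               qual1 = 30L, qual2 = 30L))
    expected <- dplyr::bind_rows(
      expect_read("clipA/1", "chr1", 1001L, "73M",
                  ref_chunk(ref, "chr1", 1001, 1073),
                  q0(0L, 0L, 0L, rep(30L, 70))),
      expect_read("clipA/2", "chr1", 1101L, "76M",
                  ref_chunk(ref, "chr1", 1101, 1176), flat(30L, 76)),
      expect_read("clipB/1", "chr1", 2001L, "76M",
                  ref_chunk(ref, "chr1", 2001, 2076), flat(28L, 76)),
      expect_read("clipB/2", "chr1", 2101L, "76M",
                  ref_chunk(ref, "chr1", 2101, 2176), flat(28L, 76)),
      expect_read("clipC/1", "chr1", 2401L, "76M",
                  ref_chunk(ref, "chr1", 2401, 2476), flat(30L, 76)),
      expect_read("clipC/2", "chr1", 2501L, "73M",
                  ref_chunk(ref, "chr1", 2501, 2573),
                  q0(rep(30L, 70), 0L, 0L, 0L)))
    fates <- tibble::tibble(
      qname = c("clipA", "clipB", "clipC"),
      fate = c("masked-split-2", "split-2", "masked-split-2"))

  } else if (name == "mapq255") {
    # MAPQ 255 ("unavailable") is reassigned 50 and survives the default
    # cutoff of 40; genuine multi-mappers (MAPQ 3) are discarded.
    reads <- dplyr::bind_rows(
      sim_pair(ref, "uniq", "chr1", 1001L, "76M", 1051L, "76M",
               qual1 = 30L, qual2 = 30L, mapq = 255L),
      sim_pair(ref, "multi", "chr1", 1501L, "76M", 1601L, "76M",
               mapq = 3L))
    expected <- expect_read("uniq", "chr1", 1001L, "126M",
                            ref_chunk(ref, "chr1", 1001, 1126),
                            flat(30L, 126), mapq = 50L)
    fates <- tibble::tibble(qname = c("uniq", "multi"),
                            fate = c("merged-1", "discarded-qc"))

  } else if (name == "single_vs_pair_dup") {
    # singles flow only when properly_paired = FALSE. dupS starts at the
    # paired group's forward 5' anchor and is discarded as a duplicate
    # despite its higher qualities; sglA/sglB form a single-read group and
    # the higher-quality sum wins.
    config <- prep_config(properly_paired = FALSE)
    reads <- dplyr::bind_rows(
      sim_pair(ref, "pairP", "chr1", 1001L, "76M", 1101L, "76M",
               qual1 = 30L, qual2 = 30L),
      sim_read(ref, "dupS", "chr1", 1001L, "76M", paired = FALSE, qual = 40L),
      sim_read(ref, "sglA", "chr1", 2001L, "76M", paired = FALSE, qual = 30L),
      sim_read(ref, "sglB", "chr1", 2001L, "76M", paired = FALSE, qual = 35L))
    expected <- dplyr::bind_rows(
      expect_read("pairP/1", "chr1", 1001L, "76M",
                  ref_chunk(ref, "chr1", 1001, 1076), flat(30L, 76)),
      expect_read("pairP/2", "chr1", 1101L, "76M",
                  ref_chunk(ref, "chr1", 1101, 1176), flat(30L, 76)),
      expect_read("sglB", "chr1", 2001L, "76M",
                  ref_chunk(ref, "chr1", 2001, 2076), flat(35L, 76)))
    fates <- tibble::tibble(
      qname = c("pairP", "dupS", "sglA", "sglB"),
      fate = c("merged-split-2", "discarded-duplicate",
               "discarded-duplicate", "primary-single"))

  } else { # exon_inconsistent_overlap
    # 'inc': the first mate skips 1031-1130 inside the overlap while the
    # second mate aligns across it -> untrustworthy mapping, discarded.
    # 'con': both mates skip the same intron (1531-1630) -> merged.
    reads <- dplyr::bind_rows(
      sim_pair(ref, "inc", "chr1", 1001L, "30M100N46M", 1021L, "76M",
               qual1 = 30L, qual2 = 30L),
      sim_pair(ref, "con", "chr1", 1501L, "30M100N46M", 1521L, "10M100N66M",
               qual1 = 30L, qual2 = 35L))
    expected <- dplyr::bind_rows(
      expect_read("con/1", "chr1", 1501L, "30M",
                  ref_chunk(ref, "chr1", 1501, 1530),
                  q0(rep(30L, 20), rep(35L, 10))),
      expect_read("con/2", "chr1", 1631L, "66M",
                  ref_chunk(ref, "chr1", 1631, 1696), flat(35L, 66)))
    fates <- tibble::tibble(qname = c("inc", "con"),
                            fate = c("discarded-merge", "merged-split-2"))
  }

  contigs <- stats::setNames(Biostrings::width(ref), names(ref))
  reads <- sort_alignments(reads, contigs)
  attr(expected, "contigs") <- contigs
  list(name = name, reference = ref, reads = reads, config = config,
       expected = sort_alignments(expected, contigs), fates = fates)
}

#' Planted-rate fixture for the mismatch profiler
#'
#' Generates `n_reads` first-in-pair 76 bp alignments (half forward, half
#' reverse) whose per-cycle mismatch counts from each read end are planted
#' exactly, so the profiled rates are known by construction:
#' `start_counts[i] / n_reads` at cycle `i` from the 5' end and
#' `end_counts[i] / n_reads` from the 3' end. Each read carries a correct
#' MD tag; the matching reference is returned for the FASTA-based route.
#'
#' The default counts put the start/end mismatch rates at 2%, 1.5%, 0.75%
#' and 0.5% for cycles 1-4: the rate first drops below a 1% threshold at
#' cycle 3 on both sides, so [suggest_flanks()] returns 3 and 3.
#'
#' @param seed integer seed.
#' @param n_reads number of reads (default 400).
#' @param read_length read length (default 76).
#' @param start_counts,end_counts planted mismatch counts per cycle from
#'   each end; their lengths set the profiled range.
#' @return list with `reads`, `reference`, `rates_start`, `rates_end`.
#' @export
sim_profile_fixture <- function(seed = 1L, n_reads = 400L, read_length = 76L,
                                start_counts = c(8L, 6L, 3L, 2L),
                                end_counts = c(8L, 6L, 3L, 2L)) {
  k <- length(start_counts)
  stopifnot(length(end_counts) == k, n_reads >= 2L * sum(start_counts, end_counts),
            read_length > 2L * k)
  ref <- sim_reference(1L, 5000L, seed)
  pos <- withr::with_seed(seed + 1L,
    sample(seq_len(5000L - read_length), n_reads, replace = TRUE))
  rev <- rep(c(FALSE, TRUE), length.out = n_reads)
  # one planted mismatch per chosen read: reads are assigned to (side,
  # cycle) slots in order, so no read carries two mismatches
  slot <- rep(NA_integer_, n_reads)
  side <- rep(NA_character_, n_reads)
  i <- 1L
  for (cyc in seq_len(k)) for (j in seq_len(start_counts[cyc])) {
    slot[i] <- cyc; side[i] <- "start"; i <- i + 1L
  }
  for (cyc in seq_len(k)) for (j in seq_len(end_counts[cyc])) {
    slot[i] <- cyc; side[i] <- "end"; i <- i + 1L
  }
  reads <- vector("list", n_reads)
  for (r in seq_len(n_reads)) {
    stored <- NA_integer_
    if (!is.na(slot[r])) {
      cyc_start <- if (side[r] == "start") slot[r] else read_length - slot[r] + 1L
      stored <- if (rev[r]) read_length - cyc_start + 1L else cyc_start
    }
    sub <- if (is.na(stored)) integer(0) else stored
    md <- if (is.na(stored)) {
      as.character(read_length)
    } else {
      refbase <- substr(ref_chunk(ref, "chr1", pos[r] + stored - 1L,
                                  pos[r] + stored - 1L), 1L, 1L)
      paste0(stored - 1L, refbase, read_length - stored)
    }
    reads[[r]] <- sim_read(ref, sprintf("prof%04d", r), "chr1", pos[r],
                           paste0(read_length, "M"), reverse = rev[r],
                           paired = TRUE, first = TRUE, qual = 30L,
                           sub = sub, md = md)
  }
  reads <- dplyr::bind_rows(reads)
  contigs <- stats::setNames(Biostrings::width(ref), names(ref))
  reads <- sort_alignments(reads, contigs)
  list(reads = reads, reference = ref,
       rates_start = start_counts / n_reads,
       rates_end = end_counts / n_reads)
}

#' Randomized small alignment sets for property testing
#'
#' Draws a handful of read pairs and singles (duplicated, spliced,
#' soft-clipped, overlapping, discordant or low-quality at random) on a
#' fresh synthetic contig, together with a randomly drawn configuration.
#' Deterministic for a given seed. Record counts stay small (<= 40) so a
#' brute-force re-application of the cleaning rules is feasible.
#'
#' @param seed integer seed.
#' @return list with `reads` (position-sorted alignment tibble), `config`
#'   and `reference`.
#' @export
sim_random_input <- function(seed = 1L) {
  ref <- sim_reference(1L, 3000L, seed)
  withr::with_seed(seed + 1000L, {
    config <- prep_config(
      properly_paired = FALSE,
      keep_mismatches = sample(c(TRUE, FALSE), 1L),
      soft_clips_exist = sample(c(TRUE, FALSE), 1L),
      min_flank_start = sample(c(0L, 2L), 1L),
      min_flank_end = sample(c(0L, 2L), 1L))
    rlen <- 60L
    n_loci <- sample(4:8, 1L)
    loci <- sample(seq(101L, 2200L, by = 45L), n_loci)
    out <- list()
    mkread <- function(qname, pos, cigar, reverse, paired, first, proper,
                       mapq, perturb = 0.03) {
      qlen <- query_consumed(cigar_ops(cigar))
      r <- sim_read(ref, qname, "chr1", pos, cigar, reverse = reverse,
                    paired = paired, first = first, proper = proper,
                    mapq = mapq, qual = sample(0:40, qlen, replace = TRUE),
                    sub = which(stats::runif(qlen) < perturb), fill = "T")
      r
    }
    for (li in seq_along(loci)) {
      locus <- loci[li]
      nm <- sprintf("r%02d", li)
      if (stats::runif(1) < 0.8) {
        # a pair, possibly spliced / clipped / discordant / duplicated
        gap <- sample(80:150, 1L)
        spliced_f <- stats::runif(1) < 0.3
        cigar_f <- if (spliced_f) sprintf("25M%dN35M", gap) else "60M"
        pos_f <- locus
        if (!spliced_f && stats::runif(1) < 0.3) {
          cigar_f <- "5S55M"
          pos_f <- locus + 5L
        }
        span_f <- ref_consumed(cigar_ops(cigar_f))
        insert <- sample(-20:120, 1L)
        pos_s <- max(1L, locus + insert)
        cigar_s <- if (spliced_f && stats::runif(1) < 0.5) {
          # share the first mate's junction when the window would demand it
          off <- pos_s - pos_f
          if (off > 0L && off < 25L) sprintf("%dM%dN35M", 25L - off, gap) else "60M"
        } else "60M"
        same_strand <- stats::runif(1) < 0.1
        mapq <- sample(c(50L, 50L, 50L, 255L, 2L), 1L)
        p1 <- mkread(nm, pos_f, cigar_f, reverse = FALSE, paired = TRUE,
                     first = TRUE, proper = !same_strand, mapq = mapq)
        p2 <- mkread(nm, pos_s, cigar_s, reverse = !same_strand, paired = TRUE,
                     first = FALSE, proper = !same_strand, mapq = mapq)
        p1$flag <- p1$flag + FLAG_MATE_REVERSE * (!same_strand)
        p1$rnext <- "chr1"; p1$pnext <- pos_s
        p2$rnext <- "chr1"; p2$pnext <- pos_f
        out[[length(out) + 1L]] <- p1
        out[[length(out) + 1L]] <- p2
        if (stats::runif(1) < 0.35) {
          # duplicate copy: same placement, fresh qualities, perturbed bases
          d1 <- mkread(paste0(nm, "d"), pos_f, cigar_f, FALSE, TRUE, TRUE,
                       proper = !same_strand, mapq = mapq, perturb = 0.05)
          d2 <- mkread(paste0(nm, "d"), pos_s, cigar_s, !same_strand, TRUE,
                       FALSE, proper = !same_strand, mapq = mapq,
                       perturb = 0.05)
          d1$flag <- d1$flag + FLAG_MATE_REVERSE * (!same_strand)
          out[[length(out) + 1L]] <- d1
          out[[length(out) + 1L]] <- d2
        }
        if (stats::runif(1) < 0.15) {
          sec <- p1
          sec$flag <- sec$flag + FLAG_SECONDARY
          sec$qname <- nm
          out[[length(out) + 1L]] <- sec
        }
      } else {
        spliced <- stats::runif(1) < 0.3
        cigar <- if (spliced) sprintf("30M%dN30M", sample(80:150, 1L)) else "60M"
        out[[length(out) + 1L]] <- mkread(nm, locus, cigar,
                                          reverse = stats::runif(1) < 0.5,
                                          paired = FALSE, first = FALSE,
                                          proper = FALSE,
                                          mapq = sample(c(50L, 255L, 2L), 1L))
      }
    }
    reads <- dplyr::bind_rows(out)
    contigs <- stats::setNames(Biostrings::width(ref), names(ref))
    reads <- sort_alignments(reads, contigs)
    list(reads = reads, config = config, reference = ref)
  })
}
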