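# Hand-built records for unit tests (arbitrary sequences, no reference).

qv <- function(...) rnaprep:::int_to_qual(c(...))

mk_read <- function(qname = "r1", flag = 0L, rname = "chr1", pos = 1000L,
                    mapq = 50L, cigar = "10M", seq = NULL, qual = NULL) {
  n <- sum(as.integer(regmatches(cigar, gregexpr("[0-9]+(?=[MIS])", cigar,
                                                 perl = TRUE))[[1]]))
  if (is.null(seq)) seq <- paste(rep("A", n), collapse = "")
  if (is.null(qual)) qual <- qv(rep(30L, n))
  alignment_tibble(qname = qname, flag = flag, rname = rname, pos = pos,
                   mapq = mapq, cigar = cigar, seq = seq, qual = qual)
}

# a concordant FR pair: first mate forward at pos1, second reverse at pos2
mk_pair <- function(qname = "p1", pos1 = 1000L, pos2 = 1100L,
                    cigar1 = "10M", cigar2 = "10M", mapq = 50L,
                    seq1 = NULL, seq2 = NULL, qual1 = NULL, qual2 = NULL,
                    rname = "chr1", proper = TRUE) {
  f <- 1L + 2L * proper + 32L + 64L
  s <- 1L + 2L * proper + 16L + 128L
  dplyr::bind_rows(
    mk_read(qname, f, rname, pos1, mapq, cigar1, seq1, qual1),
    mk_read(qname, s, rname, pos2, mapq, cigar2, seq2, qual2))
}
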