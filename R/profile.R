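# Per-cycle mismatch profiling. Base changes concentrate in the first
# sequencing cycles (random-hexamer priming during first-strand cDNA
# synthesis) and the last ones (quality decay, adapter read-through).
# Measuring the mismatch fraction per cycle from each read end tells the
# user how many flank bases are worth masking.

#' Per-cycle mismatch profile of aligned reads
#'
#' For each cycle position `1..k` counted from the 5' end (`side ==
#' "start"`) and from the 3' end (`side == "end"`) of the reads, in
#' sequencing order (reversed for reverse-strand alignments), computes the
#' fraction of aligned bases that differ from the reference. Soft-clipped
#' and inserted bases carry no reference base and are excluded, though
#' clipped bases still count towards the cycle numbering. Mismatch status
#' comes from the MD tag when present, else from `reference`; records
#' providing neither raise an error.
#'
#' @param reads an alignment tibble, or a path to a BAM/SAM file.
#' @param k number of cycle positions to profile from each end (default 4).
#' @param scope which reads to profile: `"first"` (default) uses
#'   first-in-pair reads only — the first strand carries the
#'   hexamer-priming errors and its parameters are conventionally applied
#'   to all reads — `"second"` the second mates, `"all"` every mapped
#'   primary.
#' @param reference optional `Biostrings::DNAStringSet` (or FASTA path)
#'   used when MD tags are absent.
#' @param min_base_quality exclude bases with quality below this value
#'   (default 0, i.e. keep all); useful to re-profile after masking.
#' @return a `mismatch_profile` object: a tibble with columns `side`,
#'   `position`, `n`, `mismatches`, `rate` (`NA` where no bases were
#'   observed).
#' @export
#' @examples
#' fx <- sim_profile_fixture(seed = 1)
#' prof <- mismatch_profile(fx$reads, k = 4)
#' suggest_flanks(prof, threshold = 0.01)
mismatch_profile <- function(reads, k = 4L, scope = c("first", "second", "all"),
                             reference = NULL, min_base_quality = 0L) {
  scope <- match.arg(scope)
  if (is.character(reads) && length(reads) == 1L) {
    reads <- read_alignments(reads)
  }
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  keep <- !is_unmapped(reads$flag) & !is_secondary(reads$flag) &
    !is_supplementary(reads$flag)
  keep <- keep & switch(scope,
    first = is_first_mate(reads$flag),
    second = flag_has(reads$flag, FLAG_SECOND),
    all = TRUE)
  reads <- reads[keep, , drop = FALSE]
  n_start <- mis_start <- integer(k)
  n_end <- mis_end <- integer(k)
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, , drop = FALSE]
    al <- aligned_base_status(r, reference)
    if (nrow(al) == 0L) next
    len <- nchar(r$seq)
    if (min_base_quality > 0L) {
      q <- qual_to_int(r$qual)
      al <- al[q[al$qidx] >= min_base_quality, , drop = FALSE]
    }
    cyc_start <- if (is_reverse(r$flag)) len - al$qidx + 1L else al$qidx
    cyc_end <- len - cyc_start + 1L
    for (j in seq_len(nrow(al))) {
      if (cyc_start[j] <= k) {
        n_start[cyc_start[j]] <- n_start[cyc_start[j]] + 1L
        mis_start[cyc_start[j]] <- mis_start[cyc_start[j]] + al$mismatch[j]
      }
      if (cyc_end[j] <= k) {
        n_end[cyc_end[j]] <- n_end[cyc_end[j]] + 1L
        mis_end[cyc_end[j]] <- mis_end[cyc_end[j]] + al$mismatch[j]
      }
    }
  }
  out <- tibble::tibble(
    side = rep(c("start", "end"), each = k),
    position = rep(seq_len(k), 2L),
    n = c(n_start, n_end),
    mismatches = c(mis_start, mis_end),
    rate = ifelse(c(n_start, n_end) > 0L,
                  c(mis_start, mis_end) / c(n_start, n_end), NA_real_))
  structure(out, k = k, scope = scope,
            class = c("mismatch_profile", class(out)))
}

#' Per aligned base of one record: stored query index and mismatch status.
#' @noRd
aligned_base_status <- function(read, reference = NULL) {
  ops <- cigar_ops(read$cigar)
  qidx <- integer(0)
  rposs <- integer(0)
  qpos <- 0L
  rpos <- read$pos - 1L
  for (j in seq_len(nrow(ops))) {
    op <- ops$op[j]
    len <- ops$len[j]
    if (op == "M") {
      qidx <- c(qidx, (qpos + 1L):(qpos + len))
      rposs <- c(rposs, (rpos + 1L):(rpos + len))
      qpos <- qpos + len
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + len
    }
  }
  if (length(qidx) == 0L) {
    return(tibble::tibble(qidx = integer(), mismatch = logical()))
  }
  if (!is.na(read$md)) {
    mm <- md_mismatch_flags(read$md, length(qidx))
  } else if (!is.null(reference)) {
    refseq <- reference[[read$rname]]
    rb <- strsplit(as.character(Biostrings::subseq(refseq, 1L, length(refseq))),
                   "", fixed = TRUE)[[1]][rposs]
    qb <- strsplit(read$seq, "", fixed = TRUE)[[1]][qidx]
    mm <- toupper(qb) != toupper(rb)
  } else {
    stop("read '", read$qname,
         "' has no MD tag and no reference was supplied", call. = FALSE)
  }
  tibble::tibble(qidx = qidx, mismatch = mm)
}

#' Mismatch flags over the aligned (M) columns encoded by an MD tag.
#' @noRd
md_mismatch_flags <- function(md, n_aligned) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  mm <- logical(0)
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      mm <- c(mm, rep(FALSE, as.integer(t)))
    } else if (startsWith(t, "^")) {
      # deletion: consumes reference only
    } else {
      mm <- c(mm, TRUE)
    }
  }
  if (length(mm) != n_aligned) {
    stop("MD tag '", md, "' does not cover ", n_aligned, " aligned bases",
         call. = FALSE)
  }
  mm
}

#' Recommend flank-masking widths from a mismatch profile
#'
#' For each side, the suggested flank is the first (1-based) cycle position
#' at which the mismatch rate falls below `threshold` — masking up to and
#' including the first acceptable cycle. If the rate is already below the
#' threshold at position 1 no masking is needed and 0 is returned; if it
#' never falls below the threshold within the profiled range, the range
#' width `k` is returned with a warning. Undefined rates (no observed
#' bases) never satisfy the threshold.
#'
#' @param profile a [mismatch_profile()].
#' @param threshold acceptable mismatch fraction (default 0.01, i.e. 1%).
#' @return named integer vector `c(min_flank_start, min_flank_end)`.
#' @export
suggest_flanks <- function(profile, threshold = 0.01) {
  stopifnot(inherits(profile, "mismatch_profile"), threshold > 0)
  one_side <- function(side) {
    p <- profile[profile$side == side, , drop = FALSE]
    p <- p[order(p$position), , drop = FALSE]
    below <- !is.na(p$rate) & p$rate < threshold
    if (length(below) == 0L || !any(below)) {
      warning("mismatch rate never falls below ", threshold,
              " within the first ", attr(profile, "k"),
              " positions (", side, " side)", call. = FALSE)
      return(attr(profile, "k"))
    }
    i <- which(below)[1L]
    if (i == 1L) 0L else i
  }
  c(min_flank_start = one_side("start"), min_flank_end = one_side("end"))
}

#' Write a mismatch profile as a tab-separated table
#'
#' @param profile a [mismatch_profile()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
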