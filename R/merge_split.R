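# Overlap merging and intron splitting. Overlapping mates are collapsed so
# the shared fragment is observed once; intron-spanning alignments are cut
# into exonic fragments so no output CIGAR contains an N operation.

#' Zero base qualities at read ends
#'
#' Masks the first `min_flank_start` and last `min_flank_end` base qualities
#' of each read in sequencing order: for reverse-strand alignments "first"
#' is the rightmost stored base, since stored bases are in reference
#' orientation. With `soft_clips_exist = TRUE` only reads whose CIGAR
#' contains soft clips are masked. Masking applies to the original,
#' unmerged, unsplit read, so it must run before [merge_pair()] /
#' [split_introns()]. If the two flanks cover the whole read every quality
#' is zeroed but the read is retained.
#'
#' @param reads an alignment tibble.
#' @param config a [prep_config()].
#' @return the tibble with masked qualities.
#' @export
mask_flanks <- function(reads, config = prep_config()) {
  mfs <- config$min_flank_start
  mfe <- config$min_flank_end
  if ((mfs == 0L && mfe == 0L) || nrow(reads) == 0L) return(reads)
  target <- if (config$soft_clips_exist) {
    has_soft_clip(reads$cigar)
  } else {
    rep(TRUE, nrow(reads))
  }
  for (i in which(target)) {
    q <- qual_to_int(reads$qual[i])
    len <- length(q)
    s <- min(mfs, len)
    e <- min(mfe, len)
    if (is_reverse(reads$flag[i])) {
      if (s > 0L) q[(len - s + 1L):len] <- 0L
      if (e > 0L) q[seq_len(e)] <- 0L
    } else {
      if (s > 0L) q[seq_len(s)] <- 0L
      if (e > 0L) q[(len - e + 1L):len] <- 0L
    }
    reads$qual[i] <- int_to_qual(q)
  }
  reads
}

#' Remove soft-clipped bases from records
#'
#' Drops `S` (and `H`) CIGAR operations and trims the corresponding bases
#' from `seq`/`qual`. Unaligned bases must not reach a variant caller as
#' aligned evidence; run after [mask_flanks()], whose soft-clip conditional
#' inspects the original CIGAR.
#'
#' @param reads an alignment tibble.
#' @return the tibble with clips removed.
#' @export
strip_soft_clips <- function(reads) {
  idx <- which(grepl("[SH]", reads$cigar))
  for (i in idx) {
    ops <- cigar_ops(reads$cigar[i])
    cl <- clip_lengths(reads$cigar[i])
    len <- nchar(reads$seq[i])
    reads$seq[i] <- substr(reads$seq[i], cl[["lead"]] + 1L, len - cl[["trail"]])
    reads$qual[i] <- substr(reads$qual[i], cl[["lead"]] + 1L, len - cl[["trail"]])
    reads$cigar[i] <- cigar_string(ops[!ops$op %in% c("S", "H"), , drop = FALSE])
  }
  reads
}

#' Reference interval shared by both mates
#'
#' The intersection of the two mates' aligned reference spans, as an
#' inclusive `c(start, end)` coordinate pair, or `integer(0)` when the
#' mates do not overlap.
#'
#' @param pair a two-row alignment tibble.
#' @return integer vector of length 2, or `integer(0)`.
#' @export
overlap_window <- function(pair) {
  stopifnot(nrow(pair) == 2L)
  span <- reference_span(pair)
  start <- max(pair$pos)
  end <- min(pair$pos + span - 1L)
  if (start > end) return(integer(0))
  c(start, end)
}

#' Intron intervals (inclusive) skipped by a record's N operations.
#' @noRd
intron_intervals <- function(read) {
  ops <- cigar_ops(read$cigar)
  rpos <- read$pos - 1L
  out <- list()
  for (k in seq_len(nrow(ops))) {
    if (ops$op[k] %in% c("M", "D", "N")) {
      if (ops$op[k] == "N") {
        out[[length(out) + 1L]] <- c(rpos + 1L, rpos + ops$len[k])
      }
      rpos <- rpos + ops$len[k]
    }
  }
  out
}

#' Do both mates imply the same exonic segmentation of their overlap?
#'
#' Within the overlap window the two mates must skip exactly the same
#' intron intervals; a pair whose mates disagree has an untrustworthy
#' mapping and is discarded. Pairs without an overlap are vacuously
#' consistent.
#'
#' @param pair a two-row alignment tibble.
#' @return `TRUE` or `FALSE`.
#' @export
exon_consistent <- function(pair) {
  w <- overlap_window(pair)
  if (length(w) == 0L) return(TRUE)
  clip <- function(read) {
    iv <- intron_intervals(read)
    iv <- lapply(iv, function(x) c(max(x[1L], w[1L]), min(x[2L], w[2L])))
    iv <- Filter(function(x) x[1L] <= x[2L], iv)
    sort(vapply(iv, function(x) paste(x, collapse = "-"), character(1)))
  }
  identical(clip(pair[1L, , drop = FALSE]), clip(pair[2L, , drop = FALSE]))
}

#' Decompose a clip-free record into reference-anchored columns.
#' @noRd
read_columns <- function(read) {
  ops <- cigar_ops(read$cigar)
  stopifnot(!any(ops$op %in% c("S", "H")))
  bases <- strsplit(read$seq, "", fixed = TRUE)[[1]]
  quals <- qual_to_int(read$qual)
  rpos <- read$pos - 1L
  qpos <- 0L
  anchor <- read$pos - 1L
  m <- list()
  d <- integer()
  ins <- list()
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]
    len <- ops$len[k]
    if (op == "M") {
      m[[length(m) + 1L]] <- tibble::tibble(
        rpos = (rpos + 1L):(rpos + len),
        base = bases[(qpos + 1L):(qpos + len)],
        qual = quals[(qpos + 1L):(qpos + len)])
      rpos <- rpos + len
      qpos <- qpos + len
      anchor <- rpos
    } else if (op == "I") {
      ins[[length(ins) + 1L]] <- tibble::tibble(
        anchor = anchor,
        seq = paste(bases[(qpos + 1L):(qpos + len)], collapse = ""),
        qual = list(quals[(qpos + 1L):(qpos + len)]))
      qpos <- qpos + len
    } else if (op == "D") {
      d <- c(d, (rpos + 1L):(rpos + len))
      rpos <- rpos + len
      anchor <- rpos
    } else if (op == "N") {
      rpos <- rpos + len
    }
  }
  list(m = dplyr::bind_rows(m), d = d, ins = dplyr::bind_rows(ins))
}

#' Rebuild alignment records from merged reference columns, cutting a new
#' fragment at every coverage gap (gaps are intron skips by construction).
#' Leading/trailing deletion columns are trimmed; fragments without aligned
#' bases are dropped.
#' @noRd
columns_to_reads <- function(m, d, ins, template) {
  covered <- sort(unique(c(m$rpos, d)))
  if (length(covered) == 0L) return(template[0L, , drop = FALSE])
  frag_of <- cumsum(c(1L, as.integer(diff(covered) > 1L)))
  m_at <- m[match(covered, m$rpos), , drop = FALSE]  # NA rows where D
  is_m <- covered %in% m$rpos
  out <- list()
  for (f in unique(frag_of)) {
    sel <- which(frag_of == f)
    # trim deletion columns at fragment edges
    while (length(sel) > 0L && !is_m[sel[1L]]) sel <- sel[-1L]
    while (length(sel) > 0L && !is_m[sel[length(sel)]]) sel <- sel[-length(sel)]
    if (length(sel) == 0L) next
    op_seq <- character(0)
    seq_out <- character(0)
    qual_out <- integer(0)
    for (j in sel) {
      if (is_m[j]) {
        op_seq <- c(op_seq, "M")
        seq_out <- c(seq_out, m_at$base[j])
        qual_out <- c(qual_out, m_at$qual[j])
      } else {
        op_seq <- c(op_seq, "D")
      }
      if (nrow(ins) > 0L) {
        hit <- which(ins$anchor == covered[j])
        for (h in hit) {
          nb <- nchar(ins$seq[h])
          op_seq <- c(op_seq, rep("I", nb))
          seq_out <- c(seq_out, strsplit(ins$seq[h], "", fixed = TRUE)[[1]])
          qual_out <- c(qual_out, ins$qual[[h]])
        }
      }
    }
    rec <- template
    rec$pos <- covered[sel[1L]]
    rec$cigar <- cigar_string(tibble::tibble(op = op_seq, len = 1L))
    rec$seq <- paste(seq_out, collapse = "")
    rec$qual <- int_to_qual(qual_out)
    out[[length(out) + 1L]] <- rec
  }
  dplyr::bind_rows(out)
}

#' Merge an overlapping read pair into single-strand evidence
#'
#' Produces unpaired forward-strand records covering the union of the two
#' mates' aligned spans. In the overlap, agreeing bases keep the higher of
#' the two qualities; at disagreeing bases the pair is discarded unless
#' `keep_mismatches = TRUE`, in which case a base with quality below 10
#' loses to the higher-quality base and a credible conflict (both qualities
#' >= 10) keeps the first-in-pair base with quality zeroed. Pairs whose
#' mates imply different exon structure in the overlap are discarded
#' ([exon_consistent()]). Non-overlapping mates are emitted as two separate
#' fragments. Spliced spans are cut at each intron, so the result may hold
#' several records; each carries the lower of the two mate MAPQs.
#'
#' Reads are clip-stripped on entry if needed; [mask_flanks()] must already
#' have been applied (masking is defined on the original reads).
#'
#' @param pair a two-row alignment tibble (a QC-passed pair).
#' @param config a [prep_config()].
#' @return an alignment tibble of 0 (discarded) or more fragments.
#' @export
merge_pair <- function(pair, config = prep_config()) {
  stopifnot(nrow(pair) == 2L)
  pair <- strip_soft_clips(pair)
  first <- pair[order(!is_first_mate(pair$flag))[1L], , drop = FALSE]
  second <- pair[order(!is_first_mate(pair$flag))[2L], , drop = FALSE]
  template <- first
  template$mapq <- min(pair$mapq)
  template$flag <- 0L
  template$rnext <- "*"
  template$pnext <- 0L
  template$tlen <- 0L
  template$md <- NA_character_
  w <- overlap_window(pair)
  if (length(w) == 0L) {
    frags <- dplyr::bind_rows(split_read(first), split_read(second))
    frags$mapq <- min(pair$mapq)
    return(frags)
  }
  if (!exon_consistent(pair)) return(first[0L, , drop = FALSE])
  cf <- read_columns(first)
  cs <- read_columns(second)
  both <- dplyr::inner_join(cf$m, cs$m, by = "rpos", suffix = c("_f", "_s"))
  conflict <- both[both$base_f != both$base_s, , drop = FALSE]
  if (nrow(conflict) > 0L && !config$keep_mismatches) {
    return(first[0L, , drop = FALSE])
  }
  resolve <- function(bf, qf, bs, qs) {
    if (bf == bs) return(c(bf, max(qf, qs)))
    if (qf < 10L || qs < 10L) {
      if (qs > qf) return(c(bs, qs))
      return(c(bf, qf))
    }
    c(bf, 0L)  # credible conflict: first-in-pair base, quality zeroed
  }
  shared <- t(mapply(resolve, both$base_f, both$qual_f, both$base_s, both$qual_s))
  m_shared <- tibble::tibble(rpos = both$rpos,
                             base = as.character(shared[, 1L]),
                             qual = as.integer(shared[, 2L]))
  only_f <- cf$m[!cf$m$rpos %in% both$rpos, , drop = FALSE]
  only_s <- cs$m[!cs$m$rpos %in% both$rpos, , drop = FALSE]
  m <- dplyr::arrange(dplyr::bind_rows(m_shared, only_f, only_s), .data$rpos)
  d <- setdiff(union(cf$d, cs$d), m$rpos)
  # insertions: first-in-pair wins inside its own span
  f_span <- c(first$pos, first$pos + reference_span(first) - 1L)
  ins <- dplyr::bind_rows(
    cf$ins,
    if (nrow(cs$ins) > 0L) {
      cs$ins[cs$ins$anchor < f_span[1L] | cs$ins$anchor >= f_span[2L], , drop = FALSE]
    })
  if (is.null(ins)) ins <- cf$ins
  columns_to_reads(m, d, ins, template)
}

#' Split one clip-free record at its intron skips.
#' @noRd
split_read <- function(read) {
  stopifnot(nrow(read) == 1L)
  read$flag <- 0L
  read$rnext <- "*"
  read$pnext <- 0L
  read$tlen <- 0L
  read$md <- NA_character_
  if (!has_intron(read$cigar)) return(read)
  ops <- cigar_ops(read$cigar)
  # segment id per op: I ops anchor to the last reference-consuming segment
  seg <- integer(nrow(ops))
  cur <- 1L
  last_md_seg <- 1L
  for (k in seq_len(nrow(ops))) {
    if (ops$op[k] == "N") {
      cur <- cur + 1L
      seg[k] <- NA_integer_
    } else if (ops$op[k] == "I") {
      seg[k] <- last_md_seg
    } else {
      seg[k] <- cur
      last_md_seg <- cur
    }
  }
  ref_start <- read$pos + cumsum(c(0L, utils::head(
    ifelse(ops$op %in% c("M", "D", "N"), ops$len, 0L), -1L)))
  q_start <- 1L + cumsum(c(0L, utils::head(
    ifelse(ops$op %in% c("M", "I", "S"), ops$len, 0L), -1L)))
  out <- list()
  for (s in sort(unique(seg[!is.na(seg)]))) {
    rows <- which(seg == s)
    sub <- ops[rows, , drop = FALSE]
    sub$ref_start <- ref_start[rows]
    sub$q_start <- q_start[rows]
    sub <- sub[order(sub$q_start, sub$ref_start), , drop = FALSE]
    # trim edge deletions
    while (nrow(sub) > 0L && sub$op[1L] == "D") sub <- sub[-1L, , drop = FALSE]
    while (nrow(sub) > 0L && sub$op[nrow(sub)] == "D") sub <- sub[-nrow(sub), , drop = FALSE]
    if (!any(sub$op == "M")) next
    qidx <- unlist(lapply(which(sub$op %in% c("M", "I")), function(j) {
      sub$q_start[j]:(sub$q_start[j] + sub$len[j] - 1L)
    }))
    frag <- read
    frag$pos <- sub$ref_start[which(sub$op %in% c("M", "D"))[1L]]
    frag$cigar <- cigar_string(sub[, c("op", "len")])
    frag$seq <- paste(strsplit(read$seq, "", fixed = TRUE)[[1]][qidx], collapse = "")
    frag$qual <- int_to_qual(qual_to_int(read$qual)[qidx])
    out[[length(out) + 1L]] <- frag
  }
  dplyr::bind_rows(out)
}

#' Split intron-spanning records into exonic fragments
#'
#' Each maximal `N`-free CIGAR run becomes its own record, positioned after
#' the skipped introns; base qualities carry over unchanged (flank masking
#' is already encoded in them). Records without `N` pass through unchanged.
#' When a read yields several fragments they are renamed with `/1`, `/2`,
#' ... ordinal suffixes. Output records are flagged unpaired and forward.
#'
#' @param reads an alignment tibble (soft clips are stripped on entry).
#' @param config a [prep_config()] (unused; kept for pipeline symmetry).
#' @return an alignment tibble of fragments.
#' @export
split_introns <- function(reads, config = prep_config()) {
  reads <- strip_soft_clips(reads)
  out <- lapply(seq_len(nrow(reads)), function(i) {
    rename_fragments(split_read(reads[i, , drop = FALSE]))
  })
  dplyr::bind_rows(out)
}

#' Apply ordinal name suffixes when a parent emits several fragments.
#' @noRd
rename_fragments <- function(frags) {
  if (nrow(frags) > 1L) {
    frags$qname <- paste0(frags$qname, "/", seq_len(nrow(frags)))
  }
  frags
}
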