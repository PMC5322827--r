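# Brute-force oracle: re-applies the cleaning rules independently of the
# package implementation, at the level of per-reference-position base
# columns. CIGAR geometry comes from GenomicAlignments (the package's own
# code parses CIGARs itself), record handling is plain base R, and no
# output records are ever reconstructed — the oracle's answer is directly
# the multiset of non-zero-quality bases per reference position.

ora_qints <- function(q) utf8ToInt(q) - 33L

ora_clips <- function(cigar) {
  op <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  len <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  keep <- op != "H"
  op <- op[keep]; len <- len[keep]
  lead <- if (length(op) > 0 && op[1] == "S") len[1] else 0L
  trail <- if (length(op) > 1 && op[length(op)] == "S") len[length(op)] else 0L
  c(lead, trail)
}

ora_fp <- function(pos, cigar, rev) {
  cl <- ora_clips(cigar)
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  if (rev) pos + w - 1L + cl[2] else pos - cl[1]
}

# M columns of one record: reference position, stored query index, base,
# quality (query space includes soft-clipped bases, matching cycle order)
ora_mcols <- function(rec) {
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    rec$cigar, pos = rec$pos, ops = "M")[[1]]
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(rec$cigar, ops = "M")[[1]]
  rpos <- unlist(Map(seq.int, BiocGenerics::start(rr), BiocGenerics::end(rr)))
  qidx <- unlist(Map(seq.int, BiocGenerics::start(qr), BiocGenerics::end(qr)))
  data.frame(rname = rec$rname, rpos = as.integer(rpos),
             base = strsplit(rec$seq, "")[[1]][qidx],
             qual = ora_qints(rec$qual)[qidx],
             stringsAsFactors = FALSE)
}

ora_nints <- function(rec) {
  nr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    rec$cigar, pos = rec$pos, ops = "N")[[1]]
  if (length(nr) == 0) return(character(0))
  paste(BiocGenerics::start(nr), BiocGenerics::end(nr), sep = "-")
}

ora_mask <- function(m, cfg) {
  for (i in seq_len(nrow(m))) {
    if (cfg$soft_clips_exist && !grepl("S", m$cigar[i], fixed = TRUE)) next
    q <- ora_qints(m$qual[i])
    len <- length(q)
    s <- min(cfg$min_flank_start, len)
    e <- min(cfg$min_flank_end, len)
    if (bitwAnd(m$flag[i], 16L) != 0L) {
      if (s > 0) q[(len - s + 1):len] <- 0L
      if (e > 0) q[1:e] <- 0L
    } else {
      if (s > 0) q[1:s] <- 0L
      if (e > 0) q[(len - e + 1):len] <- 0L
    }
    m$qual[i] <- intToUtf8(q + 33L)
  }
  m
}

# pick a group's primary by quality sum and fold the others' bases into it
ora_sel_reconcile <- function(members) {
  sums <- vapply(members, function(m) sum(ora_qints(paste(m$qual, collapse = ""))),
                 numeric(1))
  minpos <- vapply(members, function(m) min(m$pos), integer(1))
  nms <- vapply(members, function(m) m$qname[1], character(1))
  pi <- order(-sums, minpos, nms)[1]
  prim <- members[[pi]]
  zeroed <- lapply(prim$seq, function(s) rep(FALSE, nchar(s)))
  for (m in members[-pi]) {
    if (nrow(m) != nrow(prim)) next
    for (i in seq_len(nrow(prim))) {
      if (m$pos[i] != prim$pos[i] || m$cigar[i] != prim$cigar[i] ||
          nchar(m$seq[i]) != nchar(prim$seq[i])) next
      pb <- strsplit(prim$seq[i], "")[[1]]
      sb <- strsplit(m$seq[i], "")[[1]]
      pq <- ora_qints(prim$qual[i])
      sq <- ora_qints(m$qual[i])
      for (j in which(pb != sb)) {
        if (zeroed[[i]][j]) next
        if (pq[j] < 10L || sq[j] < 10L) {
          if (sq[j] > pq[j]) { pb[j] <- sb[j]; pq[j] <- sq[j] }
        } else {
          pq[j] <- 0L
          zeroed[[i]][j] <- TRUE
        }
      }
      prim$seq[i] <- paste(pb, collapse = "")
      prim$qual[i] <- intToUtf8(pq + 33L)
    }
  }
  prim
}

# expected multiset of (contig, position, base, quality) with quality > 0
oracle_pileup <- function(reads, cfg) {
  df <- as.data.frame(reads, stringsAsFactors = FALSE)
  df$mapq[df$mapq == 255L] <- 50L
  keep <- bitwAnd(df$flag, 4L) == 0L & bitwAnd(df$flag, 256L) == 0L &
    bitwAnd(df$flag, 2048L) == 0L & df$mapq >= cfg$map_cutoff
  df <- df[keep, , drop = FALSE]
  paired <- df[bitwAnd(df$flag, 1L) != 0L, , drop = FALSE]
  singles <- df[bitwAnd(df$flag, 1L) == 0L, , drop = FALSE]
  pairs <- list()
  for (nm in unique(paired$qname)) {
    sub <- paired[paired$qname == nm, , drop = FALSE]
    if (nrow(sub) == 2L) {
      sub <- sub[order(bitwAnd(sub$flag, 64L) == 0L), , drop = FALSE]
      pairs[[length(pairs) + 1L]] <- sub
    } else {
      singles <- rbind(singles, sub)
    }
  }
  if (cfg$properly_paired) singles <- singles[0L, , drop = FALSE]
  ok <- vapply(pairs, function(p) {
    rev <- bitwAnd(p$flag, 16L) != 0L
    if (p$rname[1] != p$rname[2]) return(FALSE)
    if (rev[1] == rev[2]) return(FALSE)
    if (p$pos[which(rev)] < p$pos[which(!rev)]) return(FALSE)
    if (min(p$mapq) < cfg$map_cutoff) return(FALSE)
    if (cfg$properly_paired && !all(bitwAnd(p$flag, 2L) != 0L)) return(FALSE)
    TRUE
  }, logical(1))
  pairs <- pairs[ok]

  rev_of <- function(p) bitwAnd(p$flag, 16L) != 0L
  pkey <- vapply(pairs, function(p) {
    rev <- rev_of(p)
    fps <- mapply(ora_fp, p$pos, p$cigar, rev)
    paste(p$rname[1], fps[!rev], fps[rev], sep = "|")
  }, character(1))
  groups <- if (length(pairs) > 0) {
    split(seq_along(pairs), factor(pkey, levels = unique(pkey)))
  } else list()

  anchors <- character(0)
  for (g in groups) {
    p <- pairs[[g[1]]]
    rev <- rev_of(p)
    for (j in 1:2) {
      anchors <- c(anchors, paste(p$rname[j], ora_fp(p$pos[j], p$cigar[j], rev[j]),
                                  if (rev[j]) "-" else "+", sep = "|"))
    }
  }
  skey <- vapply(seq_len(nrow(singles)), function(i) {
    rv <- bitwAnd(singles$flag[i], 16L) != 0L
    paste(singles$rname[i], ora_fp(singles$pos[i], singles$cigar[i], rv),
          if (rv) "-" else "+", sep = "|")
  }, character(1))
  claimed <- skey %in% anchors
  singles <- singles[!claimed, , drop = FALSE]
  skey <- skey[!claimed]

  pile <- list()
  for (g in groups) {
    prim <- ora_sel_reconcile(pairs[g])
    prim <- ora_mask(prim, cfg)
    w <- GenomicAlignments::cigarWidthAlongReferenceSpace(prim$cigar)
    w1 <- max(prim$pos)
    w2 <- min(prim$pos + w - 1L)
    cf <- ora_mcols(prim[1L, ])
    cs <- ora_mcols(prim[2L, ])
    if (w1 > w2) {
      pile[[length(pile) + 1L]] <- rbind(cf, cs)
      next
    }
    clipw <- function(iv) {
      if (length(iv) == 0) return(character(0))
      se <- do.call(rbind, strsplit(iv, "-", fixed = TRUE))
      s <- pmax(as.integer(se[, 1]), w1)
      e <- pmin(as.integer(se[, 2]), w2)
      sort(paste(s, e, sep = "-")[s <= e])
    }
    if (!identical(clipw(ora_nints(prim[1L, ])), clipw(ora_nints(prim[2L, ])))) next
    shared <- merge(cf, cs, by = c("rname", "rpos"))
    if (any(shared$base.x != shared$base.y) && !cfg$keep_mismatches) next
    res <- shared[, c("rname", "rpos")]
    res$base <- NA_character_
    res$qual <- NA_integer_
    for (i in seq_len(nrow(shared))) {
      if (shared$base.x[i] == shared$base.y[i]) {
        res$base[i] <- shared$base.x[i]
        res$qual[i] <- max(shared$qual.x[i], shared$qual.y[i])
      } else if (shared$qual.x[i] < 10L || shared$qual.y[i] < 10L) {
        if (shared$qual.y[i] > shared$qual.x[i]) {
          res$base[i] <- shared$base.y[i]; res$qual[i] <- shared$qual.y[i]
        } else {
          res$base[i] <- shared$base.x[i]; res$qual[i] <- shared$qual.x[i]
        }
      } else {
        res$base[i] <- shared$base.x[i]; res$qual[i] <- 0L
      }
    }
    pile[[length(pile) + 1L]] <- res
    pile[[length(pile) + 1L]] <- cf[!cf$rpos %in% shared$rpos, , drop = FALSE]
    pile[[length(pile) + 1L]] <- cs[!cs$rpos %in% shared$rpos, , drop = FALSE]
  }
  if (nrow(singles) > 0) {
    for (k in unique(skey)) {
      rows <- which(skey == k)
      members <- lapply(rows, function(i) singles[i, , drop = FALSE])
      prim <- ora_sel_reconcile(members)
      prim <- ora_mask(prim, cfg)
      pile[[length(pile) + 1L]] <- ora_mcols(prim)
    }
  }
  out <- if (length(pile) > 0) do.call(rbind, pile) else
    data.frame(rname = character(), rpos = integer(), base = character(),
               qual = integer(), stringsAsFactors = FALSE)
  out <- out[out$qual > 0L, , drop = FALSE]
  out <- out[order(out$rname, out$rpos, out$base, out$qual), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# pileup of an output record set (same representation as the oracle's)
pipeline_pileup <- function(out) {
  if (nrow(out) == 0) {
    return(data.frame(rname = character(), rpos = integer(), base = character(),
                      qual = integer(), stringsAsFactors = FALSE))
  }
  cols <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
    ora_mcols(as.data.frame(out[i, , drop = FALSE]))
  }))
  cols <- cols[cols$qual > 0L, , drop = FALSE]
  cols <- cols[order(cols$rname, cols$rpos, cols$base, cols$qual), , drop = FALSE]
  rownames(cols) <- NULL
  cols
}
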