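# Duplicate handling. Duplicates are read pairs (or singles) sharing
# unclipped 5' coordinates and orientations. One primary is kept per group
# (highest total base quality) and the discarded copies vote on its bases:
# credible disagreements zero the primary's quality, low-quality
# disagreements are resolved towards the better base. This intentionally
# differs from conventional duplicate marking, which never edits the
# primary record.

#' Duplicate key of a pair or single
#'
#' For a pair: contig plus the unclipped 5' coordinates of the forward and
#' reverse mate. For a single read: contig, unclipped 5' coordinate and
#' strand.
#'
#' @param entity a one-row (single) or two-row (pair) alignment tibble.
#' @return a string key.
#' @export
duplicate_key <- function(entity) {
  fp <- five_prime(entity)
  if (nrow(entity) == 2L) {
    fwd <- which(fp$strand == "+")
    rev <- which(fp$strand == "-")
    stopifnot(length(fwd) == 1L, length(rev) == 1L)
    paste(fp$rname[fwd], fp$pos5[fwd], fp$pos5[rev], sep = "|")
  } else {
    paste(fp$rname, fp$pos5, fp$strand, sep = "|")
  }
}

#' Partition pairs and singles into duplicate groups
#'
#' Pairs sharing a key form a group. A single read whose (contig,
#' 5' coordinate, strand) coincides with either mate of a pair group joins
#' that group as a discardable member; remaining singles group among
#' themselves by their own key.
#'
#' @param pairs list of two-row alignment tibbles.
#' @param singles an alignment tibble.
#' @return a list of groups, each a list with elements `pairs` (list, may be
#'   empty), `singles` (tibble) and `mixed` (logical: singles ride along
#'   with a paired group).
#' @export
group_duplicates <- function(pairs, singles) {
  pair_keys <- vapply(pairs, duplicate_key, character(1))
  groups <- list()
  if (length(pairs) > 0L) {
    for (k in unique(pair_keys)) {
      groups[[k]] <- list(pairs = pairs[pair_keys == k],
                          singles = singles[0L, , drop = FALSE],
                          mixed = FALSE)
    }
  }
  single_claimed <- rep(FALSE, nrow(singles))
  if (nrow(singles) > 0L && length(pairs) > 0L) {
    # lookup: a pair group claims singles matching either mate's 5' anchor
    anchors <- new.env(parent = emptyenv())
    for (k in unique(pair_keys)) {
      p <- groups[[k]]$pairs[[1L]]
      fp <- five_prime(p)
      for (j in 1:2) {
        a <- paste(fp$rname[j], fp$pos5[j], fp$strand[j], sep = "|")
        assign(a, k, envir = anchors)
      }
    }
    skeys <- vapply(seq_len(nrow(singles)), function(i) {
      duplicate_key(singles[i, , drop = FALSE])
    }, character(1))
    for (i in seq_along(skeys)) {
      if (exists(skeys[i], envir = anchors)) {
        k <- get(skeys[i], envir = anchors)
        groups[[k]]$singles <- dplyr::bind_rows(groups[[k]]$singles,
                                                singles[i, , drop = FALSE])
        groups[[k]]$mixed <- TRUE
        single_claimed[i] <- TRUE
      }
    }
  }
  rest <- singles[!single_claimed, , drop = FALSE]
  if (nrow(rest) > 0L) {
    skeys <- vapply(seq_len(nrow(rest)), function(i) {
      duplicate_key(rest[i, , drop = FALSE])
    }, character(1))
    for (k in unique(skeys)) {
      groups[[paste0("s:", k)]] <- list(
        pairs = list(),
        singles = rest[skeys == k, , drop = FALSE],
        mixed = FALSE)
    }
  }
  unname(groups)
}

#' Select the primary member of a duplicate group
#'
#' Among paired members the pair with the highest total base-quality sum
#' over both mates wins; groups with no pairs pick the single read with the
#' highest quality sum. Ties break deterministically by leftmost position,
#' then read name.
#'
#' @param members a list of alignment tibbles (each one- or two-row).
#' @return the index of the primary member.
#' @export
select_primary <- function(members) {
  stopifnot(length(members) > 0L)
  sums <- vapply(members, entity_qual_sum, numeric(1))
  pos <- vapply(members, function(m) min(m$pos), integer(1))
  nm <- vapply(members, function(m) m$qname[1L], character(1))
  order(-sums, pos, nm)[1L]
}

#' Reconcile a discarded duplicate into the primary read
#'
#' Compared base by base where both reads have identical placement (same
#' position and CIGAR): where bases agree nothing changes; where they differ
#' and either base quality is below 10 the higher-quality base (and its
#' quality) is kept; where both qualities are at least 10 the primary's base
#' stays but its quality is set to 0, recording the disagreement. Positions
#' zeroed by an earlier conflict stay zeroed — a later duplicate cannot
#' resurrect a disputed base.
#'
#' @param primary,secondary one-row alignment tibbles with equal `pos` and
#'   `cigar` (otherwise the secondary contributes nothing and `primary` is
#'   returned unchanged).
#' @param zeroed optional logical vector marking positions already zeroed by
#'   conflict; used when folding several duplicates in sequence.
#' @return the updated primary (one-row tibble); the running `zeroed` vector
#'   is attached as attribute `"zeroed"`.
#' @export
reconcile_bases <- function(primary, secondary, zeroed = NULL) {
  stopifnot(nrow(primary) == 1L, nrow(secondary) == 1L)
  n <- nchar(primary$seq)
  if (is.null(zeroed)) zeroed <- rep(FALSE, n)
  if (primary$pos != secondary$pos || primary$cigar != secondary$cigar ||
      nchar(secondary$seq) != n) {
    attr(primary, "zeroed") <- zeroed
    return(primary)
  }
  pb <- strsplit(primary$seq, "", fixed = TRUE)[[1]]
  sb <- strsplit(secondary$seq, "", fixed = TRUE)[[1]]
  pq <- qual_to_int(primary$qual)
  sq <- qual_to_int(secondary$qual)
  for (i in which(pb != sb)) {
    if (zeroed[i]) next
    if (pq[i] < 10L || sq[i] < 10L) {
      if (sq[i] > pq[i]) {
        pb[i] <- sb[i]
        pq[i] <- sq[i]
      }
    } else {
      pq[i] <- 0L
      zeroed[i] <- TRUE
    }
  }
  primary$seq <- paste(pb, collapse = "")
  primary$qual <- int_to_qual(pq)
  primary$md <- NA_character_
  attr(primary, "zeroed") <- zeroed
  primary
}

#' Fold all discarded duplicates of a group into its primary entity.
#' Mates are compared first-vs-first and second-vs-second (for singles,
#' read-vs-read); members whose placement differs are skipped.
#' @noRd
reconcile_group <- function(primary, others) {
  if (length(others) == 0L) return(primary)
  k <- nrow(primary)
  zeroed <- lapply(seq_len(k), function(i) rep(FALSE, nchar(primary$seq[i])))
  for (o in others) {
    if (nrow(o) != k) next
    for (i in seq_len(k)) {
      upd <- reconcile_bases(primary[i, , drop = FALSE],
                             o[i, , drop = FALSE], zeroed[[i]])
      zeroed[[i]] <- attr(upd, "zeroed")
      attr(upd, "zeroed") <- NULL
      primary[i, ] <- upd
    }
  }
  primary
}

#' Deduplicate a QC-passed stream
#'
#' Groups pairs and singles by duplicate key, keeps one reconciled primary
#' per group and discards the rest. In mixed groups (singles sharing a
#' paired group's coordinates) the singles are discarded outright and do not
#' vote on the primary's bases.
#'
#' @param pairs list of two-row alignment tibbles (first-in-pair row first).
#' @param singles an alignment tibble.
#' @return list with deduplicated `pairs`, `singles` and `n_discarded`
#'   (records removed).
#' @export
dedup_reads <- function(pairs, singles) {
  n_in <- 2L * length(pairs) + nrow(singles)
  groups <- group_duplicates(pairs, singles)
  out_pairs <- list()
  out_singles <- singles[0L, , drop = FALSE]
  for (g in groups) {
    if (length(g$pairs) > 0L) {
      i <- select_primary(g$pairs)
      prim <- reconcile_group(g$pairs[[i]], g$pairs[-i])
      out_pairs[[length(out_pairs) + 1L]] <- prim
      # mixed-group singles are dropped without contributing bases
    } else {
      members <- lapply(seq_len(nrow(g$singles)), function(i) {
        g$singles[i, , drop = FALSE]
      })
      i <- select_primary(members)
      prim <- reconcile_group(members[[i]], members[-i])
      out_singles <- dplyr::bind_rows(out_singles, prim)
    }
  }
  n_kept <- 2L * length(out_pairs) + nrow(out_singles)
  list(pairs = out_pairs, singles = out_singles, n_discarded = n_in - n_kept)
}
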