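# Read- and pair-level quality control: MAPQ normalisation, removal of
# non-primary and low-quality records, and discard of geometrically
# discordant pairs.

#' Normalise the "mapping quality unavailable" sentinel
#'
#' Some splice-aware aligners emit MAPQ 255 (the SAM "not available"
#' sentinel) for uniquely mapped reads; such records are reassigned MAPQ 50
#' so they survive the default cutoff. All other values pass unchanged.
#'
#' @param reads an alignment tibble.
#' @return the tibble with `mapq == 255` replaced by 50.
#' @export
reassign_mapq <- function(reads) {
  reads$mapq[reads$mapq == 255L] <- 50L
  reads
}

#' Single-record quality control
#'
#' A record passes when it is mapped, primary (neither secondary nor
#' supplementary) and its mapping quality — after [reassign_mapq()] — is not
#' strictly below `map_cutoff`. Reads with MAPQ exactly at the cutoff pass.
#'
#' @param reads an alignment tibble.
#' @param config a [prep_config()].
#' @return logical vector, `TRUE` for records to keep.
#' @export
passes_single_qc <- function(reads, config = prep_config()) {
  mapq <- ifelse(reads$mapq == 255L, 50L, reads$mapq)
  !is_unmapped(reads$flag) &
    !is_secondary(reads$flag) &
    !is_supplementary(reads$flag) &
    mapq >= config$map_cutoff
}

#' Pair-level quality control
#'
#' A pair is discarded when the mates are on the same strand, point outwards
#' (the leftmost-aligned mate is on the reverse strand), map to different
#' contigs, when the lower of the two mapping qualities is below
#' `map_cutoff`, or — with `properly_paired = TRUE` — when either mate lacks
#' the proper-pair flag. Mates starting at the same position count as
#' inward-facing.
#'
#' @param pair a two-row alignment tibble (one pair).
#' @param config a [prep_config()].
#' @return `TRUE` when the pair is acceptable.
#' @export
passes_pair_qc <- function(pair, config = prep_config()) {
  stopifnot(nrow(pair) == 2L)
  if (pair$rname[1L] != pair$rname[2L]) return(FALSE)
  rev <- is_reverse(pair$flag)
  if (rev[1L] == rev[2L]) return(FALSE)
  if (pair$pos[which(rev)] < pair$pos[which(!rev)]) return(FALSE)
  mapq <- ifelse(pair$mapq == 255L, 50L, pair$mapq)
  if (min(mapq) < config$map_cutoff) return(FALSE)
  if (config$properly_paired && !all(is_proper(pair$flag))) return(FALSE)
  TRUE
}

#' Group a record stream into mate pairs and singles
#'
#' Mates are matched by read name among paired-flagged primaries. A name
#' seen more than twice signals malformed input and raises an error. Reads
#' without the paired flag, and paired reads whose mate never appears, are
#' returned as singles.
#'
#' @param reads an alignment tibble of QC-passed primaries.
#' @return a list with `pairs` (a list of two-row tibbles, first-in-pair
#'   row first) and `singles` (a tibble).
#' @export
collect_pairs <- function(reads) {
  paired <- reads[is_paired(reads$flag), , drop = FALSE]
  singles <- reads[!is_paired(reads$flag), , drop = FALSE]
  if (nrow(paired) == 0L) return(list(pairs = list(), singles = singles))
  cnt <- table(paired$qname)
  if (any(cnt > 2L)) {
    stop("more than two primary records share read name '",
         names(cnt)[cnt > 2L][1L], "'", call. = FALSE)
  }
  full <- names(cnt)[cnt == 2L]
  orphan <- paired[!paired$qname %in% full, , drop = FALSE]
  pairs <- list()
  if (length(full) > 0L) {
    both <- paired[paired$qname %in% full, , drop = FALSE]
    split_idx <- split(seq_len(nrow(both)), both$qname)
    # keep encounter order of pairs as they appear in the sorted stream
    first_seen <- vapply(split_idx, min, integer(1))
    split_idx <- split_idx[order(first_seen)]
    pairs <- lapply(split_idx, function(i) {
      p <- both[i, , drop = FALSE]
      p[order(!is_first_mate(p$flag)), , drop = FALSE]
    })
    names(pairs) <- NULL
  }
  list(pairs = pairs, singles = dplyr::bind_rows(singles, orphan))
}

#' Apply all QC stages to a record stream
#'
#' Runs [reassign_mapq()], drops records failing [passes_single_qc()],
#' collects mates, drops pairs failing [passes_pair_qc()], and — under
#' `properly_paired = TRUE` — discards reads whose mate is absent or
#' unmapped.
#'
#' @param reads an alignment tibble.
#' @param config a [prep_config()].
#' @return list with `pairs` (list of two-row tibbles), `singles` (tibble)
#'   and `n_discarded` (records removed).
#' @export
qc_filter <- function(reads, config = prep_config()) {
  n_in <- nrow(reads)
  reads <- reassign_mapq(reads)
  reads <- reads[passes_single_qc(reads, config), , drop = FALSE]
  pc <- collect_pairs(reads)
  ok <- vapply(pc$pairs, passes_pair_qc, logical(1), config = config)
  pairs <- pc$pairs[ok]
  singles <- if (config$properly_paired) {
    pc$singles[0L, , drop = FALSE]
  } else {
    pc$singles
  }
  n_kept <- 2L * length(pairs) + nrow(singles)
  list(pairs = pairs, singles = singles, n_discarded = n_in - n_kept)
}
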