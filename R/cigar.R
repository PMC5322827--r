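#' CIGAR algebra
#'
#' Small helpers for parsing and interrogating CIGAR strings. `=`/`X` are
#' folded into `M`; padding (`P`) is rejected as unsupported input (it does
#' not occur in splice-aware aligner output).
#'
#' @param cigar a single CIGAR string (e.g. `"30M100N46M"`).
#' @return `cigar_ops()` returns a tibble with columns `op` and `len`.
#' @keywords internal
cigar_ops <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L, !is.na(cigar))
  if (cigar == "*") {
    return(tibble::tibble(op = character(), len = integer()))
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (paste(toks, collapse = "") != cigar) {
    stop("malformed CIGAR string: ", cigar, call. = FALSE)
  }
  op <- substring(toks, nchar(toks), nchar(toks))
  len <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
  if (any(op == "P")) stop("padded (P) alignments are not supported", call. = FALSE)
  if (any(len < 1L)) stop("CIGAR operation of length 0: ", cigar, call. = FALSE)
  op[op %in% c("=", "X")] <- "M"
  tibble::tibble(op = op, len = len)
}

#' Collapse an op/len table back into a CIGAR string, merging adjacent runs
#' of the same operation.
#' @noRd
cigar_string <- function(ops) {
  if (nrow(ops) == 0L) return("*")
  keep_run <- c(TRUE, ops$op[-1L] != ops$op[-nrow(ops)])
  grp <- cumsum(keep_run)
  len <- as.integer(tapply(ops$len, grp, sum))
  op <- ops$op[keep_run]
  paste0(len, op, collapse = "")
}

ref_consumed <- function(ops) sum(ops$len[ops$op %in% c("M", "D", "N")])
query_consumed <- function(ops) sum(ops$len[ops$op %in% c("M", "I", "S")])

#' Leading/trailing soft-clip lengths (hard clips are transparent).
#' @noRd
clip_lengths <- function(cigar) {
  ops <- cigar_ops(cigar)
  core <- ops[ops$op != "H", , drop = FALSE]
  lead <- if (nrow(core) > 0L && core$op[1L] == "S") core$len[1L] else 0L
  trail <- if (nrow(core) > 1L && core$op[nrow(core)] == "S") core$len[nrow(core)] else 0L
  if (nrow(core) == 1L && core$op[1L] == "S") trail <- 0L
  c(lead = lead, trail = trail)
}

has_soft_clip <- function(cigar) grepl("S", cigar, fixed = TRUE)
has_intron <- function(cigar) grepl("N", cigar, fixed = TRUE)

#' Reference span of mapped alignments
#'
#' Total number of reference bases consumed by the `M`, `D` and `N`
#' operations of each record's CIGAR. Soft clips consume query only and do
#' not contribute.
#'
#' @param reads an alignment tibble (see [read_alignments()]).
#' @return integer vector, one span per record.
#' @export
#' @examples
#' r <- sim_scenario("spliced_pair")$reads
#' reference_span(r)
reference_span <- function(reads) {
  if (any(is_unmapped(reads$flag))) {
    stop("reference_span() is undefined for unmapped reads", call. = FALSE)
  }
  vapply(reads$cigar, function(cg) ref_consumed(cigar_ops(cg)), integer(1),
         USE.NAMES = FALSE)
}

#' Unclipped 5' coordinate of each alignment
#'
#' The sequencing-start position of the read on the reference, adjusted for
#' soft clipping: forward-strand reads start at `pos` minus the leading
#' soft-clip length; reverse-strand reads start at their unclipped right end
#' (`pos + reference_span - 1` plus the trailing soft-clip length). This is
#' the coordinate used in duplicate keys, so it is robust to aligners
#' trimming read ends differently.
#'
#' @param reads an alignment tibble.
#' @return a tibble with columns `rname`, `pos5` and `strand` (`"+"`/`"-"`).
#' @export
five_prime <- function(reads) {
  if (any(is_unmapped(reads$flag))) {
    stop("five_prime() is undefined for unmapped reads", call. = FALSE)
  }
  rev <- is_reverse(reads$flag)
  clips <- t(vapply(reads$cigar, clip_lengths, integer(2)))
  span <- reference_span(reads)
  pos5 <- ifelse(rev,
                 reads$pos + span - 1L + clips[, "trail"],
                 reads$pos - clips[, "lead"])
  tibble::tibble(rname = reads$rname,
                 pos5 = as.integer(pos5),
                 strand = ifelse(rev, "-", "+"))
}
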