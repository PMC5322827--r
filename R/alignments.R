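# Alignment records are rows of a tibble with the SAM fields:
#   qname, flag, rname, pos (1-based leftmost), mapq, cigar,
#   rnext, pnext, tlen, seq, qual (ASCII-33 encoded), md (MD tag or NA)
# Flag helpers interpret the standard SAM bits.

FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

flag_has <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L
is_paired <- function(flag) flag_has(flag, FLAG_PAIRED)
is_proper <- function(flag) flag_has(flag, FLAG_PROPER)
is_unmapped <- function(flag) flag_has(flag, FLAG_UNMAPPED)
is_reverse <- function(flag) flag_has(flag, FLAG_REVERSE)
is_first_mate <- function(flag) flag_has(flag, FLAG_FIRST)
is_secondary <- function(flag) flag_has(flag, FLAG_SECONDARY)
is_supplementary <- function(flag) flag_has(flag, FLAG_SUPPLEMENTARY)

#' Construct alignment records
#'
#' Builds a validated alignment tibble from parallel vectors. Mostly useful
#' for tests and for the bundled scenario generators; real data enters
#' through [read_alignments()].
#'
#' @param qname,flag,rname,pos,mapq,cigar,seq,qual core SAM fields; `qual`
#'   is the ASCII-33 encoded string, as in SAM text.
#' @param rnext,pnext,tlen mate locators; default to unset.
#' @param md optional MD tag values (`NA` when absent).
#' @return an alignment tibble.
#' @export
alignment_tibble <- function(qname, flag, rname, pos, mapq, cigar, seq, qual,
                             rnext = "*", pnext = 0L, tlen = 0L, md = NA_character_) {
  x <- tibble::tibble(
    qname = as.character(qname), flag = as.integer(flag),
    rname = as.character(rname), pos = as.integer(pos),
    mapq = as.integer(mapq), cigar = as.character(cigar),
    rnext = as.character(rnext), pnext = as.integer(pnext),
    tlen = as.integer(tlen), seq = as.character(seq),
    qual = as.character(qual), md = as.character(md)
  )
  validate_alignments(x)
  x
}

#' @noRd
validate_alignments <- function(x) {
  needed <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual", "md")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0L) {
    stop("alignment tibble is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0L) return(invisible(x))
  if (any(nchar(x$seq) != nchar(x$qual))) {
    stop("seq and qual lengths differ", call. = FALSE)
  }
  mapped <- !is_unmapped(x$flag)
  qlen <- vapply(x$cigar, function(cg) query_consumed(cigar_ops(cg)), integer(1),
                 USE.NAMES = FALSE)
  bad <- mapped & qlen != nchar(x$seq)
  if (any(bad)) {
    stop("query-consuming CIGAR length does not match seq for read(s): ",
         paste(utils::head(x$qname[bad], 3), collapse = ", "), call. = FALSE)
  }
  if (any(mapped & (is.na(x$pos) | x$pos < 1L))) {
    stop("mapped reads must have pos >= 1", call. = FALSE)
  }
  if (any(x$mapq < 0L | x$mapq > 255L)) {
    stop("mapq must be in [0, 255]", call. = FALSE)
  }
  invisible(x)
}

#' Read alignments from BAM or SAM
#'
#' Loads all records of a BAM (or plain-text SAM) file into an alignment
#' tibble, in file order, carrying the MD tag when present. The header's
#' contig table is attached as the `"contigs"` attribute (a named integer
#' vector of lengths) so that downstream writes preserve contig ordering.
#'
#' @param path path to a `.bam` or `.sam` file.
#' @return an alignment tibble with a `"contigs"` attribute.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  contigs <- hdr$targets
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize", "seq", "qual"),
    tag = "MD")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  md <- res$tag$MD
  if (is.null(md)) md <- rep(NA_character_, length(res$qname))
  x <- tibble::tibble(
    qname = res$qname,
    flag = as.integer(res$flag),
    rname = as.character(res$rname),
    pos = as.integer(res$pos),
    mapq = as.integer(res$mapq),
    cigar = ifelse(is.na(res$cigar), "*", res$cigar),
    rnext = ifelse(is.na(as.character(res$mrnm)), "*", as.character(res$mrnm)),
    pnext = ifelse(is.na(res$mpos), 0L, as.integer(res$mpos)),
    tlen = ifelse(is.na(res$isize), 0L, as.integer(res$isize)),
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    md = as.character(md)
  )
  x$mapq[is.na(x$mapq)] <- 255L
  attr(x, "contigs") <- contigs
  x
}

#' Write alignments to BAM or SAM
#'
#' Formats records as SAM text and, for `.bam` destinations, converts,
#' coordinate-sorts and indexes the result with htslib (via Rsamtools).
#'
#' @param reads an alignment tibble.
#' @param path destination ending in `.bam` or `.sam`.
#' @param contigs named integer vector of contig lengths (defaults to the
#'   tibble's `"contigs"` attribute).
#' @param pg optional character vector of extra `@PG` header lines.
#' @return the destination path, invisibly (`.bam` output is indexed).
#' @export
write_alignments <- function(reads, path, contigs = attr(reads, "contigs"),
                             pg = NULL) {
  if (is.null(contigs)) stop("contig table required to write alignments", call. = FALSE)
  reads <- sort_alignments(reads, contigs)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)),
           pg)
  body <- character(0)
  if (nrow(reads) > 0L) {
    opt <- ifelse(is.na(reads$md), "", paste0("\tMD:Z:", reads$md))
    body <- paste0(reads$qname, "\t", reads$flag, "\t", reads$rname, "\t",
                   reads$pos, "\t", reads$mapq, "\t", reads$cigar, "\t",
                   reads$rnext, "\t", reads$pnext, "\t", reads$tlen, "\t",
                   reads$seq, "\t", reads$qual, opt)
  }
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    sam <- tempfile(fileext = ".sam")
    on.exit(unlink(sam), add = TRUE)
    writeLines(c(hdr, body), sam)
    dest <- sub("\\.bam$", "", path, ignore.case = TRUE)
    out <- Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
    return(invisible(out))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Sort records by header contig order, then position.
#' @noRd
sort_alignments <- function(reads, contigs) {
  if (nrow(reads) == 0L) return(reads)
  key <- match(reads$rname, names(contigs))
  if (anyNA(key)) {
    stop("record(s) on contig absent from header: ",
         paste(unique(reads$rname[is.na(key)]), collapse = ", "), call. = FALSE)
  }
  out <- reads[order(key, reads$pos, reads$qname, reads$flag), , drop = FALSE]
  attr(out, "contigs") <- contigs
  out
}

#' Error if a record stream is not coordinate-sorted.
#' @noRd
assert_position_sorted <- function(reads) {
  if (nrow(reads) < 2L) return(invisible(TRUE))
  same <- reads$rname[-1L] == reads$rname[-nrow(reads)]
  regress <- same & diff(reads$pos) < 0L
  if (any(regress)) {
    i <- which(regress)[1L] + 1L
    stop("input is not position-sorted: record '", reads$qname[i], "' at ",
         reads$rname[i], ":", reads$pos[i], " follows position ",
         reads$pos[i - 1L], call. = FALSE)
  }
  invisible(TRUE)
}
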