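#' Pre-processing parameters
#'
#' Bundles the six user-facing parameters controlling the cleaning pipeline.
#'
#' @param soft_clips_exist logical; when `TRUE`, flank masking is applied
#'   only to reads whose CIGAR contains soft clips (aggressive aligners mark
#'   troubled read ends as soft clips, and those reads carry most of the
#'   end-of-read errors). Default `FALSE`: mask all reads.
#' @param properly_paired logical; when `TRUE` (default) only intact read
#'   pairs are processed and reads whose mate is absent or unmapped are
#'   discarded. When `FALSE`, such singles flow through deduplication and
#'   splitting (they are never overlap-merged).
#' @param map_cutoff integer in `[0, 254]`; minimum acceptable mapping
#'   quality for a read pair (strictly lower values are discarded). The
#'   default of 40 sits between the multi-mapper scores (0-3) and the
#'   unique-mapper scores (50) of the common splice-aware aligners.
#' @param keep_mismatches logical; when `FALSE` (default), overlapping mates
#'   that disagree at any overlap base are discarded as untrustworthy. When
#'   `TRUE` the overlap is reconciled base by base instead.
#' @param min_flank_start,min_flank_end non-negative integers; number of
#'   base qualities zeroed at the start / end of each read in sequencing
#'   order, to neutralise random-hexamer priming errors (start) and quality
#'   decay or adapter read-through (end). Defaults 0 (no masking). Use
#'   [mismatch_profile()] and [suggest_flanks()] to choose values.
#' @return a `prep_config` object (a named list).
#' @export
#' @examples
#' prep_config(map_cutoff = 40, min_flank_start = 3, min_flank_end = 3)
prep_config <- function(soft_clips_exist = FALSE, properly_paired = TRUE,
                        map_cutoff = 40L, keep_mismatches = FALSE,
                        min_flank_start = 0L, min_flank_end = 0L) {
  map_cutoff <- as.integer(map_cutoff)
  min_flank_start <- as.integer(min_flank_start)
  min_flank_end <- as.integer(min_flank_end)
  stopifnot(
    is.logical(soft_clips_exist), length(soft_clips_exist) == 1L,
    is.logical(properly_paired), length(properly_paired) == 1L,
    is.logical(keep_mismatches), length(keep_mismatches) == 1L,
    length(map_cutoff) == 1L, !is.na(map_cutoff),
    map_cutoff >= 0L, map_cutoff <= 254L,
    min_flank_start >= 0L, min_flank_end >= 0L
  )
  structure(
    list(soft_clips_exist = soft_clips_exist,
         properly_paired = properly_paired,
         map_cutoff = map_cutoff,
         keep_mismatches = keep_mismatches,
         min_flank_start = min_flank_start,
         min_flank_end = min_flank_end),
    class = "prep_config"
  )
}

#' @export
print.prep_config <- function(x, ...) {
  cat("<prep_config>\n")
  for (nm in names(x)) cat("  ", nm, " = ", x[[nm]], "\n", sep = "")
  invisible(x)
}
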