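# Pipeline orchestration: QC -> deduplication -> flank masking -> overlap
# merging -> intron splitting, then coordinate sorting.

#' Clean a stream of alignment records
#'
#' Runs the full pre-processing pipeline on an alignment tibble and returns
#' the cleaned records: QC filtering ([qc_filter()]), duplicate collapsing
#' ([dedup_reads()]), flank masking on the original reads ([mask_flanks()]),
#' overlap merging ([merge_pair()]) and intron splitting. Every output
#' record is unpaired, forward-strand, splice-free and clip-free.
#'
#' @param reads an alignment tibble (see [read_alignments()]).
#' @param config a [prep_config()].
#' @param contigs optional named integer vector of contig lengths used for
#'   output ordering; defaults to the tibble's `"contigs"` attribute.
#' @return an alignment tibble of cleaned records, coordinate-sorted, with
#'   per-stage counters attached as attribute `"stats"` (a one-row tibble:
#'   `n_input`, `n_qc_discarded`, `n_duplicate_discarded`,
#'   `n_merge_discarded`, `n_output`).
#' @export
#' @examples
#' sc <- sim_scenario("overlap_agree")
#' out <- prep_reads(sc$reads, sc$config)
#' attr(out, "stats")
prep_reads <- function(reads, config = prep_config(),
                       contigs = attr(reads, "contigs")) {
  validate_alignments(reads)
  n_input <- nrow(reads)
  qc <- qc_filter(reads, config)
  dd <- dedup_reads(qc$pairs, qc$singles)
  pairs <- lapply(dd$pairs, mask_flanks, config = config)
  singles <- mask_flanks(dd$singles, config)
  out <- list()
  n_merge_discarded <- 0L
  for (p in pairs) {
    frags <- merge_pair(p, config)
    if (nrow(frags) == 0L) {
      n_merge_discarded <- n_merge_discarded + 2L
    } else {
      out[[length(out) + 1L]] <- rename_fragments(frags)
    }
  }
  for (i in seq_len(nrow(singles))) {
    single <- strip_soft_clips(singles[i, , drop = FALSE])
    out[[length(out) + 1L]] <- rename_fragments(split_read(single))
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) out <- reads[0L, , drop = FALSE]
  if (!is.null(contigs)) {
    out <- sort_alignments(out, contigs)
  } else {
    out <- out[order(out$rname, out$pos, out$qname), , drop = FALSE]
  }
  attr(out, "contigs") <- contigs
  attr(out, "stats") <- tibble::tibble(
    n_input = n_input,
    n_qc_discarded = qc$n_discarded,
    n_duplicate_discarded = dd$n_discarded,
    n_merge_discarded = n_merge_discarded,
    n_output = nrow(out))
  out
}

#' Pre-process a BAM file for SNP calling
#'
#' File-level front end to [prep_reads()]: reads a position-sorted BAM (or
#' SAM), refuses unsorted input, runs the cleaning pipeline and writes a
#' coordinate-sorted, indexed BAM ready for a haplotype-based variant
#' caller. A `@PG` header line documents the parameters used.
#'
#' @param input path to a position-sorted BAM/SAM file.
#' @param output path for the output BAM (`.bam`).
#' @param config a [prep_config()].
#' @return a `prep_run` object: list with `input`, `output`, `config`,
#'   `reads` (the cleaned records) and `stats` (per-stage counters).
#' @export
prep_bam <- function(input, output, config = prep_config()) {
  reads <- read_alignments(input)
  assert_position_sorted(reads)
  out <- prep_reads(reads, config)
  pg <- sprintf(
    "@PG\tID:rnaprep\tPN:rnaprep\tVN:%s\tCL:soft_clips_exist=%s properly_paired=%s map_cutoff=%d keep_mismatches=%s min_flank_start=%d min_flank_end=%d",
    as.character(utils::packageVersion("rnaprep")),
    config$soft_clips_exist, config$properly_paired, config$map_cutoff,
    config$keep_mismatches, config$min_flank_start, config$min_flank_end)
  write_alignments(out, output, contigs = attr(reads, "contigs"), pg = pg)
  structure(list(input = input, output = output, config = config,
                 reads = out, stats = attr(out, "stats")),
            class = "prep_run")
}

#' @export
print.prep_run <- function(x, ...) {
  s <- x$stats
  cat("<prep_run> ", x$input, " -> ", x$output, "\n", sep = "")
  cat(sprintf("  records in:          %d\n", s$n_input))
  cat(sprintf("  QC discarded:        %d\n", s$n_qc_discarded))
  cat(sprintf("  duplicate discarded: %d\n", s$n_duplicate_discarded))
  cat(sprintf("  merge discarded:     %d\n", s$n_merge_discarded))
  cat(sprintf("  fragments out:       %d\n", s$n_output))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Per-stage counters of a pipeline run
#'
#' @param x a `prep_run` from [prep_bam()].
#' @param ... unused.
#' @return a one-row tibble of stage counters.
#' @method glance prep_run
#' @export
glance.prep_run <- function(x, ...) x$stats

#' Cleaned records of a pipeline run as a tibble
#'
#' @param x a `prep_run` from [prep_bam()].
#' @param ... unused.
#' @return the cleaned alignment tibble.
#' @method tidy prep_run
#' @export
tidy.prep_run <- function(x, ...) tibble::as_tibble(x$reads)

#' Mismatch profile as a plain tibble
#'
#' @param x a [mismatch_profile()].
#' @param ... unused.
#' @return a tibble with columns `side`, `position`, `n`, `mismatches`,
#'   `rate`.
#' @method tidy mismatch_profile
#' @export
tidy.mismatch_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("side", "position", "n", "mismatches", "rate")])
}

#' One-row summary of a mismatch profile
#'
#' @param x a [mismatch_profile()].
#' @param ... unused.
#' @return a one-row tibble with the profiled range, scope, total base
#'   count and the overall mismatch rate.
#' @method glance mismatch_profile
#' @export
glance.mismatch_profile <- function(x, ...) {
  tibble::tibble(k = attr(x, "k"), scope = attr(x, "scope"),
                 n_bases = sum(x$n), mismatch_rate = sum(x$mismatches) / sum(x$n))
}

#' Plot a per-cycle mismatch profile
#'
#' Bar chart of mismatch rate per cycle position, one panel per read end,
#' with an optional threshold line.
#'
#' @param object a [mismatch_profile()].
#' @param threshold optional mismatch-rate threshold drawn as a dashed line.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mismatch_profile
#' @export
autoplot.mismatch_profile <- function(object, threshold = NULL, ...) {
  df <- tidy(object)
  df$side <- factor(df$side, levels = c("start", "end"),
                    labels = c("from read start", "from read end"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position), y = .data$rate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(x = "cycle position from read end", y = "mismatch rate") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Plot per-stage record counts of a pipeline run
#'
#' @param object a `prep_run` from [prep_bam()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot prep_run
#' @export
autoplot.prep_run <- function(object, ...) {
  s <- object$stats
  df <- tibble::tibble(
    stage = factor(c("input", "QC discarded", "duplicate discarded",
                     "merge discarded", "output"),
                   levels = c("input", "QC discarded", "duplicate discarded",
                              "merge discarded", "output")),
    records = c(s$n_input, s$n_qc_discarded, s$n_duplicate_discarded,
                s$n_merge_discarded, s$n_output))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$records)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "records") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
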