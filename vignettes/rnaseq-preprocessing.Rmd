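---
title: "Cleaning spliced RNA-seq alignments for SNP calling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning spliced RNA-seq alignments for SNP calling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaprep)
```

## Why RNA-seq alignments need cleaning before variant calling

Haplotype-driven SNP callers reconstruct local haplotypes by assembling the
reads covering a window of at most a few kilobases. An RNA-seq read aligned
across a large intron (an `N` operation in its CIGAR) spans far more
reference than it contains sequence, which disrupts that assembly; spliced
alignments therefore cannot be fed to such callers directly. Splitting every
read at its introns, however, destroys two kinds of information that callers
normally recover from intact reads: which fragments came from one sequencing
read (so per-read end-masking would be applied to the wrong bases), and
whether the two mates of a pair overlapped (so the same molecule would be
counted twice in a pileup).

rnaprep resolves this by *encoding all per-read information into base
qualities before splitting*. The pipeline runs, in order:

1. **Quality control** (`qc_filter()`). MAPQ 255 — the SAM sentinel for
   "unavailable", used by some aligners for uniquely mapped reads — is
   reassigned to 50; unmapped, secondary and supplementary records are
   dropped; reads below the MAPQ cutoff are dropped; pairs whose mates are
   on the same strand, point outwards, or map to different contigs are
   dropped; with `properly_paired = TRUE` (the default) reads whose mate is
   absent or unmapped are dropped too.
2. **Duplicate collapsing** (`dedup_reads()`). Duplicates are pairs sharing
   unclipped 5' coordinates and orientations. The pair with the highest
   total base-quality sum is kept, and each discarded copy votes on its
   bases: where copies disagree and either base quality is below 10 the
   higher-quality base is substituted; where both are credible (>= 10) the
   kept base's quality is set to 0, recording the conflict. This
   deliberately differs from conventional duplicate marking, which never
   edits the retained record.
3. **Flank masking** (`mask_flanks()`). The first `min_flank_start` and last
   `min_flank_end` base qualities of each read, in sequencing order, are
   set to 0. This neutralises the elevated error rates at read starts
   (random-hexamer mispriming during first-strand cDNA synthesis) and read
   ends (quality decay, adapter read-through). Because masking runs before
   merging and splitting, it applies to the *original* read ends, which is
   the whole point of the stage ordering.
4. **Overlap merging** (`merge_pair()`). The mates' aligned intervals are
   intersected; agreeing overlap bases keep the higher quality, and
   disagreements either discard the pair (`keep_mismatches = FALSE`,
   default) or are resolved by the same quality-10 rule as deduplication.
   Mates implying different exon structure inside the overlap are discarded
   as untrustworthy mappings.
5. **Intron splitting** (`split_introns()`). Every maximal `N`-free CIGAR
   run becomes its own record; soft-clipped bases are removed; all outputs
   are flagged unpaired and forward-strand.

The result is a coordinate-sorted, indexed BAM whose records contain no
`N` operations, no pairing structure, and base qualities that already
express masking, duplicate conflicts and overlap reconciliation — a caller
can be run on it with minimal settings and no further recalibration.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `map_cutoff` | 40 | minimum MAPQ for a read pair (the lower mate counts); reads *strictly below* the cutoff are dropped. 40 sits between multi-mapper scores (0–3) and unique-mapper scores (50) of the common splice-aware aligners, so any value from 4 to 49 behaves identically there. |
| `properly_paired` | `TRUE` | process intact pairs only; when `FALSE`, orphans and unpaired reads flow through deduplication and splitting (never merging). |
| `keep_mismatches` | `FALSE` | keep overlapping mates that disagree in the overlap, resolving base by base; the default discards such pairs. |
| `min_flank_start`, `min_flank_end` | 0 | bases masked at each read end, in sequencing order (for a reverse-strand alignment the "start" is the rightmost stored base). |
| `soft_clips_exist` | `FALSE` | when `TRUE`, flank masking is restricted to reads whose CIGAR contains soft clips — aggressive aligners clip troubled read ends, and those reads carry most of the end errors. |

### Choosing the flank widths

`mismatch_profile()` measures, for cycles 1..k from each read end, the
fraction of aligned bases disagreeing with the reference (from MD tags, or
from a reference FASTA when tags are absent). Soft-clipped and inserted
bases have no reference base and are excluded, but clipped bases still
count toward cycle numbering, so the cycles are true sequencing cycles.
`suggest_flanks()` returns, per side, the first cycle at which the rate
falls below the chosen threshold — masking up to and including the first
acceptable cycle, which reproduces the conventional reading of the
worked example (rates of 2%, 1.5%, 0.75%, 0.5% against a 1% threshold
suggest a flank of 3). If cycle 1 is already below the threshold, 0 is
returned: that boundary case is a design choice here, since masking a
cycle that is already acceptable serves no purpose. If the rate never
falls below the threshold within `k` cycles, `k` is returned with a
warning. By default only first-in-pair reads are profiled — the first
strand carries the hexamer-priming errors — and the resulting widths are
conventionally applied to all reads; profile `scope = "second"` to check
that the second strand is compatible.

```{r profile}
fx <- sim_profile_fixture(seed = 1)
prof <- mismatch_profile(fx$reads, k = 4)
tidy(prof)
suggest_flanks(prof, threshold = 0.01)
```

## Numerical and representational choices

Several behaviours are genuinely underdetermined by the method's verbal
description; the package fixes them as follows, and the test suite pins
each one.

* **Coordinates** are 1-based inclusive throughout, the R/Bioconductor
  convention; SAM text is itself 1-based, so no conversion ever happens.
* **Duplicate keys use unclipped 5' coordinates** (position adjusted by
  soft-clip lengths). Whether the key should be clipped or unclipped is not
  specified anywhere; the unclipped choice matches standard
  duplicate-marking practice and makes the key robust to aligners clipping
  the same physical read differently.
* **Quality exactly 10** goes to the zeroing branch in both reconciliation
  and merging ("below 10" is strict). A conflicting base of quality 10 is
  treated as credible-but-disputed rather than as noise, the conservative
  reading: conflicting credible bases should not vote.
* **Ties in primary selection** (equal quality sums) break by leftmost
  position, then read name — determinism across runs and platforms.
* **Zeroed stays zeroed.** Duplicate copies are folded into the primary one
  at a time in input order; once a position has been zeroed by a credible
  conflict, later copies cannot re-substitute a base there (quality 0 would
  otherwise re-trigger the low-quality branch and resurrect a disputed
  base).
* **Copies with different placement** (position or CIGAR differing from the
  primary's) contribute no base votes: per-base correspondence would be
  ill-defined. They are still discarded as duplicates.
* **Merged-record bookkeeping**: the merged read takes the pair's name, the
  *minimum* of the two MAPQs (consistent with the pair-level cutoff
  reading), and on a credible overlap conflict under
  `keep_mismatches = TRUE` the first-in-pair base is written with quality
  0 (mirroring deduplication, where the primary's base is kept).
  Non-overlapping mates are emitted as two unpaired fragments rather than
  one record with an invented reference gap.
* **Indels at stage boundaries**: an insertion adjacent to an intron
  attaches to the preceding exonic fragment; deletions at a fragment edge
  are trimmed (a record cannot begin or end in `D`); insertions inside the
  mate overlap are taken from the first-in-pair mate only — indel-aware
  merging is out of scope, and inserted bases carry no reference position.
* **Fragment naming**: when a read or pair emits several fragments they are
  renamed `name/1`, `name/2`, ... so downstream tools see unique names and
  the parent remains recoverable by prefix; a single emitted record keeps
  its original name.
* **Degenerate masking** (`min_flank_start + min_flank_end` >= read length)
  zeroes every quality but keeps the read.
* **Hard clips** are ignored; padding (`P`) operations are rejected as
  unsupported input; `=`/`X` are folded into `M`. CRAM is not supported.

## What the synthetic fixtures emulate — and what they do not

The package ships no external data. `sim_reference()` builds deterministic
pseudo-random contigs; `sim_scenario()` builds ten small position-sorted
record sets, each exercising one rule (duplicate clusters, agreeing and
disagreeing overlaps, spliced pairs, discordant orientations, cross-contig
pairs, soft clips, MAPQ 255, single-vs-pair duplicates, exon-inconsistent
overlaps), together with hand-derived expected outputs;
`sim_random_input()` draws randomized mixtures of all of the above; and
`sim_profile_fixture()` plants exact per-cycle mismatch counts (the
defaults place rates at 2%, 1.5%, 0.75% and 0.5% across cycles 1–4 from
both ends, crossing a 1% threshold at cycle 3).

These fixtures emulate the *rules*, not the sequencing process: there is no
realistic error model, no quality–error correlation, no fragment-size
distribution, no expression structure, and reads are short and few. Passing
tests therefore demonstrate that the record-level transformations are
applied exactly as specified, at pileup level, against an independently
coded brute-force oracle — they do not demonstrate downstream precision or
sensitivity of any variant caller on real data, which depends on aligner
behaviour and coverage structure outside this package's control.

Problem sizes used by the test suite: ten golden scenarios of at most 40
records each, 200 randomized record sets (each also at most 40 records)
compared against the brute-force oracle, and a 400-read profiler fixture.

## Known limitations

* The whole input is held in memory as a tibble; this is a desk-scale
  design. The record-level functions are pure and could be driven
  region-by-region for large files, but no streaming driver is provided.
* Indels are carried through deterministically but not reconciled across
  mates; callers should not take merged-read indels as evidence.
* After splitting, two fragments of *different* parents can legitimately
  share a start coordinate; uniqueness of duplicate keys is guaranteed for
  the entities emitted by deduplication, not for post-split fragments.
  (Re-running the pipeline on its own output will collapse such fragment
  pairs; on inputs where no such collision exists — including all bundled
  scenarios — a re-run is an exact fixed point.)
* Pre-set duplicate flags (0x400) from upstream tools are ignored: the
  package performs its own deduplication.
* RNA-editing sites are not excluded; downstream evaluation against DNA
  truth sets should handle them separately.

## A complete run

```{r pipeline}
sc <- sim_scenario("spliced_pair")
out <- prep_reads(sc$reads, sc$config)
attr(out, "stats")
out[, c("qname", "rname", "pos", "mapq", "cigar")]
```

The spliced first mate (`30M100N46M`) and its overlapping unspliced mate
merge into a single forward-strand observation and split at the intron:
fragment `/1` is the first exon, fragment `/2` covers the second exon plus
the mate's exclusive tail, with the overlap counted once at the higher of
the two qualities.
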