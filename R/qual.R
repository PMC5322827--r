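# Phred base-quality helpers. Qualities are stored SAM-encoded (ASCII-33)
# alongside seq so that per-record strings stay parallel.

qual_to_int <- function(q) {
  if (is.na(q) || q == "*") return(integer())
  utf8ToInt(q) - 33L
}

int_to_qual <- function(x) {
  if (length(x) == 0L) return("*")
  intToUtf8(x + 33L)
}

qual_sum <- function(q) sum(qual_to_int(q))

# Sum of base qualities over all records of an entity (pair or single).
entity_qual_sum <- function(reads) sum(vapply(reads$qual, qual_sum, numeric(1)))
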