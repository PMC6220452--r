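# Small GenomicRanges shims: the annotation tables are plain
# data.frames (1-based inclusive), converted on demand for overlap
# queries.

as_granges <- function(df, start = df$start, end = df$end) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(start, end))
}

overlaps_any_feature <- function(query, subject) {
  IRanges::overlapsAny(as_granges(query), as_granges(subject))
}
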