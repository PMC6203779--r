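# Shared fixtures: tiny in-memory tracks, temp BED/bedGraph writers, and
# brute-force per-base interval oracles used across the suite.

make_gr <- function(chrom, start, end, strand = "*", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand, ...)
}

# build a tss_track from data.frames (chrom, pos, count)
make_track <- function(plus = NULL, minus = NULL) {
  empty <- data.frame(chrom = character(), pos = integer(), count = numeric())
  divtx:::new_tss_track(divtx:::.track_side(if (is.null(plus)) empty else plus),
                        divtx:::.track_side(if (is.null(minus)) empty else minus))
}

write_tmp <- function(lines, ext = ".bed") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# brute-force base-set oracle: the set of 1-based positions covered by a
# GRanges on one chromosome
base_set <- function(gr, chrom) {
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  if (length(gr) == 0L) return(integer(0))
  sort(unique(unlist(mapply(seq, GenomicRanges::start(gr),
                            GenomicRanges::end(gr), SIMPLIFY = FALSE))))
}

random_dna <- function(n, gc = 0.4) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}
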