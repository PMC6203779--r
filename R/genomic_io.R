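# Readers/writers for BED and stranded bedGraph, interval algebra, and peak
# annotation. In-memory coordinates follow the Bioconductor convention
# (GRanges, 1-based inclusive); all files on disk follow the BED convention
# (0-based half-open). Conversion happens only at the I/O boundary.

#' Annotation configuration
#'
#' Distance and extension parameters used when annotating NDR peaks against
#' transcript starts. Species presets follow common usage for compact vs.
#' large genomes: promoters are called within +/-200 bp of a transcript start
#' for human, +/-400 bp for fly, +/-500 bp for worm.
#'
#' @param promoter_distance Maximum distance (bp) between a peak and a
#'   transcript start for the peak to be annotated as that gene's promoter.
#' @param extension Number of bp by which peaks are extended on each side
#'   before merging (so that narrow peak calls do not truncate TSS signal).
#' @param species Optional preset: one of \code{"human"}, \code{"fly"},
#'   \code{"worm"}. Overrides \code{promoter_distance} and also carries the
#'   background quantile used by \code{\link{estimate_cutoff}}.
#' @return A list with class \code{"annotation_config"}.
#' @export
annotation_config <- function(promoter_distance = 200L, extension = 75L,
                              species = NULL) {
  quantile <- 0.999
  if (!is.null(species)) {
    species <- match.arg(species, c("human", "fly", "worm"))
    promoter_distance <- switch(species, human = 200L, fly = 400L, worm = 500L)
    quantile <- switch(species, human = 0.9999, fly = 0.999, worm = 0.999)
  }
  if (promoter_distance <= 0) stop("promoter_distance must be > 0")
  if (extension < 0) stop("extension must be >= 0")
  structure(list(promoter_distance = as.integer(promoter_distance),
                 extension = as.integer(extension),
                 quantile = quantile, species = species),
            class = "annotation_config")
}

#' Read a BED3/BED6 file into a GRanges
#'
#' Tab-separated BED with 0-based half-open coordinates. Lines with
#' \code{start >= end} or non-numeric coordinates abort with an error naming
#' the offending line number.
#'
#' @param path Path to a BED file.
#' @return A \code{GRanges} sorted by (chrom, start), with metadata columns
#'   \code{name} and \code{score} when present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad)) {
    stop(sprintf("%s: line %d has %d fields; BED needs at least 3",
                 path, bad[1], nf[bad[1]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | !nzchar(chrom))
  if (length(bad)) {
    stop(sprintf("%s: line %d: malformed coordinates", path, bad[1]))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop(sprintf("%s: line %d: start >= end (%d >= %d)", path, bad[1],
                 as.integer(start[bad[1]]), as.integer(end[bad[1]])))
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), ".")
  score <- ifelse(nf >= 5L,
                  suppressWarnings(as.numeric(vapply(fields, function(f) f[min(5L, length(f))], ""))),
                  0)
  score[is.na(score)] <- 0
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], "."), ".")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start + 1L, end = end),
                               strand = strand, name = name, score = score)
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges as BED
#'
#' @param gr A \code{GRanges}; metadata columns \code{name} and \code{score}
#'   are used when present.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  name <- if (!is.null(gr$name)) as.character(gr$name) else rep(".", n)
  score <- if (!is.null(gr$score)) gr$score else rep(0, n)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = name, score = score, strand = strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extend peaks and merge overlaps
#'
#' Drops peaks narrower than \code{min_width}, extends the rest by
#' \code{extension} bp on each side (clamped at position 1), and merges any
#' intervals that then overlap or abut.
#'
#' @param peaks A \code{GRanges} of peak calls.
#' @param extension Extension in bp on each side (default 75).
#' @param min_width Minimum input peak width in bp; narrower peaks are
#'   discarded before extension (default 50).
#' @return A sorted, disjoint \code{GRanges}.
#' @export
extend_and_merge <- function(peaks, extension = 75L, min_width = 50L) {
  if (extension < 0) stop("extension must be >= 0")
  peaks <- peaks[GenomicRanges::width(peaks) >= min_width]
  if (length(peaks) == 0L) return(GenomicRanges::granges(peaks))
  ext <- GenomicRanges::granges(peaks)
  GenomicRanges::start(ext) <- pmax(1L, GenomicRanges::start(ext) - as.integer(extension))
  GenomicRanges::end(ext) <- GenomicRanges::end(ext) + as.integer(extension)
  merged <- GenomicRanges::reduce(GenomeInfoDb::sortSeqlevels(ext),
                                  ignore.strand = TRUE)
  GenomicRanges::sort(merged, ignore.strand = TRUE)
}

#' Annotate peaks as promoter / intergenic / other
#'
#' A peak is a promoter when it lies within \code{promoter_distance} bp of a
#' transcript start on exactly one strand (the gene strand is recorded); a
#' peak within that distance of starts on both strands is flagged
#' \code{bidirectional-removed} and excluded from downstream directional
#' analyses. Peaks touching no transcript start are \code{intergenic} when
#' they do not intersect any transcript body, otherwise \code{other}.
#'
#' @param peaks A \code{GRanges} of (extended, merged) peaks.
#' @param tss A \code{GRanges} of width-1 transcript starts with strand, or a
#'   data.frame with columns \code{chrom}, \code{pos} (1-based), \code{strand}.
#' @param genes Optional \code{GRanges} of transcript bodies (start-end
#'   spans) used to distinguish intergenic from genic non-promoter peaks.
#' @param config An \code{\link{annotation_config}}.
#' @return \code{peaks} with metadata columns \code{annotation} (one of
#'   \code{promoter}, \code{intergenic}, \code{other},
#'   \code{bidirectional-removed}) and \code{gene_strand} (\code{NA} unless
#'   promoter).
#' @export
annotate_peaks <- function(peaks, tss, genes = NULL,
                           config = annotation_config()) {
  if (is.data.frame(tss)) {
    tss <- GenomicRanges::GRanges(tss$chrom,
                                  IRanges::IRanges(tss$pos, tss$pos),
                                  strand = tss$strand)
  }
  d <- config$promoter_distance
  win <- GenomicRanges::granges(tss)
  GenomicRanges::start(win) <- pmax(1L, GenomicRanges::start(win) - d)
  GenomicRanges::end(win) <- GenomicRanges::end(win) + d
  tss_strand <- as.character(BiocGenerics::strand(tss))
  hit_plus <- IRanges::overlapsAny(peaks, win[tss_strand == "+"],
                                   ignore.strand = TRUE)
  hit_minus <- IRanges::overlapsAny(peaks, win[tss_strand == "-"],
                                    ignore.strand = TRUE)
  ann <- rep("intergenic", length(peaks))
  gene_strand <- rep(NA_character_, length(peaks))
  ann[hit_plus & !hit_minus] <- "promoter"
  gene_strand[hit_plus & !hit_minus] <- "+"
  ann[hit_minus & !hit_plus] <- "promoter"
  gene_strand[hit_minus & !hit_plus] <- "-"
  ann[hit_plus & hit_minus] <- "bidirectional-removed"
  if (!is.null(genes) && length(genes)) {
    genic <- IRanges::overlapsAny(peaks, genes, ignore.strand = TRUE)
    ann[ann == "intergenic" & genic] <- "other"
  }
  peaks$annotation <- ann
  peaks$gene_strand <- gene_strand
  peaks
}

# ---- stranded per-base 5'-end track ----------------------------------------

new_tss_track <- function(plus, minus) {
  structure(list(plus = plus, minus = minus), class = "tss_track")
}

# df: chrom, pos (1-based), count -> named per-chrom list of sorted vectors
.track_side <- function(df) {
  if (nrow(df) == 0L) return(structure(list(), names = character()))
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  lapply(split(df[c("pos", "count")], df$chrom),
         function(d) list(pos = as.integer(d$pos), count = as.numeric(d$count)))
}

.parse_bedgraph_side <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), count = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad)) stop(sprintf("%s: line %d: bedGraph needs 4 fields", path, bad[1]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  val <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(val) | start >= end)
  if (length(bad)) stop(sprintf("%s: line %d: malformed bedGraph record", path, bad[1]))
  if (any(val < 0)) {
    stop(sprintf("%s: line %d: negative count", path, which(val < 0)[1]))
  }
  # expand multi-base runs to per-base records (1-based positions)
  w <- end - start
  pos <- sequence(w, from = start + 1L)
  data.frame(chrom = rep(chrom, w), pos = pos, count = rep(val, w))
}

#' Read stranded per-base 5'-end counts from a pair of bedGraph files
#'
#' One bedGraph per strand, integer counts of nascent-RNA read 5' ends per
#' base. Runs spanning several bases are expanded; two records covering the
#' same base on the same strand are rejected as ill-formed.
#'
#' @param path_plus,path_minus bedGraph files for the + and - strand.
#' @return A \code{tss_track}: sparse per-chromosome position/count maps for
#'   each strand (positions 1-based).
#' @export
read_stranded_bedgraph <- function(path_plus, path_minus) {
  plus <- .parse_bedgraph_side(path_plus)
  minus <- .parse_bedgraph_side(path_minus)
  for (side in list(c("plus", path_plus), c("minus", path_minus))) {
    df <- if (side[1] == "plus") plus else minus
    if (anyDuplicated(df[c("chrom", "pos")])) {
      stop(sprintf("%s: overlapping bedGraph records on the same strand", side[2]))
    }
  }
  plus <- plus[plus$count > 0, , drop = FALSE]
  minus <- minus[minus$count > 0, , drop = FALSE]
  new_tss_track(.track_side(plus), .track_side(minus))
}

#' Write a tss_track as a pair of per-base bedGraph files
#'
#' @param track A \code{tss_track}.
#' @param path_plus,path_minus Output paths.
#' @export
write_stranded_bedgraph <- function(track, path_plus, path_minus) {
  emit <- function(side, path) {
    rows <- lapply(names(side), function(chrom) {
      d <- side[[chrom]]
      keep <- d$count > 0
      data.frame(chrom = chrom, start = d$pos[keep] - 1L, end = d$pos[keep],
                 count = d$count[keep])
    })
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 count = numeric())
    utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  emit(track$plus, path_plus)
  emit(track$minus, path_minus)
  invisible(track)
}

#' @export
print.tss_track <- function(x, ...) {
  tot <- function(side) sum(vapply(side, function(d) sum(d$count), 0))
  cat("tss_track:", length(union(names(x$plus), names(x$minus))),
      "chromosomes;", tot(x$plus), "plus-strand and", tot(x$minus),
      "minus-strand read 5'-ends\n")
  invisible(x)
}

#' Extract per-base counts of a track within an interval
#'
#' @param track A \code{tss_track}.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive interval bounds.
#' @param strand \code{"+"} or \code{"-"}.
#' @return data.frame with columns \code{pos}, \code{count} (only bases with
#'   nonzero counts; sorted by position).
#' @export
track_slice <- function(track, chrom, start, end, strand) {
  side <- if (strand == "+") track$plus else track$minus
  d <- side[[chrom]]
  if (is.null(d)) return(data.frame(pos = integer(), count = numeric()))
  keep <- d$pos >= start & d$pos <= end
  data.frame(pos = d$pos[keep], count = d$count[keep])
}

# total counts per strand (used for conservation checks)
track_totals <- function(track) {
  tot <- function(side) sum(vapply(side, function(d) sum(d$count), 0))
  c(plus = tot(track$plus), minus = tot(track$minus))
}

# ---- strand-aware coordinate helpers ---------------------------------------

# Oriented window around an anchor: offsets `from..to` are in transcription
# direction ("downstream" of a minus-strand anchor means decreasing
# coordinates). Returns 1-based inclusive genomic (start, end).
oriented_window <- function(pos, strand, from, to) {
  stopifnot(from <= to)
  if (strand == "+") c(pos + from, pos + to) else c(pos - to, pos - from)
}

# Genomic position at oriented offset
oriented_pos <- function(pos, strand, offset) {
  if (strand == "+") pos + offset else pos - offset
}
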