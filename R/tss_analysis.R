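# TSS significance calling against an empirical gene-body background,
# Set A / Set B selection with convergent-pair filtering, directionality
# ratios, and the entropy-based distribution-pattern (DP) score.

#' Control regions downstream of peaks
#'
#' For every peak carrying at least one read 5'-end on at least one strand, a
#' window of the peak's own width is placed immediately downstream with
#' respect to each strand (higher coordinates for +, lower for -). Bases
#' overlapping any peak are subtracted out, so the windows sample gene-body
#' background (read-through or cap-selection escape) rather than NDR signal.
#'
#' @param peaks_with_signal \code{GRanges}: peaks with >= 1 read 5'-end on
#'   >= 1 strand.
#' @param all_peaks \code{GRanges}: all peaks, subtracted from the windows.
#' @param chrom_lengths Optional named vector of chromosome lengths; windows
#'   running past a chromosome end are truncated with a warning.
#' @return A \code{GRanges} of disjoint control intervals.
#' @export
build_control_regions <- function(peaks_with_signal, all_peaks,
                                  chrom_lengths = NULL) {
  if (length(peaks_with_signal) == 0L) return(GenomicRanges::GRanges())
  w <- GenomicRanges::width(peaks_with_signal)
  chrom <- as.character(GenomicRanges::seqnames(peaks_with_signal))
  s <- GenomicRanges::start(peaks_with_signal)
  e <- GenomicRanges::end(peaks_with_signal)
  up_start <- pmax(1L, s - w)
  up_end <- s - 1L
  down_start <- e + 1L
  down_end <- e + w
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[chrom])
    if (any(down_end > lim, na.rm = TRUE)) {
      warning("control windows truncated at chromosome end")
      down_end <- pmin(down_end, lim)
    }
  }
  keep_up <- up_end >= up_start
  keep_down <- down_end >= down_start
  win <- GenomicRanges::GRanges(
    c(chrom[keep_up], chrom[keep_down]),
    IRanges::IRanges(c(up_start[keep_up], down_start[keep_down]),
                     c(up_end[keep_up], down_end[keep_down])))
  win <- GenomicRanges::reduce(win, ignore.strand = TRUE)
  out <- GenomicRanges::setdiff(win, GenomicRanges::reduce(
    GenomicRanges::granges(all_peaks), ignore.strand = TRUE),
    ignore.strand = TRUE)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Empirical background cutoff for significant TSS bases
#'
#' Builds the empirical distribution of read 5'-ends per base over every base
#' of every control window on both strands (zero-count bases included) and
#' takes its empirical quantile (type 1: the smallest observed value whose
#' cumulative frequency reaches \code{quantile}). The cutoff is floored at 1
#' read so an all-zero background never admits everything.
#'
#' @param track A \code{tss_track}.
#' @param control_regions \code{GRanges} of control windows.
#' @param quantile Background quantile in (0, 1); 0.999 is the usual choice
#'   for compact genomes and 0.9999 for human-scale data.
#' @return A \code{background_model} with elements \code{cutoff}, \code{n}
#'   (number of strand-bases), \code{quantile}, and \code{nonzero} (the
#'   nonzero counts observed).
#' @export
estimate_cutoff <- function(track, control_regions, quantile = 0.999) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  if (length(control_regions) == 0L) stop("control regions are empty")
  chrom <- as.character(GenomicRanges::seqnames(control_regions))
  s <- GenomicRanges::start(control_regions)
  e <- GenomicRanges::end(control_regions)
  nonzero <- numeric(0)
  for (i in seq_along(control_regions)) {
    for (str in c("+", "-")) {
      d <- track_slice(track, chrom[i], s[i], e[i], str)
      nonzero <- c(nonzero, d$count)
    }
  }
  n <- 2 * sum(GenomicRanges::width(control_regions))
  k <- ceiling(quantile * n)
  n_zero <- n - length(nonzero)
  cutoff <- if (k <= n_zero) 0 else sort(nonzero)[k - n_zero]
  cutoff <- max(1, cutoff)
  structure(list(cutoff = cutoff, n = n, quantile = quantile,
                 nonzero = nonzero),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: cutoff %g read 5'-ends (quantile %g over %d strand-bases)\n",
              x$cutoff, x$quantile, x$n))
  invisible(x)
}

#' Per-peak stranded TSS summary
#'
#' Totals and modal positions of read 5'-ends per strand within each peak.
#' The mode is the base with the most 5'-ends; ties resolve to the 5'-most
#' position with respect to the strand. Forward is the annotated gene strand
#' for promoters and the higher-total strand otherwise.
#'
#' @param peaks Annotated \code{GRanges} (see \code{\link{annotate_peaks}}).
#' @param track A \code{tss_track}.
#' @return A data.frame, one row per peak: \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive), \code{annotation}, \code{fwd_strand},
#'   \code{fwd_total}, \code{rev_total}, \code{fwd_mode}, \code{rev_mode}
#'   (positions; NA when the strand has no reads), \code{fwd_mode_count},
#'   \code{rev_mode_count}, \code{dp_fwd}, \code{dp_rev} (bits; NA when no
#'   reads), \code{log_ratio} (log2 pseudo-counted forward/reverse totals).
#' @export
peak_tss_summary <- function(peaks, track) {
  n <- length(peaks)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  s <- GenomicRanges::start(peaks)
  e <- GenomicRanges::end(peaks)
  ann <- if (!is.null(peaks$annotation)) peaks$annotation else rep("intergenic", n)
  gene_strand <- if (!is.null(peaks$gene_strand)) peaks$gene_strand else rep(NA_character_, n)
  out <- data.frame(peak_id = if (!is.null(peaks$name) && !anyDuplicated(peaks$name))
                      peaks$name else sprintf("peak_%05d", seq_len(n)),
                    chrom = chrom, start = s, end = e,
                    annotation = ann, fwd_strand = NA_character_,
                    fwd_total = 0, rev_total = 0,
                    fwd_mode = NA_integer_, rev_mode = NA_integer_,
                    fwd_mode_count = 0, rev_mode_count = 0,
                    dp_fwd = NA_real_, dp_rev = NA_real_,
                    log_ratio = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sides <- lapply(c("+", "-"), function(str)
      track_slice(track, chrom[i], s[i], e[i], str))
    names(sides) <- c("+", "-")
    totals <- vapply(sides, function(d) sum(d$count), 0)
    fwd <- if (ann[i] == "promoter" && !is.na(gene_strand[i])) gene_strand[i]
           else if (totals["-"] > totals["+"]) "-" else "+"
    rev <- if (fwd == "+") "-" else "+"
    mode_of <- function(d, str) {
      if (nrow(d) == 0L) return(c(NA_integer_, 0))
      top <- d[d$count == max(d$count), , drop = FALSE]
      pos <- if (str == "+") min(top$pos) else max(top$pos)
      c(pos, max(d$count))
    }
    mf <- mode_of(sides[[fwd]], fwd)
    mr <- mode_of(sides[[rev]], rev)
    out$fwd_strand[i] <- fwd
    out$fwd_total[i] <- totals[fwd]
    out$rev_total[i] <- totals[rev]
    out$fwd_mode[i] <- mf[1]
    out$rev_mode[i] <- mr[1]
    out$fwd_mode_count[i] <- mf[2]
    out$rev_mode_count[i] <- mr[2]
    if (nrow(sides[[fwd]])) out$dp_fwd[i] <- dp_score(sides[[fwd]]$count)$value
    if (nrow(sides[[rev]])) out$dp_rev[i] <- dp_score(sides[[rev]]$count)$value
    out$log_ratio[i] <- directionality_ratio(totals[fwd], totals[rev])
  }
  out
}

#' Assign Set A / Set B labels
#'
#' Set A: the forward-strand modal base reaches the background cutoff. Set B:
#' both strands' modal bases reach the cutoff \emph{and} the TSS pair is
#' divergent. A pair is convergent (and removed from Set B) when each mode
#' lies downstream of the other with respect to its own strand, i.e. the two
#' initiation events point toward each other.
#'
#' @param records Output of \code{\link{peak_tss_summary}}.
#' @param cutoff Background cutoff (reads), e.g.
#'   \code{estimate_cutoff(...)$cutoff}.
#' @return \code{records} with columns \code{set_label} (\code{"none"},
#'   \code{"A"}, or \code{"B"}; B implies A-qualifying on forward) and
#'   \code{convergent} (logical).
#' @export
select_sets <- function(records, cutoff) {
  a <- records$fwd_mode_count >= cutoff
  both <- a & records$rev_mode_count >= cutoff
  # convergent geometry: reverse mode strictly downstream of forward mode in
  # the forward direction (mirrored when the forward strand is -)
  conv <- both & !is.na(records$fwd_mode) & !is.na(records$rev_mode) &
    ifelse(records$fwd_strand == "+",
           records$rev_mode > records$fwd_mode,
           records$rev_mode < records$fwd_mode)
  records$convergent <- conv
  records$set_label <- ifelse(both & !conv, "B", ifelse(a, "A", "none"))
  records
}

#' Distribution-pattern (DP) score of a TSS profile
#'
#' Shannon entropy (base 2) of the per-base read 5'-end distribution over the
#' positions that carry at least one read: \eqn{DP = -\sum_i p_i \log_2 p_i}
#' with \eqn{p_i} the fraction of the strand's reads at position \eqn{i}. Low
#' values indicate focused initiation, high values dispersed initiation.
#'
#' @param counts Numeric vector of per-position counts (zeros allowed; they
#'   are excluded from the support).
#' @return A list with \code{value} (bits) and \code{n_positions} (support
#'   size), class \code{"dp_score"}.
#' @export
dp_score <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("dp_score needs at least one positive count")
  p <- counts / sum(counts)
  value <- -sum(p * log2(p))
  structure(list(value = value, n_positions = length(p)), class = "dp_score")
}

#' @export
print.dp_score <- function(x, ...) {
  cat(sprintf("DP = %.4f bits over %d positions\n", x$value, x$n_positions))
  invisible(x)
}

#' Pseudo-counted log2 directionality ratio
#'
#' \code{log2((fwd + pseudocount) / (rev + pseudocount))}; the pseudocount of
#' 1 keeps the ratio defined for strands without reads and shrinks extreme
#' ratios at low depth.
#'
#' @param fwd_total,rev_total Non-negative totals of read 5'-ends.
#' @param pseudocount Added to numerator and denominator (default 1).
#' @return log2 ratio (vectorised).
#' @export
directionality_ratio <- function(fwd_total, rev_total, pseudocount = 1) {
  if (any(fwd_total < 0) || any(rev_total < 0)) stop("totals must be >= 0")
  log2((fwd_total + pseudocount) / (rev_total + pseudocount))
}
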