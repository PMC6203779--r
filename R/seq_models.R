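# Core-promoter sequence scoring: a position-specific first-order Markov
# model over a TSS-centered window scored as a log-likelihood ratio against a
# zero-order background, plus motif scanning against a local background,
# 6-mer strand asymmetry, and GC%/GC-skew profiles.

BASES <- c("A", "C", "G", "T")

#' Read a FASTA genome
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase chromosome sequences.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

# integer codes 1..4 for ACGT, NA otherwise; x: character vector of
# equal-length sequences -> n x L integer matrix
.encode_seqs <- function(x) {
  L <- nchar(x[1])
  m <- matrix(match(unlist(strsplit(x, "", fixed = TRUE)), BASES),
              nrow = length(x), ncol = L, byrow = TRUE)
  m
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract strand-oriented windows from a genome
#'
#' Windows of \code{2*flank + 1} nt centered on \code{centers}, read in the
#' direction of \code{strand} (reverse-complemented for \code{-}). Windows
#' overlapping a chromosome edge come back as \code{NA}.
#'
#' @param genome Named character vector (see \code{\link{read_genome}}).
#' @param chrom Chromosome name.
#' @param centers 1-based center positions.
#' @param strand \code{"+"} or \code{"-"}.
#' @param flank Flank size in bp (default 50, i.e. 101-nt windows).
#' @return Character vector of windows (NA where out of range).
#' @export
extract_windows <- function(genome, chrom, centers, strand, flank = 50L) {
  seq <- genome[[chrom]]
  if (is.null(seq)) stop("chromosome not in genome: ", chrom)
  len <- nchar(seq)
  s <- centers - flank
  e <- centers + flank
  ok <- s >= 1 & e <= len
  out <- rep(NA_character_, length(centers))
  if (any(ok)) {
    w <- substring(seq, s[ok], e[ok])
    if (strand == "-") w <- .revcomp(w)
    out[ok] <- w
  }
  out
}

#' Train the position-specific first-order core-promoter model
#'
#' From TSS-centered windows (typically +/-50 bp around the modal initiation
#' base of Set A peaks), estimates for every window position the probability
#' of each base conditioned on the preceding base (a positional dinucleotide
#' model); the first position uses its marginal base distribution. The
#' background is the zero-order base composition of the training windows.
#' N bases are excluded from all counts.
#'
#' @param sequences Character vector of equal-length training windows
#'   (uppercase ACGTN). Windows of the wrong length are dropped with a
#'   warning.
#' @param pseudocount Added to every transition count (default 0.5).
#' @param flank Flank size; window length must be \code{2*flank + 1}.
#' @return A \code{core_promoter_model}.
#' @export
train_core_model <- function(sequences, pseudocount = 0.5, flank = 50L) {
  L <- 2L * flank + 1L
  bad <- nchar(sequences) != L | is.na(sequences)
  if (any(bad)) {
    warning(sum(bad), " training windows dropped (length != ", L, ")")
    sequences <- sequences[!bad]
  }
  if (length(sequences) < 2L) stop("too few training windows")
  m <- .encode_seqs(sequences)
  # background: zero-order composition of all training bases
  bg_counts <- tabulate(m, nbins = 4L)
  background <- bg_counts / sum(bg_counts)
  # position 1 marginal
  c1 <- tabulate(m[, 1L], nbins = 4L)
  marg1 <- (c1 + pseudocount) / (sum(c1) + 4 * pseudocount)
  cond <- array(NA_real_, dim = c(L, 4L, 4L),
                dimnames = list(NULL, BASES, BASES))
  for (p in 2:L) {
    prev <- m[, p - 1L]
    base <- m[, p]
    ok <- !is.na(prev) & !is.na(base)
    cnt <- matrix(tabulate((base[ok] - 1L) * 4L + prev[ok], nbins = 16L),
                  nrow = 4L)  # rows prev, cols base
    cnt <- cnt + pseudocount
    cond[p, , ] <- cnt / rowSums(cnt)
  }
  lr <- log2(sweep(cond, 3L, background, "/"))
  lr1 <- log2(marg1 / background)
  structure(list(flank = flank, length = L, pseudocount = pseudocount,
                 background = stats::setNames(background, BASES),
                 marg1 = stats::setNames(marg1, BASES),
                 cond = cond, lr = lr, lr1 = lr1,
                 n_train = length(sequences)),
            class = "core_promoter_model")
}

#' @export
print.core_promoter_model <- function(x, ...) {
  cat(sprintf("core_promoter_model: first-order, %d-nt window, %d training windows\n",
              x$length, x$n_train))
  cat("background:", paste(sprintf("%s=%.3f", BASES, x$background), collapse = " "), "\n")
  invisible(x)
}

#' Score windows with a core-promoter model
#'
#' Log2 likelihood ratio of the positional first-order chain against the
#' zero-order background, summed over the window. Positions containing N (as
#' base or preceding base) contribute 0.
#'
#' @param model A \code{core_promoter_model}.
#' @param sequences Character vector of windows, each of the model's window
#'   length.
#' @return Numeric vector of scores (bits).
#' @export
score_window <- function(model, sequences) {
  L <- model$length
  if (any(nchar(sequences) != L)) {
    stop("sequence length must equal the model window length (", L, ")")
  }
  m <- .encode_seqs(sequences)
  score <- ifelse(is.na(m[, 1L]), 0, model$lr1[m[, 1L]])
  for (p in 2:L) {
    prev <- m[, p - 1L]
    base <- m[, p]
    contrib <- model$lr[cbind(p, prev, base)]
    contrib[is.na(contrib)] <- 0
    score <- score + contrib
  }
  unname(score)
}

#' Aggregate per-strand sequence feature for a peak
#'
#' Scores a model window around every base of the peak that carries at least
#' one read 5'-end on the given strand, sums the scores, and divides by the
#' peak width. Windows overlapping a chromosome edge contribute 0.
#'
#' @param model A \code{core_promoter_model}.
#' @param track A \code{tss_track}.
#' @param peak A single-row list/data.frame with \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive), or a length-1 \code{GRanges}.
#' @param strand \code{"+"} or \code{"-"}.
#' @param genome Named character vector of chromosome sequences.
#' @return Scalar: summed window scores divided by peak width (0 when no
#'   base qualifies).
#' @export
aggregate_sequence_feature <- function(model, track, peak, strand, genome) {
  if (inherits(peak, "GRanges")) {
    peak <- list(chrom = as.character(GenomicRanges::seqnames(peak))[1],
                 start = GenomicRanges::start(peak)[1],
                 end = GenomicRanges::end(peak)[1])
  }
  width <- peak$end - peak$start + 1L
  if (width <= 0) stop("peak width must be > 0")
  d <- track_slice(track, peak$chrom, peak$start, peak$end, strand)
  if (nrow(d) == 0L) return(0)
  w <- extract_windows(genome, peak$chrom, d$pos, strand, model$flank)
  w <- w[!is.na(w)]
  if (length(w) == 0L) return(0)
  sum(score_window(model, w)) / width
}

#' Scan a PWM against a sequence with a local zero-order background
#'
#' Log-odds of the motif at every start position, computed against the base
#' composition of a \code{bg_window}-bp window centered on the motif
#' occurrence (clipped at the sequence edges; one pseudo-observation of each
#' base avoids zero frequencies). Scores below zero are set to zero.
#'
#' @param pwm Probability matrix, rows = motif positions, columns A, C, G, T.
#' @param sequence A single sequence (uppercase).
#' @param bg_window Background window size in bp (default 100).
#' @return Numeric vector of clipped scores, one per start position (empty
#'   when the sequence is shorter than the motif).
#' @export
scan_motif <- function(pwm, sequence, bg_window = 100L) {
  pwm <- as.matrix(pwm)
  Lm <- nrow(pwm)
  codes <- match(strsplit(sequence, "", fixed = TRUE)[[1]], BASES)
  len <- length(codes)
  if (len < Lm) return(numeric(0))
  n_pos <- len - Lm + 1L
  # cumulative base counts for O(1) window composition
  ind <- matrix(0L, nrow = len, ncol = 4L)
  ok <- !is.na(codes)
  ind[cbind(which(ok), codes[ok])] <- 1L
  cum <- apply(ind, 2L, cumsum)
  cum <- rbind(0L, cum)
  centers <- seq_len(n_pos) + (Lm - 1L) %/% 2L
  bs <- pmax(1L, centers - (bg_window %/% 2L - 1L))
  be <- pmin(len, centers + bg_window %/% 2L)
  bg <- (cum[be + 1L, , drop = FALSE] - cum[bs, , drop = FALSE]) + 1
  bg <- bg / rowSums(bg)
  score <- numeric(n_pos)
  lp <- log2(pwm)
  for (j in seq_len(Lm)) {
    b <- codes[seq_len(n_pos) + j - 1L]
    contrib <- unname(lp[j, ][b]) - log2(bg[cbind(seq_len(n_pos), b)])
    contrib[is.na(b)] <- 0
    score <- score + contrib
  }
  unname(pmax(score, 0))
}

#' 6-mer forward/reverse asymmetry table
#'
#' Counts overlapping k-mers in strand-oriented windows downstream of forward
#' and of reverse TSSs and ranks k-mers by the pseudo-counted
#' forward-to-reverse occurrence ratio.
#'
#' @param fwd_windows,rev_windows Character vectors of strand-oriented window
#'   sequences (conventionally 500 bp downstream of each TSS).
#' @param k k-mer size (default 6).
#' @return data.frame with columns \code{kmer}, \code{fwd}, \code{rev},
#'   \code{ratio} = (fwd+1)/(rev+1), and \code{rank} (1 = most
#'   forward-enriched), one row per possible k-mer.
#' @export
kmer_asymmetry <- function(fwd_windows, rev_windows, k = 6L) {
  count <- function(w) {
    if (length(w) == 0L) {
      return(stats::setNames(rep(0, 4^k),
                             Biostrings::mkAllStrings(BASES, k)))
    }
    colSums(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(w), width = k))
  }
  f <- count(fwd_windows)
  r <- count(rev_windows)
  ratio <- (f + 1) / (r + 1)
  data.frame(kmer = names(f), fwd = as.numeric(f), rev = as.numeric(r),
             ratio = as.numeric(ratio),
             rank = rank(-ratio, ties.method = "first"),
             stringsAsFactors = FALSE)
}

#' Positional GC% and GC-skew profiles
#'
#' GC percentage and GC-skew \eqn{(g - c)/(g + c)} in a sliding window along
#' each region, averaged positionally across regions. Windows containing no
#' G or C return skew 0 (with a warning), where the ratio is undefined.
#'
#' @param regions Character vector of equal-length, strand-oriented
#'   sequences.
#' @param window Sliding window size in bp (default 50).
#' @param step Step size in bp (default 1).
#' @return data.frame with columns \code{offset} (1-based window start
#'   within the region), \code{gc_percent}, \code{gc_skew}.
#' @export
gc_profiles <- function(regions, window = 50L, step = 1L) {
  stopifnot(length(unique(nchar(regions))) == 1L)
  warned <- FALSE
  per <- lapply(regions, function(s) {
    fr <- Biostrings::letterFrequencyInSlidingView(
      Biostrings::DNAString(s), view.width = window, letters = c("G", "C"))
    g <- fr[, "G"]; c_ <- fr[, "C"]
    tot <- g + c_
    if (any(tot == 0) && !warned) {
      warning("windows with no G or C: GC-skew set to 0")
      warned <<- TRUE
    }
    skew <- ifelse(tot == 0, 0, (g - c_) / tot)
    cbind(gc = tot / window * 100, skew = skew)
  })
  n_win <- nrow(per[[1]])
  idx <- seq(1L, n_win, by = step)
  gc_m <- matrix(vapply(per, function(m) m[idx, "gc"], numeric(length(idx))),
                 nrow = length(idx))
  skew_m <- matrix(vapply(per, function(m) m[idx, "skew"], numeric(length(idx))),
                   nrow = length(idx))
  gc <- rowMeans(gc_m)
  skew <- rowMeans(skew_m)
  data.frame(offset = idx, gc_percent = gc, gc_skew = skew)
}
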