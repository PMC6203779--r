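# Chromatin-state discovery: peak-masked, log-scaled, 10-bp-binned multi-mark
# signal; a multivariate (diagonal) Gaussian HMM whose transition matrix is
# tied to 0.9 on the diagonal and 0.1/(n-1) elsewhere and never re-estimated;
# Baum-Welch over emissions and initial probabilities; posterior decoding;
# and state positional-coverage profiles around oriented anchors.
#
# Forward-backward runs in lockstep over all segments at once (matrices of
# segments x states). Segments shorter than the longest one are padded with
# unit emission densities, which leaves their likelihood and posteriors
# unchanged because the tied transition rows sum to 1.

#' Read a bedGraph signal file
#'
#' @param path bedGraph path (0-based half-open intervals, 4th column value).
#' @return data.frame with columns \code{chrom}, \code{start} (0-based),
#'   \code{end}, \code{value}.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  if (any(df$start >= df$end)) stop(path, ": malformed bedGraph interval")
  df
}

#' Bin, mask, and log-scale histone-mark signal
#'
#' Per 10-bp bin and per mark: the mean per-base signal, zeroed wherever the
#' bin midpoint falls outside that mark's peak calls (so only peak-supported
#' signal enters the model), then log(x + 1) transformed so read-count-like
#' values resemble a Gaussian. Bins where all marks are zero are discarded;
#' the remaining bins form contiguous segments.
#'
#' @param mark_signals Named list: per mark, a bedGraph path or a data.frame
#'   as returned by \code{\link{read_bedgraph}}.
#' @param mark_peaks Named list (same names): per mark, a BED path or a
#'   \code{GRanges} of peak calls.
#' @param bin_size Bin size in bp (default 10).
#' @return A \code{chromatin_matrix}: list of per-segment (bins x marks)
#'   matrices plus a \code{segment_info} table (chrom, 1-based genomic start
#'   of the first bin, n_bins).
#' @export
preprocess_chromatin <- function(mark_signals, mark_peaks, bin_size = 10L) {
  stopifnot(length(mark_signals) >= 1L,
            identical(sort(names(mark_signals)), sort(names(mark_peaks))))
  marks <- names(mark_signals)
  sig <- lapply(mark_signals, function(x) if (is.character(x)) read_bedgraph(x) else x)
  pk <- lapply(mark_peaks, function(x) if (is.character(x)) read_bed(x) else x)
  chrom_sets <- lapply(sig, function(d) sort(unique(d$chrom)))
  all_chroms <- sort(unique(unlist(chrom_sets)))
  for (m in marks) {
    miss <- setdiff(all_chroms, chrom_sets[[m]])
    if (length(miss)) {
      stop("mark ", m, " is missing chromosomes: ", paste(miss, collapse = ", "))
    }
  }
  if (any(vapply(sig, function(d) any(d$value < 0), FALSE))) {
    stop("mark signal must be non-negative")
  }
  seg_mats <- list()
  seg_info <- list()
  for (chrom in all_chroms) {
    n_bins_chrom <- max(vapply(sig, function(d) {
      dd <- d[d$chrom == chrom, ]
      if (nrow(dd)) max(dd$end) else 0L
    }, 0L))
    n_bins_chrom <- (n_bins_chrom + bin_size - 1L) %/% bin_size
    if (n_bins_chrom == 0L) next
    vals <- matrix(0, nrow = n_bins_chrom, ncol = length(marks),
                   dimnames = list(NULL, marks))
    for (mi in seq_along(marks)) {
      d <- sig[[mi]][sig[[mi]]$chrom == chrom, ]
      if (nrow(d) == 0L) next
      b0 <- d$start %/% bin_size
      b1 <- (d$end - 1L) %/% bin_size
      npc <- b1 - b0 + 1L
      row <- rep(seq_len(nrow(d)), npc)
      bin <- sequence(npc, from = b0 + 1L)  # 1-based bin index
      ov <- pmin(d$end[row], bin * bin_size) -
        pmax(d$start[row], (bin - 1L) * bin_size)
      acc <- rowsum(d$value[row] * ov, bin)
      vals[as.integer(rownames(acc)), mi] <-
        vals[as.integer(rownames(acc)), mi] + acc[, 1] / bin_size
      # mask: bin midpoint must fall inside a peak of this mark
      p <- pk[[mi]]
      p <- p[as.character(GenomicRanges::seqnames(p)) == chrom]
      nz <- which(vals[, mi] != 0)
      if (length(nz)) {
        mid <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
          (nz - 1L) * bin_size + bin_size %/% 2L + 1L, width = 1L))
        inside <- IRanges::overlapsAny(mid, p, ignore.strand = TRUE)
        vals[nz[!inside], mi] <- 0
      }
    }
    vals <- log1p(vals)
    keep <- rowSums(vals) > 0
    if (!any(keep)) next
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      seg_mats[[length(seg_mats) + 1L]] <-
        vals[starts[j]:ends[j], , drop = FALSE]
      seg_info[[length(seg_info) + 1L]] <-
        data.frame(chrom = chrom,
                   start = (starts[j] - 1L) * bin_size + 1L,
                   n_bins = ends[j] - starts[j] + 1L)
    }
  }
  structure(list(segments = seg_mats,
                 segment_info = if (length(seg_info)) do.call(rbind, seg_info)
                   else data.frame(chrom = character(), start = integer(),
                                   n_bins = integer()),
                 bin_size = as.integer(bin_size), mark_names = marks),
            class = "chromatin_matrix")
}

#' @export
print.chromatin_matrix <- function(x, ...) {
  cat(sprintf("chromatin_matrix: %d segments, %d bins of %d bp, marks: %s\n",
              length(x$segments), sum(x$segment_info$n_bins), x$bin_size,
              paste(x$mark_names, collapse = ", ")))
  invisible(x)
}

# tied transition matrix: 0.9 self, 0.1/(n-1) otherwise
tied_transition <- function(n_states, diagonal = 0.9) {
  off <- (1 - diagonal) / (n_states - 1)
  m <- matrix(off, n_states, n_states)
  diag(m) <- diagonal
  m
}

# log emission densities (diagonal Gaussian) for one segment: T x n matrix
.log_emission <- function(x, means, vars) {
  n <- nrow(means)
  out <- matrix(0, nrow(x), n)
  for (k in seq_len(n)) {
    z <- sweep(x, 2L, means[k, ], "-")
    out[, k] <- -0.5 * (rowSums(sweep(z^2, 2L, vars[k, ], "/")) +
                          sum(log(2 * pi * vars[k, ])))
  }
  out
}

# Lockstep scaled forward-backward over a list of segments.
# Returns loglik (total), gamma (list per segment, T x n), gamma1 (M x n).
.forward_backward <- function(segments, means, vars, init, A) {
  M <- length(segments)
  n <- nrow(means)
  Tlen <- vapply(segments, nrow, 0L)
  Tmax <- max(Tlen)
  # padded relative densities: exp(logB - per-(segment,t) max), 1 beyond T
  B <- array(1, dim = c(M, Tmax, n))
  mxs <- matrix(0, M, Tmax)
  for (i in seq_len(M)) {
    lb <- .log_emission(segments[[i]], means, vars)
    mx <- apply(lb, 1L, max)
    B[i, seq_len(Tlen[i]), ] <- exp(lb - mx)
    mxs[i, seq_len(Tlen[i])] <- mx
  }
  Bt <- function(t) matrix(B[, t, ], M, n)
  alpha <- array(0, dim = c(M, Tmax, n))
  a <- matrix(init, M, n, byrow = TRUE) * Bt(1L)
  rs <- rowSums(a)
  a <- a / rs
  ll <- log(rs) + mxs[, 1L]
  alpha[, 1L, ] <- a
  if (Tmax >= 2L) for (t in 2:Tmax) {
    a <- (a %*% A) * Bt(t)
    rs <- rowSums(a)
    a <- a / rs
    ll <- ll + log(rs) + mxs[, t]
    alpha[, t, ] <- a
  }
  # backward + gamma
  gamma <- lapply(seq_len(M), function(i) matrix(0, Tlen[i], n))
  beta <- matrix(1, M, n)
  g <- matrix(alpha[, Tmax, ], M, n) * beta
  g <- g / rowSums(g)
  for (i in which(Tlen == Tmax)) gamma[[i]][Tmax, ] <- g[i, ]
  if (Tmax >= 2L) for (t in (Tmax - 1L):1L) {
    bb <- Bt(t + 1L) * beta
    beta <- bb %*% t(A)
    beta <- beta / rowSums(beta)
    g <- matrix(alpha[, t, ], M, n) * beta
    g <- g / rowSums(g)
    for (i in which(Tlen >= t)) gamma[[i]][t, ] <- g[i, ]
  }
  list(loglik = sum(ll), gamma = gamma,
       gamma1 = t(vapply(gamma, function(g) g[1L, ], numeric(n))))
}

#' Fit the tied-transition Gaussian HMM by Baum-Welch
#'
#' Expectation-maximisation over per-state emission means/variances
#' (diagonal covariance) and initial state probabilities. The transition
#' matrix stays fixed at the tied values (0.9 self-transition,
#' 0.1/(n_states - 1) otherwise) throughout. Only segments of at least
#' \code{min_train_len} bp enter training. Means are initialised by k-means
#' on a subsample of bins under the given seed, so identical seeds give
#' identical fits.
#'
#' @param data A \code{chromatin_matrix}.
#' @param n_states Number of states (>= 2).
#' @param min_train_len Minimum segment length in bp for training (default
#'   500).
#' @param max_iter,tol EM stopping rule: stop when the relative
#'   log-likelihood improvement drops below \code{tol} (default 1e-6) or
#'   after \code{max_iter} iterations (default 100).
#' @param seed RNG seed for initialisation.
#' @param var_floor Lower bound on emission variances (default 1e-3).
#' @param train_on Optional character vector of chromosome names; when
#'   given, only segments on these chromosomes are used for training
#'   (decoding is still genome-wide).
#' @return A \code{gauss_hmm} with elements \code{means}, \code{vars},
#'   \code{init_probs}, \code{transition}, \code{loglik_trace},
#'   \code{n_states}, \code{mark_names}, \code{bin_size}.
#' @export
fit_hmm <- function(data, n_states, min_train_len = 500L, max_iter = 100L,
                    tol = 1e-6, seed = 1L, var_floor = 1e-3,
                    train_on = NULL) {
  if (n_states < 2L) stop("n_states must be >= 2")
  keep <- data$segment_info$n_bins * data$bin_size >= min_train_len
  if (!is.null(train_on)) keep <- keep & data$segment_info$chrom %in% train_on
  segments <- data$segments[keep]
  if (length(segments) == 0L) stop("no segments pass min_train_len")
  X <- do.call(rbind, segments)
  m <- ncol(X)
  set.seed(seed)
  sub <- if (nrow(X) > 20000L) X[sample.int(nrow(X), 20000L), , drop = FALSE] else X
  km <- suppressWarnings(stats::kmeans(sub, centers = n_states, nstart = 5L,
                                       iter.max = 50L))
  means <- km$centers
  gvar <- pmax(apply(X, 2L, stats::var), var_floor)
  vars <- matrix(gvar, n_states, m, byrow = TRUE)
  init <- rep(1 / n_states, n_states)
  A <- tied_transition(n_states)
  trace <- numeric(0)
  ll_prev <- -Inf
  total_bins <- nrow(X)
  for (iter in seq_len(max_iter)) {
    fb <- .forward_backward(segments, means, vars, init, A)
    trace <- c(trace, fb$loglik)
    S0 <- numeric(n_states)
    S1 <- matrix(0, n_states, m)
    S2 <- matrix(0, n_states, m)
    for (i in seq_along(segments)) {
      g <- fb$gamma[[i]]
      S0 <- S0 + colSums(g)
      S1 <- S1 + t(g) %*% segments[[i]]
      S2 <- S2 + t(g) %*% (segments[[i]]^2)
    }
    dead <- S0 < 1e-8 * total_bins
    if (any(dead)) {
      warning("re-seeding ", sum(dead), " degenerate state(s)")
      for (k in which(dead)) {
        means[k, ] <- X[sample.int(nrow(X), 1L), ]
        vars[k, ] <- gvar
      }
      S0[dead] <- NA
    }
    live <- !dead
    means[live, ] <- S1[live, , drop = FALSE] / S0[live]
    vars[live, ] <- pmax(S2[live, , drop = FALSE] / S0[live] -
                           means[live, , drop = FALSE]^2, var_floor)
    init <- colMeans(fb$gamma1)
    init <- init / sum(init)
    if (is.finite(ll_prev) &&
        abs(fb$loglik - ll_prev) < tol * abs(ll_prev)) {
      ll_prev <- fb$loglik
      break
    }
    ll_prev <- fb$loglik
  }
  dimnames(means) <- list(paste0("S", seq_len(n_states)), data$mark_names)
  dimnames(vars) <- dimnames(means)
  structure(list(n_states = n_states, means = means, vars = vars,
                 init_probs = init, transition = A,
                 loglik_trace = trace, mark_names = data$mark_names,
                 bin_size = data$bin_size, seed = seed),
            class = "gauss_hmm")
}

#' @export
print.gauss_hmm <- function(x, ...) {
  cat(sprintf("gauss_hmm: %d states over %d mark(s); %d EM iterations, loglik %.2f\n",
              x$n_states, length(x$mark_names), length(x$loglik_trace),
              utils::tail(x$loglik_trace, 1)))
  print(round(x$means, 3))
  invisible(x)
}

#' Posterior decoding of chromatin states
#'
#' Forward-backward posteriors under the fitted model; each bin is labelled
#' with the state of maximal posterior probability (not the Viterbi path).
#'
#' @param model A \code{gauss_hmm}.
#' @param data A \code{chromatin_matrix} with the same marks in the same
#'   order as used for fitting.
#' @return A \code{state_track}: per-segment integer state labels and
#'   posterior matrices, plus the segment table.
#' @export
decode <- function(model, data) {
  if (!identical(model$mark_names, data$mark_names)) {
    stop("mark names/order differ between model and data")
  }
  fb <- .forward_backward(data$segments, model$means, model$vars,
                          model$init_probs, model$transition)
  states <- lapply(fb$gamma, function(g) max.col(g, ties.method = "first"))
  structure(list(segment_info = data$segment_info, states = states,
                 posterior = fb$gamma, n_states = model$n_states,
                 bin_size = data$bin_size, loglik = fb$loglik),
            class = "state_track")
}

#' @export
print.state_track <- function(x, ...) {
  cat(sprintf("state_track: %d segments, %d bins, %d states\n",
              length(x$states), sum(lengths(x$states)), x$n_states))
  invisible(x)
}

#' Simulate segments from a tied-transition Gaussian HMM
#'
#' Draws state paths from the tied transition matrix and uniform initial
#' probabilities, then emits diagonal-Gaussian observations. Used for
#' parameter-recovery studies.
#'
#' @param means n_states x n_marks matrix of emission means.
#' @param sds n_states x n_marks matrix of emission standard deviations.
#' @param n_segments,seg_length Number and length (bins) of segments.
#' @param diagonal Self-transition probability (default 0.9).
#' @param bin_size Bin size recorded on the result (default 10).
#' @param seed RNG seed.
#' @return List with \code{data} (a \code{chromatin_matrix}) and
#'   \code{states} (list of true state paths).
#' @export
simulate_hmm <- function(means, sds, n_segments, seg_length, diagonal = 0.9,
                         bin_size = 10L, seed = 1L) {
  set.seed(seed)
  n <- nrow(means)
  m <- ncol(means)
  A <- tied_transition(n, diagonal)
  states <- vector("list", n_segments)
  segs <- vector("list", n_segments)
  for (i in seq_len(n_segments)) {
    s <- integer(seg_length)
    s[1] <- sample.int(n, 1L)
    for (t in 2:seg_length) s[t] <- sample.int(n, 1L, prob = A[s[t - 1L], ])
    x <- means[s, , drop = FALSE] +
      matrix(stats::rnorm(seg_length * m), seg_length, m) * sds[s, , drop = FALSE]
    states[[i]] <- s
    segs[[i]] <- x
  }
  data <- structure(list(
    segments = segs,
    segment_info = data.frame(chrom = sprintf("sim%04d", seq_len(n_segments)),
                              start = 1L, n_bins = seg_length),
    bin_size = as.integer(bin_size),
    mark_names = if (!is.null(colnames(means))) colnames(means)
      else paste0("mark", seq_len(m))),
    class = "chromatin_matrix")
  list(data = data, states = states)
}

# flatten a state_track to per-chromosome bin-indexed vectors (bin i covers
# genomic [start + (i-1)*bin, ...)); NA where unlabeled
.state_vectors <- function(track) {
  info <- track$segment_info
  out <- list()
  for (chrom in unique(info$chrom)) {
    idx <- which(info$chrom == chrom)
    last <- max((info$start[idx] - 1L) %/% track$bin_size +
                  info$n_bins[idx])
    v <- rep(NA_integer_, last)
    for (i in idx) {
      b0 <- (info$start[i] - 1L) %/% track$bin_size
      v[(b0 + 1L):(b0 + info$n_bins[i])] <- track$states[[i]]
    }
    out[[chrom]] <- v
  }
  out
}

#' Positional state coverage around oriented anchors
#'
#' For every offset within \code{+/-flank} bp of the anchors (offsets in
#' transcription direction; minus-strand anchors are mirrored), the fraction
#' of anchors whose bin at that offset carries each state. Unlabeled bins
#' are allowed, so fractions over states sum to at most 1.
#'
#' @param track A \code{state_track}.
#' @param anchors data.frame with \code{chrom}, \code{pos} (1-based),
#'   \code{strand}.
#' @param flank Flank in bp.
#' @return Matrix of fractions, rows = offsets (bp, attr and rownames),
#'   columns = states.
#' @export
state_coverage <- function(track, anchors, flank) {
  bs <- track$bin_size
  vecs <- .state_vectors(track)
  offsets <- seq(-(flank %/% bs) * bs, (flank %/% bs) * bs, by = bs)
  out <- matrix(0, length(offsets), track$n_states,
                dimnames = list(offsets, paste0("S", seq_len(track$n_states))))
  n_anchor <- nrow(anchors)
  sign <- ifelse(anchors$strand == "-", -1L, 1L)
  for (oi in seq_along(offsets)) {
    g <- anchors$pos + sign * offsets[oi]
    bin <- (g - 1L) %/% bs + 1L
    st <- rep(NA_integer_, n_anchor)
    for (chrom in unique(anchors$chrom)) {
      sel <- anchors$chrom == chrom
      v <- vecs[[chrom]]
      if (is.null(v)) next
      b <- bin[sel]
      ok <- b >= 1L & b <= length(v)
      st[sel][ok] <- v[b[ok]]
    }
    tab <- tabulate(st, nbins = track$n_states)
    out[oi, ] <- tab / n_anchor
  }
  out
}

#' Convert a segmentation to a GRanges of constant-state runs
#'
#' @param track A \code{state_track}.
#' @return \code{GRanges} with metadata column \code{state}.
#' @export
segmentation_granges <- function(track) {
  info <- track$segment_info
  rows <- list()
  for (i in seq_along(track$states)) {
    r <- rle(track$states[[i]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    rows[[i]] <- data.frame(
      chrom = info$chrom[i],
      start = info$start[i] + (starts - 1L) * track$bin_size,
      end = info$start[i] + ends * track$bin_size - 1L,
      state = paste0("S", r$values))
  }
  df <- do.call(rbind, rows)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         state = df$state)
}
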