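# Synthetic-data generator: a coherent bundle (genome FASTA, NDR peak BED,
# gene annotation BED, stranded per-base 5'-end bedGraphs, per-mark signal
# bedGraphs and peak BEDs, ATAC-like signal) with planted ground truth for
# every downstream stage: true directionality mixture component, per-strand
# rates, TSS positions and shape concentration, planted core-promoter
# motifs, and the true chromatin-state path per bin.

#' Simulation configuration
#'
#' Defaults describe a compact synthetic genome on which the whole pipeline
#' runs in minutes while preserving the statistical structure the analysis
#' assumes: a two-component Gaussian mixture of true log2 forward/reverse
#' ratios, negative-binomial forward depths with Poisson-coupled reverse
#' depths, Dirichlet-multinomial TSS shapes, rate-coupled TATA/Inr-like core
#' promoter motifs, a 5' splice-site-like 6-mer planted in gene bodies, and
#' histone-mark tracks emitted from a known tied-transition Gaussian HMM
#' whose +1/-1 nucleosome asymmetry is coupled to the true ratio.
#'
#' @param n_promoters,n_enhancers Numbers of elements (default 600 / 200).
#' @param chrom_lengths Named vector (default 4 chromosomes of 500 kb).
#' @param gc_content Genome GC fraction, i.i.d. bases (default 0.40).
#' @param ndr_width Range of NDR widths in bp (default 150-300).
#' @param mixture_weights,mixture_means,mixture_sds Two-component mixture of
#'   the true log2 ratio, components named balanced/skewed (defaults 0.6/0.4,
#'   means 0.8/4.0, sds 0.7/1.0).
#' @param depth_mean Negative-binomial mean forward total per promoter
#'   (default 1000, typical of well-sampled nascent-RNA 5'-end libraries at
#'   active promoters, and deep enough that the set of read-carrying bases
#'   saturates on both strands); enhancers are scaled by
#'   \code{enhancer_depth_factor} (default 0.3).
#' @param nb_dispersion NB dispersion (default 0.3; size = 1/dispersion).
#' @param profile_halfwidth TSS profile support half-width in bp (default 10).
#' @param profile_decay Per-bp geometric decay of the profile shape (default
#'   0.7).
#' @param concentration_range Per-element Dirichlet concentration multiplier,
#'   drawn log-uniformly (default 0.1-10): low = focused (low DP), high =
#'   dispersed.
#' @param tata,tata_offset,tata_prob TATA-like consensus, its oriented start
#'   offset relative to the TSS, and the planting probability (defaults
#'   TATAAA at -31, 0.5).
#' @param inr,inr_offset,inr_prob Initiator-like consensus with the A at the
#'   TSS (defaults TCAGTT at -2, 0.9).
#' @param motif_mut_max Maximum per-base motif mutation probability, named
#'   per directionality component; the actual probability is
#'   \code{motif_mut_max[component] * (1 - rate quantile)}, coupling motif
#'   strength to the strand's initiation rate (default 0.45 for both
#'   components).
#' @param splice_motif,splice_fold 6-mer planted in 500 bp windows
#'   downstream of forward TSSs at \code{splice_fold} times its background
#'   expectation (defaults GTGAGT, 5).
#' @param contamination_rate Expected background read 5'-ends per gene-body
#'   base on the sense strand (default 0.05).
#' @param gene_length Gene body length in bp (default 1500).
#' @param mark_flank Histone-mark region on each side of the NDR in bp
#'   (default 1000).
#' @param mark_sd Emission sd on the log-signal scale (default 0.4).
#' @param mark_asym_sd Sd of the per-element random downstream/upstream
#'   H3K4me3 asymmetry on the log-signal scale (default 0.70): element-level
#'   chromatin asymmetry not explained by initiation directionality, so the
#'   mark ratio is an informative but imperfect proxy of the true ratio.
#' @param motif_noise_sd Sd of the per-strand jitter added to the rate
#'   quantile before it sets motif strength (default 0.60): element-level
#'   variability in core-promoter strength beyond initiation rate.
#' @param k4me3_coupling Continuous coupling of downstream-minus-upstream
#'   H3K4me3 log-signal to the centered true ratio, named per directionality
#'   component (default 0.10 for both). Together with \code{mark_asym_sd}
#'   and \code{motif_noise_sd} this keeps sequence and chromatin features
#'   moderately informative proxies of directionality (cross-validated
#'   predicted-vs-measured correlations around 0.6-0.7, the regime reported
#'   for real promoter data), so the class-level difference in mean ratio
#'   is only partly mediated by the emitted features and the two regulatory
#'   regimes remain a genuine mixture in the feature-to-ratio
#'   relationship.
#' @return A list with class \code{"sim_config"}.
#' @export
sim_config <- function(n_promoters = 600L, n_enhancers = 200L,
                       chrom_lengths = stats::setNames(rep(500000L, 4),
                                                       paste0("chr", 1:4)),
                       gc_content = 0.40,
                       ndr_width = c(150L, 300L),
                       mixture_weights = c(balanced = 0.6, skewed = 0.4),
                       mixture_means = c(balanced = 0.8, skewed = 4.0),
                       mixture_sds = c(balanced = 0.7, skewed = 1.0),
                       depth_mean = 1000, enhancer_depth_factor = 0.3,
                       nb_dispersion = 0.3,
                       profile_halfwidth = 10L, profile_decay = 0.7,
                       concentration_range = c(0.1, 10),
                       tata = "TATAAA", tata_offset = -31L, tata_prob = 0.5,
                       inr = "TCAGTT", inr_offset = -2L, inr_prob = 0.9,
                       motif_mut_max = c(balanced = 0.45, skewed = 0.45),
                       splice_motif = "GTGAGT", splice_fold = 5,
                       contamination_rate = 0.05,
                       gene_length = 1500L,
                       mark_flank = 1000L, mark_sd = 0.4,
                       mark_asym_sd = 0.70, motif_noise_sd = 0.60,
                       k4me3_coupling = c(balanced = 0.10, skewed = 0.10)) {
  cfg <- as.list(environment())
  # scalar coupling knobs apply to both components
  for (nm in c("motif_mut_max", "k4me3_coupling")) {
    if (length(cfg[[nm]]) == 1L) {
      cfg[[nm]] <- c(balanced = unname(cfg[[nm]]), skewed = unname(cfg[[nm]]))
    }
  }
  structure(cfg, class = "sim_config")
}

# emission means (log-signal) of the planted chromatin states
.truth_states <- function() {
  m <- rbind(ndr = c(0.5, 0.5),
             nuc_up = c(1.5, 2.2),
             nuc_down = c(2.4, 2.2))
  colnames(m) <- c("H3K4me3", "H3K4me1")
  m
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

# write a motif into a per-base character vector, oriented by strand:
# oriented offset off means the motif's first base sits `off` bp downstream
# of the TSS in transcription direction
.plant_motif <- function(seqvec, tss, strand, motif, off, mut_prob, comp) {
  bases <- strsplit(motif, "", fixed = TRUE)[[1]]
  L <- length(bases)
  mut <- stats::runif(L) < mut_prob
  if (any(mut)) {
    bases[mut] <- sample(names(comp), sum(mut), replace = TRUE, prob = comp)
  }
  for (j in seq_len(L)) {
    o <- off + j - 1L
    g <- if (strand == "+") tss + o else tss - o
    if (g >= 1L && g <= length(seqvec)) {
      seqvec[g] <- if (strand == "+") bases[j] else .complement[[bases[j]]]
    }
  }
  seqvec
}

#' Generate a synthetic dataset bundle with ground truth
#'
#' Emits the exact file formats the pipeline consumes (FASTA genome, NDR
#' peaks BED, genes BED, per-strand 5'-end bedGraphs, per-mark signal
#' bedGraph + peak BED, ATAC-like signal bedGraph) plus \code{truth.tsv} and
#' \code{truth_states.tsv}. Identical seeds give byte-identical bundles.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A \code{\link{sim_config}}.
#' @param seed RNG seed.
#' @return Invisibly, a list with \code{paths}, \code{truth} (data.frame),
#'   \code{truth_states}, \code{config}, and \code{state_means}.
#' @export
generate_dataset <- function(out_dir, config = sim_config(), seed = 1L) {
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  chroms <- names(cfg$chrom_lengths)
  n_chrom <- length(chroms)
  n_total <- cfg$n_promoters + cfg$n_enhancers
  comp <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
            G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)

  # ---- element layout -------------------------------------------------------
  margin <- cfg$mark_flank + 600L
  n_per <- ceiling(n_total / n_chrom)
  spacing <- floor(min(cfg$chrom_lengths - 2 * margin) / n_per)
  if (spacing < cfg$gene_length + max(cfg$ndr_width) + 600L) {
    stop("infeasible config: elements do not fit the genome")
  }
  el <- data.frame(element_id = sprintf("el_%04d", seq_len(n_total)))
  el$class <- sample(c(rep("promoter", cfg$n_promoters),
                       rep("enhancer", cfg$n_enhancers)))
  slot_chrom <- rep(chroms, each = n_per)[seq_len(n_total)]
  slot_idx <- rep(seq_len(n_per), times = n_chrom)[seq_len(n_total)]
  el$chrom <- slot_chrom
  center <- margin + (slot_idx - 0.5) * spacing +
    sample(-200:200, n_total, replace = TRUE)
  w <- sample(cfg$ndr_width[1]:cfg$ndr_width[2], n_total, replace = TRUE)
  el$ndr_start <- as.integer(round(center - w / 2))
  el$ndr_end <- el$ndr_start + w - 1L
  el$strand <- sample(c("+", "-"), n_total, replace = TRUE)
  # divergent geometry: forward TSS in the downstream 2/3 of the NDR,
  # reverse TSS upstream of it on the opposite strand
  fwd_frac <- 0.68; rev_frac <- 0.30
  el$fwd_tss <- ifelse(el$strand == "+",
                       el$ndr_start + round(fwd_frac * w),
                       el$ndr_end - round(fwd_frac * w))
  el$rev_tss <- ifelse(el$strand == "+",
                       el$ndr_start + round(rev_frac * w),
                       el$ndr_end - round(rev_frac * w))

  # ---- true directionality mixture and depths ------------------------------
  comp_id <- sample(names(cfg$mixture_weights), n_total, replace = TRUE,
                    prob = cfg$mixture_weights)
  el$component <- comp_id
  el$true_ratio <- stats::rnorm(n_total, cfg$mixture_means[comp_id],
                                cfg$mixture_sds[comp_id])
  depth <- ifelse(el$class == "promoter", cfg$depth_mean,
                  cfg$depth_mean * cfg$enhancer_depth_factor)
  el$fwd_total <- stats::rnbinom(n_total, size = 1 / cfg$nb_dispersion,
                                 mu = depth)
  el$rev_total <- stats::rpois(n_total, el$fwd_total * 2^(-el$true_ratio))
  el$divergent <- el$fwd_total >= 1 & el$rev_total >= 1
  el$concentration <- exp(stats::runif(n_total,
                                       log(cfg$concentration_range[1]),
                                       log(cfg$concentration_range[2])))

  # ---- genome ---------------------------------------------------------------
  seqs <- lapply(cfg$chrom_lengths, function(len)
    sample(names(comp), len, replace = TRUE, prob = comp))

  # motif planting, strength coupled to the strand's rate quantile
  rate_q <- rank(c(el$fwd_total, el$rev_total)) / (2 * n_total)
  rate_q <- pmin(1, pmax(0, rate_q + stats::rnorm(2 * n_total, 0,
                                                  cfg$motif_noise_sd)))
  fwd_q <- rate_q[seq_len(n_total)]
  rev_q <- rate_q[n_total + seq_len(n_total)]
  el$tata_fwd <- stats::runif(n_total) < cfg$tata_prob
  el$inr_fwd <- stats::runif(n_total) < cfg$inr_prob
  el$tata_rev <- stats::runif(n_total) < cfg$tata_prob
  el$inr_rev <- stats::runif(n_total) < cfg$inr_prob
  for (i in seq_len(n_total)) {
    ch <- el$chrom[i]
    fs <- el$strand[i]
    rs <- if (fs == "+") "-" else "+"
    if (el$inr_fwd[i]) {
      seqs[[ch]] <- .plant_motif(seqs[[ch]], el$fwd_tss[i], fs, cfg$inr,
                                 cfg$inr_offset,
                                 cfg$motif_mut_max[[el$component[i]]] * (1 - fwd_q[i]), comp)
    }
    if (el$tata_fwd[i]) {
      seqs[[ch]] <- .plant_motif(seqs[[ch]], el$fwd_tss[i], fs, cfg$tata,
                                 cfg$tata_offset,
                                 cfg$motif_mut_max[[el$component[i]]] * (1 - fwd_q[i]), comp)
    }
    if (el$inr_rev[i]) {
      seqs[[ch]] <- .plant_motif(seqs[[ch]], el$rev_tss[i], rs, cfg$inr,
                                 cfg$inr_offset,
                                 cfg$motif_mut_max[[el$component[i]]] * (1 - rev_q[i]), comp)
    }
    if (el$tata_rev[i]) {
      seqs[[ch]] <- .plant_motif(seqs[[ch]], el$rev_tss[i], rs, cfg$tata,
                                 cfg$tata_offset,
                                 cfg$motif_mut_max[[el$component[i]]] * (1 - rev_q[i]), comp)
    }
  }

  # splice-site-like 6-mer in the first 500 bp of promoter gene bodies, at
  # splice_fold times its expected background occurrence per window
  p_hex <- prod(comp[strsplit(cfg$splice_motif, "")[[1]]])
  lambda <- cfg$splice_fold * p_hex * (500 - nchar(cfg$splice_motif) + 1)
  for (i in which(el$class == "promoter")) {
    n_occ <- stats::rpois(1L, lambda)
    if (n_occ == 0) next
    offs <- sample.int(500L - nchar(cfg$splice_motif), n_occ)
    for (o in offs) {
      seqs[[el$chrom[i]]] <- .plant_motif(seqs[[el$chrom[i]]], el$fwd_tss[i],
                                          el$strand[i], cfg$splice_motif,
                                          o, 0, comp)
    }
  }

  # ---- per-base 5'-end counts ----------------------------------------------
  hw <- cfg$profile_halfwidth
  shape <- cfg$profile_decay^abs(-hw:hw)
  shape <- shape / sum(shape)
  plus_rows <- list(); minus_rows <- list()
  add_counts <- function(chrom, pos, counts, strand) {
    keep <- counts > 0
    row <- data.frame(chrom = chrom, pos = pos[keep], count = counts[keep])
    if (strand == "+") plus_rows[[length(plus_rows) + 1L]] <<- row
    else minus_rows[[length(minus_rows) + 1L]] <<- row
  }
  for (i in seq_len(n_total)) {
    fs <- el$strand[i]
    rs <- if (fs == "+") "-" else "+"
    sgn <- if (fs == "+") 1L else -1L
    for (side in c("fwd", "rev")) {
      tot <- if (side == "fwd") el$fwd_total[i] else el$rev_total[i]
      if (tot == 0) next
      tss <- if (side == "fwd") el$fwd_tss[i] else el$rev_tss[i]
      str <- if (side == "fwd") fs else rs
      ssgn <- if (str == "+") 1L else -1L
      alpha <- el$concentration[i] * 50 * shape
      g <- stats::rgamma(length(alpha), shape = alpha)
      p <- g / sum(g)
      cnt <- as.vector(stats::rmultinom(1L, tot, p))
      add_counts(el$chrom[i], tss + ssgn * (-hw:hw), cnt, str)
    }
    # gene-body contamination on the sense strand of promoters
    if (el$class[i] == "promoter" && cfg$contamination_rate > 0) {
      n_bg <- stats::rpois(1L, cfg$contamination_rate * cfg$gene_length)
      if (n_bg > 0) {
        pos <- el$fwd_tss[i] + sgn * sample.int(cfg$gene_length, n_bg,
                                                replace = TRUE)
        tab <- table(pos)
        add_counts(el$chrom[i], as.integer(names(tab)), as.vector(tab), fs)
      }
    }
  }
  collapse <- function(rows) {
    df <- do.call(rbind, rows)
    if (is.null(df) || nrow(df) == 0L) {
      return(data.frame(chrom = character(), pos = integer(),
                        count = numeric()))
    }
    agg <- stats::aggregate(count ~ chrom + pos, df, sum)
    agg[order(agg$chrom, agg$pos), ]
  }
  track <- new_tss_track(.track_side(collapse(plus_rows)),
                         .track_side(collapse(minus_rows)))

  # ---- chromatin-mark tracks from the planted state model ------------------
  st_means <- .truth_states()
  marks <- colnames(st_means)
  mark_rows <- stats::setNames(vector("list", length(marks)), marks)
  peak_rows <- list()
  truth_state_rows <- list()
  ratio_c <- el$true_ratio - mean(el$true_ratio)
  asym <- stats::rnorm(n_total, 0, cfg$mark_asym_sd)
  for (i in seq_len(n_total)) {
    reg_s <- el$ndr_start[i] - cfg$mark_flank
    reg_e <- el$ndr_end[i] + cfg$mark_flank
    b0 <- ceiling((reg_s - 1L) / 10)         # first bin fully inside
    b1 <- reg_e %/% 10 - 1L                  # last bin fully inside
    if (b1 < b0) next
    bins <- b0:b1
    mid <- bins * 10L + 5L                   # 0-based bin midpoints
    oriented_down <- if (el$strand[i] == "+") mid >= el$ndr_end[i]
                     else mid < el$ndr_start[i] - 1L
    oriented_up <- if (el$strand[i] == "+") mid < el$ndr_start[i] - 1L
                   else mid >= el$ndr_end[i]
    state <- ifelse(oriented_down, 3L, ifelse(oriented_up, 2L, 1L))
    adj <- (cfg$k4me3_coupling[[el$component[i]]] * ratio_c[i] + asym[i]) *
      (as.numeric(oriented_down) - as.numeric(oriented_up))
    for (mi in seq_along(marks)) {
      mu <- st_means[state, mi] + if (marks[mi] == "H3K4me3") adj else 0
      val_log <- pmax(mu + stats::rnorm(length(bins), 0, cfg$mark_sd), 0.02)
      mark_rows[[mi]][[length(mark_rows[[mi]]) + 1L]] <-
        data.frame(chrom = el$chrom[i], start = bins * 10L,
                   end = bins * 10L + 10L, value = expm1(val_log))
    }
    peak_rows[[length(peak_rows) + 1L]] <-
      data.frame(chrom = el$chrom[i], start = b0 * 10L, end = (b1 + 1L) * 10L)
    r <- rle(state)
    ends_r <- cumsum(r$lengths)
    starts_r <- ends_r - r$lengths + 1L
    truth_state_rows[[length(truth_state_rows) + 1L]] <-
      data.frame(element_id = el$element_id[i], chrom = el$chrom[i],
                 start = bins[starts_r] * 10L + 1L,
                 end = bins[pmin(ends_r, length(bins))] * 10L + 10L,
                 state = r$values)
  }

  # ---- ATAC-like accessibility signal --------------------------------------
  atac_val <- (el$fwd_total + el$rev_total + 1) * stats::runif(n_total, 0.8, 1.2)
  atac <- data.frame(chrom = el$chrom, start = el$ndr_start - 1L,
                     end = el$ndr_end, value = atac_val)
  atac <- atac[order(atac$chrom, atac$start), ]

  # ---- write the bundle -----------------------------------------------------
  paths <- list()
  wt <- function(df, file, digits = NULL) {
    p <- file.path(out_dir, file)
    if (!is.null(digits)) df$value <- sprintf(paste0("%.", digits, "f"), df$value)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    p
  }
  genome_set <- Biostrings::DNAStringSet(vapply(seqs, paste0, "",
                                                collapse = ""))
  names(genome_set) <- chroms
  paths$genome <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(genome_set, paths$genome)
  paths$peaks <- wt(data.frame(chrom = el$chrom, start = el$ndr_start - 1L,
                               end = el$ndr_end, name = el$element_id,
                               score = 0, strand = ".")[order(el$chrom, el$ndr_start), ],
                    "ndr_peaks.bed")
  prom <- el[el$class == "promoter", ]
  gene_start <- ifelse(prom$strand == "+", prom$fwd_tss,
                       prom$fwd_tss - cfg$gene_length + 1L)
  genes <- data.frame(chrom = prom$chrom, start = gene_start - 1L,
                      end = gene_start + cfg$gene_length - 1L,
                      name = sub("^el", "gene", prom$element_id), score = 0,
                      strand = prom$strand)
  paths$genes <- wt(genes[order(genes$chrom, genes$start), ], "genes.bed")
  paths$procap_plus <- file.path(out_dir, "procap_plus.bedgraph")
  paths$procap_minus <- file.path(out_dir, "procap_minus.bedgraph")
  write_stranded_bedgraph(track, paths$procap_plus, paths$procap_minus)
  paths$atac <- wt(atac, "atac.bedgraph", digits = 4)
  paths$mark_signals <- list()
  paths$mark_peaks <- list()
  for (m in marks) {
    df <- do.call(rbind, mark_rows[[m]])
    df <- df[order(df$chrom, df$start), ]
    paths$mark_signals[[m]] <- wt(df, paste0(m, ".bedgraph"), digits = 4)
    pdf <- do.call(rbind, peak_rows)
    pdf <- pdf[order(pdf$chrom, pdf$start), ]
    pdf$name <- "."; pdf$score <- 0; pdf$strand <- "."
    paths$mark_peaks[[m]] <- wt(pdf, paste0(m, "_peaks.bed"))
  }
  truth_states <- do.call(rbind, truth_state_rows)
  paths$truth <- file.path(out_dir, "truth.tsv")
  utils::write.table(el, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth_states <- file.path(out_dir, "truth_states.tsv")
  utils::write.table(truth_states, paths$truth_states, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(paths = paths, truth = el, truth_states = truth_states,
                 config = cfg, state_means = st_means, seed = seed))
}

#' Score inferred outputs against generator truth
#'
#' Joins inference results to the ground-truth table by element id and
#' computes per-stage recovery metrics: Set-B recall of truly divergent
#' elements, skewed/balanced classification accuracy and adjusted Rand
#' index, and correlations of predicted vs. true log2 ratios.
#'
#' @param truth Ground-truth data.frame from \code{\link{generate_dataset}}.
#' @param inferred data.frame with \code{element_id} and any of:
#'   \code{set_label}, \code{class} (skewed/balanced), \code{predicted}
#'   (predicted log2 ratio), \code{log_ratio} (measured log2 ratio).
#' @return data.frame with columns \code{metric}, \code{value}, \code{n}.
#' @export
truth_report <- function(truth, inferred) {
  if (!all(inferred$element_id %in% truth$element_id)) {
    stop("inferred element ids not present in truth")
  }
  m <- merge(truth, inferred, by = "element_id",
             suffixes = c("_truth", ""))
  rows <- list()
  add <- function(metric, value, n) {
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric, value = value,
                                             n = n)
  }
  if ("set_label" %in% names(inferred)) {
    div <- m[m$divergent, ]
    add("set_b_recall", mean(div$set_label == "B"), nrow(div))
  }
  if ("class" %in% names(inferred)) {
    ok <- !is.na(m$class)
    add("component_accuracy", mean(m$class[ok] == m$component[ok]), sum(ok))
    add("component_ari", adjusted_rand_index(m$class[ok], m$component[ok]),
        sum(ok))
  }
  if ("predicted" %in% names(inferred)) {
    ok <- is.finite(m$predicted)
    add("predicted_vs_true_cor", stats::cor(m$predicted[ok], m$true_ratio[ok]),
        sum(ok))
  }
  if ("log_ratio" %in% names(inferred)) {
    ok <- is.finite(m$log_ratio)
    add("measured_vs_true_cor", stats::cor(m$log_ratio[ok], m$true_ratio[ok]),
        sum(ok))
  }
  do.call(rbind, rows)
}
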