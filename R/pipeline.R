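# End-to-end orchestration: annotate -> tss-call -> seq-score -> chromhmm ->
# features -> direction-model, driven by a single config (list or YAML).
# Every stage writes plain TSV/BED intermediates into the output directory;
# a rerun with the same config and seed reproduces them byte-identically.

#' Default pipeline configuration for a generated bundle
#'
#' @param data_dir Directory written by \code{\link{generate_dataset}}.
#' @param out_dir Output directory for stage results.
#' @param seed Master seed; stage seeds are derived from it.
#' @return Config list accepted by \code{\link{run_all}}.
#' @export
default_run_config <- function(data_dir, out_dir, seed = 1L) {
  marks <- c("H3K4me3", "H3K4me1")
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    inputs = list(
      genome = file.path(data_dir, "genome.fa"),
      peaks = file.path(data_dir, "ndr_peaks.bed"),
      genes = file.path(data_dir, "genes.bed"),
      procap_plus = file.path(data_dir, "procap_plus.bedgraph"),
      procap_minus = file.path(data_dir, "procap_minus.bedgraph"),
      atac = file.path(data_dir, "atac.bedgraph"),
      mark_signals = stats::setNames(
        as.list(file.path(data_dir, paste0(marks, ".bedgraph"))), marks),
      mark_peaks = stats::setNames(
        as.list(file.path(data_dir, paste0(marks, "_peaks.bed"))), marks),
      truth = file.path(data_dir, "truth.tsv")),
    params = list(promoter_distance = 200L, extension = 75L, min_width = 50L,
                  quantile = 0.999, pseudocount = 0.5, flank = 50L,
                  n_states = 3L, bin_size = 10L, train_on = "chr1",
                  k_range = 1:4, folds = 10L, k4me3_mark = "H3K4me3",
                  coverage_flank = 1000L),
    stages = list(annotate = TRUE, tss = TRUE, seq = TRUE, chromatin = TRUE,
                  features = TRUE, models = TRUE))
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file with the structure of
#'   \code{\link{default_run_config}}.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$species)) {
    preset <- annotation_config(species = cfg$species)
    cfg$params$promoter_distance <- preset$promoter_distance
    if (is.null(cfg$params$quantile)) cfg$params$quantile <- preset$quantile
  }
  cfg
}

.need_file <- function(path, stage) {
  if (is.null(path) || !file.exists(path)) {
    stop(sprintf("stage '%s' requires missing file: %s", stage,
                 if (is.null(path)) "<unset>" else path), call. = FALSE)
  }
  path
}

.wtsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Transcript starts from gene/transcript spans
#'
#' @param genes \code{GRanges} of transcript bodies with strand.
#' @return Width-1 \code{GRanges} of transcript start positions.
#' @export
genes_to_tss <- function(genes) {
  str <- as.character(BiocGenerics::strand(genes))
  pos <- ifelse(str == "-", GenomicRanges::end(genes),
                GenomicRanges::start(genes))
  GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                         IRanges::IRanges(pos, pos), strand = str)
}

# max bedGraph value over a set of query intervals (1-based inclusive)
.region_max <- function(sig_split, chrom, start, end) {
  d <- sig_split[[chrom]]
  if (is.null(d)) return(0)
  hit <- d$start < end & d$end >= start   # d is 0-based half-open
  if (!any(hit)) return(0)
  max(d$value[hit])
}

#' Run the full directionality pipeline
#'
#' Executes, in dependency order: peak extension/merging and annotation; TSS
#' significance calling against the empirical downstream-window background
#' with Set A/B selection; core-promoter model training and per-strand
#' aggregate sequence scoring (with midpoint negative controls and 6-mer
#' asymmetry); chromatin-state segmentation; feature-table construction;
#' and the statistical models (ratio mixture + BIC, partial correlations,
#' mixture-of-regressions directionality model with 10-fold CV). When the
#' config points at a generator \code{truth.tsv}, recovery metrics are
#' appended to the summary.
#'
#' @param config A config list (see \code{\link{default_run_config}}) or a
#'   YAML path.
#' @return Invisibly, a list of in-memory stage results (paths in
#'   \code{$paths}, summary data.frame in \code{$summary}).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  p <- cfg$params
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  summary_rows <- list()
  note <- function(key, value) {
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(key = key, value = as.character(value))
  }
  res <- list()

  # ---- stage: annotate ------------------------------------------------------
  if (!isTRUE(cfg$stages$annotate)) stop("stage 'annotate' is required")
  message("[annotate] peaks: ", cfg$inputs$peaks)
  raw_peaks <- read_bed(.need_file(cfg$inputs$peaks, "annotate"))
  genes <- read_bed(.need_file(cfg$inputs$genes, "annotate"))
  merged <- extend_and_merge(raw_peaks, extension = p$extension,
                             min_width = p$min_width)
  # carry element ids through the merge for truth joins
  ov <- GenomicRanges::findOverlaps(merged, raw_peaks, ignore.strand = TRUE)
  ids <- tapply(raw_peaks$name[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov),
                function(x) paste(sort(x), collapse = ","))
  merged$name <- rep(".", length(merged))
  merged$name[as.integer(names(ids))] <- unname(ids)
  tss_ann <- genes_to_tss(genes)
  acfg <- annotation_config(promoter_distance = p$promoter_distance,
                            extension = p$extension)
  peaks <- annotate_peaks(merged, tss_ann, genes = genes, config = acfg)
  paths$annotated_peaks <- write_bed(
    GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                           IRanges::IRanges(GenomicRanges::start(peaks),
                                            GenomicRanges::end(peaks)),
                           name = paste0(peaks$name, "|", peaks$annotation)),
    file.path(cfg$out_dir, "annotated_peaks.bed"))
  note("n_peaks", length(peaks))
  note("n_promoter", sum(peaks$annotation == "promoter"))
  note("n_intergenic", sum(peaks$annotation == "intergenic"))
  note("n_bidirectional_removed", sum(peaks$annotation == "bidirectional-removed"))
  res$peaks <- peaks

  # ---- stage: tss -----------------------------------------------------------
  if (!isTRUE(cfg$stages$tss)) {
    stop("stage 'tss' is disabled but required by downstream stages")
  }
  message("[tss] 5'-end tracks")
  track <- read_stranded_bedgraph(.need_file(cfg$inputs$procap_plus, "tss"),
                                  .need_file(cfg$inputs$procap_minus, "tss"))
  records <- peak_tss_summary(peaks, track)
  with_signal <- peaks[records$fwd_total + records$rev_total > 0]
  control <- build_control_regions(with_signal, peaks)
  bg <- estimate_cutoff(track, control, quantile = p$quantile)
  records <- records[records$annotation != "bidirectional-removed", ]
  records <- select_sets(records, bg$cutoff)
  records$element_id <- records$peak_id
  paths$tss_summary <- .wtsv(records, file.path(cfg$out_dir, "tss_summary.tsv"))
  note("background_cutoff", bg$cutoff)
  note("n_set_A", sum(records$set_label %in% c("A", "B")))
  note("n_set_B", sum(records$set_label == "B"))
  res$records <- records
  res$background <- bg

  # ---- stage: seq -----------------------------------------------------------
  model <- NULL
  if (isTRUE(cfg$stages$seq)) {
    message("[seq] core-promoter model")
    genome <- read_genome(.need_file(cfg$inputs$genome, "seq"))
    setA <- records[records$set_label %in% c("A", "B") &
                      records$annotation == "promoter", ]
    # training windows read on the forward (gene) strand
    train_w <- character(0)
    for (ch in unique(setA$chrom)) {
      for (str in c("+", "-")) {
        d <- setA[setA$chrom == ch & setA$fwd_strand == str, ]
        if (nrow(d)) {
          train_w <- c(train_w,
                       extract_windows(genome, ch, d$fwd_mode, str, p$flank))
        }
      }
    }
    train_w <- train_w[!is.na(train_w)]
    model <- train_core_model(train_w, pseudocount = p$pseudocount,
                              flank = p$flank)
    setB <- records[records$set_label == "B", ]
    score_at <- function(d, centers, strands) {
      out <- rep(NA_real_, nrow(d))
      for (ch in unique(d$chrom)) for (str in c("+", "-")) {
        sel <- d$chrom == ch & strands == str & !is.na(centers)
        if (!any(sel)) next
        w <- extract_windows(genome, ch, centers[sel], str, p$flank)
        ok <- !is.na(w)
        out[sel][ok] <- score_window(model, w[ok])
      }
      out
    }
    rev_strand <- ifelse(setB$fwd_strand == "+", "-", "+")
    mid <- as.integer(round((setB$fwd_mode + setB$rev_mode) / 2))
    seqsc <- data.frame(element_id = setB$element_id,
                        fwd_tss_score = score_at(setB, setB$fwd_mode, setB$fwd_strand),
                        rev_tss_score = score_at(setB, setB$rev_mode, rev_strand),
                        mid_score_fwd = score_at(setB, mid, setB$fwd_strand))
    agg_fwd <- numeric(nrow(setB)); agg_rev <- numeric(nrow(setB))
    for (i in seq_len(nrow(setB))) {
      pk <- list(chrom = setB$chrom[i], start = setB$start[i], end = setB$end[i])
      agg_fwd[i] <- aggregate_sequence_feature(model, track, pk,
                                               setB$fwd_strand[i], genome)
      agg_rev[i] <- aggregate_sequence_feature(model, track, pk,
                                               rev_strand[i], genome)
    }
    seqsc$agg_seq_fwd <- agg_fwd
    seqsc$agg_seq_rev <- agg_rev
    paths$seq_scores <- .wtsv(seqsc, file.path(cfg$out_dir, "seq_scores.tsv"))
    # 6-mer asymmetry from 500 bp windows downstream of Set-B promoter TSSs
    setBp <- setB[setB$annotation == "promoter", ]
    down_win <- function(centers, strands) {
      out <- character(0)
      for (ch in unique(setBp$chrom)) for (str in c("+", "-")) {
        sel <- setBp$chrom == ch & strands == str
        if (!any(sel)) next
        s <- ifelse(str == "+", centers[sel] + 1L, centers[sel] - 500L)
        w <- substring(genome[[ch]], pmax(1L, s), pmax(1L, s) + 499L)
        if (str == "-") w <- .revcomp(w)
        out <- c(out, w[nchar(w) == 500L])
      }
      out
    }
    rev_strand_p <- ifelse(setBp$fwd_strand == "+", "-", "+")
    kmers <- kmer_asymmetry(down_win(setBp$fwd_mode, setBp$fwd_strand),
                            down_win(setBp$rev_mode, rev_strand_p))
    paths$kmer_asymmetry <- .wtsv(kmers[order(kmers$rank), ],
                                  file.path(cfg$out_dir, "kmer_asymmetry.tsv"))
    res$seq_scores <- seqsc
    res$core_model <- model
    res$kmers <- kmers
    note("n_training_windows", model$n_train)
    note("median_fwd_tss_score", round(stats::median(seqsc$fwd_tss_score, na.rm = TRUE), 4))
    note("median_midpoint_score", round(stats::median(seqsc$mid_score_fwd, na.rm = TRUE), 4))
  }

  # ---- stage: chromatin -----------------------------------------------------
  if (isTRUE(cfg$stages$chromatin)) {
    message("[chromatin] HMM segmentation")
    for (m in names(cfg$inputs$mark_signals)) {
      .need_file(cfg$inputs$mark_signals[[m]], "chromatin")
      .need_file(cfg$inputs$mark_peaks[[m]], "chromatin")
    }
    cmat <- preprocess_chromatin(cfg$inputs$mark_signals,
                                 cfg$inputs$mark_peaks,
                                 bin_size = p$bin_size)
    hmm <- fit_hmm(cmat, n_states = p$n_states, seed = cfg$seed + 1L,
                   train_on = p$train_on)
    seg <- decode(hmm, cmat)
    seg_gr <- segmentation_granges(seg)
    seg_gr$name <- seg_gr$state
    paths$segmentation <- write_bed(seg_gr,
                                    file.path(cfg$out_dir, "segmentation.bed"))
    emis <- data.frame(state = rownames(hmm$means), hmm$means,
                       check.names = FALSE)
    paths$state_means <- .wtsv(emis, file.path(cfg$out_dir, "state_means.tsv"))
    setB <- records[records$set_label == "B", ]
    anchors <- data.frame(chrom = setB$chrom,
                          pos = as.integer(round((setB$start + setB$end) / 2)),
                          strand = setB$fwd_strand)
    cov <- state_coverage(seg, anchors, flank = p$coverage_flank)
    paths$state_coverage <- .wtsv(
      data.frame(offset = as.integer(rownames(cov)), cov, check.names = FALSE),
      file.path(cfg$out_dir, "state_coverage.tsv"))
    res$chromatin <- cmat
    res$hmm <- hmm
    res$segmentation <- seg
    note("hmm_states", p$n_states)
    note("hmm_loglik", round(utils::tail(hmm$loglik_trace, 1), 2))
  }

  # ---- stage: features ------------------------------------------------------
  if (isTRUE(cfg$stages$features)) {
    if (!isTRUE(cfg$stages$seq)) stop("stage 'features' needs stage 'seq'")
    message("[features] directional feature table")
    raw_by_id <- stats::setNames(seq_along(raw_peaks), raw_peaks$name)
    atac_sig <- read_bedgraph(.need_file(cfg$inputs$atac, "features"))
    atac_split <- split(atac_sig, atac_sig$chrom)
    k4 <- read_bedgraph(.need_file(
      cfg$inputs$mark_signals[[p$k4me3_mark]], "features"))
    k4_split <- split(k4, k4$chrom)
    setB <- records[records$set_label == "B", ]
    sq <- res$seq_scores[match(setB$element_id, res$seq_scores$element_id), ]
    width <- setB$end - setB$start + 1L
    ft <- data.frame(element_id = setB$element_id,
                     annotation = setB$annotation,
                     fwd_rate = setB$fwd_total / width,
                     rev_rate = setB$rev_total / width,
                     fwd_seq = sq$agg_seq_fwd, rev_seq = sq$agg_seq_rev,
                     dp_fwd = setB$dp_fwd, dp_rev = setB$dp_rev,
                     log_ratio = setB$log_ratio)
    atac_max <- numeric(nrow(setB)); k4_fwd <- numeric(nrow(setB))
    k4_rev <- numeric(nrow(setB))
    for (i in seq_len(nrow(setB))) {
      # non-extended peak boundaries for accessibility and flank maxima
      ri <- raw_by_id[[setB$element_id[i]]]
      rs <- GenomicRanges::start(raw_peaks)[ri]
      re <- GenomicRanges::end(raw_peaks)[ri]
      ch <- setB$chrom[i]
      atac_max[i] <- .region_max(atac_split, ch, rs, re)
      if (setB$fwd_strand[i] == "+") {
        k4_fwd[i] <- .region_max(k4_split, ch, re + 1L, re + 1000L)
        k4_rev[i] <- .region_max(k4_split, ch, rs - 1000L, rs - 1L)
      } else {
        k4_fwd[i] <- .region_max(k4_split, ch, rs - 1000L, rs - 1L)
        k4_rev[i] <- .region_max(k4_split, ch, re + 1L, re + 1000L)
      }
    }
    ft$atac_max <- atac_max
    ft$k4me3_fwd <- k4_fwd
    ft$k4me3_rev <- k4_rev
    paths$features <- .wtsv(ft, file.path(cfg$out_dir, "features.tsv"))
    res$features <- ft
  }

  # ---- stage: models --------------------------------------------------------
  if (isTRUE(cfg$stages$models)) {
    if (!isTRUE(cfg$stages$features)) stop("stage 'models' needs stage 'features'")
    message("[models] mixtures, partial correlations, CV")
    ft <- res$features
    # 1-D ratio mixture with BIC over promoters with significant forward TSS
    ratios <- records$log_ratio[records$set_label %in% c("A", "B") &
                                  records$annotation == "promoter"]
    sel <- select_k(ratios, K_range = p$k_range, n_init = 5L,
                    seed = cfg$seed + 2L)
    paths$ratio_mixture <- .wtsv(
      data.frame(K = as.integer(names(sel$bic)), bic = sel$bic),
      file.path(cfg$out_dir, "ratio_mixture_bic.tsv"))
    note("selected_k", sel$best_k)
    # partial correlations over the directional features
    num <- ft[, c("fwd_rate", "rev_rate", "fwd_seq", "rev_seq", "dp_fwd",
                  "dp_rev", "atac_max", "k4me3_fwd", "k4me3_rev")]
    pc <- partial_correlation(num)
    paths$partial_cor <- .wtsv(data.frame(feature = rownames(pc), pc,
                                          check.names = FALSE),
                               file.path(cfg$out_dir, "partial_correlations.tsv"))
    # directionality predictor: sequence-score difference (already on a log
    # scale) and log2 pseudo-counted H3K4me3 flank ratio
    prom <- ft[ft$annotation == "promoter", ]
    X <- cbind(seq_ratio = prom$fwd_seq - prom$rev_seq,
               k4me3_ratio = log2((prom$k4me3_fwd + 1) / (prom$k4me3_rev + 1)))
    y <- prom$log_ratio
    mix <- fit_mixture_linear(X, y, K = 2L, n_init = 10L,
                              seed = cfg$seed + 3L)
    pred <- predict_directionality(mix, X, y = y)
    pred_df <- data.frame(element_id = prom$element_id,
                          log_ratio = y, predicted = pred$predicted,
                          component = pred$component, class = pred$class)
    paths$direction_predictions <- .wtsv(pred_df,
      file.path(cfg$out_dir, "direction_predictions.tsv"))
    cv <- cross_validate(X, y, K = 2L, folds = p$folds,
                         seed = cfg$seed + 4L, n_init = 5L)
    paths$cv <- .wtsv(cv$per_fold, file.path(cfg$out_dir, "cv_report.tsv"))
    for (j in seq_len(nrow(cv$summary))) {
      note(paste0("cv_mean_cor_", cv$summary$feature_set[j]),
           round(cv$summary$cor[j], 4))
    }
    note("predicted_vs_measured_cor", round(stats::cor(pred$predicted, y), 4))
    res$mixlm <- mix
    res$predictions <- pred_df
    res$cv <- cv
    res$ratio_mixture <- sel
    # recovery metrics against generator truth when available
    if (!is.null(cfg$inputs$truth) && file.exists(cfg$inputs$truth)) {
      truth <- utils::read.delim(cfg$inputs$truth)
      inf <- merge(records[, c("element_id", "set_label", "log_ratio")],
                   pred_df[, c("element_id", "predicted", "class")],
                   by = "element_id", all.x = TRUE)
      tr <- truth_report(truth, inf)
      paths$truth_report <- .wtsv(tr, file.path(cfg$out_dir, "truth_report.tsv"))
      for (j in seq_len(nrow(tr))) note(tr$metric[j], round(tr$value[j], 4))
      res$truth_report <- tr
    }
  }

  summary <- do.call(rbind, summary_rows)
  paths$summary <- .wtsv(summary, file.path(cfg$out_dir, "summary.tsv"))
  res$summary <- summary
  res$paths <- paths
  invisible(res)
}
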