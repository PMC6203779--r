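# divtx — transcription initiation directionality at promoters and enhancers

Most eukaryotic regulatory regions can initiate transcription in both
orientations from a shared nucleosome-depleted region (NDR), each direction
from its own core promoter. **divtx** quantifies this *initiation
directionality* — the log2 ratio of forward to reverse nascent-RNA 5'-end
counts — and models how core-promoter sequence and flanking histone
modifications explain it. It is aimed at regulatory-genomics analysts
working with PRO-cap/GRO-cap-style 5'-end data, ATAC-seq peaks, and
histone-mark ChIP tracks.

The package implements, as tested reusable components:

* **TSS significance calling** against an empirical gene-body background:
  control windows placed downstream of each peak on both strands, an
  empirical per-base 5'-end distribution (zeros included), and a quantile
  cutoff (default 0.999); peaks are classed into **Set A** (significant
  forward initiation) and **Set B** (significant divergent initiation, with
  convergent TSS pairs filtered out).
* **TSS shape**: the DP score, the Shannon entropy
  `DP = −Σ pᵢ log₂ pᵢ` of the per-base 5'-end distribution over
  read-carrying positions (low = focused, high = dispersed), and the
  pseudo-counted directionality ratio `log₂((f+1)/(r+1))`.
* A **position-specific first-order core-promoter model** over ±50 bp
  TSS-centered windows, scored as a log2 likelihood ratio against a
  zero-order background, with NDR midpoints as matched negative controls;
  per-strand aggregate sequence features; local-background **motif
  scanning**; **6-mer forward/reverse asymmetry** tables; GC%/GC-skew
  profiles.
* A **tied-transition multivariate Gaussian HMM** over peak-masked,
  log-scaled, 10-bp-binned histone-mark signal (0.9 self-transition,
  0.1/(n−1) otherwise, never re-estimated; Baum–Welch over emissions and
  initial probabilities; posterior decoding; state coverage profiles
  around oriented anchors).
* **Spearman partial correlations** over directional feature tables, a
  **1-D Gaussian mixture with BIC component selection** for ratio
  distributions, and a **two-component mixture of linear regressions**
  predicting directionality from the sequence-score and H3K4me3
  forward/reverse contrasts, with 10-fold cross-validation over feature
  subsets.
* A **synthetic-data generator** emitting a coherent bundle (FASTA genome,
  NDR/gene BEDs, stranded per-base bedGraphs, mark tracks and peaks) with
  planted ground truth for every stage, and a one-call pipeline
  `run_all()`.

See `vignettes/directionality-methods.Rmd` for the models, assumptions,
parameter defaults, and known limitations.

## Worked example

Generate the default synthetic bundle (4 × 500 kb genome, 600 promoters,
200 enhancers) and run the full pipeline:

```r
library(divtx)
generate_dataset("sim", sim_config(), seed = 7)
res <- run_all(default_run_config("sim", "run", seed = 7))
print(res$summary, row.names = FALSE)
```

which prints (about half a minute in total):

```
                      key     value
                  n_peaks       800
               n_promoter       600
             n_intergenic       200
  n_bidirectional_removed         0
        background_cutoff         1
                  n_set_A       800
                  n_set_B       799
       n_training_windows       600
     median_fwd_tss_score    4.7765
    median_midpoint_score   -5.3354
               hmm_states         3
               hmm_loglik -65925.64
               selected_k         2
         cv_mean_cor_both    0.2777
  cv_mean_cor_k4me3_ratio    0.2399
    cv_mean_cor_seq_ratio    0.1619
predicted_vs_measured_cor       0.9
             set_b_recall         1
       component_accuracy    0.9667
            component_ari    0.8706
    predicted_vs_true_cor    0.9004
     measured_vs_true_cor    0.9929
```

Reading the output: all 800 NDRs pass the forward cutoff (Set A) and 799
qualify as divergent (Set B); the trained core-promoter model separates
true TSS windows (median score +4.8 bits) from NDR-midpoint negative
controls (−5.3 bits); BIC selects two components for the ratio
distribution (`selected_k`); and the two-component regression mixture
recovers the planted skewed/balanced classes with 96.7% accuracy
(adjusted Rand 0.87) while its explanatory predictions correlate 0.90 with
the planted true ratios. The `cv_mean_cor_*` rows are the strictly
out-of-sample 10-fold correlations, with both features together beating
either feature alone.

Per-stage tables (`tss_summary.tsv`, `seq_scores.tsv`,
`kmer_asymmetry.tsv`, `segmentation.bed`, `features.tsv`,
`partial_correlations.tsv`, `direction_predictions.tsv`, `cv_report.tsv`,
`truth_report.tsv`) are written into the output directory; a rerun with
the same seed reproduces them byte-identically.

Individual components work standalone, e.g.:

```r
dp_score(c(3, 1))              # DP = 0.8113 bits over 2 positions
directionality_ratio(63, 15)   # log2(64/16) = 2
```

A thin command-line wrapper is installed at
`inst/scripts/divtx.R` (`simulate`, `run-all`, `annotate` subcommands).

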