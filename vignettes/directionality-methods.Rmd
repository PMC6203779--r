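---
title: "Quantifying transcription initiation directionality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription initiation directionality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divtx)
```

# The problem

Most eukaryotic regulatory regions sit inside a nucleosome-depleted region
(NDR) and can initiate transcription in both orientations, each direction
from its own core promoter. The *directionality* of a region is the ratio of
forward to reverse initiation — forward meaning the annotated gene's strand
at promoters and the higher-count strand at enhancers. divtx quantifies
directionality from stranded nascent-RNA 5'-end counts (PRO-cap/GRO-cap
style data), relates it to core-promoter sequence and to flanking histone
modifications, and asks how well those features predict it.

The pipeline runs in six stages: NDR annotation, TSS significance calling,
core-promoter sequence scoring, chromatin-state segmentation, feature
assembly, and statistical modelling. A synthetic-data generator with full
ground truth exercises every stage.

# Coordinate conventions

All files on disk follow the BED convention (0-based, half-open). All
in-memory containers are `GRanges` and therefore 1-based inclusive, the
Bioconductor convention; conversion happens only inside the readers and
writers. "Downstream" of a minus-strand feature means decreasing
coordinates; a single strand-aware window helper implements this so that
every module treats orientation identically.

# TSS significance calling

Nascent-RNA 5'-end libraries carry a low-rate background of non-TSS signal
inside gene bodies (incomplete cap selection, degradation products). Rather
than assume a parametric error model, the significance cutoff is estimated
empirically: for every NDR peak with at least one read, two control windows
of the peak's own width are placed immediately downstream of the peak with
respect to each strand, overlaps with any peak are subtracted out, and the
empirical distribution of 5'-ends per base — zero bases included, both
strands pooled — is accumulated over all control windows. The cutoff is the
distribution's empirical quantile (type-1: the smallest observed value
whose cumulative frequency reaches the target), floored at one read so an
all-zero background never admits everything. The quantile defaults to
0.999; 0.9999 is the recommended preset for deeply sequenced human-scale
data.

Two peak sets follow. **Set A**: the forward-strand modal base (the base
with the most 5'-ends; ties resolve to the 5'-most position with respect to
the strand) reaches the cutoff. **Set B**: both strands' modal bases reach
the cutoff *and* the pair is divergent. A pair is convergent — and removed —
when each mode lies downstream of the other with respect to its own strand,
i.e. the two initiation events point at each other; such pairs are gene-end
or internal artefacts, not divergent promoters.

Two quantities summarise each region:

* the **DP (distribution pattern) score**, the Shannon entropy
  $-\sum_i p_i \log_2 p_i$ of the per-base 5'-end distribution over the
  positions carrying at least one read: 0 for perfectly focused initiation,
  $\log_2 n$ for initiation spread evenly over $n$ positions;
* the **directionality ratio** $\log_2\frac{f+1}{r+1}$ over the forward and
  reverse strand totals; the pseudocount keeps the ratio defined at zero
  coverage and shrinks extreme low-depth ratios.

# Core-promoter sequence model

A position-specific first-order Markov model is trained on the ±50 bp
windows around Set-A forward modes: for each of the 101 positions, the
probability of each base conditioned on the preceding base (the first
position uses its marginal), with a pseudocount (default 0.5) on every
transition count and N bases excluded. A window is scored as the log2
likelihood ratio of this positional chain against the zero-order base
composition of the training windows. Midpoints between the forward and
reverse TSS serve as matched negative controls: they share the NDR's
accessibility and composition but no initiation site.

The per-strand aggregate *sequence feature* of a peak scores a window
around every base with at least one 5'-end on that strand, sums the scores
and divides by peak width — a sequence-weighted measure of how much of the
strand's initiation is supported by core-promoter-like sequence.

Design notes: the background is zero-order and taken from the training
windows (a first-order genome-wide background would absorb part of the
signal the model should capture); windows that overlap a chromosome edge
are dropped in training and contribute zero in aggregation; positions whose
base or predecessor is N contribute zero.

Motif scanning is deliberately separate from the trained model: a
probability PWM is scored log-odds against the base composition of a 100 bp
window centered on each candidate occurrence (one pseudo-observation per
base avoids zeros), and scores below zero are clipped to zero. The local
background makes a TATA-like hit inside a GC-rich context score higher
than the same hit inside an AT-rich context, which is the behaviour wanted
when comparing motif strength across heterogeneous regions.

Sequence asymmetry around divergent TSSs is summarised by counting
overlapping 6-mers in 500 bp windows downstream of forward and of reverse
TSSs and ranking 6-mers by the pseudo-counted forward/reverse occurrence
ratio, and by positional GC% and GC-skew $(g-c)/(g+c)$ profiles in sliding
50 bp windows (windows with no G or C return skew 0 with a warning).

# Chromatin-state segmentation

Histone-mark signal is reduced to 10 bp bins: per-bin mean signal, zeroed
wherever the bin midpoint falls outside that mark's peak calls (only
peak-supported signal is informative; the rest is background), then
log(x+1)-transformed so read-count-like values are roughly Gaussian. Bins
where every mark is zero are discarded and the remainder forms contiguous
segments.

States are learned with a multivariate Gaussian hidden Markov model whose
transition matrix is *tied*: 0.9 on the diagonal and 0.1/(n−1) elsewhere,
and never re-estimated. The tying acts as a smoothness prior at 10 bp
resolution and removes the transition matrix from the optimisation;
Baum-Welch therefore updates only the per-state emission means, variances
(diagonal covariance by default — full covariance is rarely stable at this
resolution and mark count) and the initial state probabilities. Only
segments of at least 500 bp enter training, and a `train_on` filter allows
training on a chromosome subset while decoding genome-wide. Segmentation
uses posterior decoding (per-bin argmax of the forward–backward
posteriors), not Viterbi: per-bin marginal accuracy is what the coverage
profiles consume.

Numerical choices: k-means initialisation of the means on a subsample of
bins under a fixed seed (identical seeds give bit-identical fits); variance
floor 1e-3; a state that loses all responsibility is re-seeded at a random
data point with a warning; convergence at relative log-likelihood
improvement below 1e-6 or 100 iterations. The forward–backward recursions
run in lockstep across segments (matrices of segments × states); shorter
segments are padded with unit emission densities, which leaves their
likelihood and posteriors exactly unchanged because the tied transition
rows sum to one.

The number of states is user-set (default 11, in line with published
chromatin-state maps over six-mark panels; the synthetic pipeline uses the
generator's three planted states). State labels are reported as ranked
emission-mean tables; biological naming is left to the user.

# Directional features and statistical models

For each Set-B region the feature table records, per direction: the
initiation rate (strand total / peak width), the aggregate sequence score,
the DP score, the maximum accessibility signal inside the non-extended
peak, and the maximum H3K4me3 signal in the 1 kb flank downstream
(forward) or upstream (reverse) of the non-extended peak.

**Ratio mixture.** The distribution of directionality ratios is modelled
with 1-D Gaussian mixtures of unequal variances; the number of components
is chosen by BIC, $-2\ln L + p\ln n$ with $p = 3K-1$, minimised over K
(ties to the smaller K). A two-component answer corresponds to distinct
balanced and skewed regulatory regimes.

**Partial correlations.** Pairwise Spearman partial correlations given all
other features: columns are rank-transformed, and the partial correlation
is read off the inverse rank-correlation matrix,
$\rho_{ij\cdot\text{rest}} = -P_{ij}/\sqrt{P_{ii}P_{jj}}$; a singular
matrix falls back to the pseudoinverse with a warning. Rank-based partial
correlations are invariant under monotone feature transforms, which
matters because rates, entropies and log-ratios live on very different
scales.

**Directionality model.** The measured log2 ratio is regressed on two
predictors — the forward/reverse contrast of the aggregate sequence score
and of the H3K4me3 flank maxima — with a two-component mixture of linear
regressions fitted by EM (responsibilities from the component densities;
weighted least squares per component; predictors standardised internally,
the response untouched; best of 10 seeded restarts, half of them
initialised from soft splits along the response, which is the natural
starting point for a bimodal ratio distribution). The component with the
larger mean absolute fitted ratio is labelled *skewed*, the other
*balanced*.

The sequence predictor is the *difference* of the forward and reverse
aggregate scores rather than a pseudo-counted ratio: the aggregate score
is itself a signed log-likelihood-ratio density, so a difference is the
log-scale contrast, whereas a ratio of signed quantities is undefined. The
H3K4me3 predictor is $\log_2\frac{\text{fwd}+1}{\text{rev}+1}$ of the
flank maxima.

Two distinct uses of the fitted mixture must not be conflated:

* *classification* of regions into skewed/balanced uses the explanatory
  assignment — responsibilities computed from the full densities including
  the measured ratio;
* *prediction* of held-out ratios in cross-validation never sees the
  response: the mixing-weight-averaged component prediction is used.
  Assigning held-out points with their measured response would leak it
  into the "prediction" (on pure noise it manufactures a correlation of
  about 0.4); with the weight-averaged predictor the null correctly gives
  zero.

Ten-fold cross-validation reports the per-fold correlation of predicted
and measured ratios for three feature sets — both predictors, sequence
only, H3K4me3 only — so the contribution of each feature class can be
compared.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
a scale where the whole pipeline runs in well under a minute: 4
chromosomes × 500 kb of i.i.d. 40% GC sequence, 600 promoters and 200
enhancers on a jittered grid with 1 kb mark flanks and 1.5 kb gene bodies.
Per element:

* the true log2 ratio comes from a two-component Gaussian mixture
  (balanced N(0.8, 0.7²) with weight 0.6, skewed N(4.0, 1.0²) with weight
  0.4);
* the forward total is negative binomial (mean 1000 for promoters, ×0.3
  for enhancers, dispersion 0.3) and the reverse total is Poisson around
  forward × 2^(−ratio);
* per-base TSS profiles are Dirichlet-multinomial over ±10 bp around each
  TSS with a per-element concentration (log-uniform on 0.1–10) that
  controls the DP score; the reverse TSS sits upstream of the forward TSS
  within the NDR (divergent geometry);
* a TATA-like element (TATAAA starting at −31) and an Inr-like element
  (TCAGTT with the A at the TSS) are planted with probabilities 0.5 and
  0.9; motif degeneracy decreases with the strand's depth rank
  (per-base mutation up to 0.45), with element-level jitter;
* GTGAGT, the 5' splice-site consensus, is planted in the first 500 bp of
  gene bodies at five times its background expectation, giving the 6-mer
  asymmetry analysis a planted positive;
* histone tracks are emitted from three planted states (NDR, upstream −1
  nucleosome, downstream +1 nucleosome) with Gaussian log-signal;
  downstream-vs-upstream H3K4me3 is additionally shifted by 0.10–0.15 ×
  the centred true ratio plus an element-level asymmetry noise (sd 0.7);
* gene bodies receive sense-strand background 5'-ends at a configurable
  contamination rate (default 0.05/base), which is what the control-window
  background model has to defeat.

Two calibration choices deserve emphasis. First, sequencing depth is high
enough that the set of read-carrying bases saturates on both strands;
otherwise the aggregate sequence feature mechanically encodes the count
ratio through its support size rather than through sequence. Second, the
coupling and noise defaults deliberately make the features *moderately*
informative proxies of directionality — cross-validated predictive
correlations in the 0.6–0.9 band rather than ~1 — matching the regime
reported for real promoter data (~0.65–0.69). If the features mediated the
class-level ratio difference completely, the two regulatory regimes would
collapse into a single regression relationship and no mixture model (ours
or any other) could recover them; the residual, feature-independent part
of the class difference is what makes the skewed/balanced mixture
identifiable.

What the generator does **not** emulate: realistic nucleotide composition
(no isochores, CpG islands or repeats), read-level noise (5'-end counts
are drawn directly), replicate structure, copy-number or mappability
artefacts, and distance-dependent chromatin correlations beyond the HMM's
geometric run lengths. Passing tests on this generator therefore
demonstrate correctness of the implementations and recoverability of
planted structure, not performance on real libraries.

# Problem sizes used in the checks

The packaged checks run the generator at its default scale (800 elements,
2 Mb) for the end-to-end pipeline; 300 all-motif promoters over 0.9 Mb for
the sequence-model discrimination check (elements without any planted
motif are indistinguishable from background by construction, so the
discrimination population is the planted-motif one); 200 segments × 100
bins for HMM recovery; n = 2000 for the regression-mixture and
component-selection studies. These sizes make every stochastic check
stable across seeds while keeping a full run of the suite inside a few
minutes.

# Known limitations

* The convergent-pair filter uses modal bases only; a region with a
  convergent mode but substantial divergent secondary initiation is still
  excluded from Set B.
* The empirical cutoff assumes the gene-body background downstream of
  peaks is representative of background inside peaks.
* With diagonal emission covariance, strongly covarying marks can split
  one biological state into two; the full-covariance flag trades that
  against stability.
* The mixture of regressions assumes Gaussian residuals on the log2 ratio
  scale; heavy-tailed measured ratios (very low reverse counts) are
  shrunk by the pseudocount but not modelled.
* BIC component selection is consistent but conservative at small n;
  with fewer than ~10·K observations per candidate K the selection is not
  trustworthy.
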