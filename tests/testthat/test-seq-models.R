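plant <- function(seqs, motif, at, prob = 1) {
  set.seed(123)
  hit <- runif(length(seqs)) < prob
  substr(seqs[hit], at, at + nchar(motif) - 1L) <- motif
  seqs
}

test_that("core model training learns planted transitions and normalises", {
  set.seed(11)
  win <- vapply(1:300, function(i) random_dna(101), "")
  win <- plant(win, "TATAAA", 21, prob = 0.7)  # offset -30 from the center
  m <- train_core_model(win)
  # conditional distributions sum to 1 for every (position, previous base)
  for (p in c(2, 21, 60, 101)) {
    expect_equal(unname(rowSums(m$cond[p, , ])), rep(1, 4), tolerance = 1e-12)
  }
  expect_equal(sum(m$background), 1, tolerance = 1e-12)
  # planted T->A transitions enriched > 2x over background at motif positions
  expect_gt(m$cond[22, "T", "A"] / m$background["A"], 2)
  expect_gt(m$cond[24, "T", "A"] / m$background["A"], 2)

  # wrong-length windows are dropped with a warning
  expect_warning(m2 <- train_core_model(c(win, "ACGT")), "dropped")
  expect_equal(m2$n_train, 300L)
})

test_that("a degenerate model scores its own training sequence maximally", {
  set.seed(2)
  s <- random_dna(101)
  m <- train_core_model(rep(s, 60), pseudocount = 0.1)
  self <- score_window(m, s)
  others <- score_window(m, vapply(1:200, function(i) random_dna(101), ""))
  expect_true(all(self > others))
})

test_that("scores are near zero on background-matched sequences and symmetric", {
  set.seed(4)
  train <- vapply(1:2000, function(i) random_dna(101, gc = 0.5), "")
  m <- train_core_model(train)
  sc <- score_window(m, vapply(1:400, function(i) random_dna(101, gc = 0.5), ""))
  # null expectation ~ 0 over 101 positions (small negative finite-sample
  # bias from the estimated transition tables)
  expect_lt(abs(mean(sc)), 1.5)
  expect_error(score_window(m, "ACGT"), "length")

  # strand symmetry: reverse-complement-trained model on reverse-complemented
  # input reproduces the forward score (exact up to edge-marginal terms,
  # which vanish for composition-balanced training data)
  m_rc <- train_core_model(divtx:::.revcomp(train))
  test <- vapply(1:50, function(i) random_dna(101, gc = 0.5), "")
  expect_equal(score_window(m_rc, divtx:::.revcomp(test)),
               score_window(m, test), tolerance = 0.5)
})

test_that("aggregate sequence feature equals the brute-force windowed sum", {
  set.seed(9)
  genome <- list(chr1 = random_dna(2000))
  m <- train_core_model(vapply(1:100, function(i) random_dna(101), ""))
  peak <- list(chrom = "chr1", start = 801, end = 1000)
  # no reads -> 0
  expect_equal(aggregate_sequence_feature(m, make_track(), peak, "+", genome), 0)
  # one read base -> score / width
  tr1 <- make_track(plus = data.frame(chrom = "chr1", pos = 900, count = 3))
  w <- substr(genome$chr1, 850, 950)
  expect_equal(aggregate_sequence_feature(m, tr1, peak, "+", genome),
               score_window(m, w) / 200)
  # three read bases on the minus strand match the brute-force sum
  pos <- c(850, 900, 951)
  tr3 <- make_track(minus = data.frame(chrom = "chr1", pos = pos, count = 1))
  manual <- sum(score_window(m, divtx:::.revcomp(
    substring(genome$chr1, pos - 50, pos + 50)))) / 200
  expect_equal(aggregate_sequence_feature(m, tr3, peak, "-", genome), manual)
})

test_that("motif scanning is background-corrected, zero-clipped, and localises", {
  consensus_pwm <- function(motif) {
    b <- strsplit(motif, "")[[1]]
    p <- matrix(0.02, length(b), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    p[cbind(seq_along(b), match(b, c("A", "C", "G", "T")))] <- 0.94
    p
  }
  pwm <- consensus_pwm("TATAAA")
  set.seed(21)
  seq <- random_dna(300, gc = 0.5)
  substr(seq, 150, 155) <- "TATAAA"
  sc <- scan_motif(pwm, seq)
  expect_equal(which.max(sc), 150L)
  expect_gt(sc[150], 0)
  expect_equal(sum(sc == max(sc)), 1L)

  # uniform PWM scores 0 after clipping wherever the background window is
  # composition-uniform (interior positions of a cyclic ACGT sequence)
  upwm <- matrix(0.25, 6, 4)
  usc <- scan_motif(upwm, strrep("ACGT", 50))
  expect_equal(usc[60:130], rep(0, 71))
  # sequence shorter than the motif -> empty
  expect_length(scan_motif(pwm, "ACG"), 0L)

  # hand-computed background correction: identical TATAAA occurrence scores
  # higher in a GC-rich context than in an AT-rich one
  at_ctx <- paste0(strrep("AT", 25), "TATAAA", strrep("TA", 25))
  gc_ctx <- paste0(strrep("GC", 25), "TATAAA", strrep("CG", 25))
  s_at <- scan_motif(pwm, at_ctx)[51]
  s_gc <- scan_motif(pwm, gc_ctx)[51]
  expect_gt(s_gc, s_at)
  # oracle for the GC context, bg window = centered 100 bp with +1 pseudo
  # counts: 6 motif bases (T,A,T,A,A,A) among 94 G/C -> bg A = (4+1)/104,
  # bg T = (2+1)/104
  expect_equal(s_gc, 4 * log2(0.94 / (5 / 104)) + 2 * log2(0.94 / (3 / 104)),
               tolerance = 1e-10)
})

test_that("k-mer asymmetry counts overlap, ranks enrichment, and is symmetric", {
  # identical window sets -> all ratios 1
  w <- c("ACGTACGTAC", "GGGTTTAAAC")
  tab <- kmer_asymmetry(w, w, k = 6)
  expect_true(all(tab$ratio == 1))
  expect_equal(nrow(tab), 4^6)
  expect_equal(sort(tab$rank), 1:4^6)
  # total k-mer count equals sum(window_length - k + 1)
  expect_equal(sum(tab$fwd), sum(nchar(w) - 6 + 1))

  # hand-countable single pair
  t2 <- kmer_asymmetry("AAAAAAAAAA", "CCCCCCCCCC", k = 6)
  expect_equal(t2$fwd[t2$kmer == "AAAAAA"], 5)
  expect_equal(t2$rev[t2$kmer == "CCCCCC"], 5)
  expect_equal(t2$ratio[t2$kmer == "AAAAAA"], 6)
  expect_equal(t2$rank[t2$kmer == "AAAAAA"], 1L)

  # planted 5x enrichment is recovered in the top ranks
  set.seed(31)
  fwd <- vapply(1:100, function(i) random_dna(500), "")
  for (i in seq_along(fwd)) {
    at <- sample(490, 2)
    substr(fwd[i], at[1], at[1] + 5) <- "GTGAGT"
    substr(fwd[i], at[2], at[2] + 5) <- "GTGAGT"
  }
  rev <- vapply(1:100, function(i) random_dna(500), "")
  t3 <- kmer_asymmetry(fwd, rev)
  expect_lte(t3$rank[t3$kmer == "GTGAGT"], 5L)
})

test_that("GC profiles follow the sliding-window skew definition", {
  g <- gc_profiles(strrep("G", 60))
  expect_true(all(g$gc_percent == 100))
  expect_true(all(g$gc_skew == 1))
  c_ <- gc_profiles(strrep("C", 60))
  expect_true(all(c_$gc_skew == -1))
  alt <- gc_profiles(strrep("GC", 30))
  expect_true(all(alt$gc_skew == 0))
  # window with g = 3, c = 1 -> skew 0.5
  reg <- paste0("GGGC", strrep("A", 46))
  expect_equal(gc_profiles(reg)$gc_skew, 0.5)
  expect_equal(gc_profiles(reg)$gc_percent, 8)
  # no G or C in the window -> skew 0 with a warning
  expect_warning(z <- gc_profiles(strrep("A", 50)), "skew")
  expect_equal(z$gc_skew, 0)
})
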