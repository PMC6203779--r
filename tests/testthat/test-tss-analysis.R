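test_that("control regions flank peaks on both sides minus peak overlap", {
  peaks <- make_gr("chr1", 101, 200)  # BED chr1:100-200
  ctrl <- build_control_regions(peaks, peaks)
  # + window downstream (higher coords), - window downstream (lower coords)
  expect_identical(base_set(ctrl, "chr1"), c(1:100, 201:300))

  # control window fully inside another peak contributes nothing
  all_pk <- c(peaks, make_gr("chr1", 201, 320))
  ctrl2 <- build_control_regions(peaks, all_pk)
  expect_identical(base_set(ctrl2, "chr1"), 1:100)

  # property: subtraction equals the per-base set oracle
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    s <- sort(sample(500:9000, n))
    e <- pmin(9800, s + sample(50:400, n, replace = TRUE))
    pk <- GenomicRanges::reduce(make_gr("chr1", s, e))
    sig <- pk[sample(length(pk), max(1, length(pk) - 1))]
    ctrl <- build_control_regions(sig, pk)
    oracle <- integer(0)
    for (i in seq_along(sig)) {
      w <- GenomicRanges::width(sig)[i]
      st <- GenomicRanges::start(sig)[i]; en <- GenomicRanges::end(sig)[i]
      oracle <- c(oracle, seq(max(1, st - w), st - 1),
                  seq(en + 1, en + w))
    }
    oracle <- setdiff(sort(unique(oracle)), base_set(pk, "chr1"))
    expect_identical(base_set(ctrl, "chr1"), as.integer(oracle))
  }
})

test_that("estimate_cutoff equals the sort-based empirical quantile with floor 1", {
  # 1000 control bases, ten of them with 5 reads, quantile 0.999 -> cutoff 5
  ctrl <- make_gr("chr1", 1, 500)  # 500 bases x 2 strands = 1000
  tr <- make_track(plus = data.frame(chrom = "chr1", pos = 1:10, count = 5))
  bg <- estimate_cutoff(tr, ctrl, 0.999)
  expect_equal(bg$cutoff, 5)
  expect_equal(bg$n, 1000)

  # all-zero background floors at 1
  expect_equal(estimate_cutoff(make_track(), ctrl, 0.5)$cutoff, 1)
  expect_error(estimate_cutoff(tr, ctrl, 1.2), "quantile")
  expect_error(estimate_cutoff(tr, GenomicRanges::GRanges(), 0.9), "empty")

  # property: exact agreement with quantile(type = 1) on random instances
  set.seed(99)
  for (rep in 1:30) {
    len <- sample(50:400, 1)
    ctrl <- make_gr("chr1", 1, len)
    npos <- sample(0:len, 1)
    plus <- if (npos > 0)
      data.frame(chrom = "chr1", pos = sample(len, npos),
                 count = rgeom(npos, 0.3) + 1) else NULL
    tr <- make_track(plus = plus)
    q <- runif(1, 0.5, 0.9995)
    full <- rep(0, 2 * len)
    if (npos > 0) full[seq_len(npos)] <- plus$count
    expect_equal(estimate_cutoff(tr, ctrl, q)$cutoff,
                 max(1, unname(quantile(full, q, type = 1))))
  }

  # large-n geometric background matches the oracle exactly
  set.seed(1)
  len <- 50000  # 1e5 strand-bases
  counts <- rgeom(2 * len, 0.5)
  plus <- data.frame(chrom = "chr1", pos = 1:len, count = counts[1:len])
  minus <- data.frame(chrom = "chr1", pos = 1:len,
                      count = counts[(len + 1):(2 * len)])
  tr <- make_track(plus = plus[plus$count > 0, ], minus = minus[minus$count > 0, ])
  expect_equal(estimate_cutoff(tr, make_gr("chr1", 1, len), 0.9999)$cutoff,
               max(1, unname(quantile(counts, 0.9999, type = 1))))
})

test_that("set selection applies the cutoff and removes convergent pairs only", {
  rec <- function(fwd_strand, fwd_mode, rev_mode, fwd_cnt = 20, rev_cnt = 18) {
    data.frame(fwd_strand = fwd_strand, fwd_mode = fwd_mode,
               rev_mode = rev_mode, fwd_mode_count = fwd_cnt,
               rev_mode_count = rev_cnt)
  }
  cutoff <- 14
  # forward only above cutoff -> A
  expect_equal(select_sets(rec("+", 150, 120, 20, 0), cutoff)$set_label, "A")
  # both above, reverse mode upstream of forward -> divergent -> B
  expect_equal(select_sets(rec("+", 150, 120), cutoff)$set_label, "B")
  # both above, reverse mode downstream of forward -> convergent -> excluded
  conv <- select_sets(rec("+", 120, 150), cutoff)
  expect_equal(conv$set_label, "A")
  expect_true(conv$convergent)
  # geometry oracle over the four orientation cases
  expect_equal(select_sets(rec("-", 150, 120), cutoff)$set_label, "A")  # convergent
  expect_equal(select_sets(rec("-", 120, 150), cutoff)$set_label, "B")  # divergent
  # below cutoff on both -> none
  expect_equal(select_sets(rec("+", 150, 120, 5, 3), cutoff)$set_label, "none")
})

test_that("DP score is Shannon entropy over read-carrying positions", {
  expect_equal(dp_score(c(4, 4, 4, 4))$value, 2)
  expect_equal(dp_score(10)$value, 0)
  expect_equal(dp_score(c(3, 1))$value,
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-12)
  expect_error(dp_score(c(0, 0)), "positive")
  expect_error(dp_score(-1), "non-negative")
  # zeros are excluded from the support
  expect_equal(dp_score(c(0, 5, 0, 5))$n_positions, 2L)

  # permutation invariance and maximality of the uniform profile
  set.seed(3)
  for (rep in 1:10) {
    x <- rpois(8, 4) + 1
    expect_equal(dp_score(sample(x))$value, dp_score(x)$value)
    expect_lte(dp_score(x)$value, log2(length(x)) + 1e-12)
  }
})

test_that("directionality ratio is the pseudo-counted log2 ratio and antisymmetric", {
  expect_equal(directionality_ratio(100, 100), 0)
  expect_equal(directionality_ratio(0, 0), 0)
  expect_equal(directionality_ratio(63, 15), 2)
  expect_error(directionality_ratio(-1, 5), ">= 0")
  set.seed(5)
  f <- rpois(50, 20); r <- rpois(50, 5)
  expect_equal(directionality_ratio(f, r), -directionality_ratio(r, f))
})

test_that("peak summary records totals, 5'-most tie-broken modes, and forward strand", {
  peaks <- make_gr("chr1", 101, 300)
  peaks$annotation <- "promoter"; peaks$gene_strand <- "+"; peaks$name <- "p1"
  tr <- make_track(
    plus = data.frame(chrom = "chr1", pos = c(200, 210, 220), count = c(7, 7, 2)),
    minus = data.frame(chrom = "chr1", pos = c(150, 160), count = c(3, 3)))
  s <- peak_tss_summary(peaks, tr)
  expect_equal(s$fwd_total, 16)
  expect_equal(s$rev_total, 6)
  expect_equal(s$fwd_mode, 200)      # tie -> 5'-most on +
  expect_equal(s$rev_mode, 160)      # tie -> 5'-most on - (highest coord)
  expect_equal(s$log_ratio, log2(17 / 7))
  # enhancer: forward is the higher-count strand
  peaks$annotation <- "intergenic"; peaks$gene_strand <- NA
  tr2 <- make_track(
    plus = data.frame(chrom = "chr1", pos = 200, count = 2),
    minus = data.frame(chrom = "chr1", pos = 150, count = 9))
  s2 <- peak_tss_summary(peaks, tr2)
  expect_equal(s2$fwd_strand, "-")
  expect_equal(s2$fwd_total, 9)
})
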