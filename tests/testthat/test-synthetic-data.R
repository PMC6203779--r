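small_cfg <- function(...) {
  sim_config(n_promoters = 30, n_enhancers = 10,
             chrom_lengths = stats::setNames(rep(60000L, 4), paste0("chr", 1:4)),
             ...)
}

test_that("identical seeds give byte-identical bundles", {
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  generate_dataset(d1, small_cfg(), seed = 42)
  generate_dataset(d2, small_cfg(), seed = 42)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed changes the data
  d3 <- file.path(tempdir(), "sim_c")
  generate_dataset(d3, small_cfg(), seed = 43)
  expect_false(all(unname(tools::md5sum(list.files(d3, full.names = TRUE))) ==
                     unname(tools::md5sum(f1))))
})

test_that("emitted bedGraph column sums equal the drawn totals exactly", {
  d <- file.path(tempdir(), "sim_sums")
  out <- generate_dataset(d, small_cfg(contamination_rate = 0), seed = 5)
  tr <- read_stranded_bedgraph(out$paths$procap_plus, out$paths$procap_minus)
  expect_equal(sum(divtx:::track_totals(tr)),
               sum(out$truth$fwd_total) + sum(out$truth$rev_total))
  # per-strand: forward totals sit on the element's orientation strand
  plus_expected <- sum(out$truth$fwd_total[out$truth$strand == "+"]) +
    sum(out$truth$rev_total[out$truth$strand == "-"])
  expect_equal(unname(divtx:::track_totals(tr)["plus"]), plus_expected)
})

test_that("outputs round-trip through the i/o layer unchanged", {
  d <- file.path(tempdir(), "sim_rt")
  out <- generate_dataset(d, small_cfg(), seed = 6)
  peaks <- read_bed(out$paths$peaks)
  idx <- match(peaks$name, out$truth$element_id)
  expect_equal(GenomicRanges::start(peaks), out$truth$ndr_start[idx])
  expect_equal(GenomicRanges::end(peaks), out$truth$ndr_end[idx])
  tr <- read_stranded_bedgraph(out$paths$procap_plus, out$paths$procap_minus)
  p2 <- tempfile(); m2 <- tempfile()
  write_stranded_bedgraph(tr, p2, m2)
  expect_identical(readLines(p2), readLines(out$paths$procap_plus))
  expect_identical(readLines(m2), readLines(out$paths$procap_minus))
  # genome is a valid FASTA of the configured lengths
  g <- read_genome(out$paths$genome)
  expect_equal(unname(nchar(g)), rep(60000L, 4))
})

test_that("planted TSS geometry is divergent and motifs sit where configured", {
  d <- file.path(tempdir(), "sim_geom")
  out <- generate_dataset(d, small_cfg(motif_mut_max = 0, tata_prob = 1,
                                       inr_prob = 1),
                          seed = 9)
  tr <- out$truth
  # reverse TSS upstream of forward TSS with respect to the gene strand
  expect_true(all(ifelse(tr$strand == "+", tr$rev_tss < tr$fwd_tss,
                         tr$rev_tss > tr$fwd_tss)))
  g <- read_genome(out$paths$genome)
  i <- which(tr$strand == "+")[1]
  win <- substr(g[[tr$chrom[i]]], tr$fwd_tss[i] - 50, tr$fwd_tss[i] + 50)
  expect_equal(substr(win, 51 - 31, 51 - 26), "TATAAA")  # start offset -31
  expect_equal(substr(win, 51 - 2, 51 + 3), "TCAGTT")    # Inr A at the TSS
  j <- which(tr$strand == "-")[1]
  winm <- divtx:::.revcomp(substr(g[[tr$chrom[j]]], tr$fwd_tss[j] - 50,
                                  tr$fwd_tss[j] + 50))
  expect_equal(substr(winm, 51 - 31, 51 - 26), "TATAAA")
})

test_that("drawn log-ratios converge to the configured mixture", {
  cfg <- sim_config(n_promoters = 4000, n_enhancers = 1000,
                    chrom_lengths = stats::setNames(rep(1400000L, 10),
                                                    paste0("chr", 1:10)))
  d <- file.path(tempdir(), "sim_ks")
  out <- generate_dataset(d, cfg, seed = 1)
  pmixture <- function(q) {
    w <- cfg$mixture_weights
    w["balanced"] * pnorm(q, cfg$mixture_means["balanced"],
                          cfg$mixture_sds["balanced"]) +
      w["skewed"] * pnorm(q, cfg$mixture_means["skewed"],
                          cfg$mixture_sds["skewed"])
  }
  ks <- suppressWarnings(ks.test(out$truth$true_ratio, pmixture))
  expect_lt(unname(ks$statistic), 0.05)
  # single-component truth collapses the mixture
  cfg1 <- small_cfg(mixture_weights = c(balanced = 1, skewed = 0))
  out1 <- generate_dataset(file.path(tempdir(), "sim_one"), cfg1, seed = 2)
  expect_true(all(out1$truth$component == "balanced"))
})

test_that("infeasible configurations are rejected", {
  cfg <- sim_config(n_promoters = 500, n_enhancers = 100,
                    chrom_lengths = c(chr1 = 50000L))
  expect_error(generate_dataset(tempdir(), cfg, seed = 1), "fit")
})

test_that("truth_report metrics match hand computation on a toy example", {
  truth <- data.frame(element_id = paste0("el_", 1:5),
                      component = c("skewed", "skewed", "balanced",
                                    "balanced", "balanced"),
                      true_ratio = c(4, 3, 1, 0.5, 0),
                      divergent = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  perfect <- data.frame(element_id = paste0("el_", 1:5),
                        set_label = c("B", "B", "B", "B", "A"),
                        class = truth$component,
                        predicted = truth$true_ratio)
  r <- truth_report(truth, perfect)
  expect_equal(r$value[r$metric == "set_b_recall"], 1)
  expect_equal(r$value[r$metric == "component_accuracy"], 1)
  expect_equal(r$value[r$metric == "component_ari"], 1)
  expect_equal(r$value[r$metric == "predicted_vs_true_cor"], 1)
  expect_equal(r$n[r$metric == "set_b_recall"], 4)  # only divergent elements

  # one wrong set label and one wrong class, computed by hand
  partial <- perfect
  partial$set_label[1] <- "A"          # recall 3/4
  partial$class[3] <- "skewed"         # accuracy 4/5
  r2 <- truth_report(truth, partial)
  expect_equal(r2$value[r2$metric == "set_b_recall"], 0.75)
  expect_equal(r2$value[r2$metric == "component_accuracy"], 0.8)

  # shuffled class labels fall to chance-level ARI
  set.seed(30)
  big <- data.frame(element_id = sprintf("el_%03d", 1:200),
                    component = sample(c("skewed", "balanced"), 200, TRUE),
                    true_ratio = rnorm(200), divergent = TRUE)
  shuffled <- data.frame(element_id = big$element_id,
                         class = sample(big$component))
  r3 <- truth_report(big, shuffled)
  expect_lt(abs(r3$value[r3$metric == "component_ari"]), 0.15)
  expect_error(truth_report(truth,
                            data.frame(element_id = "nope", class = "skewed")),
               "ids")
})
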