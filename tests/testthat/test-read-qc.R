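# Five-rule QC: trimming cap, per-rule thresholds, pair-aware co-removal,
# and exact agreement with the generator's defect labels.

test_that("3' trimming removes the trailing low-quality run, capped at 29", {
  base <- rdna(150, seed = 1)
  q29 <- paste0(phred_chr(35, 121), phred_chr(10, 29))
  tr <- trim_3prime_lowq(base, q29)
  expect_equal(nchar(tr$seq), 121)
  expect_equal(tr$trimmed, 29)

  # run of 40: cap applies, 11 low-quality bases remain for rule 2
  q40 <- paste0(phred_chr(35, 110), phred_chr(10, 40))
  tr40 <- trim_3prime_lowq(base, q40)
  expect_equal(nchar(tr40$seq), 121)
  qc <- filter_pairs(fix_pair(base, q40, base, phred_chr(35, 150)))
  expect_equal(qc$report$decision[1], "kept")  # 11 < 30 after trimming

  q_all <- phred_chr(30, 150)
  tr_id <- trim_3prime_lowq(base, q_all)
  expect_identical(tr_id$seq, base)
  expect_equal(tr_id$trimmed, 0)
})

test_that("ambiguous-base and low-quality rules use the stated thresholds", {
  base <- rdna(150, seed = 2)
  two_n <- paste0("N", substr(base, 2, 80), "N", substr(base, 82, 150))
  qc <- filter_pairs(fix_pair(two_n))
  expect_equal(qc$report$decision[1], "discarded_ambiguous")

  one_n <- paste0("N", substr(base, 2, 150))
  qc1 <- filter_pairs(fix_pair(one_n))
  expect_equal(qc1$report$decision[1], "kept")

  # exactly 30 interior bases at Q19 (3' end high): discarded by rule 2
  q30 <- paste0(phred_chr(35, 10), phred_chr(19, 30), phred_chr(35, 110))
  qc2 <- filter_pairs(fix_pair(base, q30))
  expect_equal(qc2$report$decision[1], "discarded_lowq")
  # 29 low-quality bases: kept
  q29 <- paste0(phred_chr(35, 10), phred_chr(19, 29), phred_chr(35, 111))
  qc3 <- filter_pairs(fix_pair(base, q29))
  expect_equal(qc3$report$decision[1], "kept")
})

test_that("adapter and host discards take the mate down too", {
  host <- fix_host()
  base <- rdna(150, seed = 3)
  adap <- paste0(substr(base, 1, 120), substr(default_adapter(), 1, 30))
  qc <- filter_pairs(fix_pair(adap, NULL, base, NULL))
  expect_equal(qc$report$decision, c("discarded_adapter", "discarded_mate"))
  expect_equal(nrow(qc$kept), 0)

  host_read <- substr(host$sequences[[1]], 501, 650)
  qc2 <- filter_pairs(fix_pair(host_read, NULL, base, NULL), host = host)
  expect_equal(qc2$report$decision, c("discarded_host", "discarded_mate"))

  # ambiguous discard only orphans the mate into the singleton stream
  two_n <- paste0("NN", substr(base, 3, 150))
  qc3 <- filter_pairs(fix_pair(two_n, NULL, base, NULL))
  expect_equal(qc3$report$decision, c("discarded_ambiguous", "kept"))
  expect_equal(qc3$report$stream, c("none", "singleton"))
  expect_equal(nrow(qc3$singletons), 1)
})

test_that("QC decisions equal generator defect labels exactly", {
  g <- generate_genomes(4, c(6000, 9000), plasmid_prob = 0.3, seed = 23)
  host <- fix_host()
  ab <- setNames(rep(0.25, 4), unique(g$metadata$species[g$metadata$source]))
  rr <- simulate_reads(g, ab, 800,
                       defect_rates = c(ambiguous = 0.06, low_quality = 0.06,
                                        adapter = 0.06, host = 0.06),
                       host_genome = host, seed = 29)
  qc <- filter_pairs(rr$pairs, host = host)
  m <- merge(rr$labels, qc$report, by = c("pair_id", "mate"))
  map <- c(ambiguous = "discarded_ambiguous", low_quality = "discarded_lowq",
           adapter = "discarded_adapter", host = "discarded_host")
  ok <- ifelse(m$defect == "clean",
               m$decision %in% c("kept", "discarded_mate"),
               m$decision == map[m$defect])
  expect_equal(sum(!ok), 0)
  # kept + discarded partition the input
  expect_equal(nrow(qc$kept) * 2 + nrow(qc$singletons) +
                 sum(qc$report$stream == "none"), 2 * nrow(rr$pairs))
})

test_that("QC is idempotent on its own kept output", {
  g <- generate_genomes(3, c(5000, 7000), plasmid_prob = 0, seed = 37)
  host <- fix_host()
  ab <- setNames(rep(1 / 3, 3), unique(g$metadata$species[g$metadata$source]))
  rr <- simulate_reads(g, ab, 400,
                       defect_rates = c(ambiguous = 0.05, low_quality = 0.05,
                                        adapter = 0.05, host = 0.05),
                       host_genome = host, seed = 41)
  qc1 <- filter_pairs(rr$pairs, host = host)
  qc2 <- filter_pairs(qc1$kept, host = host)
  expect_identical(as.data.frame(qc2$kept), as.data.frame(qc1$kept))
  expect_true(all(qc2$report$decision == "kept"))
  expect_true(all(qc2$report$trimmed_bases == 0))
})
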