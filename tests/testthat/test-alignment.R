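# Desk-scale aligner: exactness on planted substrings, all-hits semantics,
# false-positive control, agreement with a brute-force oracle, and the
# external-format readers.

test_that("a verbatim substring yields exactly one perfect hit", {
  tgt <- c(t1 = rdna(3000, seed = 51), t2 = rdna(3000, seed = 52))
  idx <- alignment_index(tgt, k = 16)
  read <- substr(tgt[["t1"]], 501, 650)
  h <- align_reads(c(r1 = read), idx, min_score = 50, max_evalue = 1e-5)
  expect_equal(nrow(h), 1)
  expect_equal(h$target_id, "t1")
  expect_equal(h$identity, 1)
  expect_equal(h$raw_score, 150)

  # reverse-complement reads are found on the other strand
  hrc <- align_reads(c(r1 = equimeta:::revcomp(read)), idx,
                     min_score = 50, max_evalue = 1e-5)
  expect_equal(hrc$target_id, "t1")
  expect_equal(hrc$strand, -1)
})

test_that("all_hits reports duplicate targets and is a superset of best_hit", {
  a <- rdna(2000, seed = 53)
  idx <- alignment_index(c(t1 = a, t2 = a, t3 = rdna(2000, seed = 54)),
                         k = 16)
  read <- substr(a, 101, 250)
  all_h <- align_reads(c(r = read), idx, mode = "all_hits",
                       min_score = 50, max_evalue = 1e-5)
  best_h <- align_reads(c(r = read), idx, mode = "best_hit",
                        min_score = 50, max_evalue = 1e-5)
  expect_setequal(all_h$target_id, c("t1", "t2"))
  expect_equal(nrow(best_h), 1)
  expect_true(all(paste(best_h$read_id, best_h$target_id) %in%
                    paste(all_h$read_id, all_h$target_id)))
})

test_that("random reads against an unrelated 1 Mb target rarely pass 1e-5", {
  tgt <- c(big = rdna(1e6, seed = 55))
  idx <- alignment_index(tgt, k = 16)
  reads <- vapply(1:200, function(i) rdna(150, seed = 500 + i), character(1))
  names(reads) <- paste0("r", 1:200)
  h <- align_reads(reads, idx, min_score = 0, max_evalue = 1e-5)
  expect_lte(length(unique(h$read_id)), 2)  # >= 99% of trials hit-free
})

test_that("aligner agrees with the brute-force sliding-window oracle", {
  targets <- c(t1 = rdna(1200, seed = 61), t2 = rdna(1200, seed = 62))
  idx <- alignment_index(targets, k = 12)
  set.seed(63)
  for (i in 1:6) {
    src <- sample(names(targets), 1)
    start <- sample(1000, 1)
    read <- substr(targets[[src]], start, start + 99)
    # up to 3 scattered substitutions
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      pos <- sample(100, nmut)
      for (p in pos) {
        old <- substr(read, p, p)
        substr(read, p, p) <- setdiff(c("A", "C", "G", "T"), old)[sample(3, 1)]
      }
    }
    h <- align_reads(setNames(read, "r"), idx, min_score = 30,
                     max_evalue = 1, min_identity = 0.9)
    orc <- oracle_align(read, targets, min_identity = 0.9)
    orc <- orc[vapply(orc, function(b) b$score >= 30, logical(1))]
    expect_setequal(h$target_id, names(orc))
    for (tn in h$target_id)
      expect_equal(h$raw_score[h$target_id == tn], orc[[tn]]$score)
  }
})

test_that("six-frame protein search finds spiked genes from DNA reads", {
  g <- generate_genomes(2, c(6000, 8000), plasmid_prob = 0, seed = 65)
  s <- spike_genes(g, 0, 2, seed = 9)
  ann <- s$cazy_catalog$annotation[1, ]
  read <- substr(s$genomes$sequences[[ann$host_accession]],
                 ann$start + 3, ann$start + 152)
  idx <- alignment_index(s$cazy_catalog$sequences, alphabet = "protein")
  h <- align_reads(setNames(read, "r"), idx)
  h <- h[h$score > 60 & h$evalue < 1e-5, ]
  expect_equal(unique(h$target_id), ann$gene_id)
  expect_equal(max(h$identity), 1)
})

test_that("external m8 and SAM hits are normalized faithfully", {
  m8 <- tempfile()
  writeLines(c("r1\tg1\t99.0\t100\t1\t0\t1\t100\t5\t104\t1e-20\t180",
               "r2\tg2\t95.0\t80\t4\t0\t1\t80\t1\t80\t1e-6\t60.0"), m8)
  h <- read_external_hits(m8, "blast_m8")
  expect_equal(h$score, c(180, 60))
  expect_equal(h$evalue, c(1e-20, 1e-6))
  # strict "more than 60": the 60.0-bit hit is excluded downstream
  merged <- merge_mate_hits(h, h[0, ], min_score = 60)
  expect_equal(merged$gene_id, "g1")

  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(read_external_hits(empty, "blast_m8")), 0)

  badm8 <- tempfile()
  writeLines("r1\tg1\tonly-three-fields", badm8)
  expect_error(read_external_hits(badm8, "blast_m8"), "line 1")

  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@SQ\tSN:chr1\tLN:1000",
               paste0("r1\t0\tchr1\t100\t42\t10M\t*\t0\t0\t",
                      "ACGTACGTAC\tFFFFFFFFFF\tAS:i:48"),
               "r2\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\tFFFFFFFFFF"), sam)
  hs <- read_external_hits(sam, "sam")
  expect_equal(nrow(hs), 1)  # unmapped record dropped
  expect_equal(hs$read_id, "r1")
  expect_equal(hs$score, 48)
})

test_that("degenerate aligner inputs error clearly", {
  expect_error(alignment_index(character(0)), "empty")
  expect_error(alignment_index(c("ACGT", "GGGG")), "unique names")
})
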