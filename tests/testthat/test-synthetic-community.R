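# Ground-truth generator: determinism, invariants, and the statistical
# structure the downstream stages rely on.

test_that("genome generation is deterministic and respects its contracts", {
  g1 <- generate_genomes(3, c(5000, 8000), plasmid_prob = 0.5, seed = 7)
  g2 <- generate_genomes(3, c(5000, 8000), plasmid_prob = 0.5, seed = 7)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$metadata, g2$metadata)

  g0 <- generate_genomes(4, c(5000, 8000), plasmid_prob = 0, seed = 3)
  expect_false(any(g0$metadata$replicon == "plasmid"))

  # stored GC equals GC recomputed from the sequence
  gc <- equimeta:::gc_fraction_of(g1$sequences)
  expect_equal(unname(gc), g1$metadata$gc_fraction, tolerance = 1e-12)
  expect_equal(unname(nchar(g1$sequences)), g1$metadata$length_bp)

  # 1-4 records per species, plasmids attached to an existing parent
  per_sp <- table(g1$metadata$species[g1$metadata$replicon != "plasmid"])
  expect_true(all(per_sp >= 1 & per_sp <= 4))
  plas <- g1$metadata[g1$metadata$replicon == "plasmid", ]
  expect_true(all(plas$parent %in% g1$metadata$accession))

  expect_error(generate_genomes(0), "n_species")
  expect_error(generate_genomes(3, c(10, 20)), "length_range")
})

test_that("spiked genes are verbatim substrings and catalogs reproducible", {
  g <- generate_genomes(4, c(6000, 9000), plasmid_prob = 0.5, seed = 11)
  s1 <- spike_genes(g, 4, 5, seed = 5)
  s2 <- spike_genes(g, 4, 5, seed = 5)
  expect_identical(s1$arg_catalog$sequences, s2$arg_catalog$sequences)
  expect_identical(s1$cazy_catalog$sequences, s2$cazy_catalog$sequences)

  all_dna <- c(s1$arg_catalog$sequences, s1$cazy_catalog$dna)
  for (i in seq_len(nrow(s1$spiked_genes))) {
    tr <- s1$spiked_genes[i, ]
    expect_identical(
      substr(s1$genomes$sequences[[tr$accession]], tr$start, tr$end),
      unname(all_dna[[tr$gene_id]]))
  }
  # annotations carry phenotype / family labels
  expect_true(all(nzchar(s1$arg_catalog$annotation$phenotype)))
  expect_true(all(grepl("^(GH|GT|PL|CE|AA|CBM)[0-9]+$",
                        s1$cazy_catalog$annotation$family)))
  expect_equal(s1$cazy_catalog$annotation$length_aa,
               nchar(s1$cazy_catalog$sequences),
               ignore_attr = TRUE)

  s0 <- spike_genes(g, 0, 0, seed = 1)
  expect_length(s0$arg_catalog$sequences, 0)
  expect_identical(s0$genomes$sequences, g$sequences)

  expect_error(
    spike_genes(generate_genomes(1, c(1000, 1100), 0, seed = 2),
                1, 0, seed = 2, arg_length_range = c(2000, 2000)),
    "longer than")
})

test_that("design generator plants recoverable effects and sums to one", {
  species <- sprintf("sp%02d", 1:12)
  cohorts <- data.frame(habitat = c("domestic", "feral"),
                        site = c("A", "B"), n = c(20, 20))
  eff <- list(list(species = "sp03", variable = "habitat", level = "feral",
                   fold = 4))
  d1 <- generate_design(species, cohorts, eff, seed = 42)
  d2 <- generate_design(species, cohorts, eff, seed = 42)
  expect_identical(d1$design, d2$design)
  expect_identical(d1$abundance, d2$abundance)

  expect_equal(unname(rowSums(d1$abundance)), rep(1, 40), tolerance = 1e-9)

  feral <- d1$design$habitat == "feral"
  ratio <- mean(d1$abundance[feral, "sp03"]) /
    mean(d1$abundance[!feral, "sp03"])
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)

  d0 <- generate_design(species, cohorts, list(), seed = 1)
  expect_equal(nrow(d0$signal), 0)

  expect_error(generate_design(species,
                               data.frame(habitat = "domestic",
                                          site = "A", n = 4)),
               "2 habitats")
})

test_that("read simulator: clean runs survive QC and pairing is preserved", {
  g <- generate_genomes(3, c(5000, 8000), plasmid_prob = 0, seed = 13)
  ab <- setNames(rep(1 / 3, 3),
                 unique(g$metadata$species[g$metadata$source]))
  rr <- simulate_reads(g, ab, 300, defect_rates = c(), seed = 4)
  expect_true(all(rr$labels$defect == "clean"))
  expect_equal(nrow(rr$labels), 2 * nrow(rr$pairs))
  qc <- filter_pairs(rr$pairs, host = fix_host())
  expect_equal(nrow(qc$kept), 300)
  expect_true(all(qc$report$decision == "kept"))

  r2 <- simulate_reads(g, ab, 300, defect_rates = c(), seed = 4)
  expect_identical(rr$pairs, r2$pairs)

  expect_error(simulate_reads(g, ab, 10,
                              defect_rates = c(ambiguous = 0.9, host = 0.2)),
               "sum")
})

test_that("single-species reads profile back to that species", {
  g <- generate_genomes(4, c(8000, 12000), plasmid_prob = 0, seed = 17,
                        max_variants = 1)
  sp <- unique(g$metadata$species[g$metadata$source])
  ab <- setNames(c(1, 0, 0, 0), sp)
  rr <- simulate_reads(g, ab, 400, seed = 6)
  cur <- curate_genomes(g)
  res <- profile_sample(rr$pairs, cur$kept,
                        profiler_config(n_pairs_per_subsample = 400,
                                        n_repeats = 1), seed = 1)
  est <- res$profile[setdiff(names(res$profile), "unassigned")]
  expect_gt(est[[sp[1]]] / sum(est), 0.99)
})

test_that("pair base arithmetic and FASTQ round trip", {
  expect_identical(total_bases(15e6, 150), 4.5e9)
  g <- generate_genomes(2, c(5000, 6000), plasmid_prob = 0, seed = 19)
  ab <- setNames(c(0.5, 0.5), unique(g$metadata$species[g$metadata$source]))
  rr <- simulate_reads(g, ab, 50, read_len = 150, seed = 2)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq_pairs(rr$pairs, f1, f2)
  back <- read_fastq_pairs(f1, f2)
  expect_identical(back$seq1, rr$pairs$seq1)
  expect_identical(back$qual2, rr$pairs$qual2)
  expect_true(all(nchar(back$seq1) == 150, nchar(back$seq2) == 150))
})
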