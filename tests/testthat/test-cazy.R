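# CAZy profiling: merge semantics, fractional splitting, length
# adjustment, family counting and pathway grouping.

mk_hits <- function(read_id, target_id, score = 100, evalue = 1e-10) {
  data.frame(read_id = read_id, target_id = target_id, score = score,
             evalue = evalue, stringsAsFactors = FALSE)
}

test_that("mate hits merge as a filtered union", {
  m <- merge_mate_hits(mk_hits("p1", "g1"), mk_hits("p1", "g2"))
  expect_setequal(m$gene_id, c("g1", "g2"))

  # strict thresholds: score exactly 60 and evalue exactly 1e-5 excluded
  m2 <- merge_mate_hits(mk_hits("p1", "g1", score = 60),
                        mk_hits("p1", "g2", evalue = 1e-5))
  expect_equal(nrow(m2), 0)
  m3 <- merge_mate_hits(mk_hits("p1", "g1", score = 60.01),
                        mk_hits("p1", "g2", evalue = 0.99e-5))
  expect_equal(nrow(m3), 2)

  # both mates hitting the same gene count once
  m4 <- merge_mate_hits(mk_hits("p1", "g1"), mk_hits("p1", "g1"))
  expect_equal(nrow(m4), 1)
})

test_that("fractional splitting and gene-length adjustment", {
  cat3 <- data.frame(gene_id = c("g1", "g2", "g3"),
                     family = c("GT2", "GH3", "GH5"),
                     length_aa = c(300, 300, 300))
  ph <- data.frame(pair_id = "p1", gene_id = c("g1", "g2", "g3"))
  fa <- fractional_family_abundance(ph, cat3, relative = FALSE,
                                    length_adjust = FALSE)
  expect_equal(unname(fa[c("GT2", "GH3", "GH5")]), rep(1 / 3, 3))

  # 100 aa vs 200 aa, one unique read each: 2:1 after length adjustment
  cat2 <- data.frame(gene_id = c("a", "b"), family = c("GH2", "GH31"),
                     length_aa = c(100, 200))
  ph2 <- data.frame(pair_id = c("p1", "p2"), gene_id = c("a", "b"))
  fa2 <- fractional_family_abundance(ph2, cat2, relative = FALSE)
  expect_equal(unname(fa2[["GH2"]] / fa2[["GH31"]]), 2)

  # weight conservation before adjustment
  set.seed(7)
  pairs <- sprintf("p%03d", 1:50)
  ph3 <- do.call(rbind, lapply(pairs, function(p)
    data.frame(pair_id = p,
               gene_id = sample(cat3$gene_id, sample(1:3, 1)))))
  fa3 <- fractional_family_abundance(ph3, cat3, relative = FALSE)
  expect_equal(sum(attr(fa3, "gene_weights")), 50)

  # splitting one gene's reads over two same-length genes of one family
  # leaves the family abundance unchanged
  cat_dup <- data.frame(gene_id = c("x1", "x2"), family = c("GT4", "GT4"),
                        length_aa = c(150, 150))
  one <- fractional_family_abundance(
    data.frame(pair_id = paste0("p", 1:6), gene_id = "x1"),
    cat_dup, relative = FALSE)
  split2 <- fractional_family_abundance(
    data.frame(pair_id = paste0("p", 1:6),
               gene_id = rep(c("x1", "x2"), 3)),
    cat_dup, relative = FALSE)
  expect_equal(one[["GT4"]], split2[["GT4"]])

  expect_error(
    fractional_family_abundance(data.frame(pair_id = "p", gene_id = "nope"),
                                cat3), "missing from the catalog")
})

test_that("family counting and pathway groups", {
  cat_ <- data.frame(gene_id = c("g1", "g2", "g3"),
                     family = c("GT2", "GT2", "GT35"),
                     length_aa = c(100, 100, 100))
  expect_equal(count_cazy_families(data.frame(pair_id = character(0),
                                              gene_id = character(0)), cat_),
               0L)
  expect_equal(count_cazy_families(
    data.frame(pair_id = c("p1", "p2"), gene_id = c("g1", "g2")), cat_), 1L)

  map <- c(GT35 = "starch_glycogen", GH5 = "cellulose")
  pg <- pathway_group_abundance(c(GT35 = 1), map)
  expect_equal(unname(pg["starch_glycogen"]), 1)
  expect_equal(unname(pg["cellulose"]), 0)
  expect_message(pg0 <- pathway_group_abundance(c(GT2 = 1), c()), "other")
  expect_equal(unname(pg0), c(0, 0))

  # swapping starch and cellulose reads swaps the group values
  a <- pathway_group_abundance(c(GT35 = 0.7, GH5 = 0.3), map)
  b <- pathway_group_abundance(c(GT35 = 0.3, GH5 = 0.7), map)
  expect_equal(unname(a["starch_glycogen"]), unname(b["cellulose"]))
})

test_that("spiked families are all recovered at adequate depth", {
  g <- generate_genomes(3, c(15000, 20000), plasmid_prob = 0, seed = 91)
  s <- spike_genes(g, 0, 7, seed = 13,
                   cazy_length_range = c(600, 900))
  sp <- unique(g$metadata$species[g$metadata$source])
  ab <- setNames(rep(1 / 3, 3), sp)
  rr <- simulate_reads(s$genomes, ab, 2500, seed = 15)
  res <- cazy_profile_sample(rr$pairs, s$cazy_catalog)
  n_spiked <- length(unique(s$cazy_catalog$annotation$family))
  expect_equal(res$n_families, n_spiked)
  gw <- attr(res$family_abundance, "gene_weights")
  expect_equal(sum(gw), length(unique(res$pair_hits$pair_id)))
})
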