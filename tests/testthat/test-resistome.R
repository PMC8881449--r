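# Resistome abundance and the co-assignment network.

arg_cat <- data.frame(
  gene_id = c("tetQ_01", "tetW_02", "lnuC_03"),
  phenotype = c("tetracycline", "tetracycline", "lincosamide"),
  mechanism = c("ribosomal protection", "ribosomal protection",
                "nucleotidyltransferase"),
  length_bp = c(900, 900, 600), stringsAsFactors = FALSE)

test_that("ARG abundance: empty, single-gene, and ratio cases", {
  none <- arg_abundance(data.frame(pair_id = character(0),
                                   gene_id = character(0)), arg_cat)
  expect_equal(none$n_args, 0L)
  expect_true(all(none$gene_abundance == 0))

  only_q <- arg_abundance(data.frame(pair_id = paste0("p", 1:5),
                                     gene_id = "tetQ_01"), arg_cat)
  expect_equal(unname(only_q$phenotype_abundance["tetracycline"]), 1)
  expect_equal(only_q$n_args, 1L)

  # 3:1 read ratio at equal gene lengths -> 3:1 abundance
  ph <- data.frame(pair_id = paste0("p", 1:8),
                   gene_id = c(rep("tetQ_01", 6), rep("tetW_02", 2)))
  ab <- arg_abundance(ph, arg_cat, relative = FALSE)
  expect_equal(unname(ab$gene_abundance["tetQ_01"] /
                        ab$gene_abundance["tetW_02"]), 3)
  expect_equal(ab$n_args, 2L)
})

test_that("cohort-mean edge weights match the hand case", {
  gmeta <- data.frame(accession = "G1", replicon = "chromosome")
  design <- data.frame(sample_id = c("s1", "s2"),
                       habitat = c("domestic", "domestic"),
                       site = c("A", "A"))
  ah <- list(s1 = data.frame(pair_id = "p1", gene_id = "tetQ_01"),
             s2 = data.frame(pair_id = character(0),
                             gene_id = character(0)))
  gh <- list(s1 = data.frame(pair_id = "p1", accession = "G1"),
             s2 = data.frame(pair_id = character(0),
                             accession = character(0)))
  net <- co_assignment_edges(ah, gh, arg_cat, gmeta, design,
                             c(s1 = 100, s2 = 100))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 0.005)  # mean of {0.01, 0}
  expect_equal(net$edges$replicon, "chromosome")

  # no co-assigned reads anywhere -> no edges
  net0 <- co_assignment_edges(
    list(s1 = ah$s2, s2 = ah$s2), gh, arg_cat, gmeta, design,
    c(s1 = 100, s2 = 100))
  expect_equal(nrow(net0$edges), 0)

  expect_error(co_assignment_edges(ah, gh, arg_cat, gmeta,
                                   design[1, ], c(s1 = 100, s2 = 100)),
               "missing from design")
})

test_that("edge weights are invariant to sample order; sums are bounded", {
  set.seed(23)
  gmeta <- data.frame(accession = c("G1", "G2"),
                      replicon = c("chromosome", "plasmid"))
  design <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                       habitat = c("domestic", "domestic", "feral", "feral"),
                       site = "A")
  mk <- function(n) {
    pid <- sample(sprintf("p%02d", 1:30), n)
    list(arg = data.frame(pair_id = pid,
                          gene_id = sample(arg_cat$gene_id, n, TRUE)),
         gen = data.frame(pair_id = sample(sprintf("p%02d", 1:30), n),
                          accession = sample(gmeta$accession, n, TRUE)))
  }
  hits <- lapply(setNames(c(12, 9, 15, 7), design$sample_id),
                 function(n) mk(n))
  ah <- lapply(hits, `[[`, "arg"); gh <- lapply(hits, `[[`, "gen")
  np <- setNames(rep(30, 4), design$sample_id)
  net <- co_assignment_edges(ah, gh, arg_cat, gmeta, design, np)
  perm <- c("s3", "s1", "s4", "s2")
  net_p <- co_assignment_edges(ah[perm], gh[perm], arg_cat, gmeta,
                               design, np)
  expect_equal(net$edges, net_p$edges)

  # per cohort: sum over genomes of an edge weight <= phenotype node size
  for (ch in unique(net$edges$cohort)) {
    e <- net$edges[net$edges$cohort == ch, ]
    n <- net$nodes[net$nodes$cohort == ch & net$nodes$type == "phenotype", ]
    for (ph in unique(e$phenotype)) {
      expect_lte(sum(e$weight[e$phenotype == ph]),
                 n$size[n$node == ph] + 1e-12)
    }
  }
})

test_that("the network exports as GraphML per cohort", {
  gmeta <- data.frame(accession = "G1", replicon = "plasmid")
  design <- data.frame(sample_id = c("s1", "s2"),
                       habitat = c("domestic", "feral"), site = "A")
  ah <- list(s1 = data.frame(pair_id = "p1", gene_id = "tetQ_01"),
             s2 = data.frame(pair_id = "p2", gene_id = "lnuC_03"))
  gh <- list(s1 = data.frame(pair_id = "p1", accession = "G1"),
             s2 = data.frame(pair_id = "p2", accession = "G1"))
  net <- co_assignment_edges(ah, gh, arg_cat, gmeta, design,
                             c(s1 = 50, s2 = 50))
  out <- file.path(tempdir(), "net.graphml")
  paths <- write_resistome_graphml(net, out)
  expect_length(paths, 2)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(paths[1], format = "graphml")
  expect_gte(igraph::gorder(g), 2)
})
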