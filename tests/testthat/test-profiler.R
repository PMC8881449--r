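# Subsample-and-average profiling: the redistribution rule, weight
# conservation, subsampling semantics, averaging, and the rare filter.

test_that("subsampling is exact, reproducible, and warns when short", {
  g <- generate_genomes(2, c(5000, 6000), plasmid_prob = 0, seed = 71)
  ab <- setNames(c(0.5, 0.5), unique(g$metadata$species[g$metadata$source]))
  rr <- simulate_reads(g, ab, 100, seed = 3)
  s_all <- subsample_pairs(rr$pairs, 100, seed = 1)
  expect_setequal(s_all$pair_id, rr$pairs$pair_id)
  s10a <- subsample_pairs(rr$pairs, 10, seed = 5)
  s10b <- subsample_pairs(rr$pairs, 10, seed = 5)
  expect_identical(s10a$pair_id, s10b$pair_id)
  s10c <- subsample_pairs(rr$pairs, 10, seed = 6)
  expect_false(identical(sort(s10a$pair_id), sort(s10c$pair_id)))
  expect_warning(subsample_pairs(rr$pairs, 200, seed = 1), "using all")
})

test_that("profile_once implements the two-pass redistribution rule", {
  lens <- c(A = 1000, B = 1000)
  # all unique to A
  p1 <- profile_once(rep(list("A"), 10), 10, lens)
  expect_equal(p1[["A"]], 1)
  expect_equal(p1[["unassigned"]], 0)

  # 80 unique A, 20 unique B, equal lengths
  sets <- c(rep(list("A"), 80), rep(list("B"), 20))
  p2 <- profile_once(sets, 100, lens)
  expect_equal(p2[["A"]], 0.8)
  expect_equal(p2[["B"]], 0.2)

  # 50 unique A + 50 shared {A,B}: one redistribution pass gives B zero
  sets3 <- c(rep(list("A"), 50), rep(list(c("A", "B")), 50))
  p3 <- profile_once(sets3, 100, lens, redistribute_iters = 1)
  expect_equal(p3[["A"]], 1)
  expect_equal(p3[["B"]], 0)

  # all-shared reads split uniformly when no unique evidence exists
  p4 <- profile_once(rep(list(c("A", "B")), 10), 10, lens)
  expect_equal(p4[["A"]], 0.5)

  # length normalization: equal read counts, 2x genome length => half share
  p5 <- profile_once(c(rep(list("A"), 50), rep(list("B"), 50)), 100,
                     c(A = 1000, B = 2000))
  expect_equal(p5[["A"]] / p5[["B"]], 2)

  # unassigned fraction: weights + unassigned account for every pair
  p6 <- profile_once(rep(list("A"), 60), 100, lens)
  expect_equal(p6[["unassigned"]], 0.4)
  expect_equal(sum(p6), 1)
})

test_that("averaging identical repeats equals a single profile", {
  g <- generate_genomes(3, c(6000, 8000), plasmid_prob = 0, seed = 73)
  ab <- setNames(c(0.5, 0.3, 0.2),
                 unique(g$metadata$species[g$metadata$source]))
  rr <- simulate_reads(g, ab, 300, seed = 7)
  cur <- curate_genomes(g)
  cfg <- profiler_config(n_pairs_per_subsample = 300, n_repeats = 3)
  res <- profile_sample(rr$pairs, cur$kept, cfg, seed = 11)
  for (r in 2:3)
    expect_equal(res$per_repeat[r, ], res$per_repeat[1, ])
  expect_equal(res$profile, res$per_repeat[1, ])
})

test_that("the rare filter removes species in <= 2 samples, order-free", {
  mat <- rbind(
    s1 = c(a = 0.5, b = 0.3, c = 0.2, unassigned = 0),
    s2 = c(a = 0.6, b = 0.4, c = 0.0, unassigned = 0),
    s3 = c(a = 0.7, b = 0.0, c = 0.3, unassigned = 0),
    s4 = c(a = 0.8, b = 0.2, c = 0.0, unassigned = 0),
    s5 = c(a = 0.9, b = 0.1, c = 0.0, unassigned = 0))
  f <- equimeta:::rare_species_filter(mat, 2)
  expect_equal(f$removed, "c")  # present in exactly 2 of 5 samples
  expect_equal(unname(rowSums(f$matrix)), rep(1, 5), tolerance = 1e-12)
  f_perm <- equimeta:::rare_species_filter(mat[c(3, 1, 5, 2, 4), ], 2)
  expect_equal(f_perm$removed, "c")
})

test_that("kingdom-level aggregation sums member species", {
  mat <- rbind(s1 = c(x = 0.2, y = 0.3, z = 0.5))
  agg <- aggregate_features(mat, c(x = "bacteria", y = "bacteria",
                                   z = "archaea"))
  expect_equal(agg["s1", "bacteria"], 0.5)
  expect_equal(agg["s1", "archaea"], 0.5)
  agg2 <- aggregate_features(mat, c(x = "bacteria"))
  expect_equal(agg2["s1", "other"], 0.8)
})

test_that("cohort profiling recovers a small community and maps most reads", {
  g <- generate_genomes(4, c(8000, 12000), plasmid_prob = 0.3, seed = 79,
                        max_variants = 1)
  sp <- unique(g$metadata$species[g$metadata$source])
  ab <- setNames(c(0.4, 0.3, 0.2, 0.1), sp)
  cur <- curate_genomes(g)
  samples <- list(
    s1 = simulate_reads(g, ab, 600, seed = 81)$pairs,
    s2 = simulate_reads(g, ab, 600, seed = 82)$pairs,
    s3 = simulate_reads(g, ab, 600, seed = 83)$pairs)
  cfg <- profiler_config(n_pairs_per_subsample = 400, n_repeats = 3,
                         rare_sample_threshold = 0)
  res <- profile_cohort(samples, cur$kept, cfg, seed = 17)
  expect_equal(dim(res$abundance), c(3, length(sp) + 1))
  expect_equal(unname(rowSums(res$abundance)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(res$mapped_read_ratio > 0.95))
  est <- res$abundance[, sp]
  est <- est / rowSums(est)
  expect_lt(max(abs(t(est) - ab[colnames(est)])), 0.1)
})
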