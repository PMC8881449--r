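# Subsample-and-average taxonomic profiling. For each sample, read pairs
# are repeatedly subsampled, aligned against the curated genome database in
# all-hits mode, converted to a species profile by two-pass fractional
# assignment (unique reads first, multi-mapped weight redistributed
# proportionally), length-normalized, and the repeat profiles averaged.
# Species seen in no more than `rare_sample_threshold` samples are then
# removed and rows renormalized.

#' Profiler configuration
#'
#' @param n_pairs_per_subsample pairs drawn per subsample (field-scale runs
#'   use 15 million; the desk default is 50,000).
#' @param n_repeats number of subsample repeats averaged (field scale 100,
#'   desk default 10).
#' @param rare_sample_threshold species detected in at most this many
#'   samples are filtered out after averaging.
#' @param redistribute_iters redistribution passes for multi-mapped reads
#'   (1 = single proportional reassignment; >1 refines iteratively).
#' @param length_normalize divide species weights by mean representative
#'   genome length before relative scaling.
#' @param min_score,max_evalue,min_identity alignment thresholds for genome
#'   hits.
#' @param k seed length of the genome index.
#' @return a named list of class `profiler_config`.
#' @export
profiler_config <- function(n_pairs_per_subsample = 50000, n_repeats = 10,
                            rare_sample_threshold = 2,
                            redistribute_iters = 1, length_normalize = TRUE,
                            min_score = 50, max_evalue = 1e-5,
                            min_identity = 0.9, k = 16) {
  cfg <- as.list(environment())
  if (cfg$n_pairs_per_subsample < 1 || cfg$n_repeats < 1 ||
      cfg$redistribute_iters < 1 || cfg$rare_sample_threshold < 0)
    stopf("invalid profiler configuration")
  class(cfg) <- "profiler_config"
  cfg
}

#' Subsample read pairs without replacement
#'
#' @param pairs a [read_pairs()] object.
#' @param n pairs to draw; if fewer exist, all are used once (with a
#'   warning).
#' @param seed integer seed.
#' @return a [read_pairs()] subset.
#' @export
subsample_pairs <- function(pairs, n, seed = NULL) {
  stopifnot(inherits(pairs, "read_pairs"))
  if (!nrow(pairs)) stopf("no read pairs to subsample")
  if (n < 1) stopf("n must be >= 1")
  idx <- subsample_indices(nrow(pairs), n, seed)
  structure(pairs[idx, , drop = FALSE], class = class(pairs))
}

subsample_indices <- function(n_avail, n, seed = NULL) {
  if (n >= n_avail) {
    if (n > n_avail)
      warning(sprintf("requested %d pairs but only %d available; using all",
                      n, n_avail), call. = FALSE)
    return(seq_len(n_avail))
  }
  with_rng(seed, sample.int(n_avail, n))
}

# species hit sets per pair from a genome hit table
pair_species_sets <- function(hits, accession_species) {
  if (!nrow(hits)) return(list())
  sp <- accession_species[hits$target_id]
  if (anyNA(sp)) stopf("hit target not present in genome metadata")
  sets <- split(sp, hits$read_id)
  lapply(sets, unique)
}

#' Species profile of one subsample
#'
#' Two-pass fractional assignment: pass 1 counts read pairs hitting exactly
#' one species; pass 2 splits each multi-species pair's unit weight across
#' its hit species proportionally to the current species weights (uniformly
#' if those are all zero), repeated `redistribute_iters` times. Species
#' weights are then divided by mean representative genome length (when
#' enabled) and scaled to relative abundance; pairs with no hits form the
#' explicit `unassigned` fraction.
#'
#' @param pair_species list mapping pair id -> character vector of hit
#'   species (as from alignment in all-hits mode).
#' @param n_pairs total pairs in the subsample (assigned + unassigned).
#' @param species_lengths named vector of mean representative genome
#'   lengths (chromosome + attached plasmids) per species.
#' @param redistribute_iters,length_normalize see [profiler_config()].
#' @return named numeric vector over species plus `"unassigned"`,
#'   summing to 1.
#' @export
profile_once <- function(pair_species, n_pairs, species_lengths,
                         redistribute_iters = 1, length_normalize = TRUE) {
  species <- names(species_lengths)
  counts <- setNames(numeric(length(species)), species)
  n_assigned <- length(pair_species)
  if (n_assigned > n_pairs) stopf("more assigned pairs than pairs")
  if (n_assigned) {
    sizes <- lengths(pair_species)
    uniq <- unlist(pair_species[sizes == 1], use.names = FALSE)
    u <- counts
    if (length(uniq)) {
      tab <- table(factor(uniq, levels = species))
      u[] <- as.numeric(tab)
    }
    multi <- pair_species[sizes > 1]
    w <- u
    for (it in seq_len(redistribute_iters)) {
      a <- u
      for (set in multi) {
        ws <- w[set]
        tot <- sum(ws)
        if (tot > 0) a[set] <- a[set] + ws / tot
        else a[set] <- a[set] + 1 / length(set)
      }
      w <- a
    }
    counts <- w
  }
  if (length_normalize) counts <- counts / species_lengths
  assigned_frac <- n_assigned / n_pairs
  rel <- if (sum(counts) > 0) counts / sum(counts) * assigned_frac else counts
  c(rel, unassigned = 1 - assigned_frac)
}

# mean representative genome span per species: chromosome/contig records
# plus plasmids attached to them, averaged within species
species_mean_lengths <- function(db) {
  spans <- genome_span(db)
  m <- db$metadata
  main <- m[m$replicon != "plasmid", , drop = FALSE]
  vapply(split(spans[main$accession], main$species), mean, numeric(1))
}

#' Profile one sample by subsample-and-average
#'
#' Aligns the full read pool once (both mates; a pair's species set is the
#' union over its mates) and then draws `n_repeats` subsamples of
#' `n_pairs_per_subsample` pairs, averaging the per-subsample profiles.
#'
#' @param pairs a [read_pairs()] object (post QC).
#' @param db curated [genome_set()] database.
#' @param cfg a [profiler_config()].
#' @param seed integer seed.
#' @return list with `profile` (mean relative abundance incl. `unassigned`),
#'   `per_repeat` (repeats x features matrix), `mapped_read_ratio`.
#' @export
profile_sample <- function(pairs, db, cfg = profiler_config(), seed = NULL) {
  stopifnot(inherits(pairs, "read_pairs"), inherits(db, "genome_set"))
  idx <- alignment_index(db, alphabet = "dna", k = cfg$k,
                         target_kind = "genome")
  acc_sp <- setNames(db$metadata$species, db$metadata$accession)
  reads <- c(setNames(pairs$seq1, pairs$pair_id),
             setNames(pairs$seq2, pairs$pair_id))
  hits <- align_reads(reads, idx, mode = "all_hits",
                      min_score = cfg$min_score, max_evalue = cfg$max_evalue,
                      min_identity = cfg$min_identity)
  psets <- pair_species_sets(hits, acc_sp)
  profile_from_sets(psets, pairs$pair_id, cfg, seed,
                    species_mean_lengths(db))
}

# core repeat-and-average loop, reusing precomputed pair->species sets
profile_from_sets <- function(psets, pool_ids, cfg, seed, sp_len) {
  n_pool <- length(pool_ids)
  reps <- matrix(0, cfg$n_repeats, length(sp_len) + 1,
                 dimnames = list(NULL, c(names(sp_len), "unassigned")))
  mapped <- numeric(cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    idx <- subsample_indices(n_pool, cfg$n_pairs_per_subsample,
                             derive_seed(seed, r))
    ids <- pool_ids[idx]
    sub_sets <- psets[intersect(ids, names(psets))]
    reps[r, ] <- profile_once(sub_sets, length(idx), sp_len,
                              cfg$redistribute_iters, cfg$length_normalize)
    mapped[r] <- length(sub_sets) / length(idx)
  }
  list(profile = colMeans(reps), per_repeat = reps,
       mapped_read_ratio = mean(mapped))
}

#' Profile a cohort of samples
#'
#' Runs [profile_sample()] per sample, assembles the samples x features
#' abundance matrix, removes species detected in at most
#' `rare_sample_threshold` samples, and renormalizes rows.
#'
#' @param samples named list of [read_pairs()] objects.
#' @param db curated [genome_set()] database.
#' @param cfg a [profiler_config()].
#' @param seed integer seed.
#' @return list with `abundance` (samples x features matrix incl.
#'   `unassigned`, rows sum to 1), `mapped_read_ratio` (per sample),
#'   `removed_species`.
#' @export
profile_cohort <- function(samples, db, cfg = profiler_config(),
                           seed = NULL) {
  if (!length(samples)) stopf("no samples")
  if (is.null(names(samples))) stopf("samples must be named")
  res <- lapply(seq_along(samples), function(i)
    profile_sample(samples[[i]], db, cfg, derive_seed(seed, 1000 + i)))
  mat <- do.call(rbind, lapply(res, `[[`, "profile"))
  rownames(mat) <- names(samples)
  rare_filtered <- rare_species_filter(mat, cfg$rare_sample_threshold)
  list(abundance = rare_filtered$matrix,
       mapped_read_ratio = setNames(
         vapply(res, `[[`, numeric(1), "mapped_read_ratio"), names(samples)),
       removed_species = rare_filtered$removed)
}

# drop species present (>0) in <= threshold samples; renormalize rows
rare_species_filter <- function(mat, threshold) {
  species <- setdiff(colnames(mat), "unassigned")
  presence <- colSums(mat[, species, drop = FALSE] > 0)
  removed <- species[presence <= threshold]
  keep <- c(setdiff(species, removed), intersect("unassigned", colnames(mat)))
  out <- mat[, keep, drop = FALSE]
  rs <- rowSums(out)
  rs[rs == 0] <- 1
  list(matrix = out / rs, removed = removed)
}

#' Aggregate abundance columns by a feature mapping
#'
#' Sums member-feature abundances per group (e.g. species -> kingdom for
#' kingdom-level composition).
#'
#' @param mat samples x features abundance matrix.
#' @param map named character vector feature -> group; unmapped features go
#'   to `"other"`.
#' @return samples x groups matrix.
#' @export
aggregate_features <- function(mat, map) {
  grp <- map[colnames(mat)]
  grp[is.na(grp)] <- "other"
  t(rowsum(t(mat), grp))
}
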