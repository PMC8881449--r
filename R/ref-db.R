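# Reference genome curation: per-species outlier removal by Tukey's fences
# (coefficient 2) on genome length and GC content, selection of the three
# longest genomes per completeness class, and complete-linkage clustering of
# unnamed "Genus sp." genomes at k-mer Jaccard distance 0.9 with the longest
# genome of each cluster as representative.

#' Tukey's fences outlier filter
#'
#' Keeps `v` iff `Q1 - k*IQR <= v <= Q3 + k*IQR`, quartiles by linear
#' interpolation between order statistics (quantile type 7).
#'
#' @param values numeric vector (non-empty).
#' @param k fence coefficient (the curation default is 2).
#' @return logical keep-mask of the same length.
#' @export
tukey_fences_filter <- function(values, k = 2.0) {
  if (!length(values)) stopf("tukey_fences_filter: empty value list")
  if (k < 0) stopf("fence coefficient must be >= 0")
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values >= q[1] - k * iqr & values <= q[2] + k * iqr
}

#' Select up to three longest representatives of a species group
#'
#' Complete and draft genomes are ranked separately (then combined by the
#' caller); ties in length break lexicographically by accession.
#'
#' @param meta data.frame with columns `accession`, `length_bp`, and
#'   optionally `completeness`.
#' @param n_top representatives per completeness class.
#' @param by_completeness rank within each completeness class separately.
#' @return character vector of selected accessions.
#' @export
select_representatives <- function(meta, n_top = 3, by_completeness = TRUE) {
  if (!nrow(meta)) return(character(0))
  pick <- function(m) {
    ord <- order(-m$length_bp, m$accession)
    m$accession[ord[seq_len(min(n_top, nrow(m)))]]
  }
  if (by_completeness && "completeness" %in% names(meta)) {
    sel <- unlist(lapply(split(meta, meta$completeness), pick))
  } else sel <- pick(meta)
  sort(unique(sel))
}

# complete-linkage (or single-linkage) clusters from a distance matrix,
# cut at the given height; returns integer cluster ids
linkage_clusters <- function(D, threshold, linkage = c("complete", "single")) {
  linkage <- match.arg(linkage)
  n <- nrow(D)
  if (n == 1) return(setNames(1L, rownames(D)))
  hc <- hclust(as.dist(D), method = linkage)
  cutree(hc, h = threshold)
}

#' Cluster unnamed genomes of one genus
#'
#' Pairwise distance is 1 minus the Jaccard similarity of canonical k-mer
#' sets; agglomerative clustering (complete linkage by default) is cut at
#' the distance threshold, and the longest genome of each cluster (ties by
#' accession) becomes its representative.
#'
#' @param pool a [genome_set()] whose records share a genus, or a named
#'   character vector of sequences.
#' @param threshold distance threshold in (0, 1].
#' @param k k-mer length for the Jaccard distance.
#' @param linkage `"complete"` (default) or `"single"`.
#' @return list with `clusters` (named integer vector accession -> cluster),
#'   `representatives` (accessions, one per cluster), `distance` (matrix).
#' @export
cluster_unnamed <- function(pool, threshold = 0.9, k = 12,
                            linkage = "complete") {
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  seqs <- if (inherits(pool, "genome_set")) pool$sequences else pool
  if (!length(seqs))
    return(list(clusters = setNames(integer(0), character(0)),
                representatives = character(0),
                distance = matrix(0, 0, 0)))
  ord <- order(names(seqs))
  seqs <- seqs[ord]
  D <- cpp_kmer_jaccard_dist(unname(seqs), as.integer(k))
  dimnames(D) <- list(names(seqs), names(seqs))
  cl <- linkage_clusters(D, threshold, linkage)
  reps <- vapply(split(names(cl), cl), function(acc) {
    len <- nchar(seqs[acc])
    acc[order(-len, acc)][1]
  }, character(1))
  list(clusters = cl, representatives = unname(reps), distance = D)
}

#' Curate a reference genome set
#'
#' Runs the three curation steps per species: (1) complete and draft
#' genomes handled separately and recombined, (2) within-species discard of
#' genomes with abnormal length or GC content (Tukey's fences, coefficient
#' `tukey_k`; a genome failing either fence is discarded) followed by
#' selection of the three longest genomes, (3) genus-level pooling of
#' unnamed "Genus sp." genomes, complete-linkage clustering at
#' `cluster_threshold`, keeping the longest genome per cluster. Plasmid
#' records do not enter the filters; they follow the fate of their parent
#' replicon.
#'
#' @param genomes a [genome_set()].
#' @param tukey_k fence coefficient.
#' @param cluster_threshold distance cut for unnamed-genome clustering.
#' @param kmer_k k-mer length of the Jaccard distance.
#' @param linkage clustering linkage, `"complete"` or `"single"`.
#' @param n_top representatives per species and completeness class.
#' @return list of class `curation_result`: `kept` ([genome_set()]),
#'   `report` (per-record decision and reason), `cluster_assignments`
#'   (named integer vector for unnamed genomes).
#' @export
curate_genomes <- function(genomes, tukey_k = 2, cluster_threshold = 0.9,
                           kmer_k = 12, linkage = "complete", n_top = 3) {
  stopifnot(inherits(genomes, "genome_set"))
  meta <- genomes$metadata
  meta <- meta[order(meta$accession), , drop = FALSE]  # determinism contract
  main <- meta[meta$replicon != "plasmid", , drop = FALSE]
  decision <- setNames(rep("kept", nrow(main)), main$accession)
  reason <- setNames(rep("", nrow(main)), main$accession)

  # step 2 within species (per completeness class): Tukey fences on length
  # and GC, then top-3 by length
  for (grp in split(main, main$species)) {
    for (sub in split(grp, grp$completeness)) {
      ok_len <- tukey_fences_filter(sub$length_bp, tukey_k)
      ok_gc <- tukey_fences_filter(sub$gc_fraction, tukey_k)
      out <- !(ok_len & ok_gc)
      decision[sub$accession[out]] <- "discarded_outlier"
      reason[sub$accession[out]] <-
        ifelse(!ok_len[out] & !ok_gc[out], "length+gc",
               ifelse(!ok_len[out], "length", "gc"))[seq_len(sum(out))]
    }
    if (grp$named[1]) {
      surv <- grp[decision[grp$accession] == "kept", , drop = FALSE]
      sel <- select_representatives(surv, n_top = n_top)
      drop <- setdiff(surv$accession, sel)
      decision[drop] <- "discarded_rank"
      reason[drop] <- "beyond_top3"
    }
  }

  # step 3: genus-level clustering of unnamed genomes that survived fences
  cluster_assignments <- setNames(integer(0), character(0))
  un <- main[!main$named & decision[main$accession] == "kept", , drop = FALSE]
  if (nrow(un)) {
    for (gpool in split(un, un$genus)) {
      cl <- cluster_unnamed(genomes$sequences[gpool$accession],
                            threshold = cluster_threshold, k = kmer_k,
                            linkage = linkage)
      offset <- if (length(cluster_assignments))
        max(cluster_assignments) else 0L
      cluster_assignments <- c(cluster_assignments, cl$clusters + offset)
      drop <- setdiff(names(cl$clusters), cl$representatives)
      decision[drop] <- "discarded_cluster"
      reason[drop] <- "non_representative"
    }
  }

  kept_main <- names(decision)[decision == "kept"]
  plas <- meta[meta$replicon == "plasmid", , drop = FALSE]
  kept_plasmids <- plas$accession[plas$parent %in% kept_main]
  kept <- subset_genomes(genomes, c(kept_main, kept_plasmids))
  report <- data.frame(
    accession = main$accession, species = main$species,
    genus = main$genus, completeness = main$completeness,
    decision = decision[main$accession], reason = reason[main$accession],
    cluster = cluster_assignments[main$accession],
    stringsAsFactors = FALSE)
  structure(list(kept = kept, report = report,
                 cluster_assignments = cluster_assignments),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  tab <- table(x$report$decision)
  cat("<curation_result>\n")
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  cat(sprintf("  kept records incl. plasmids: %d\n", length(x$kept)))
  invisible(x)
}
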