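# CAZy functional profiling: mates aligned separately against the protein
# catalog, alignments merged per pair with score > 60 and E-value < 1e-5,
# each pair's unit weight split equally over its mapped genes, per-gene
# weights adjusted by gene length (divided by kilo-amino-acids), summed per
# family.

#' Merge mate-level gene hits into per-pair hit sets
#'
#' Union of both mates' hits, filtered with strict thresholds
#' (`score > min_score` and `evalue < max_evalue`).
#'
#' @param hits_r1,hits_r2 hit data.frames keyed by pair id in `read_id`.
#' @param min_score bit score threshold (exclusive).
#' @param max_evalue E-value threshold (exclusive).
#' @return data.frame `pair_id`, `gene_id`, one row per distinct pair-gene
#'   assignment.
#' @export
merge_mate_hits <- function(hits_r1, hits_r2, min_score = 60,
                            max_evalue = 1e-5) {
  h <- rbind(hits_r1[, c("read_id", "target_id", "score", "evalue")],
             hits_r2[, c("read_id", "target_id", "score", "evalue")])
  h <- h[h$score > min_score & h$evalue < max_evalue, , drop = FALSE]
  h <- unique(data.frame(pair_id = h$read_id, gene_id = h$target_id,
                         stringsAsFactors = FALSE))
  rownames(h) <- NULL
  h
}

# unit weight of each pair split equally over its mapped genes
fractional_gene_weights <- function(pair_hits) {
  if (!nrow(pair_hits))
    return(setNames(numeric(0), character(0)))
  n_genes <- table(pair_hits$pair_id)
  w <- 1 / as.numeric(n_genes[pair_hits$pair_id])
  tapply(w, pair_hits$gene_id, sum)
}

#' Fractional, length-adjusted CAZy family abundance
#'
#' Each read pair contributes total weight 1, split equally over its mapped
#' genes; per-gene weights are divided by gene length in kilo-amino-acids
#' and summed within families.
#'
#' @param pair_hits data.frame from [merge_mate_hits()].
#' @param catalog CAZy catalog (list with `annotation` having `gene_id`,
#'   `family`, `length_aa`) or the annotation data.frame itself.
#' @param relative scale the family vector to sum to 1.
#' @param length_adjust divide gene weights by length in k-aa.
#' @return named numeric vector of family abundances; attribute
#'   `gene_weights` carries the per-gene totals before length adjustment.
#' @export
fractional_family_abundance <- function(pair_hits, catalog, relative = TRUE,
                                        length_adjust = TRUE) {
  ann <- if (is.data.frame(catalog)) catalog else catalog$annotation
  stopifnot(all(c("gene_id", "family", "length_aa") %in% names(ann)))
  unknown <- setdiff(pair_hits$gene_id, ann$gene_id)
  if (length(unknown))
    stopf("hits to genes missing from the catalog: %s",
          paste(head(unknown, 5), collapse = ", "))
  fam_levels <- sort(unique(ann$family))
  out <- setNames(numeric(length(fam_levels)), fam_levels)
  gw <- fractional_gene_weights(pair_hits)
  if (length(gw)) {
    i <- match(names(gw), ann$gene_id)
    adj <- if (length_adjust) as.numeric(gw) / (ann$length_aa[i] / 1000)
           else as.numeric(gw)
    fam <- tapply(adj, ann$family[i], sum)
    out[names(fam)] <- fam
    if (relative && sum(out) > 0) out <- out / sum(out)
  }
  attr(out, "gene_weights") <- gw
  out
}

#' Number of distinct CAZy families with nonzero abundance
#'
#' @inheritParams fractional_family_abundance
#' @return integer count.
#' @export
count_cazy_families <- function(pair_hits, catalog) {
  ann <- if (is.data.frame(catalog)) catalog else catalog$annotation
  if (!nrow(pair_hits)) return(0L)
  i <- match(pair_hits$gene_id, ann$gene_id)
  if (anyNA(i)) stopf("hits to genes missing from the catalog")
  length(unique(ann$family[i]))
}

#' Starch/glycogen vs cellulose pathway-group abundance
#'
#' Sums relative family abundances within each pathway group. Families not
#' in the map count as `other` (reported via a message).
#'
#' @param family_abundance named numeric vector of family abundances.
#' @param map named character vector family -> `"starch_glycogen"`,
#'   `"cellulose"` (anything else counts as other).
#' @return named numeric vector `c(starch_glycogen=, cellulose=)`.
#' @export
pathway_group_abundance <- function(family_abundance, map) {
  grp <- if (length(map)) map[names(family_abundance)] else
    rep(NA_character_, length(family_abundance))
  unmapped <- names(family_abundance)[is.na(grp) & family_abundance > 0]
  if (length(unmapped))
    message("families not in pathway map (counted as other): ",
            paste(unmapped, collapse = ", "))
  grp[is.na(grp)] <- "other"
  c(starch_glycogen = sum(family_abundance[grp == "starch_glycogen"]),
    cellulose = sum(family_abundance[grp == "cellulose"]))
}

#' CAZy profile of one sample
#'
#' Aligns both mates separately against the protein catalog (six-frame
#' translation), merges mate hits, and computes the family abundance
#' vector and family count.
#'
#' @param pairs a [read_pairs()] object (post QC).
#' @param catalog CAZy catalog list (`sequences` = protein, `annotation`).
#' @param min_score,max_evalue merge thresholds.
#' @param k protein seed length.
#' @return list with `family_abundance`, `n_families`, `pair_hits`.
#' @export
cazy_profile_sample <- function(pairs, catalog, min_score = 60,
                                max_evalue = 1e-5, k = 4) {
  idx <- alignment_index(catalog$sequences, alphabet = "protein", k = k,
                         target_kind = "cazy_gene")
  h1 <- align_reads(setNames(pairs$seq1, pairs$pair_id), idx,
                    mode = "all_hits")
  h2 <- align_reads(setNames(pairs$seq2, pairs$pair_id), idx,
                    mode = "all_hits")
  ph <- merge_mate_hits(h1, h2, min_score, max_evalue)
  list(family_abundance = fractional_family_abundance(ph, catalog),
       n_families = count_cazy_families(ph, catalog),
       pair_hits = ph)
}

#' CAZy family x sample profile of a cohort
#'
#' @param samples named list of [read_pairs()] objects.
#' @inheritParams cazy_profile_sample
#' @return list with `abundance` (samples x families relative matrix),
#'   `n_families` (per sample), `pair_hits` (per sample list).
#' @export
cazy_profile <- function(samples, catalog, min_score = 60,
                         max_evalue = 1e-5, k = 4) {
  res <- lapply(samples, cazy_profile_sample, catalog = catalog,
                min_score = min_score, max_evalue = max_evalue, k = k)
  mat <- do.call(rbind, lapply(res, function(r) as.numeric(r$family_abundance)))
  colnames(mat) <- names(res[[1]]$family_abundance)
  rownames(mat) <- names(samples)
  list(abundance = mat,
       n_families = vapply(res, `[[`, integer(1), "n_families"),
       pair_hits = lapply(res, `[[`, "pair_hits"))
}
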