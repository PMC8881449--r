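# Resistome profiling and the ARG-phenotype x reference-genome
# co-assignment network. A read pair assigned to both a resistance
# phenotype (via an ARG hit) and a reference genome lets that genome
# contribute to the phenotype; per-sample co-assignment frequencies are
# averaged within each cohort to weight network edges.

#' Per-sample ARG abundance
#'
#' Fractional weight splitting as in the CAZy profiler: each pair's unit
#' weight is split equally over its mapped ARG genes, divided by gene
#' length (kilo-bases), and summed per gene and per phenotype.
#'
#' @param pair_hits data.frame `pair_id`, `gene_id` (from
#'   [merge_mate_hits()] against the ARG catalog).
#' @param catalog ARG catalog (list with `annotation` having `gene_id`,
#'   `phenotype`, `length_bp`) or the annotation data.frame.
#' @param relative scale abundances to sum to 1.
#' @param length_adjust divide gene weights by length in kb.
#' @return list with `gene_abundance`, `phenotype_abundance`, `n_args`
#'   (distinct genes with positive weight).
#' @export
arg_abundance <- function(pair_hits, catalog, relative = TRUE,
                          length_adjust = TRUE) {
  ann <- if (is.data.frame(catalog)) catalog else catalog$annotation
  stopifnot(all(c("gene_id", "phenotype") %in% names(ann)))
  unknown <- setdiff(pair_hits$gene_id, ann$gene_id)
  if (length(unknown))
    stopf("hits to ARGs missing from the catalog: %s",
          paste(head(unknown, 5), collapse = ", "))
  gene <- setNames(numeric(nrow(ann)), ann$gene_id)
  gw <- fractional_gene_weights(pair_hits)
  n_args <- sum(gw > 0)
  if (length(gw)) {
    i <- match(names(gw), ann$gene_id)
    adj <- if (length_adjust && "length_bp" %in% names(ann))
      as.numeric(gw) / (ann$length_bp[i] / 1000) else as.numeric(gw)
    gene[names(gw)] <- adj
  }
  phen <- tapply(gene, ann$phenotype, sum)
  phen <- setNames(as.numeric(phen), names(phen))
  if (relative && sum(gene) > 0) {
    gene <- gene / sum(gene)
    phen <- phen / sum(phen)
  }
  list(gene_abundance = gene, phenotype_abundance = phen,
       n_args = as.integer(n_args))
}

#' ARG-phenotype x genome co-assignment network
#'
#' For each sample, `frequency(phenotype, genome)` is the number of read
#' pairs hit by both an ARG of that phenotype and that reference genome,
#' divided by the sample's subsampled pair count; a pair co-assigned to
#' several genomes splits its weight equally among them. Edge weight is
#' the arithmetic mean of the per-sample frequencies over all samples of a
#' cohort (samples without co-assignments contribute 0). Node sizes are
#' the cohort-mean frequencies of reads assigned to the phenotype or to
#' the genome.
#'
#' @param arg_hits_by_sample named list (per sample) of data.frames
#'   `pair_id`, `gene_id` (ARG hits).
#' @param genome_hits_by_sample named list (per sample) of data.frames
#'   with `read_id`/`pair_id` and `target_id`/`accession` genome hits.
#' @param arg_catalog ARG catalog (for the phenotype of each gene).
#' @param genome_metadata data.frame with `accession` and `replicon`.
#' @param design data.frame `sample_id`, `habitat` (the cohort variable),
#'   covering every sample.
#' @param n_pairs named vector: subsampled pair count per sample (the
#'   frequency denominator).
#' @param cohort_var design column defining the cohorts.
#' @return list with `edges` (phenotype, genome, replicon, cohort, weight)
#'   and `nodes` (node, type, cohort, size).
#' @export
co_assignment_edges <- function(arg_hits_by_sample, genome_hits_by_sample,
                                arg_catalog, genome_metadata, design,
                                n_pairs, cohort_var = "habitat") {
  ann <- if (is.data.frame(arg_catalog)) arg_catalog else
    arg_catalog$annotation
  samples <- names(arg_hits_by_sample)
  missing <- setdiff(samples, design$sample_id)
  if (length(missing))
    stopf("samples missing from design: %s", paste(missing, collapse = ", "))
  cohort_of <- setNames(design[[cohort_var]], design$sample_id)
  repl_of <- setNames(genome_metadata$replicon, genome_metadata$accession)
  phen_of <- setNames(ann$phenotype, ann$gene_id)

  per_sample_freq <- list()
  per_sample_phen <- list()
  per_sample_gen <- list()
  for (s in samples) {
    ah <- arg_hits_by_sample[[s]]
    gh <- genome_hits_by_sample[[s]]
    if (!is.null(gh$read_id) && is.null(gh$pair_id)) gh$pair_id <- gh$read_id
    if (!is.null(gh$target_id) && is.null(gh$accession))
      gh$accession <- gh$target_id
    denom <- n_pairs[[s]]
    if (is.null(denom) || is.na(denom)) stopf("no pair count for sample %s", s)
    phen_sets <- lapply(split(phen_of[ah$gene_id], ah$pair_id), unique)
    gu <- unique(gh[, c("pair_id", "accession")])
    gen_sets <- split(gu$accession, gu$pair_id)
    co <- intersect(names(phen_sets), names(gen_sets))
    acc <- list()
    for (p_id in co) {
      genomes <- gen_sets[[p_id]]
      share <- 1 / length(genomes)
      for (ph in phen_sets[[p_id]]) {
        for (g in genomes) {
          key <- paste(ph, g, sep = "\r")
          acc[[key]] <- (acc[[key]] %||% 0) + share
        }
      }
    }
    per_sample_freq[[s]] <- if (length(acc))
      setNames(unlist(acc) / denom, names(acc)) else
      setNames(numeric(0), character(0))
    # frequency of pairs assigned within each phenotype / genome
    pp <- table(unlist(lapply(phen_sets, unique)))
    gg <- table(unlist(lapply(gen_sets, unique)))
    per_sample_phen[[s]] <- setNames(as.numeric(pp) / denom, names(pp))
    per_sample_gen[[s]] <- setNames(as.numeric(gg) / denom, names(gg))
  }

  cohorts <- unique(cohort_of[samples])
  edge_rows <- list()
  node_rows <- list()
  for (ch in cohorts) {
    in_ch <- samples[cohort_of[samples] == ch]
    keys <- unique(unlist(lapply(per_sample_freq[in_ch], names)))
    for (key in keys) {
      vals <- vapply(in_ch, function(s)
        per_sample_freq[[s]][key] %|NA|% 0, numeric(1))
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      edge_rows[[length(edge_rows) + 1]] <- data.frame(
        phenotype = parts[1], genome = parts[2],
        replicon = repl_of[parts[2]] %|NA|% "contig",
        cohort = ch, weight = mean(vals), stringsAsFactors = FALSE)
    }
    for (lst in list(c("phenotype", "per_sample_phen"),
                     c("genome", "per_sample_gen"))) {
      tabs <- get(lst[2])[in_ch]
      nm <- unique(unlist(lapply(tabs, names)))
      for (x in nm) {
        vals <- vapply(in_ch, function(s) tabs[[s]][x] %|NA|% 0, numeric(1))
        node_rows[[length(node_rows) + 1]] <- data.frame(
          node = x, type = lst[1], cohort = ch, size = mean(vals),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(phenotype = character(0), genome = character(0),
               replicon = character(0), cohort = character(0),
               weight = numeric(0), stringsAsFactors = FALSE)
  edges <- edges[order(edges$cohort, edges$phenotype, edges$genome), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  nodes <- if (length(node_rows)) do.call(rbind, node_rows) else
    data.frame(node = character(0), type = character(0),
               cohort = character(0), size = numeric(0))
  list(edges = edges, nodes = nodes)
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Export the co-assignment network as GraphML
#'
#' Builds one igraph per cohort with edge weight and node attributes
#' (Cytoscape styling is carried as attributes, not rendered).
#'
#' @param network list from [co_assignment_edges()].
#' @param path output file (`<cohort>` is appended for multiple cohorts).
#' @return character vector of written paths, invisibly.
#' @export
write_resistome_graphml <- function(network, path) {
  cohorts <- unique(network$edges$cohort)
  out <- character(0)
  for (ch in cohorts) {
    e <- network$edges[network$edges$cohort == ch, , drop = FALSE]
    n <- network$nodes[network$nodes$cohort == ch, , drop = FALSE]
    vertices <- unique(data.frame(
      name = c(e$phenotype, e$genome),
      type = rep(c("phenotype", "genome"), each = nrow(e)),
      replicon = c(rep(NA_character_, nrow(e)), e$replicon),
      stringsAsFactors = FALSE))
    vertices$size <- n$size[match(vertices$name, n$node)]
    g <- igraph::graph_from_data_frame(
      data.frame(from = e$phenotype, to = e$genome, weight = e$weight),
      directed = FALSE, vertices = vertices)
    p <- if (length(cohorts) > 1)
      sub("(\\.graphml)?$", paste0(".", ch, ".graphml"), path) else path
    igraph::write_graph(g, p, format = "graphml")
    out <- c(out, p)
  }
  invisible(out)
}
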