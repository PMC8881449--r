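# Multi-sample synthetic dataset: genome panel with spiked gene catalogs, a
# host genome, a design table with planted effects, per-sample labeled
# reads, and the genus/species taxonomy tree.

#' Simulate a complete multi-sample metagenomics dataset
#'
#' Convenience wrapper tying together [generate_genomes()],
#' [spike_genes()], [generate_design()] and [simulate_reads()]; the
#' returned truth objects (abundance matrix, defect labels, spiked-gene
#' coordinates, signal species) are the oracles used to validate every
#' pipeline stage.
#'
#' @param n_species community size.
#' @param cohorts data.frame `habitat`, `site`, `n` (samples per cohort).
#' @param n_pairs read pairs per sample.
#' @param effect_spec planted effects (see [generate_design()]); `NULL`
#'   plants a single 4-fold feral effect on the first species.
#' @param defect_rates per-class QC defect rates (see [simulate_reads()]).
#' @param arg_catalog_size,cazy_catalog_size catalog sizes.
#' @param length_range,plasmid_prob genome panel settings.
#' @param host_length length of the designated host genome.
#' @param error_rate per-base sequencing error rate.
#' @param read_len read length.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return list with `genomes`, `arg_catalog`, `cazy_catalog`,
#'   `spiked_genes`, `host_genome`, `design`, `abundance`, `signal`,
#'   `reads` (per sample: `pairs`, `labels`), `tree`.
#' @export
simulate_dataset <- function(n_species = 6,
                             cohorts = data.frame(
                               habitat = c("domestic", "feral"),
                               site = c("FinF", "SpaW"),
                               n = c(4, 4)),
                             n_pairs = 1500,
                             effect_spec = NULL,
                             defect_rates = c(ambiguous = 0.02,
                                              low_quality = 0.02,
                                              adapter = 0.02, host = 0.02),
                             arg_catalog_size = 6, cazy_catalog_size = 12,
                             length_range = c(20000, 40000),
                             plasmid_prob = 0.3, host_length = 30000,
                             error_rate = 0.002, read_len = 150,
                             seed = NULL) {
  genomes <- generate_genomes(n_species, length_range, plasmid_prob,
                              seed = derive_seed(seed, 1))
  sp <- spike_genes(genomes, arg_catalog_size, cazy_catalog_size,
                    seed = derive_seed(seed, 2))
  host <- with_rng(derive_seed(seed, 3), genome_set(
    c(HOST0001 = random_dna(host_length, 0.41)),
    data.frame(accession = "HOST0001", species = "Equus caballus",
               genus = "Equus", completeness = "complete",
               replicon = "chromosome")))
  species <- unique(sp$genomes$metadata$species[sp$genomes$metadata$source])
  if (is.null(effect_spec))
    effect_spec <- list(list(species = species[1], variable = "habitat",
                             level = "feral", fold = 4))
  des <- generate_design(species, cohorts, effect_spec,
                         seed = derive_seed(seed, 4))
  reads <- lapply(seq_len(nrow(des$design)), function(i) {
    s <- des$design$sample_id[i]
    simulate_reads(sp$genomes, des$abundance[s, ], n_pairs,
                   read_len = read_len, error_rate = error_rate,
                   defect_rates = defect_rates, host_genome = host,
                   seed = derive_seed(seed, 100 + i),
                   pair_prefix = paste0(s, ".p"))
  })
  names(reads) <- des$design$sample_id
  src_meta <- sp$genomes$metadata[sp$genomes$metadata$source &
                                    sp$genomes$metadata$replicon != "plasmid", ]
  tree <- if (nrow(src_meta) >= 2)
    build_taxonomy_tree(src_meta$species, src_meta$genus) else NULL
  list(genomes = sp$genomes, arg_catalog = sp$arg_catalog,
       cazy_catalog = sp$cazy_catalog, spiked_genes = sp$spiked_genes,
       host_genome = host, design = des$design, abundance = des$abundance,
       signal = des$signal, reads = reads, tree = tree)
}

#' Write / read an abundance matrix as TSV (features as rows)
#'
#' @param mat samples x features matrix.
#' @param path file path.
#' @return the path (write) or the samples x features matrix (read).
#' @export
write_abundance_tsv <- function(mat, path) {
  df <- data.frame(feature = colnames(mat), t(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$feature
  m
}

#' Write a simulated dataset to a directory
#'
#' Emits paired FASTQ per sample, genome FASTA + metadata TSV, ARG and
#' CAZy catalogs (FASTA + annotation TSV), the host FASTA, design TSV,
#' defect label TSV, truth abundance TSV, and the taxonomy newick.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
  write_genome_set(sim$genomes, file.path(dir, "genomes.fasta"),
                   file.path(dir, "genomes.tsv"))
  write_genome_set(sim$host_genome, file.path(dir, "host.fasta"),
                   file.path(dir, "host.tsv"))
  write_fasta <- function(seqs, path, aa = FALSE) {
    x <- if (aa) Biostrings::AAStringSet(seqs) else
      Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(x, path)
  }
  if (length(sim$arg_catalog$sequences))
    write_fasta(sim$arg_catalog$sequences, file.path(dir, "arg.fasta"))
  else file.create(file.path(dir, "arg.fasta"))
  write.table(sim$arg_catalog$annotation, file.path(dir, "arg.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(sim$cazy_catalog$sequences))
    write_fasta(sim$cazy_catalog$sequences, file.path(dir, "cazy.faa"),
                aa = TRUE)
  else file.create(file.path(dir, "cazy.faa"))
  write.table(sim$cazy_catalog$annotation, file.path(dir, "cazy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$design, file.path(dir, "design.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_abundance_tsv(sim$abundance, file.path(dir, "truth_abundance.tsv"))
  labels <- do.call(rbind, lapply(names(sim$reads), function(s)
    cbind(sample_id = s, sim$reads[[s]]$labels)))
  write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (s in names(sim$reads))
    write_fastq_pairs(sim$reads[[s]]$pairs,
                      file.path(dir, "reads", paste0(s, "_R1.fastq")),
                      file.path(dir, "reads", paste0(s, "_R2.fastq")))
  if (!is.null(sim$tree))
    ape::write.tree(sim$tree, file.path(dir, "taxonomy.nwk"))
  invisible(dir)
}
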