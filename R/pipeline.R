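# End-to-end orchestration: simulate -> qc -> build_db -> profile -> cazy
# -> resistome -> diversity/associate, with a JSON manifest (per-stage
# parameter hash + output checksums) enabling resumable reruns.

#' Default pipeline configuration
#'
#' Desk-scale defaults; field-scale runs raise `profile$n_pairs_per_subsample`
#' to 15 million and `profile$n_repeats` to 100.
#'
#' @param out_dir run directory.
#' @param seed master seed; every random stage derives its own stream.
#' @return nested configuration list of class `run_config`.
#' @export
default_run_config <- function(out_dir = "equimeta_run", seed = 1) {
  structure(list(
    out_dir = out_dir, seed = seed,
    stages = c("simulate", "qc", "build_db", "profile", "cazy",
               "resistome", "diversity", "associate"),
    simulate = list(n_species = 6, n_pairs = 1500,
                    cohorts = data.frame(habitat = c("domestic", "feral"),
                                         site = c("FinF", "SpaW"),
                                         n = c(4, 4)),
                    arg_catalog_size = 6, cazy_catalog_size = 12,
                    defect_rates = c(ambiguous = 0.02, low_quality = 0.02,
                                     adapter = 0.02, host = 0.02)),
    qc = list(),
    build_db = list(tukey_k = 2, cluster_threshold = 0.9, kmer_k = 12),
    profile = list(n_pairs_per_subsample = 1000, n_repeats = 5,
                   rare_sample_threshold = 2),
    cazy = list(min_score = 60, max_evalue = 1e-5),
    resistome = list(),
    associate = list(target = "habitat", adjust_for = character(0))),
    class = "run_config")
}

#' Read / validate a pipeline configuration from YAML
#'
#' @param path YAML file; entries override [default_run_config()] values.
#' @return validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(y)) {
    if (nm %in% c("simulate", "qc", "build_db", "profile", "cazy",
                  "resistome", "associate")) {
      for (k in names(y[[nm]])) cfg[[nm]][[k]] <- y[[nm]][[k]]
    } else cfg[[nm]] <- y[[nm]]
  }
  if (!is.null(y$simulate$cohorts))
    cfg$simulate$cohorts <- as.data.frame(y$simulate$cohorts)
  if (!is.null(y$simulate$defect_rates))
    cfg$simulate$defect_rates <- unlist(y$simulate$defect_rates)
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param cfg a `run_config` list.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$out_dir) || !nzchar(cfg$out_dir))
    stopf("config: out_dir is required")
  if (is.null(cfg$seed)) stopf("config: seed is required")
  known <- c("simulate", "qc", "build_db", "profile", "cazy", "resistome",
             "diversity", "associate")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stopf("config: unknown stage(s): %s", paste(bad, collapse = ", "))
  if (!is.null(cfg$profile$n_pairs_per_subsample) &&
      cfg$profile$n_pairs_per_subsample < 1)
    stopf("config: n_pairs_per_subsample must be >= 1")
  invisible(TRUE)
}

params_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

file_md5 <- function(paths, base = NULL) {
  out <- tools::md5sum(paths)
  if (!is.null(base))
    names(out) <- sub(paste0("^", base, "/?"), "", names(out))
  out
}

#' Run the pipeline end to end
#'
#' Executes the configured stages in order, writing each stage's outputs
#' under `out_dir/<stage>/` and recording a manifest
#' (`out_dir/manifest.json`) with the stage parameter hash and output
#' checksums. With `resume = TRUE`, a stage whose parameter hash matches
#' the manifest and whose outputs are intact is skipped.
#'
#' @param config a `run_config` list ([default_run_config()],
#'   [read_run_config()]).
#' @param resume skip completed stages with matching hashes.
#' @param quiet suppress progress messages.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), resume = TRUE,
                         quiet = FALSE) {
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else list()
  say <- function(...) if (!quiet) message(sprintf(...))

  stage_runners <- list(
    simulate = run_stage_simulate, qc = run_stage_qc,
    build_db = run_stage_build_db, profile = run_stage_profile,
    cazy = run_stage_cazy, resistome = run_stage_resistome,
    diversity = run_stage_diversity, associate = run_stage_associate)

  for (stage in config$stages) {
    pars <- c(config[[stage]],
              list(.seed = config$seed, .stage = stage))
    h <- params_hash(pars)
    prev <- manifest[[stage]]
    sdir <- file.path(out, stage)
    if (resume && !is.null(prev) && identical(prev$hash, h)) {
      paths <- file.path(sdir, names(prev$outputs))
      if (length(paths) && all(file.exists(paths)) &&
          identical(unname(as.character(file_md5(paths))),
                    unname(unlist(prev$outputs)))) {
        say("[%s] up to date, skipped", stage)
        next
      }
    }
    say("[%s] running", stage)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    outputs <- tryCatch(
      stage_runners[[stage]](config, out, sdir),
      error = function(e)
        stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
    manifest[[stage]] <- list(hash = h,
                              outputs = as.list(file_md5(outputs, base = sdir)))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(manifest)
}

# -- stage implementations ---------------------------------------------------

run_stage_simulate <- function(cfg, out, sdir) {
  p <- cfg$simulate
  sim <- do.call(simulate_dataset, c(p, list(seed = cfg$seed)))
  write_dataset(sim, sdir)
  list.files(sdir, recursive = TRUE, full.names = TRUE)
}

pipeline_samples <- function(out) {
  design <- read.table(file.path(out, "simulate", "design.tsv"),
                       header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  design
}

run_stage_qc <- function(cfg, out, sdir) {
  design <- pipeline_samples(out)
  host <- read_genome_set(file.path(out, "simulate", "host.fasta"),
                          file.path(out, "simulate", "host.tsv"))
  params <- do.call(qc_params, cfg$qc)
  dir.create(file.path(sdir, "reads"), showWarnings = FALSE)
  reports <- list()
  for (s in design$sample_id) {
    pr <- read_fastq_pairs(
      file.path(out, "simulate", "reads", paste0(s, "_R1.fastq")),
      file.path(out, "simulate", "reads", paste0(s, "_R2.fastq")))
    res <- filter_pairs(pr, host = host, params = params)
    write_fastq_pairs(res$kept,
                      file.path(sdir, "reads", paste0(s, "_R1.fastq")),
                      file.path(sdir, "reads", paste0(s, "_R2.fastq")))
    reports[[s]] <- cbind(sample_id = s, res$report)
  }
  write.table(do.call(rbind, reports), file.path(sdir, "qc_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list.files(sdir, recursive = TRUE, full.names = TRUE)
}

run_stage_build_db <- function(cfg, out, sdir) {
  g <- read_genome_set(file.path(out, "simulate", "genomes.fasta"),
                       file.path(out, "simulate", "genomes.tsv"))
  p <- cfg$build_db
  cur <- curate_genomes(g, tukey_k = p$tukey_k %||% 2,
                        cluster_threshold = p$cluster_threshold %||% 0.9,
                        kmer_k = p$kmer_k %||% 12)
  write_genome_set(cur$kept, file.path(sdir, "curated.fasta"),
                   file.path(sdir, "curated.tsv"))
  write.table(cur$report, file.path(sdir, "curation_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list.files(sdir, recursive = TRUE, full.names = TRUE)
}

qc_reads_of <- function(out, s) {
  read_fastq_pairs(file.path(out, "qc", "reads", paste0(s, "_R1.fastq")),
                   file.path(out, "qc", "reads", paste0(s, "_R2.fastq")))
}

run_stage_profile <- function(cfg, out, sdir) {
  design <- pipeline_samples(out)
  db <- read_genome_set(file.path(out, "build_db", "curated.fasta"),
                        file.path(out, "build_db", "curated.tsv"))
  p <- cfg$profile
  pcfg <- profiler_config(
    n_pairs_per_subsample = p$n_pairs_per_subsample %||% 1000,
    n_repeats = p$n_repeats %||% 5,
    rare_sample_threshold = p$rare_sample_threshold %||% 2)
  samples <- lapply(design$sample_id, function(s) qc_reads_of(out, s))
  names(samples) <- design$sample_id
  res <- profile_cohort(samples, db, pcfg, seed = cfg$seed)
  write_abundance_tsv(res$abundance, file.path(sdir, "species_abundance.tsv"))
  write.table(data.frame(sample_id = names(res$mapped_read_ratio),
                         mapped_read_ratio = res$mapped_read_ratio),
              file.path(sdir, "mapped_ratio.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list.files(sdir, recursive = TRUE, full.names = TRUE)
}

read_catalog <- function(fasta, tsv, aa = FALSE) {
  ann <- read.table(tsv, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
  seqs <- if (file.size(fasta) > 0) {
    x <- if (aa) Biostrings::readAAStringSet(fasta) else
      Biostrings::readDNAStringSet(fasta)
    setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else character(0)
  list(sequences = seqs, annotation = ann)
}

run_stage_cazy <- function(cfg, out, sdir) {
  design <- pipeline_samples(out)
  cat_ <- read_catalog(file.path(out, "simulate", "cazy.faa"),
                       file.path(out, "simulate", "cazy.tsv"), aa = TRUE)
  samples <- lapply(design$sample_id, function(s) qc_reads_of(out, s))
  names(samples) <- design$sample_id
  if (length(cat_$sequences)) {
    res <- cazy_profile(samples, cat_, min_score = cfg$cazy$min_score %||% 60,
                        max_evalue = cfg$cazy$max_evalue %||% 1e-5)
    write_abundance_tsv(res$abundance, file.path(sdir, "family_abundance.tsv"))
    nf <- data.frame(sample_id = names(res$n_families),
                     n_families = res$n_families)
  } else {
    nf <- data.frame(sample_id = design$sample_id, n_families = 0L)
  }
  write.table(nf, file.path(sdir, "n_families.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list.files(sdir, recursive = TRUE, full.names = TRUE)
}

run_stage_resistome <- function(cfg, out, sdir) {
  design <- pipeline_samples(out)
  arg <- read_catalog(file.path(out, "simulate", "arg.fasta"),
                      file.path(out, "simulate", "arg.tsv"))
  db <- read_genome_set(file.path(out, "build_db", "curated.fasta"),
                        file.path(out, "build_db", "curated.tsv"))
  gidx <- alignment_index(db, alphabet = "dna", target_kind = "genome")
  arg_hits <- list(); gen_hits <- list(); n_pairs <- c()
  phen_rows <- list()
  for (s in design$sample_id) {
    pr <- qc_reads_of(out, s)
    n_pairs[s] <- nrow(pr)
    if (length(arg$sequences)) {
      aidx <- alignment_index(arg$sequences, alphabet = "dna",
                              target_kind = "arg_gene")
      h1 <- align_reads(setNames(pr$seq1, pr$pair_id), aidx)
      h2 <- align_reads(setNames(pr$seq2, pr$pair_id), aidx)
      ah <- merge_mate_hits(h1, h2)
    } else ah <- data.frame(pair_id = character(0), gene_id = character(0))
    arg_hits[[s]] <- ah
    gh <- align_reads(c(setNames(pr$seq1, pr$pair_id),
                        setNames(pr$seq2, pr$pair_id)), gidx,
                      min_score = 50, max_evalue = 1e-5, min_identity = 0.9)
    gen_hits[[s]] <- data.frame(pair_id = gh$read_id, accession = gh$target_id,
                                stringsAsFactors = FALSE)
    ab <- arg_abundance(ah, arg$annotation)
    phen_rows[[s]] <- data.frame(sample_id = s,
                                 phenotype = names(ab$phenotype_abundance),
                                 abundance = ab$phenotype_abundance,
                                 n_args = ab$n_args, row.names = NULL)
  }
  write.table(do.call(rbind, phen_rows),
              file.path(sdir, "phenotype_abundance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  net <- co_assignment_edges(arg_hits, gen_hits, arg, db$metadata,
                             design, n_pairs)
  write.table(net$edges, file.path(sdir, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(net$nodes, file.path(sdir, "nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(net$edges))
    write_resistome_graphml(net, file.path(sdir, "network.graphml"))
  list.files(sdir, recursive = TRUE, full.names = TRUE)
}

run_stage_diversity <- function(cfg, out, sdir) {
  ab <- read_abundance_tsv(file.path(out, "profile", "species_abundance.tsv"))
  treef <- file.path(out, "simulate", "taxonomy.nwk")
  tree <- if (file.exists(treef)) ape::read.tree(treef) else NULL
  if (!is.null(tree)) {
    sp <- setdiff(colnames(ab), "unassigned")
    tree_ok <- all(tree_label(sp) %in% tree$tip.label)
    if (!tree_ok) tree <- NULL
  }
  div <- diversity_report(ab, tree = tree)
  write.table(div, file.path(sdir, "diversity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(ab) >= 3) {
    pc <- pcoa_spearman(ab)
    coords <- data.frame(sample_id = rownames(pc$points), pc$points,
                         check.names = FALSE)
    write.table(coords, file.path(sdir, "pcoa.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list.files(sdir, recursive = TRUE, full.names = TRUE)
}

run_stage_associate <- function(cfg, out, sdir) {
  ab <- read_abundance_tsv(file.path(out, "profile", "species_abundance.tsv"))
  design <- pipeline_samples(out)
  p <- cfg$associate
  res <- associate(ab, design, target = p$target %||% "habitat",
                   adjust_for = p$adjust_for %||% character(0))
  write.table(res, file.path(sdir, "association.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list.files(sdir, recursive = TRUE, full.names = TRUE)
}
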