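# Synthetic multi-sample communities with known ground truth: genomes with
# drafts/variants and plasmids, spiked ARG and CAZy genes, log-normal
# abundances with planted habitat/site effects, and paired reads carrying
# labeled QC defects. Every downstream stage is validated against the truth
# objects produced here.

DNA_BASES <- c("A", "C", "G", "T")

# the 61 sense codons, used to build stop-free ORF-like gene sequences
sense_codons <- function() {
  all3 <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

mutate_dna <- function(seq, rate) {
  L <- nchar(seq)
  n <- rbinom(1, L, rate)
  if (n == 0) return(seq)
  pos <- sample.int(L, n)
  old <- substring(seq, pos, pos)
  new <- DNA_BASES[(match(old, DNA_BASES) - 1L +
                      sample.int(3, n, replace = TRUE)) %% 4L + 1L]
  cpp_apply_subs(seq, rep(1L, n), as.integer(pos), new)[[1]]
}

#' Generate a synthetic reference genome panel
#'
#' Each species receives a primary complete chromosome (the strain reads are
#' later simulated from), possibly a plasmid attached to it, and 0-3
#' additional variant records (mutated, length-jittered copies, mostly
#' drafts) so that database curation has genuine work to do. A fraction of
#' species are unnamed `"Genus sp."` placeholders destined for genus-level
#' clustering.
#'
#' @param n_species number of species (>= 1).
#' @param length_range two integers, chromosome length range in bp (>= 1000).
#' @param plasmid_prob probability that a species' source strain carries a
#'   plasmid (5-15 kb).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param p_unnamed fraction of species left as "Genus sp." placeholders.
#' @param max_variants maximum extra records per species.
#' @param variant_divergence per-base substitution rate of variant records.
#' @param p_draft_variant probability a variant record is a draft.
#' @return a [genome_set()].
#' @export
generate_genomes <- function(n_species, length_range = c(20000, 60000),
                             plasmid_prob = 0.3, seed = NULL,
                             p_unnamed = 0.3, max_variants = 3,
                             variant_divergence = 0.03,
                             p_draft_variant = 0.7) {
  if (!is.numeric(n_species) || n_species < 1) stopf("n_species must be >= 1")
  if (length(length_range) != 2 || any(length_range < 1000) ||
      length_range[1] > length_range[2])
    stopf("length_range must be two values >= 1000 in increasing order")
  if (plasmid_prob < 0 || plasmid_prob > 1) stopf("plasmid_prob must be in [0,1]")
  with_rng(seed, {
    n_genera <- max(1, ceiling(n_species / 2))
    genus_of <- sort(sample.int(n_genera, n_species, replace = TRUE))
    genus_names <- sprintf("Equigenus%02d", seq_len(n_genera))
    unnamed <- runif(n_species) < p_unnamed
    seqs <- character(0)
    meta <- list()
    acc_n <- 0L
    new_acc <- function() {
      acc_n <<- acc_n + 1L
      sprintf("SYN%04d", acc_n)
    }
    for (i in seq_len(n_species)) {
      genus <- genus_names[genus_of[i]]
      L <- round(runif(1, length_range[1], length_range[2]))
      gc <- runif(1, 0.35, 0.62)
      primary_acc <- new_acc()
      species <- if (unnamed[i]) sprintf("%s sp. %s", genus, primary_acc)
                 else sprintf("%s species%02d", genus, i)
      primary <- random_dna(L, gc)
      seqs[primary_acc] <- primary
      meta[[length(meta) + 1]] <- data.frame(
        accession = primary_acc, species = species, genus = genus,
        completeness = "complete", replicon = "chromosome",
        parent = NA_character_, named = !unnamed[i], source = TRUE)
      plasmid_seq <- NULL
      if (runif(1) < plasmid_prob) {
        pacc <- new_acc()
        plasmid_seq <- random_dna(round(runif(1, 5000, 15000)), gc)
        seqs[pacc] <- plasmid_seq
        meta[[length(meta) + 1]] <- data.frame(
          accession = pacc, species = species, genus = genus,
          completeness = "complete", replicon = "plasmid",
          parent = primary_acc, named = !unnamed[i], source = TRUE)
      }
      nv <- sample(0:max_variants, 1,
                   prob = c(0.35, 0.3, 0.2, 0.15)[seq_len(max_variants + 1)])
      for (v in seq_len(nv)) {
        vacc <- new_acc()
        vs <- mutate_dna(primary, variant_divergence)
        vs <- substr(vs, 1, round(nchar(vs) * runif(1, 0.97, 1)))
        draft <- runif(1) < p_draft_variant
        seqs[vacc] <- vs
        meta[[length(meta) + 1]] <- data.frame(
          accession = vacc, species = species, genus = genus,
          completeness = if (draft) "draft" else "complete",
          replicon = if (draft) "contig" else "chromosome",
          parent = NA_character_, named = !unnamed[i], source = FALSE)
        # variant strains of a plasmid-bearing species carry a diverged
        # plasmid copy, so every strain record represents a whole genome
        if (!is.null(plasmid_seq)) {
          vpacc <- new_acc()
          seqs[vpacc] <- mutate_dna(plasmid_seq, variant_divergence)
          meta[[length(meta) + 1]] <- data.frame(
            accession = vpacc, species = species, genus = genus,
            completeness = if (draft) "draft" else "complete",
            replicon = "plasmid", parent = vacc, named = !unnamed[i],
            source = FALSE)
        }
      }
    }
    genome_set(seqs, do.call(rbind, meta))
  })
}

#' Spike annotated ARG and CAZy genes into a genome panel
#'
#' Writes ORF-like (stop-free) gene sequences into non-overlapping positions
#' of source genomes, so that each catalog entry is a verbatim substring of
#' its host replicon. ARG genes carry a resistance phenotype and mechanism
#' (CARD-style); CAZy genes carry a family label and amino-acid length
#' (dbCAN-style) and their catalog sequence is the translated protein.
#'
#' @param genomes a [genome_set()].
#' @param arg_catalog_size,cazy_catalog_size number of genes to spike (>= 0).
#' @param seed integer seed.
#' @param arg_length_range,cazy_length_range gene length ranges in bp; CAZy
#'   lengths are rounded to codon multiples.
#' @param arg_plasmid_bias probability an ARG lands on a plasmid when
#'   plasmids exist.
#' @param arg_hosts optional accessions restricting ARG host replicons.
#' @return a list with elements `genomes` (modified panel), `arg_catalog`
#'   (`$sequences` DNA, `$annotation`), `cazy_catalog` (`$sequences`
#'   protein, `$dna`, `$annotation`) and `spiked_genes` (truth table).
#' @export
spike_genes <- function(genomes, arg_catalog_size, cazy_catalog_size,
                        seed = NULL, arg_length_range = c(600, 1500),
                        cazy_length_range = c(450, 1500),
                        arg_plasmid_bias = 0.5, arg_hosts = NULL) {
  stopifnot(inherits(genomes, "genome_set"))
  if (arg_catalog_size < 0 || cazy_catalog_size < 0)
    stopf("catalog sizes must be >= 0")
  arg_pool <- data.frame(
    stem = c("tet(Q)", "tet(W)", "tet(40)", "lnu(C)", "blaTEM", "aph(3')",
             "erm(B)", "sul2", "cfxA", "mef(A)"),
    phenotype = c("tetracycline", "tetracycline", "tetracycline",
                  "lincosamide", "beta-lactam", "aminoglycoside",
                  "macrolide", "sulfonamide", "beta-lactam", "macrolide"),
    mechanism = c("ribosomal protection", "ribosomal protection",
                  "efflux pump", "nucleotidyltransferase", "beta-lactamase",
                  "phosphotransferase", "rRNA methyltransferase",
                  "target replacement", "beta-lactamase", "efflux pump"),
    stringsAsFactors = FALSE)
  fam_pool <- c("GT2", "GH2", "GT4", "GH3", "GT35", "GT78", "GH29", "GH31",
                "GH13", "GH5", "GH9", "GH48", "CE1", "PL1", "CBM50", "AA3")
  with_rng(seed, {
    seqs <- genomes$sequences
    meta <- genomes$metadata
    used <- lapply(setNames(vector("list", length(seqs)), names(seqs)),
                   function(x) NULL)
    codons <- sense_codons()
    place_gene <- function(len, host_acc) {
      L <- nchar(seqs[[host_acc]])
      if (len > L) stopf("gene of %d bp longer than host genome %s (%d bp)",
                         len, host_acc, L)
      for (try in 1:100) {
        start <- sample.int(L - len + 1L, 1)
        iv <- c(start, start + len - 1L)
        clash <- any(vapply(used[[host_acc]], function(u)
          iv[1] <= u[2] && u[1] <= iv[2], logical(1)))
        if (!clash) {
          used[[host_acc]] <<- c(used[[host_acc]], list(iv))
          return(start)
        }
      }
      stopf("no room to place a %d bp gene in %s", len, host_acc)
    }
    make_orf <- function(len_codons) {
      paste0("ATG", paste(sample(codons, len_codons - 1, replace = TRUE),
                          collapse = ""))
    }
    src <- meta[meta$source, , drop = FALSE]
    chrom_hosts <- src$accession[src$replicon != "plasmid"]
    plasmid_hosts <- src$accession[src$replicon == "plasmid"]
    if (!is.null(arg_hosts)) {
      chrom_hosts <- intersect(chrom_hosts, arg_hosts)
      plasmid_hosts <- intersect(plasmid_hosts, arg_hosts)
    }
    spiked <- list()
    insert <- function(gene_dna, host_acc) {
      start <- place_gene(nchar(gene_dna), host_acc)
      s <- seqs[[host_acc]]
      seqs[[host_acc]] <<- paste0(substr(s, 1, start - 1), gene_dna,
                                  substr(s, start + nchar(gene_dna), nchar(s)))
      start
    }
    # ARG catalog
    arg_seqs <- character(0); arg_ann <- list()
    if (arg_catalog_size > 0) {
      picks <- arg_pool[((seq_len(arg_catalog_size) - 1) %% nrow(arg_pool)) + 1, ]
      for (i in seq_len(arg_catalog_size)) {
        len <- 3 * round(runif(1, arg_length_range[1], arg_length_range[2]) / 3)
        use_plasmid <- length(plasmid_hosts) > 0 &&
          (length(chrom_hosts) == 0 || runif(1) < arg_plasmid_bias)
        host <- if (use_plasmid) sample1(plasmid_hosts) else
          sample1(chrom_hosts)
        dna <- make_orf(len / 3)
        start <- insert(dna, host)
        gid <- sprintf("%s_%02d", gsub("[()']", "", picks$stem[i]), i)
        arg_seqs[gid] <- dna
        arg_ann[[i]] <- data.frame(
          gene_id = gid, gene_name = picks$stem[i],
          phenotype = picks$phenotype[i], mechanism = picks$mechanism[i],
          host_accession = host, start = start, end = start + len - 1L,
          length_bp = len, stringsAsFactors = FALSE)
        spiked[[length(spiked) + 1]] <- data.frame(
          gene_id = gid, accession = host, start = start,
          end = start + len - 1L, catalog = "ARG")
      }
    }
    # CAZy catalog
    cazy_dna <- character(0); cazy_ann <- list()
    if (cazy_catalog_size > 0) {
      fams <- fam_pool[((seq_len(cazy_catalog_size) - 1) %% length(fam_pool)) + 1]
      for (i in seq_len(cazy_catalog_size)) {
        len <- 3 * round(runif(1, cazy_length_range[1], cazy_length_range[2]) / 3)
        host <- sample1(src$accession[src$replicon != "plasmid"])
        dna <- make_orf(len / 3)
        start <- insert(dna, host)
        gid <- sprintf("cazy_%s_%02d", fams[i], i)
        cazy_dna[gid] <- dna
        cazy_ann[[i]] <- data.frame(
          gene_id = gid, family = fams[i], length_aa = len / 3,
          host_accession = host, start = start, end = start + len - 1L,
          stringsAsFactors = FALSE)
        spiked[[length(spiked) + 1]] <- data.frame(
          gene_id = gid, accession = host, start = start,
          end = start + len - 1L, catalog = "CAZy")
      }
    }
    cazy_aa <- if (length(cazy_dna))
      setNames(as.character(Biostrings::translate(
        Biostrings::DNAStringSet(cazy_dna))), names(cazy_dna))
      else character(0)
    list(
      genomes = genome_set(seqs, meta),
      arg_catalog = list(
        sequences = arg_seqs,
        annotation = if (length(arg_ann)) do.call(rbind, arg_ann) else
          data.frame(gene_id = character(0), gene_name = character(0),
                     phenotype = character(0), mechanism = character(0))),
      cazy_catalog = list(
        sequences = cazy_aa, dna = cazy_dna,
        annotation = if (length(cazy_ann)) do.call(rbind, cazy_ann) else
          data.frame(gene_id = character(0), family = character(0),
                     length_aa = integer(0))),
      spiked_genes = if (length(spiked)) do.call(rbind, spiked) else
        data.frame(gene_id = character(0), accession = character(0),
                   start = integer(0), end = integer(0),
                   catalog = character(0)))
  })
}

#' Generate a sample design table with planted abundance effects
#'
#' Species baseline abundances are log-normal (species-level means drawn
#' once, per-sample noise on top); designated signal species receive a
#' multiplicative fold change in the matching habitat or site. Abundances
#' are renormalized per sample to sum to one.
#'
#' @param species character vector of species names.
#' @param cohorts data.frame with columns `habitat`, `site`, `n` (samples
#'   per cohort); needs >= 2 habitats or >= 2 sites.
#' @param effect_spec list of `list(species=, variable="habitat"|"site",
#'   level=, fold=)` entries.
#' @param seed integer seed.
#' @param sigma_species,sigma_sample SDs of the species-level and
#'   sample-level log-normal components.
#' @return list with `design` (sample_id, site, habitat), `abundance`
#'   (samples x species truth matrix, rows sum to 1) and `signal`
#'   (the planted effects).
#' @export
generate_design <- function(species, cohorts, effect_spec = list(),
                            seed = NULL, sigma_species = 1,
                            sigma_sample = 0.5) {
  stopifnot(is.data.frame(cohorts),
            all(c("habitat", "site", "n") %in% names(cohorts)))
  if (length(unique(cohorts$habitat)) < 2 && length(unique(cohorts$site)) < 2)
    stopf("need >= 2 habitats or >= 2 sites for association tests")
  for (e in effect_spec) {
    stopifnot(all(c("species", "variable", "level", "fold") %in% names(e)))
    if (!e$species %in% species) stopf("signal species '%s' unknown", e$species)
  }
  with_rng(seed, {
    nsp <- length(species)
    mu <- rnorm(nsp, 0, sigma_species)
    # optional pinned baseline share for signal species: keeps the planted
    # species minor so the compositional shift on null species stays
    # negligible and the association null remains (approximately) valid
    pinned <- vapply(effect_spec, function(e)
      if (!is.null(e$baseline_share)) e$species else NA_character_,
      character(1))
    if (any(!is.na(pinned))) {
      shares <- vapply(effect_spec[!is.na(pinned)],
                       function(e) e$baseline_share, numeric(1))
      others <- !(species %in% pinned)
      denom <- sum(exp(mu[others]))
      for (j in seq_along(shares)) {
        s_idx <- which(species == pinned[!is.na(pinned)][j])
        mu[s_idx] <- log(shares[j] / (1 - sum(shares))) + log(denom)
      }
    }
    rows <- list()
    for (i in seq_len(nrow(cohorts))) {
      for (j in seq_len(cohorts$n[i])) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("%s_%s_%02d", cohorts$site[i],
                              substr(cohorts$habitat[i], 1, 3), j),
          site = cohorts$site[i], habitat = cohorts$habitat[i],
          stringsAsFactors = FALSE)
      }
    }
    design <- do.call(rbind, rows)
    if (anyDuplicated(design$sample_id)) stopf("duplicate sample ids")
    ab <- matrix(0, nrow(design), nsp,
                 dimnames = list(design$sample_id, species))
    for (s in seq_len(nrow(design))) {
      lg <- mu + rnorm(nsp, 0, sigma_sample)
      for (e in effect_spec) {
        if (design[[e$variable]][s] == e$level)
          lg[species == e$species] <- lg[species == e$species] + log(e$fold)
      }
      a <- exp(lg)
      ab[s, ] <- a / sum(a)
    }
    signal <- if (length(effect_spec))
      do.call(rbind, lapply(effect_spec, as.data.frame)) else
      data.frame(species = character(0), variable = character(0),
                 level = character(0), fold = numeric(0))
    list(design = design, abundance = ab, signal = signal)
  })
}
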