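#' Reference genome set
#'
#' Container pairing genome sequences with their per-record metadata
#' (species, genus, completeness, replicon type, plasmid parent). The unit
#' record is a replicon: a chromosome, plasmid or unresolved contig.
#'
#' @param sequences named character vector of DNA sequences; names are
#'   accessions.
#' @param metadata data.frame with one row per sequence and columns
#'   `accession`, `species`, `genus`, `completeness`
#'   (`"complete"`/`"draft"`), `replicon`
#'   (`"chromosome"`/`"plasmid"`/`"contig"`). Optional columns: `parent`
#'   (plasmid's host accession), `named` (FALSE for "Genus sp." species
#'   placeholders), `source` (TRUE for the strain reads are simulated
#'   from). `length_bp` and `gc_fraction` are recomputed from the
#'   sequences.
#' @return an object of class `genome_set`.
#' @export
genome_set <- function(sequences, metadata) {
  stopifnot(is.character(sequences), length(sequences) >= 1,
            !is.null(names(sequences)), is.data.frame(metadata))
  req <- c("accession", "species", "genus", "completeness", "replicon")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stopf("metadata lacks columns: %s", paste(miss, collapse = ", "))
  if (!setequal(metadata$accession, names(sequences)) ||
      anyDuplicated(metadata$accession))
    stopf("metadata accessions must match sequence names 1:1")
  metadata <- metadata[match(names(sequences), metadata$accession), , drop = FALSE]
  rownames(metadata) <- NULL
  bad <- setdiff(unique(metadata$replicon), c("chromosome", "plasmid", "contig"))
  if (length(bad)) stopf("unknown replicon type: %s", paste(bad, collapse = ", "))
  metadata$length_bp <- nchar(sequences)
  metadata$gc_fraction <- gc_fraction_of(sequences)
  if (is.null(metadata$parent)) metadata$parent <- NA_character_
  if (is.null(metadata$named))
    metadata$named <- !grepl(" sp\\.", metadata$species)
  if (is.null(metadata$source)) metadata$source <- TRUE
  structure(list(sequences = sequences, metadata = metadata),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("<genome_set> %d records, %d species, %d genera\n",
              nrow(m), length(unique(m$species)), length(unique(m$genus))))
  cat(sprintf("  replicons: %s\n",
              paste(sprintf("%s=%d", names(table(m$replicon)),
                            table(m$replicon)), collapse = " ")))
  cat(sprintf("  total %.2f Mb, GC %.1f-%.1f%%\n",
              sum(m$length_bp) / 1e6, 100 * min(m$gc_fraction),
              100 * max(m$gc_fraction)))
  invisible(x)
}

#' @export
length.genome_set <- function(x) length(x$sequences)

# Subset a genome_set by accession.
subset_genomes <- function(gs, accessions) {
  keep <- names(gs$sequences) %in% accessions
  if (!any(keep)) stopf("no matching accessions")
  genome_set(gs$sequences[keep],
             gs$metadata[gs$metadata$accession %in% accessions, , drop = FALSE])
}

#' Write / read a genome set as FASTA plus a metadata TSV
#'
#' @param gs a [genome_set()].
#' @param fasta_path,meta_path output/input paths.
#' @return `write_genome_set()` returns the paths invisibly;
#'   `read_genome_set()` returns a `genome_set`.
#' @export
write_genome_set <- function(gs, fasta_path, meta_path) {
  x <- Biostrings::DNAStringSet(gs$sequences)
  Biostrings::writeXStringSet(x, fasta_path)
  write.table(gs$metadata, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fasta_path, meta = meta_path))
}

#' @rdname write_genome_set
#' @export
read_genome_set <- function(fasta_path, meta_path) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  meta <- read.table(meta_path, sep = "\t", header = TRUE, quote = "",
                     comment.char = "", stringsAsFactors = FALSE)
  genome_set(seqs, meta)
}

# Per-genome span: a genome's length is its chromosome (or contig/draft
# record) plus any plasmids attached to it via `parent`.
genome_span <- function(gs) {
  m <- gs$metadata
  main <- m[m$replicon != "plasmid", , drop = FALSE]
  plas <- m[m$replicon == "plasmid", , drop = FALSE]
  extra <- setNames(rep(0, nrow(main)), main$accession)
  if (nrow(plas)) {
    add <- tapply(plas$length_bp, plas$parent, sum)
    add <- add[names(add) %in% names(extra)]
    extra[names(add)] <- extra[names(add)] + add
  }
  setNames(main$length_bp + extra, main$accession)
}
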