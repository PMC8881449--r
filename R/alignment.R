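# Read -> target alignment contract shared by the host-removal, taxonomic,
# CAZy and ARG stages. The internal desk-scale implementation is exact
# k-mer seeding plus ungapped extension (+1/-2) along the seed diagonal;
# bit scores and E-values use Karlin-Altschul statistics with fixed
# constants (lambda = 1.28, K = 0.46, the classic +1/-2 ungapped values).
# Externally produced alignments (BLAST m8, SAM) can be substituted.

#' Build an alignment index over a target set
#'
#' @param targets named character vector of target sequences, a
#'   [genome_set()], or a catalog list with a `sequences` element.
#' @param alphabet `"dna"` or `"protein"`. Protein indices are searched by
#'   six-frame translation of DNA reads.
#' @param k seed length (default 16 for DNA, 4 for protein).
#' @param target_kind label stored on hits (`"genome"`, `"arg_gene"`,
#'   `"cazy_gene"`, `"host"`).
#' @return an object of class `alignment_index`.
#' @export
alignment_index <- function(targets, alphabet = c("dna", "protein"), k = NULL,
                            target_kind = "genome") {
  alphabet <- match.arg(alphabet)
  if (inherits(targets, "genome_set")) targets <- targets$sequences
  if (is.list(targets) && !is.null(targets$sequences))
    targets <- targets$sequences
  targets <- unlist(targets)
  if (!length(targets)) stopf("empty target set")
  if (is.null(names(targets)) || anyDuplicated(names(targets)))
    stopf("targets must have unique names")
  k <- k %||% if (alphabet == "dna") 16L else 4L
  structure(list(sequences = targets, alphabet = alphabet, k = as.integer(k),
                 target_kind = target_kind),
            class = "alignment_index")
}

#' @export
print.alignment_index <- function(x, ...) {
  cat(sprintf("<alignment_index> %d %s targets (%.1f kb), seed k=%d\n",
              length(x$sequences), x$alphabet,
              sum(nchar(x$sequences)) / 1e3, x$k))
  invisible(x)
}

# six-frame translation of DNA reads; returns named character with names
# "<i>|<frame>" where i indexes the input read
six_frame <- function(seqs) {
  out <- list()
  dna <- Biostrings::DNAStringSet(seqs)
  rc <- Biostrings::reverseComplement(dna)
  for (f in 1:3) {
    for (strand in c("F", "R")) {
      x <- if (strand == "F") dna else rc
      x <- Biostrings::subseq(x, start = f,
                              width = pmax(0L, (Biostrings::width(x) - f + 1L) %/% 3L) * 3L)
      aa <- suppressWarnings(Biostrings::translate(x, if.fuzzy.codon = "X"))
      out[[paste0(strand, f)]] <- setNames(
        as.character(aa), paste0(seq_along(seqs), "|", strand, f))
    }
  }
  unlist(unname(out))
}

#' Align reads against an index
#'
#' `all_hits` mode reports every target passing the thresholds (one best
#' ungapped segment per read/target); `best_hit` keeps only the top-scoring
#' target per read. Thresholds are applied as `score > min_score`,
#' `evalue < max_evalue` (strict, matching the downstream merge rule) and
#' `identity >= min_identity`.
#'
#' @param reads named character vector of DNA read sequences.
#' @param index an [alignment_index()].
#' @param mode `"all_hits"` or `"best_hit"`.
#' @param min_score minimum bit score (exclusive).
#' @param max_evalue maximum E-value (exclusive).
#' @param min_identity minimum identity of the aligned segment.
#' @param db_len database-size term of the E-value (default: total target
#'   length).
#' @return data.frame with columns `read_id`, `target_id`, `target_kind`,
#'   `score` (bit score), `evalue`, `identity`, `raw_score`, `length`,
#'   `strand`.
#' @export
align_reads <- function(reads, index, mode = c("all_hits", "best_hit"),
                        min_score = 0, max_evalue = 10, min_identity = 0,
                        db_len = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(index, "alignment_index"))
  if (!length(reads)) return(empty_hits(index$target_kind))
  ids <- names(reads) %||% as.character(seq_along(reads))
  db <- db_len %||% sum(nchar(index$sequences))
  if (index$alphabet == "dna") {
    raw <- cpp_align(unname(reads), unname(index$sequences), index$k, TRUE,
                     1.0, -2.0, 1.28, 0.46, db, min_score, max_evalue,
                     min_identity, mode == "best_hit")
    read_id <- ids[raw$read]
  } else {
    aa <- six_frame(reads)
    raw <- cpp_align(unname(aa), unname(index$sequences), index$k, FALSE,
                     1.0, -2.0, 1.28, 0.46, db, min_score, max_evalue,
                     min_identity, FALSE)
    src <- as.integer(sub("\\|.*$", "", names(aa)[raw$read]))
    # best frame per read x target
    if (nrow(raw)) {
      key <- paste(src, raw$target)
      ord <- order(key, -raw$score)
      raw <- raw[ord[!duplicated(key[ord])], , drop = FALSE]
      src <- as.integer(sub("\\|.*$", "", names(aa)[raw$read]))
      if (mode == "best_hit" && nrow(raw)) {
        ord2 <- order(src, -raw$score, names(index$sequences)[raw$target])
        raw <- raw[ord2[!duplicated(src[ord2])], , drop = FALSE]
        src <- as.integer(sub("\\|.*$", "", names(aa)[raw$read]))
      }
    }
    read_id <- ids[src]
  }
  if (!nrow(raw)) return(empty_hits(index$target_kind))
  data.frame(read_id = read_id,
             target_id = names(index$sequences)[raw$target],
             target_kind = index$target_kind,
             score = raw$score, evalue = raw$evalue,
             identity = raw$identity, raw_score = raw$raw_score,
             length = raw$length, strand = raw$strand,
             stringsAsFactors = FALSE)
}

empty_hits <- function(kind = "genome") {
  data.frame(read_id = character(0), target_id = character(0),
             target_kind = character(0), score = numeric(0),
             evalue = numeric(0), identity = numeric(0),
             raw_score = numeric(0), length = integer(0),
             strand = integer(0), stringsAsFactors = FALSE)
}

#' Import externally produced alignments
#'
#' Normalizes BLAST tabular (m8 / outfmt 6) or SAM alignments to the
#' internal hit table, so bowtie2 or DIAMOND output can stand in for the
#' internal aligner. For m8, column 12 maps to `score` and column 11 to
#' `evalue`; for SAM, unmapped records are dropped and the `AS` tag (falling
#' back to MAPQ) maps to `score` with `evalue` set to 0.
#'
#' @param path input file.
#' @param format `"blast_m8"` or `"sam"`.
#' @param target_kind label stored on hits.
#' @return hit data.frame as from [align_reads()].
#' @export
read_external_hits <- function(path, format = c("blast_m8", "sam"),
                               target_kind = "genome") {
  format <- match.arg(format)
  if (format == "blast_m8") {
    if (file.size(path) == 0) return(empty_hits(target_kind))
    nf <- count.fields(path, sep = "\t", quote = "")
    bad <- which(nf != 12)
    if (length(bad))
      stopf("malformed m8 line %d in %s: expected 12 fields, got %d",
            bad[1], path, nf[bad[1]])
    m8 <- read.table(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
    return(data.frame(read_id = as.character(m8$V1),
                      target_id = as.character(m8$V2),
                      target_kind = target_kind,
                      score = as.numeric(m8$V12), evalue = as.numeric(m8$V11),
                      identity = as.numeric(m8$V3) / 100,
                      raw_score = NA_real_, length = as.integer(m8$V4),
                      strand = NA_integer_, stringsAsFactors = FALSE))
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "mapq"),
                               tag = "AS")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- bitwAnd(b$flag, 4L) == 0L
  if (!any(mapped)) return(empty_hits(target_kind))
  score <- b$tag$AS
  if (is.null(score)) score <- rep(NA_real_, length(b$flag))
  score <- ifelse(is.na(score), as.numeric(b$mapq), as.numeric(score))
  data.frame(read_id = b$qname[mapped],
             target_id = as.character(b$rname[mapped]),
             target_kind = target_kind,
             score = score[mapped], evalue = 0,
             identity = NA_real_, raw_score = NA_real_,
             length = NA_integer_, strand = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Write hits as TSV
#' @param hits hit data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
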