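#' Paired sequencing reads
#'
#' Mated 150-bp style read pairs with Phred+33 quality strings, the unit
#' flowing through QC and all alignment stages.
#'
#' @param pair_id character vector of unique pair identifiers.
#' @param seq1,qual1,seq2,qual2 sequences and quality strings for the R1
#'   and R2 mates; each quality string has the same length as its sequence.
#' @return an object of class `read_pairs` (a data.frame).
#' @export
read_pairs <- function(pair_id, seq1, qual1, seq2, qual2) {
  stopifnot(length(pair_id) == length(seq1), length(seq1) == length(seq2))
  if (anyDuplicated(pair_id)) stopf("pair ids must be unique")
  if (any(nchar(seq1) != nchar(qual1)) || any(nchar(seq2) != nchar(qual2)))
    stopf("sequence and quality lengths differ")
  structure(data.frame(pair_id = as.character(pair_id), seq1 = seq1,
                       qual1 = qual1, seq2 = seq2, qual2 = qual2,
                       stringsAsFactors = FALSE),
            class = c("read_pairs", "data.frame"))
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("<read_pairs> %d pairs, read length %d-%d bp\n", nrow(x),
              min(nchar(x$seq1), nchar(x$seq2)),
              max(nchar(x$seq1), nchar(x$seq2))))
  invisible(x)
}

#' Write / read paired FASTQ (Phred+33)
#'
#' @param pairs a [read_pairs()] object.
#' @param r1_path,r2_path FASTQ paths for the two mates.
#' @return `write_fastq_pairs()` returns the paths invisibly;
#'   `read_fastq_pairs()` returns a `read_pairs` object.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  w <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::BStringSet(quals)
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  w(pairs$seq1, pairs$qual1, paste0(pairs$pair_id, "/1"), r1_path)
  w(pairs$seq2, pairs$qual2, paste0(pairs$pair_id, "/2"), r2_path)
  invisible(c(r1 = r1_path, r2 = r2_path))
}

#' @rdname write_fastq_pairs
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(id = sub("/[12]$", "", sub("\\s.*$", "", names(x))),
         seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- rd(r1_path); b <- rd(r2_path)
  if (!identical(a$id, b$id)) stopf("mate ids do not match between files")
  read_pairs(a$id, a$seq, a$qual, b$seq, b$qual)
}
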