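# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means "use the current stream".
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed and a stream index, kept < 2^31.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 1000003 * index) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# sample() without the length-1 "convenience" surprise
sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Total sequenced bases in a set of read pairs
#'
#' Convenience arithmetic used when reasoning about subsampling depth:
#' `n_pairs` read pairs of length `read_len` contain
#' `n_pairs * 2 * read_len` bases (15 million 150-bp pairs = 4.5 Gb).
#'
#' @param n_pairs number of read pairs.
#' @param read_len read length in bp (both mates).
#' @return total number of bases, as a double.
#' @examples
#' total_bases(15e6, 150)  # 4.5e9
#' @export
total_bases <- function(n_pairs, read_len = 150) {
  stopifnot(n_pairs >= 0, read_len >= 1)
  as.numeric(n_pairs) * 2 * read_len
}

# Phred+33 helpers -----------------------------------------------------------

phred_to_string <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

string_to_phred <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

gc_fraction_of <- function(seq) {
  x <- Biostrings::DNAStringSet(seq)
  af <- Biostrings::letterFrequency(x, letters = c("G", "C"))
  as.numeric(rowSums(af)) / Biostrings::width(x)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
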