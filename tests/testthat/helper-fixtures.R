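# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

fix_host <- function(seed = 99, len = 20000) {
  s <- equimeta:::with_rng(seed, equimeta:::random_dna(len, 0.41))
  genome_set(setNames(s, "HOSTFIX1"),
             data.frame(accession = "HOSTFIX1", species = "Equus caballus",
                        genus = "Equus", completeness = "complete",
                        replicon = "chromosome"))
}

# one-row read_pairs with explicit sequences/qualities
fix_pair <- function(seq1, qual1 = NULL, seq2 = NULL, qual2 = NULL,
                     id = "pair1") {
  q <- function(s, qv) if (is.null(qv)) strrep(rawToChar(as.raw(33 + 35)),
                                               nchar(s)) else qv
  seq2 <- seq2 %||% seq1
  read_pairs(id, seq1, q(seq1, qual1), seq2, q(seq2, qual2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

phred_chr <- function(q, n = 1) strrep(intToUtf8(33 + q), n)

# quick random DNA under a fixed seed
rdna <- function(n, seed = NULL, gc = 0.5) {
  equimeta:::with_rng(seed, equimeta:::random_dna(n, gc))
}

# brute-force sliding-window alignment oracle: best local ungapped segment
# (+1/-2) over every diagonal of read x target, independent of the C++ path
oracle_align <- function(read, targets, min_identity = 0) {
  rv <- utf8ToInt(read)
  out <- list()
  for (tn in names(targets)) {
    best <- list(score = -Inf)
    for (orient in 1:2) {
      rs <- if (orient == 1) read else equimeta:::revcomp(read)
      r <- strsplit(rs, "")[[1]]
      t <- strsplit(targets[[tn]], "")[[1]]
      nr <- length(r); nt <- length(t)
      for (diag in (-(nr - 1)):(nt - 1)) {
        i0 <- max(1, 1 - diag); i1 <- min(nr, nt - diag)
        if (i1 < i0) next
        run <- 0; run_m <- 0; run_len <- 0
        b <- -Inf; b_m <- 0; b_len <- 0
        for (i in i0:i1) {
          eq <- r[i] == t[i + diag]
          s <- if (eq) 1 else -2
          if (run <= 0) { run <- s; run_m <- as.integer(eq); run_len <- 1 }
          else { run <- run + s; run_m <- run_m + eq; run_len <- run_len + 1 }
          if (run > b) { b <- run; b_m <- run_m; b_len <- run_len }
        }
        if (b > best$score)
          best <- list(score = b, matches = b_m, len = b_len)
      }
    }
    if (is.finite(best$score) && best$matches / best$len >= min_identity)
      out[[tn]] <- best
  }
  out
}
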