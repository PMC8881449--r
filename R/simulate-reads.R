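# Paired-read simulation with labeled QC defects. Fragments are drawn from
# each species' source strain (chromosome + attached plasmids) with weight
# abundance x replicon length; defective reads are constructed to violate
# exactly one QC rule, and clean reads are rejection-sampled against the QC
# rules so that defect labels are an exact oracle for QC decisions.

#' Built-in adapter sequence
#'
#' A fixed TruSeq-like 33-mer used both by the read simulator (adapter
#' read-through defects) and as the default for adapter detection in QC.
#'
#' @return a length-1 character vector.
#' @export
default_adapter <- function() "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

# pre-generated pool of per-read quality strings (all bases >= Q26)
quality_pool <- function(n_pool, read_len) {
  chars <- strsplit(intToUtf8(33L + 26:40), "")[[1]]
  vapply(seq_len(n_pool), function(i)
    paste(sample(chars, read_len, replace = TRUE), collapse = ""),
    character(1))
}

# draw fragments from a set of replicon sequences; returns R1/R2 strings
draw_fragments <- function(seqs, rec_idx, read_len, insert_range) {
  n <- length(rec_idx)
  lens <- nchar(seqs)[rec_idx]
  frag <- pmin(round(runif(n, insert_range[1], insert_range[2])), lens)
  frag <- pmax(frag, read_len)
  start <- floor(runif(n) * (lens - frag + 1)) + 1
  r1 <- substring(seqs[rec_idx], start, start + read_len - 1)
  r2 <- revcomp(substring(seqs[rec_idx], start + frag - read_len,
                          start + frag - 1))
  swap <- runif(n) < 0.5
  list(seq1 = ifelse(swap, r2, r1), seq2 = ifelse(swap, r1, r2))
}

apply_sequencing_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  n <- length(seqs)
  len <- nchar(seqs)
  n_err <- rbinom(n, len, error_rate)
  tot <- sum(n_err)
  if (tot == 0) return(seqs)
  idx <- rep.int(seq_len(n), n_err)
  pos <- as.integer(floor(runif(tot) * len[idx]) + 1)
  old <- substring(seqs[idx], pos, pos)
  new <- DNA_BASES[(match(old, DNA_BASES, nomatch = 1L) - 1L +
                      sample.int(3, tot, replace = TRUE)) %% 4L + 1L]
  cpp_apply_subs(seqs, idx, pos, new)
}

#' Simulate paired reads from a community with labeled QC defects
#'
#' Read pairs are drawn from the source replicons of each species with
#' probability proportional to `abundance[species] * replicon length`.
#' A fraction of pairs (per `defect_rates`) is constructed to violate
#' exactly one QC rule: `ambiguous` (>= 2 N bases on one mate),
#' `low_quality` (>= 30 interior bases below Q20 on one mate, 3' end left
#' intact so trimming cannot rescue it), `adapter` (adapter read-through on
#' one mate), `host` (both mates drawn from the designated host genome).
#' All remaining reads are labeled `clean` and are guaranteed to pass QC.
#'
#' @param genomes a [genome_set()] of the community.
#' @param abundance named numeric vector of relative species abundances.
#' @param n_pairs number of read pairs (>= 1).
#' @param read_len read length in bp.
#' @param error_rate per-base substitution error rate.
#' @param defect_rates named numeric vector with any of `ambiguous`,
#'   `low_quality`, `adapter`, `host`; each in \[0,1\], summing to <= 1.
#' @param host_genome a [genome_set()] or single sequence used for `host`
#'   defects (required if that rate is > 0).
#' @param adapter adapter sequence used for read-through defects.
#' @param insert_range fragment length range in bp.
#' @param seed integer seed.
#' @param pair_prefix prefix for pair ids.
#' @return list with `pairs` (a [read_pairs()]) and `labels` (data.frame
#'   `pair_id`, `mate` ("R1"/"R2"), `defect`).
#' @export
simulate_reads <- function(genomes, abundance, n_pairs, read_len = 150,
                           error_rate = 0.002,
                           defect_rates = c(ambiguous = 0, low_quality = 0,
                                            adapter = 0, host = 0),
                           host_genome = NULL,
                           adapter = default_adapter(),
                           insert_range = c(250, 450), seed = NULL,
                           pair_prefix = "p") {
  stopifnot(inherits(genomes, "genome_set"))
  if (n_pairs < 1) stopf("n_pairs must be >= 1")
  dr <- c(ambiguous = 0, low_quality = 0, adapter = 0, host = 0)
  if (length(defect_rates)) {
    bad <- setdiff(names(defect_rates), names(dr))
    if (length(bad)) stopf("unknown defect class: %s", paste(bad, collapse = ", "))
    dr[names(defect_rates)] <- defect_rates
  }
  if (any(dr < 0) || any(dr > 1) || sum(dr) > 1)
    stopf("defect rates must be in [0,1] and sum to <= 1")
  if (dr["host"] > 0 && is.null(host_genome))
    stopf("host defects requested but no host_genome given")
  meta <- genomes$metadata
  src <- meta[meta$source, , drop = FALSE]
  if (!nrow(src)) stopf("genome set has no source records")
  missing_sp <- setdiff(names(abundance), src$species)
  if (length(missing_sp))
    stopf("abundance names not in genome set: %s",
          paste(missing_sp, collapse = ", "))
  host_seq <- if (is.null(host_genome)) NULL
    else if (inherits(host_genome, "genome_set")) host_genome$sequences
    else as.character(host_genome)

  with_rng(seed, {
    rec_w <- abundance[src$species] * src$length_bp
    rec_w[is.na(rec_w)] <- 0
    if (sum(rec_w) <= 0) stopf("all sampling weights are zero")
    cls <- sample(c("clean", names(dr)), n_pairs, replace = TRUE,
                  prob = c(1 - sum(dr), dr))
    pool <- quality_pool(min(512L, max(64L, n_pairs)), read_len)
    qc_par <- qc_params(adapter = adapter)
    lowq_chars <- strsplit(intToUtf8(33L + 5:15), "")[[1]]

    gen_pairs <- function(idx, from_host) {
      n <- length(idx)
      if (from_host) {
        hn <- length(host_seq)
        rec <- sample.int(hn, n, replace = TRUE,
                          prob = nchar(host_seq) / sum(nchar(host_seq)))
        fr <- draw_fragments(host_seq, rec, read_len, insert_range)
        rec_id <- names(host_seq)[rec] %||% rep("host", n)
      } else {
        rec <- sample.int(nrow(src), n, replace = TRUE, prob = rec_w)
        fr <- draw_fragments(genomes$sequences[src$accession], rec,
                             read_len, insert_range)
        rec_id <- src$accession[rec]
      }
      fr$seq1 <- apply_sequencing_errors(fr$seq1, error_rate)
      fr$seq2 <- apply_sequencing_errors(fr$seq2, error_rate)
      fr$record <- rec_id
      fr
    }

    seq1 <- seq2 <- character(n_pairs)
    record <- character(n_pairs)
    comm <- which(cls != "host")
    hst <- which(cls == "host")
    if (length(comm)) {
      fr <- gen_pairs(comm, FALSE)
      seq1[comm] <- fr$seq1; seq2[comm] <- fr$seq2; record[comm] <- fr$record
    }
    if (length(hst)) {
      fr <- gen_pairs(hst, TRUE)
      seq1[hst] <- fr$seq1; seq2[hst] <- fr$seq2; record[hst] <- fr$record
    }
    qual1 <- pool[sample.int(length(pool), n_pairs, replace = TRUE)]
    qual2 <- pool[sample.int(length(pool), n_pairs, replace = TRUE)]

    # mate receiving the single-mate defects
    mate_pick <- sample(1:2, n_pairs, replace = TRUE)

    # rejection-sample base reads that would trip adapter detection by
    # chance (done before any defect is planted, so redraws cannot erase a
    # planted defect; adapter tails are planted afterwards)
    redraw_adapter_fp <- function(seqs) {
      for (round in 1:20) {
        hit <- cpp_adapter_match(seqs, adapter, qc_par$adapter_min_overlap,
                                 qc_par$adapter_max_mismatch,
                                 qc_par$adapter_clip_first)
        bad <- which(hit)
        if (!length(bad)) return(seqs)
        for (i in bad) {
          fr <- gen_pairs(i, cls[i] == "host")
          seqs[i] <- fr$seq1
        }
      }
      stopf("could not draw adapter-free reads after 20 rounds")
    }
    seq1 <- redraw_adapter_fp(seq1)
    seq2 <- redraw_adapter_fp(seq2)

    # ambiguous: plant 2-4 N bases
    for (i in which(cls == "ambiguous")) {
      k <- sample(2:4, 1)
      pos <- sample.int(read_len, k)
      if (mate_pick[i] == 1)
        seq1[i] <- cpp_apply_subs(seq1[i], rep(1L, k), pos, rep("N", k))[[1]]
      else
        seq2[i] <- cpp_apply_subs(seq2[i], rep(1L, k), pos, rep("N", k))[[1]]
    }
    # low quality: >= 30 interior bases below Q20; 3' end stays high quality
    for (i in which(cls == "low_quality")) {
      k <- sample(32:40, 1)
      pos <- sample.int(read_len - 5L, k)
      ch <- sample(lowq_chars, k, replace = TRUE)
      if (mate_pick[i] == 1)
        qual1[i] <- cpp_apply_subs(qual1[i], rep(1L, k), pos, ch)[[1]]
      else
        qual2[i] <- cpp_apply_subs(qual2[i], rep(1L, k), pos, ch)[[1]]
    }
    # adapter read-through: replace the 3' tail with an adapter prefix
    for (i in which(cls == "adapter")) {
      a_len <- sample(12:min(nchar(adapter), read_len - 20L), 1)
      patch <- function(s) paste0(substr(s, 1, read_len - a_len),
                                  substr(adapter, 1, a_len))
      if (mate_pick[i] == 1) seq1[i] <- patch(seq1[i])
      else seq2[i] <- patch(seq2[i])
    }

    ids <- sprintf("%s%06d", pair_prefix, seq_len(n_pairs))
    pairs <- read_pairs(ids, seq1, qual1, seq2, qual2)
    defect1 <- ifelse(cls == "host", "host",
                      ifelse(cls != "clean" & mate_pick == 1, cls, "clean"))
    defect2 <- ifelse(cls == "host", "host",
                      ifelse(cls != "clean" & mate_pick == 2, cls, "clean"))
    labels <- data.frame(
      pair_id = rep(ids, each = 2),
      mate = rep(c("R1", "R2"), n_pairs),
      defect = as.vector(rbind(defect1, defect2)),
      stringsAsFactors = FALSE)
    list(pairs = pairs, labels = labels, source_record = record)
  })
}
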