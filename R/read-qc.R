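# Five-rule quality control with pair-aware discarding.
#
# Rule order is trim-first: up to 29 low-quality bases are trimmed from the
# 3' end, then the trimmed read is checked against (1) >= 2 ambiguous bases,
# (2) >= 30 bases below Q20, (3) adapter contamination, (4) host alignment.
# Adapter and host discards also remove the mate; ambiguous/low-quality
# discards orphan the mate into a singleton stream.

#' QC parameter set
#'
#' @param q_threshold Phred threshold defining a low-quality base.
#' @param max_lowq a read with this many or more low-quality bases (after
#'   trimming) is discarded.
#' @param max_ambiguous a read with this many or more N bases is discarded.
#' @param max_trim cap on 3'-end low-quality trimming.
#' @param adapter adapter sequence searched as a read-suffix/adapter-prefix
#'   overlap.
#' @param adapter_min_overlap,adapter_max_mismatch overlap-search settings
#'   (minimum overlap length; maximum mismatch fraction).
#' @param adapter_clip_first bases hard-clipped from the 5' end before the
#'   adapter search (the literal effect of a `-u 6` pre-clip).
#' @param host_min_score,host_max_evalue,host_k thresholds and seed length
#'   for the host-alignment rule (bit score, E-value).
#' @return a named list of parameters.
#' @export
qc_params <- function(q_threshold = 20, max_lowq = 30, max_ambiguous = 2,
                      max_trim = 29, adapter = default_adapter(),
                      adapter_min_overlap = 8, adapter_max_mismatch = 0.1,
                      adapter_clip_first = 6, host_min_score = 50,
                      host_max_evalue = 1e-5, host_k = 16) {
  as.list(environment())
}

#' Trim low-quality bases from the 3' end
#'
#' Removes the maximal run of trailing bases below the quality threshold,
#' capped at `max_trim` bases; the read is never discarded by this rule.
#'
#' @param seq,qual sequence and Phred+33 quality string(s).
#' @param max_trim trimming cap in bases.
#' @param q_threshold Phred threshold.
#' @return list with `seq`, `qual`, `trimmed` (bases removed per read).
#' @export
trim_3prime_lowq <- function(seq, qual, max_trim = 29, q_threshold = 20) {
  st <- cpp_qc_stats(seq, qual, q_threshold, max_trim, 33L)
  list(seq = substr(seq, 1, st$kept_len),
       qual = substr(qual, 1, st$kept_len),
       trimmed = st$trim_len)
}

# per-read rule evaluation on already-trimmed reads; returns decision vector
qc_read_decision <- function(seq, qual, params, host_index) {
  st <- cpp_qc_stats(seq, qual, params$q_threshold, 0L, 33L)
  dec <- rep("kept", length(seq))
  dec[st$n_lowq >= params$max_lowq] <- "discarded_lowq"
  dec[st$n_ambig >= params$max_ambiguous] <- "discarded_ambiguous"
  adap <- cpp_adapter_match(seq, params$adapter, params$adapter_min_overlap,
                            params$adapter_max_mismatch,
                            params$adapter_clip_first)
  dec[dec == "kept" & adap] <- "discarded_adapter"
  if (!is.null(host_index)) {
    cand <- which(dec == "kept")
    if (length(cand)) {
      hits <- align_reads(setNames(seq[cand], as.character(cand)), host_index,
                          mode = "best_hit",
                          min_score = params$host_min_score,
                          max_evalue = params$host_max_evalue)
      if (nrow(hits))
        dec[as.integer(unique(hits$read_id))] <- "discarded_host"
    }
  }
  dec
}

#' Pair-aware five-rule quality control
#'
#' @param pairs a [read_pairs()] object.
#' @param host a [genome_set()], named character vector of host sequences,
#'   or `NULL` to skip the host rule.
#' @param params a [qc_params()] list.
#' @return list with `kept` (surviving [read_pairs()]), `singletons`
#'   (data.frame of orphaned mates), and `report` (one row per input read:
#'   `pair_id`, `mate`, `decision`, `trimmed_bases`, `stream`).
#' @export
filter_pairs <- function(pairs, host = NULL, params = qc_params()) {
  stopifnot(inherits(pairs, "read_pairs"))
  host_index <- if (is.null(host)) NULL else {
    hs <- if (inherits(host, "genome_set")) host$sequences else host
    alignment_index(hs, alphabet = "dna", k = params$host_k,
                    target_kind = "host")
  }
  t1 <- trim_3prime_lowq(pairs$seq1, pairs$qual1, params$max_trim,
                         params$q_threshold)
  t2 <- trim_3prime_lowq(pairs$seq2, pairs$qual2, params$max_trim,
                         params$q_threshold)
  d1 <- qc_read_decision(t1$seq, t1$qual, params, host_index)
  d2 <- qc_read_decision(t2$seq, t2$qual, params, host_index)

  # pair-aware co-removal: adapter/host discards take the mate down too
  co <- c("discarded_adapter", "discarded_host")
  m1 <- d1 == "kept" & d2 %in% co
  m2 <- d2 == "kept" & d1 %in% co
  d1[m1] <- "discarded_mate"
  d2[m2] <- "discarded_mate"

  keep_pair <- d1 == "kept" & d2 == "kept"
  single1 <- d1 == "kept" & !keep_pair
  single2 <- d2 == "kept" & !keep_pair
  stream1 <- ifelse(keep_pair, "paired", ifelse(single1, "singleton", "none"))
  stream2 <- ifelse(keep_pair, "paired", ifelse(single2, "singleton", "none"))

  kept <- read_pairs(pairs$pair_id[keep_pair], t1$seq[keep_pair],
                     t1$qual[keep_pair], t2$seq[keep_pair],
                     t2$qual[keep_pair])
  singles <- rbind(
    data.frame(pair_id = pairs$pair_id[single1],
               mate = rep("R1", sum(single1)),
               seq = t1$seq[single1], qual = t1$qual[single1],
               stringsAsFactors = FALSE),
    data.frame(pair_id = pairs$pair_id[single2],
               mate = rep("R2", sum(single2)),
               seq = t2$seq[single2], qual = t2$qual[single2],
               stringsAsFactors = FALSE))
  report <- data.frame(
    pair_id = rep(pairs$pair_id, each = 2),
    mate = rep(c("R1", "R2"), nrow(pairs)),
    decision = as.vector(rbind(d1, d2)),
    trimmed_bases = as.vector(rbind(t1$trimmed, t2$trimmed)),
    stream = as.vector(rbind(stream1, stream2)),
    stringsAsFactors = FALSE)
  list(kept = kept, singletons = singles, report = report)
}

#' @describeIn filter_pairs QC for a single read pair; returns the same
#'   structure with one pair.
#' @param pair a one-row [read_pairs()] object.
#' @export
filter_pair <- function(pair, host = NULL, params = qc_params()) {
  stopifnot(nrow(pair) == 1)
  filter_pairs(pair, host = host, params = params)
}
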