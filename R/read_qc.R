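# Read quality control: sliding-window quality trimming, minimum-length
# filtering and k-mer based host-read removal, applied in that order.

#' Sliding-window quality trim
#'
#' Scans each read 5' to 3' with a window of `window_bases` (step 1). At the
#' first window whose mean quality falls below `qscore_threshold` the read is
#' truncated at that window's start; reads shorter than the window are judged
#' on their full length. Defaults follow the standard shotgun-metagenomics
#' setting of a 50-base window at QScore 20.
#'
#' @param reads A `read_set`.
#' @param window_bases Window width in bases (>= 1).
#' @param qscore_threshold Minimum mean Phred quality per window.
#' @return The trimmed `read_set` (possibly containing empty reads).
#' @export
sliding_window_trim <- function(reads, window_bases = 50, qscore_threshold = 20) {
  reads <- as_read_set(reads)
  stopifnot(window_bases >= 1)
  if (nrow(reads) == 0) return(reads)
  keep_len <- cpp_trim_lengths(reads$qual, as.integer(window_bases),
                               qscore_threshold, 33L)
  reads$seq <- substring(reads$seq, 1L, keep_len)
  reads$qual <- substring(reads$qual, 1L, keep_len)
  as_read_set(reads)
}

#' Minimum-length filter
#'
#' Retains exactly the reads of length >= `min_length`, preserving order.
#'
#' @param reads A `read_set`.
#' @param min_length Minimum retained read length (default 50).
#' @return Filtered `read_set`.
#' @export
length_filter <- function(reads, min_length = 50) {
  reads <- as_read_set(reads)
  stopifnot(min_length >= 1)
  out <- reads[nchar(reads$seq) >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  as_read_set(out)
}

#' Host-read removal by exact k-mer matching
#'
#' A read is dropped when at least half of its k-mers occur exactly in the
#' host reference on either strand. This is a deterministic stand-in for the
#' usual alignment-based host screen; with the default k = 31 a chance hit
#' against a host-sized reference is essentially impossible, so decisions are
#' driven by genuine host-derived sequence.
#'
#' @param reads A `read_set`.
#' @param host_reference Host genome as a character string, a named character
#'   vector of contigs, or a path to a FASTA file.
#' @param k K-mer size (>= 15; default 31).
#' @param max_host_kmer_frac Drop threshold on the fraction of matching
#'   k-mers (default 0.5, i.e. dropped when >= 50 %).
#' @return Filtered `read_set` with attribute `n_dropped_host`.
#' @export
host_filter <- function(reads, host_reference, k = 31,
                        max_host_kmer_frac = 0.5) {
  reads <- as_read_set(reads)
  if (k < 15) stop("k must be >= 15", call. = FALSE)
  if (length(host_reference) == 1 && file.exists(host_reference)) {
    host_reference <- read_fasta(host_reference)
  }
  host <- paste(host_reference, collapse = strrep("N", 1))
  if (nchar(gsub("N", "", host)) == 0) {
    stop("empty host reference", call. = FALSE)
  }
  frac <- cpp_host_kmer_frac(reads$seq, host, as.integer(k))
  drop <- !is.na(frac) & frac >= max_host_kmer_frac
  out <- reads[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out <- as_read_set(out)
  attr(out, "n_dropped_host") <- sum(drop)
  out
}

#' Full read-QC pipeline
#'
#' Applies sliding-window quality trimming, the minimum-length filter and
#' (when a host reference is given) host-read removal, in that order, with
#' exact read accounting.
#'
#' @param reads A `read_set`, or a path to a FASTQ file.
#' @param host_reference Optional host reference (see [host_filter()]).
#' @param window_bases,qscore_threshold Trimming parameters.
#' @param min_length Length-filter threshold.
#' @param k Host-filter k-mer size.
#' @return List with `reads` (the surviving `read_set`) and `stats`, a
#'   one-row data frame: `reads_in`, `reads_trimmed`, `reads_dropped_short`,
#'   `reads_dropped_host`, `reads_out` (satisfying
#'   `reads_out = reads_in - reads_dropped_short - reads_dropped_host`).
#' @export
qc_pipeline <- function(reads, host_reference = NULL, window_bases = 50,
                        qscore_threshold = 20, min_length = 50, k = 31) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  reads <- as_read_set(reads)
  n_in <- nrow(reads)
  len_before <- nchar(reads$seq)
  trimmed <- sliding_window_trim(reads, window_bases, qscore_threshold)
  n_trimmed <- sum(nchar(trimmed$seq) < len_before)
  kept <- length_filter(trimmed, min_length)
  n_short <- nrow(trimmed) - nrow(kept)
  n_host <- 0L
  if (!is.null(host_reference)) {
    kept <- host_filter(kept, host_reference, k)
    n_host <- attr(kept, "n_dropped_host")
  }
  stats <- data.frame(
    reads_in = n_in, reads_trimmed = n_trimmed,
    reads_dropped_short = n_short, reads_dropped_host = n_host,
    reads_out = nrow(kept)
  )
  stopifnot(stats$reads_out == stats$reads_in - stats$reads_dropped_short -
              stats$reads_dropped_host)
  list(reads = kept, stats = stats)
}
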