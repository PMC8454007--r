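# Independent brute-force oracles and small constructors used across tests.
# These deliberately avoid the package's vectorised/C++ code paths.

# Random consensus profile: allele codes 1..4 with NA at uncovered sites.
random_profile <- function(L, coverage = 1, seed = 1, species_id = "spX",
                           sample_id = "s", mean_depth = 10) {
  withr::with_seed(seed, {
    consensus <- sample(1:4, L, replace = TRUE)
    if (coverage < 1) {
      consensus[sample.int(L, round((1 - coverage) * L))] <- NA_integer_
    }
    strain_profile(consensus, species_id, sample_id, mean_depth)
  })
}

# Profile b derived from a: flip `n_flips` covered sites, drop `n_drop` sites.
perturb_profile <- function(p, n_flips = 0, n_drop = 0, seed = 1,
                            sample_id = "s2") {
  withr::with_seed(seed, {
    consensus <- p$consensus
    cov <- which(!is.na(consensus))
    if (n_flips > 0) {
      at <- sample(cov, n_flips)
      consensus[at] <- ((consensus[at] + sample(1:3, n_flips, TRUE) - 1L) %% 4L) + 1L
    }
    if (n_drop > 0) consensus[sample(cov, n_drop)] <- NA_integer_
    strain_profile(consensus, p$species_id, sample_id, p$mean_depth)
  })
}

# Brute-force window-averaged similarity: direct double loop over windows and
# positions, independent of window_scores()/wss_score().
bf_wss <- function(a, b, window_len = 1000, min_sites = 10) {
  stopifnot(a$L == b$L)
  n_win <- ceiling(a$L / window_len)
  fracs <- c()
  for (w in seq_len(n_win)) {
    lo <- (w - 1) * window_len + 1
    hi <- min(w * window_len, a$L)
    co <- 0
    match <- 0
    for (i in lo:hi) {
      ca <- a$consensus[i]
      cb <- b$consensus[i]
      if (!is.na(ca) && !is.na(cb)) {
        co <- co + 1
        if (ca == cb) match <- match + 1
      }
    }
    if (co >= min_sites) fracs <- c(fracs, match / co)
  }
  if (length(fracs) == 0) NA_real_ else 100 * mean(fracs)
}

# Brute-force sliding-window trim: simulate the scan one window at a time.
bf_trim_length <- function(q, window = 50, threshold = 20) {
  n <- length(q)
  w <- min(window, n)
  if (n == 0) return(0L)
  for (start in 1:(n - w + 1)) {
    if (mean(q[start:(start + w - 1)]) < threshold) return(start - 1L)
  }
  n
}

# Exhaustive threshold sweep: minimum training error achievable under the
# rule "related iff score > cutoff".
bf_min_error <- function(scores, labels) {
  # the error only changes at observed scores, so evaluating the rule at each
  # observed value plus one guard below the minimum covers every split
  cand <- c(min(scores) - 1, sort(unique(scores)))
  is_rel <- labels == "related"
  min(vapply(cand, function(ct) {
    sum(is_rel & scores <= ct) + sum(!is_rel & scores > ct)
  }, 0))
}

# Count a read's k-mers occurring in a host string (either strand), brute
# force by substring search.
bf_host_kmer_hits <- function(read, host, k = 31) {
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  n <- nchar(read) - k + 1
  hits <- 0
  for (i in seq_len(max(0, n))) {
    km <- substr(read, i, i + k - 1)
    if (grepl(km, host, fixed = TRUE) || grepl(rc(km), host, fixed = TRUE)) {
      hits <- hits + 1
    }
  }
  c(hits = hits, total = max(0, n))
}

# One-read read_set with a constant or explicit quality vector.
one_read <- function(seq, q) {
  if (length(q) == 1) q <- rep(q, nchar(seq))
  as_read_set(data.frame(
    id = "r1", seq = seq,
    qual = intToUtf8(q + 33L), stringsAsFactors = FALSE))
}

# Character-level DNA-to-code conversion (1=A..4=T), independent of the
# package's lookup-table version.
seq_to_codes_chr <- function(s) {
  match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
}

# Position-wise Hamming distance via explicit character comparison.
hamming_chr <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}
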