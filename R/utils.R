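# Internal helpers shared across modules.

# Map a DNA string to integer codes 1..4 (A,C,G,T); anything else becomes NA.
seq_to_codes <- function(seq) {
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("acgt")] <- 1:4
  lut[utf8ToInt(seq)]
}

codes_to_seq <- function(codes) {
  paste(BASES[codes], collapse = "")
}

# n reproducible sub-seeds (31-bit) derived from one master seed, without
# leaking RNG state into the caller.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(2147483646L, n))
}

# Hamming distance between two equal-length DNA strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small cache of reference k-mer indexes so repeated mapping against the same
# reference does not rebuild the index. Keyed by species, length, a sequence
# hash and k; bounded to avoid holding many genomes' indexes at once.
.ref_index_cache <- new.env(parent = emptyenv())

ref_index <- function(ref, k = 31) {
  key <- paste(ref$species_id, ref$length,
               format(cpp_seq_hash(ref$sequence), digits = 17), k, sep = ":")
  hit <- get0(key, envir = .ref_index_cache)
  if (!is.null(hit)) return(hit)
  if (length(ls(.ref_index_cache)) >= 8) {
    rm(list = ls(.ref_index_cache), envir = .ref_index_cache)
  }
  assign(key, cpp_build_ref_index(ref$sequence, as.integer(k)),
         envir = .ref_index_cache)
  get(key, envir = .ref_index_cache)
}
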