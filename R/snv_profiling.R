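# SNV profiling: place reads on a species reference, tally per-position base
# counts, and call a consensus strain profile with the coverage/depth
# diagnostics the pair gate needs.

#' Map reads to a species reference and build a pileup
#'
#' Internal exact-seed mapper: each read is seeded by its 31-mers (at offsets
#' 0, k, 2k, ...) against an index of the reference, candidate placements are
#' verified ungapped, and the placement with the fewest mismatches wins
#' provided mismatches stay within `max_mismatch_frac` of the read length.
#' Intended for synthetic reads with error rates up to ~1 %; pileups from
#' real alignments should be imported with [import_pileup()] instead.
#'
#' @param reads A `read_set` (typically from [qc_pipeline()]).
#' @param ref A `reference_genome`.
#' @param k Seed k-mer length (default 31).
#' @param max_mismatch_frac Maximum mismatch fraction for a valid placement.
#' @return A `species_pileup`: list with `species_id`, `L`, `counts`
#'   (L x 4 integer matrix, columns A,C,G,T), `n_placed`, `n_reads`,
#'   `placements` (0-based start per read, NA when unplaced). Reads longer
#'   than the reference are ignored and counted in `n_too_long`.
#' @export
map_reads <- function(reads, ref, k = 31, max_mismatch_frac = 0.05) {
  stopifnot(inherits(ref, "reference_genome"))
  reads <- as_read_set(reads)
  res <- cpp_map_reads(ref_index(ref, k), reads$seq, max_mismatch_frac)
  if (res$n_too_long > 0) {
    warning(res$n_too_long, " read(s) longer than the reference were ignored",
            call. = FALSE)
  }
  counts <- res$counts
  colnames(counts) <- BASES
  structure(
    list(species_id = ref$species_id, L = ref$length, counts = counts,
         n_reads = nrow(reads), n_placed = sum(!is.na(res$pos)),
         n_too_long = res$n_too_long, placements = res$pos),
    class = "species_pileup"
  )
}

#' Per-position depth of a pileup
#'
#' @param pileup A `species_pileup`.
#' @return Integer vector of length L.
#' @export
pileup_depth <- function(pileup) {
  stopifnot(inherits(pileup, "species_pileup"))
  as.integer(rowSums(pileup$counts))
}

#' Sum pileups of the same species position-wise
#'
#' Used to pool a donor's longitudinal samples into one sample before
#' profiling, matching the convention of merging donor samples for analysis.
#'
#' @param ... `species_pileup` objects (or one list of them) over the same
#'   reference.
#' @return A pooled `species_pileup`.
#' @export
pool_pileups <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "species_pileup")) xs <- xs[[1]]
  stopifnot(length(xs) >= 1, all(vapply(xs, inherits, TRUE, "species_pileup")))
  sp <- unique(vapply(xs, `[[`, "", "species_id"))
  L <- unique(vapply(xs, `[[`, 0L, "L"))
  if (length(sp) != 1 || length(L) != 1) {
    stop("pileups must share species and reference length", call. = FALSE)
  }
  counts <- Reduce(`+`, lapply(xs, `[[`, "counts"))
  structure(
    list(species_id = sp, L = L, counts = counts,
         n_reads = sum(vapply(xs, function(x) x$n_reads %||% 0L, 0L)),
         n_placed = sum(vapply(xs, function(x) x$n_placed %||% 0L, 0L)),
         n_too_long = 0L, placements = NULL),
    class = "species_pileup"
  )
}

#' Import a pileup from a simplified mpileup-dialect TSV
#'
#' Expected columns: `ref` (species id), `pos` (1-based), `ref_base`,
#' `depth`, and per-base counts `A`, `C`, `G`, `T`. Positions are converted
#' to the 0-based internal convention, and each row's counts must sum to its
#' depth; a violation is rejected with the offending line number (header is
#' line 1).
#'
#' @param path Path to the TSV.
#' @param L Reference length; defaults to the largest position present.
#' @return A `species_pileup`.
#' @export
import_pileup <- function(path, L = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("ref", "pos", "ref_base", "depth", "A", "C", "G", "T")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("pileup TSV lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) {
    L <- L %||% 0L
    counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
    return(structure(list(species_id = NA_character_, L = L, counts = counts,
                          n_reads = NA_integer_, n_placed = NA_integer_,
                          n_too_long = 0L, placements = NULL),
                     class = "species_pileup"))
  }
  sums <- tab$A + tab$C + tab$G + tab$T
  bad <- which(sums != tab$depth)
  if (length(bad)) {
    stop("base counts do not sum to depth at line ", bad[1] + 1L, call. = FALSE)
  }
  if (any(tab$pos < 1)) stop("positions must be 1-based (>= 1)", call. = FALSE)
  L <- as.integer(L %||% max(tab$pos))
  if (any(tab$pos > L)) stop("position beyond reference length", call. = FALSE)
  counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
  counts[tab$pos, ] <- as.matrix(tab[, BASES])
  structure(
    list(species_id = tab$ref[1], L = L, counts = counts,
         n_reads = NA_integer_, n_placed = NA_integer_, n_too_long = 0L,
         placements = NULL),
    class = "species_pileup"
  )
}

#' Export a pileup to the simplified mpileup-dialect TSV
#'
#' Writes only covered positions (depth > 0), with 1-based positions.
#'
#' @param pileup A `species_pileup`.
#' @param ref A `reference_genome` supplying `ref_base` (optional; `N` used
#'   when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_pileup <- function(pileup, path, ref = NULL) {
  stopifnot(inherits(pileup, "species_pileup"))
  depth <- pileup_depth(pileup)
  idx <- which(depth > 0)
  ref_base <- if (is.null(ref)) rep("N", length(idx)) else {
    strsplit(ref$sequence, "", fixed = TRUE)[[1]][idx]
  }
  tab <- data.frame(ref = pileup$species_id, pos = idx, ref_base = ref_base,
                    depth = depth[idx], pileup$counts[idx, , drop = FALSE])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call a consensus strain profile from a pileup
#'
#' The consensus allele at each position with depth >= `site_min_depth` is
#' the majority base (ties broken in fixed A<C<G<T order). The coverage
#' fraction is the proportion of reference positions passing that depth
#' threshold and the mean depth is averaged over those positions — the two
#' diagnostics the pair-level gate tests.
#'
#' @param pileup A `species_pileup`.
#' @param sample_id Sample label.
#' @param L Reference length; defaults to the pileup's.
#' @param site_min_depth Minimum depth for a site to be called (default 4).
#' @return A `strain_profile`: list with `species_id`, `sample_id`, `L`,
#'   `consensus` (integer codes 1..4, NA where uncovered),
#'   `coverage_fraction`, `mean_depth`, `site_min_depth`.
#' @export
call_profile <- function(pileup, sample_id = "sample", L = NULL,
                         site_min_depth = 4) {
  stopifnot(inherits(pileup, "species_pileup"))
  if (site_min_depth < 1) stop("site_min_depth must be >= 1", call. = FALSE)
  L <- as.integer(L %||% pileup$L)
  if (is.na(L) || L <= 0) stop("reference length must be positive", call. = FALSE)
  consensus <- cpp_consensus(pileup$counts, as.integer(site_min_depth))
  if (length(consensus) < L) consensus <- c(consensus, rep(NA_integer_, L - length(consensus)))
  depth <- pileup_depth(pileup)
  covered <- !is.na(consensus)
  strain_profile(
    consensus = consensus,
    species_id = pileup$species_id,
    sample_id = sample_id,
    mean_depth = if (any(covered)) mean(depth[which(covered)]) else 0,
    site_min_depth = site_min_depth
  )
}

#' Construct a strain profile directly
#'
#' Low-level constructor used by [call_profile()] and by simulations that
#' build profiles without reads.
#'
#' @param consensus Integer vector of allele codes 1..4 (A,C,G,T) with NA at
#'   uncovered positions; its length is the reference length L.
#' @param species_id,sample_id Labels.
#' @param mean_depth Mean depth over covered positions.
#' @param site_min_depth Site depth threshold the consensus was called at.
#' @return A `strain_profile`.
#' @export
strain_profile <- function(consensus, species_id, sample_id,
                           mean_depth, site_min_depth = 4) {
  L <- length(consensus)
  if (L <= 0) stop("profile must have positive reference length", call. = FALSE)
  cf <- mean(!is.na(consensus))
  structure(
    list(species_id = species_id, sample_id = sample_id, L = L,
         consensus = as.integer(consensus), coverage_fraction = cf,
         mean_depth = mean_depth, site_min_depth = site_min_depth),
    class = "strain_profile"
  )
}

#' @export
print.strain_profile <- function(x, ...) {
  cat(sprintf(
    "<strain_profile> %s / %s: L=%d, coverage=%.3f, mean depth=%.2f\n",
    x$species_id, x$sample_id, x$L, x$coverage_fraction, x$mean_depth))
  invisible(x)
}

#' Write a strain profile as TSV plus JSON sidecar
#'
#' The TSV holds one row per covered position (`pos`, 1-based; `allele`);
#' the `<path>.json` sidecar carries the profile's labels and gating
#' diagnostics (`species_id`, `sample_id`, `L`, `coverage_fraction`,
#' `mean_depth`, `site_min_depth`).
#'
#' @param profile A `strain_profile`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "strain_profile"))
  idx <- which(!is.na(profile$consensus))
  tab <- data.frame(pos = idx, allele = BASES[profile$consensus[idx]])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- profile[c("species_id", "sample_id", "L", "coverage_fraction",
                    "mean_depth", "site_min_depth")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a strain profile written by [write_profile()]
#'
#' @param path Path to the profile TSV (its `.json` sidecar must sit next
#'   to it).
#' @return A `strain_profile`.
#' @export
read_profile <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  consensus <- rep(NA_integer_, meta$L)
  consensus[tab$pos] <- match(tab$allele, BASES)
  out <- strain_profile(consensus, meta$species_id, meta$sample_id,
                        meta$mean_depth, meta$site_min_depth)
  stopifnot(abs(out$coverage_fraction - meta$coverage_fraction) < 1e-9)
  out
}

#' One-call profiling of a read set
#'
#' Convenience wrapper: QC (optional) then mapping then consensus calling.
#'
#' @param reads A `read_set`.
#' @param ref A `reference_genome`.
#' @param sample_id Sample label; defaults to the read set's.
#' @param site_min_depth Site depth threshold.
#' @param run_qc Apply [qc_pipeline()] first (no host filter).
#' @param ... Passed to [qc_pipeline()].
#' @return A `strain_profile`.
#' @export
profile_reads <- function(reads, ref, sample_id = NULL, site_min_depth = 4,
                          run_qc = TRUE, ...) {
  sample_id <- sample_id %||% attr(reads, "sample_id") %||% "sample"
  if (run_qc) reads <- qc_pipeline(reads, ...)$reads
  pile <- map_reads(reads, ref)
  call_profile(pile, sample_id = sample_id, site_min_depth = site_min_depth)
}
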