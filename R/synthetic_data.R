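# Synthetic data: reference genomes, SNV-diverged strains, shotgun reads with
# controlled coverage/depth/error, and FMT scenarios with known strain origin.
# Everything is seeded so downstream stages can be tested against ground truth.

#' Generate a random reference genome
#'
#' Bases are drawn i.i.d. with the requested GC fraction (G and C equally
#' likely, likewise A and T). Deterministic for a fixed seed.
#'
#' @param species_id Species label carried through the pipeline.
#' @param length_bp Genome length in bases (>= 1000).
#' @param gc_fraction Target GC fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return A `reference_genome`: list with `species_id`, `sequence`, `length`.
#' @export
generate_reference <- function(species_id, length_bp, gc_fraction = 0.5, seed) {
  if (!is.numeric(length_bp) || length_bp < 1000) {
    stop("length_bp must be >= 1000", call. = FALSE)
  }
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    stop("gc_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  length_bp <- as.integer(length_bp)
  prob <- c((1 - gc_fraction) / 2, gc_fraction / 2,
            gc_fraction / 2, (1 - gc_fraction) / 2)
  seq <- withr::with_seed(seed, {
    paste(sample(BASES, length_bp, replace = TRUE, prob = prob), collapse = "")
  })
  structure(
    list(species_id = species_id, sequence = seq, length = length_bp),
    class = "reference_genome"
  )
}

#' Derive a strain by placing SNVs on a reference
#'
#' Exactly `n_snvs` distinct positions are mutated; the alternate base at
#' each position always differs from the reference base.
#'
#' @param ref A `reference_genome`.
#' @param n_snvs Number of SNVs, between 0 and the genome length.
#' @param seed Integer seed.
#' @param strain_id Optional strain label; defaults to
#'   `<species>_strain<n_snvs>snv`.
#' @return A `strain_genome`: list with `species_id`, `strain_id`,
#'   `base_reference`, `mutations` (data frame: 0-based `pos`, `ref`, `alt`),
#'   `sequence`, `length`.
#' @export
mutate_strain <- function(ref, n_snvs, seed, strain_id = NULL) {
  stopifnot(inherits(ref, "reference_genome"))
  L <- ref$length
  if (n_snvs < 0 || n_snvs > L) {
    stop("n_snvs must lie in [0, genome length]", call. = FALSE)
  }
  n_snvs <- as.integer(n_snvs)
  strain_id <- strain_id %||% sprintf("%s_strain%dsnv", ref$species_id, n_snvs)
  chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  mut <- withr::with_seed(seed, {
    pos <- sort(sample.int(L, n_snvs)) - 1L
    ref_base <- chars[pos + 1L]
    # shift each base 1-3 steps around the ACGT cycle so alt != ref
    shift <- sample.int(3L, n_snvs, replace = TRUE)
    alt <- BASES[((match(ref_base, BASES) - 1L + shift) %% 4L) + 1L]
    data.frame(pos = pos, ref = ref_base, alt = alt, stringsAsFactors = FALSE)
  })
  chars[mut$pos + 1L] <- mut$alt
  structure(
    list(species_id = ref$species_id, strain_id = strain_id,
         base_reference = ref$species_id, mutations = mut,
         sequence = paste(chars, collapse = ""), length = L),
    class = "strain_genome"
  )
}

#' Simulate shotgun reads from a strain genome
#'
#' Read start positions fall only inside `ceiling(covered_fraction * L)` bases
#' selected as 1 kb blocks of the genome, which makes the coverage-fraction
#' gate sharply controllable. Depth over the covered region equals
#' `mean_depth` in expectation. Substitution errors are injected per base at
#' `error_rate`; qualities are constant at `base_quality` unless a two-segment
#' `quality_profile` is given.
#'
#' @param strain A `strain_genome` (or `reference_genome`).
#' @param mean_depth Target mean depth over the covered region (> 0).
#' @param covered_fraction Fraction of the genome eligible for read starts,
#'   in (0, 1].
#' @param read_length Read length in bases (>= 30).
#' @param error_rate Per-base substitution error probability.
#' @param base_quality Constant Phred quality for every base.
#' @param seed Integer seed.
#' @param sample_id Sample label used in read names.
#' @param quality_profile Optional list(`head_q`, `tail_q`, `tail_start`):
#'   bases from 1-based position `tail_start` on get `tail_q` instead of
#'   `head_q` (used to exercise quality trimming).
#' @return A `read_set` data frame (`id`, `seq`, `qual`) with attributes
#'   `truth` (data frame of true 0-based start positions) and
#'   `covered_blocks` (0-based block start positions).
#' @export
simulate_reads <- function(strain, mean_depth, covered_fraction = 1,
                           read_length = 100, error_rate = 0,
                           base_quality = 35, seed, sample_id = "sample",
                           quality_profile = NULL) {
  stopifnot(inherits(strain, c("strain_genome", "reference_genome")))
  if (mean_depth <= 0) stop("mean_depth must be > 0", call. = FALSE)
  if (covered_fraction <= 0 || covered_fraction > 1) {
    stop("covered_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (read_length < 30) stop("read_length must be >= 30", call. = FALSE)
  L <- strain$length
  if (read_length > L) stop("read_length exceeds genome length", call. = FALSE)
  block <- 1000L
  n_blocks_total <- as.integer(ceiling(L / block))
  n_blocks <- min(n_blocks_total,
                  as.integer(ceiling(ceiling(covered_fraction * L) / block)))

  out <- withr::with_seed(seed, {
    chosen <- sort(sample.int(n_blocks_total, n_blocks))
    block_start <- (chosen - 1L) * block
    block_end <- pmin(block_start + block, L) # exclusive
    # read must fit inside the genome
    max_start <- pmin(block_end, L - read_length + 1L) # exclusive bound
    n_allowed <- pmax(0L, max_start - block_start)
    keep <- n_allowed > 0L
    block_start <- block_start[keep]
    n_allowed <- n_allowed[keep]
    covered_bases <- sum(block_end[keep] - block_start)
    n_reads <- max(1L, as.integer(round(mean_depth * covered_bases / read_length)))
    u <- sample.int(sum(n_allowed), n_reads, replace = TRUE)
    cum <- cumsum(n_allowed)
    b <- findInterval(u, c(0L, cum), left.open = TRUE)
    starts <- block_start[b] + (u - c(0L, cum)[b] - 1L)
    n_bases <- n_reads * read_length
    n_err <- if (error_rate > 0) rbinom(1, n_bases, error_rate) else 0L
    err_at <- if (n_err > 0) sample.int(n_bases, n_err) else integer()
    err_shift <- if (n_err > 0) sample.int(3L, n_err, replace = TRUE) else integer()
    seqs <- cpp_make_reads(strain$sequence, starts, read_length,
                           err_at - 1L, err_shift)
    list(starts = starts, seqs = seqs, blocks = block_start)
  })

  qual <- if (is.null(quality_profile)) {
    strrep(intToUtf8(base_quality + 33L), read_length)
  } else {
    ts <- quality_profile$tail_start
    paste0(strrep(intToUtf8(quality_profile$head_q + 33L), ts - 1L),
           strrep(intToUtf8(quality_profile$tail_q + 33L), read_length - ts + 1L))
  }
  n_reads <- length(out$seqs)
  ids <- sprintf("%s|%s|r%06d", sample_id, strain$species_id, seq_len(n_reads))
  rs <- data.frame(id = ids, seq = out$seqs, qual = rep(qual, n_reads),
                   stringsAsFactors = FALSE)
  rs <- as_read_set(rs)
  attr(rs, "truth") <- data.frame(id = ids, start = out$starts,
                                  stringsAsFactors = FALSE)
  attr(rs, "covered_blocks") <- out$blocks
  attr(rs, "sample_id") <- sample_id
  attr(rs, "species_id") <- strain$species_id
  rs
}

#' Compose an FMT scenario with known per-species strain origin
#'
#' Builds one donor and one (or more) recipients over a set of species, with
#' reads for every (sample, species) cell and a manifest recording the true
#' strain of each cell. Templates mirror the qualitative outcomes seen after
#' FMT: complete donor engraftment, persistence of the recipient's pre-FMT
#' strains, a temporal mosaic of the two, a strain unrelated to both, and
#' cells deliberately pushed below the coverage/depth gate.
#'
#' @param template One of `full_engraftment`, `recipient_persistence`,
#'   `temporal_mosaic`, `novel_strain`, `indeterminate_low_coverage`.
#' @param n_species Number of species simulated.
#' @param genome_length Reference genome length per species (bp).
#' @param timepoints Recipient sampling days; the earliest is the pre-FMT
#'   (day-0, baseline) sample, later ones are post-FMT.
#' @param mean_depth Target mean depth for ordinary cells.
#' @param read_length Read length (bp).
#' @param error_rate Per-base sequencing error rate.
#' @param base_quality Constant Phred quality.
#' @param snvs_per_kb Divergence between unrelated strains, SNVs per kb.
#' @param low_covered_fraction Covered fraction used for the designated
#'   low-coverage cells of `indeterminate_low_coverage` (must be <= 0.30 to
#'   fail the gate).
#' @param response Response label for the recipient (`R`, `NR` or `none`).
#' @param seed Integer seed; all randomness derives from it.
#' @param out_dir Optional directory; when given, FASTQ files and the
#'   manifest (TSV + JSON) are written there.
#' @return An `fmt_scenario`: list with `template`, `references`, `strains`,
#'   `reads` (nested `[[sample_id]][[species_id]]`), `manifest`, `metadata`
#'   and `params`.
#' @export
compose_scenario <- function(template,
                             n_species = 3,
                             genome_length = 1e5,
                             timepoints = c(0, 7, 31, 65),
                             mean_depth = 20,
                             read_length = 100,
                             error_rate = 0.01,
                             base_quality = 35,
                             snvs_per_kb = 1,
                             low_covered_fraction = 0.25,
                             response = "none",
                             seed = 1,
                             out_dir = NULL) {
  if (!template %in% SCENARIO_TEMPLATES) {
    stop("unknown template '", template, "'; valid templates: ",
         paste(SCENARIO_TEMPLATES, collapse = ", "), call. = FALSE)
  }
  stopifnot(n_species >= 1, length(timepoints) >= 2)
  timepoints <- sort(as.integer(timepoints))
  pre_tp <- timepoints[1]
  post_tp <- timepoints[-1]
  species <- sprintf("sp%02d", seq_len(n_species))
  n_snvs <- as.integer(round(snvs_per_kb * genome_length / 1000))

  seeds <- derive_seeds(seed, n_species * 4L)
  seed_mat <- matrix(seeds, nrow = n_species)

  references <- strains <- vector("list", n_species)
  names(references) <- names(strains) <- species
  for (i in seq_len(n_species)) {
    ref <- generate_reference(species[i], genome_length, 0.5, seed_mat[i, 1])
    donor <- mutate_strain(ref, n_snvs, seed_mat[i, 2],
                           strain_id = paste0(species[i], "_donor"))
    # the recipient's own pre-FMT strain is the reference strain itself, so
    # every unrelated strain pair differs by the nominal SNVs-per-kb rate
    recip <- mutate_strain(ref, 0L, seed_mat[i, 3],
                           strain_id = paste0(species[i], "_recipient"))
    st <- list(donor = donor, recipient = recip)
    if (template == "novel_strain") {
      st$novel <- mutate_strain(ref, n_snvs, seed_mat[i, 4],
                                strain_id = paste0(species[i], "_novel"))
    }
    references[[i]] <- ref
    strains[[i]] <- st
  }

  # sample table: donor (timepoint 0 by convention), recipient pre + post
  samples <- data.frame(
    sample_id = c("D1", paste0("R1_t", timepoints)),
    subject_id = c("D1", rep("R1", length(timepoints))),
    role = c("donor", rep("recipient", length(timepoints))),
    timepoint_days = c(0L, timepoints),
    pre_fmt = c(FALSE, timepoints == pre_tp),
    donor_link = c(NA_character_, rep("D1", length(timepoints))),
    response = c("none", rep(response, length(timepoints))),
    segment = NA_character_,
    stringsAsFactors = FALSE
  )

  post_origin <- switch(
    template,
    full_engraftment = rep("donor", length(post_tp)),
    recipient_persistence = rep("recipient", length(post_tp)),
    temporal_mosaic = rep(c("donor", "recipient"), length.out = length(post_tp)),
    novel_strain = rep("novel", length(post_tp)),
    indeterminate_low_coverage = rep("donor", length(post_tp))
  )

  cells <- expand.grid(sample_id = samples$sample_id, species_id = species,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- merge(cells, samples, by = "sample_id", sort = FALSE)
  origin_of <- function(sample_id, timepoint, role, pre) {
    if (role == "donor") return("donor")
    if (pre) return("recipient")
    post_origin[match(timepoint, post_tp)]
  }
  cells$origin <- mapply(origin_of, cells$sample_id, cells$timepoint_days,
                         cells$role, cells$pre_fmt)
  cells$true_strain_id <- mapply(function(sp, org) strains[[sp]][[org]]$strain_id,
                                 cells$species_id, cells$origin)
  low <- template == "indeterminate_low_coverage" &
    cells$role == "recipient" & !cells$pre_fmt
  cells$covered_fraction <- ifelse(low, low_covered_fraction, 1)
  cells$mean_depth <- mean_depth

  cell_seeds <- derive_seeds(seed + 1L, nrow(cells))
  reads <- list()
  for (j in seq_len(nrow(cells))) {
    sp <- cells$species_id[j]
    rs <- simulate_reads(
      strains[[sp]][[cells$origin[j]]],
      mean_depth = cells$mean_depth[j],
      covered_fraction = cells$covered_fraction[j],
      read_length = read_length, error_rate = error_rate,
      base_quality = base_quality, seed = cell_seeds[j],
      sample_id = cells$sample_id[j]
    )
    reads[[cells$sample_id[j]]][[sp]] <- rs
  }

  manifest <- cells[, c("sample_id", "subject_id", "role", "timepoint_days",
                        "pre_fmt", "response", "species_id", "true_strain_id",
                        "origin", "covered_fraction", "mean_depth")]
  manifest$template <- template

  scen <- structure(
    list(template = template, references = references, strains = strains,
         reads = reads, manifest = manifest, metadata = samples,
         params = list(n_species = n_species, genome_length = genome_length,
                       timepoints = timepoints, mean_depth = mean_depth,
                       read_length = read_length, error_rate = error_rate,
                       base_quality = base_quality, snvs_per_kb = snvs_per_kb,
                       low_covered_fraction = low_covered_fraction,
                       seed = seed)),
    class = "fmt_scenario"
  )
  if (!is.null(out_dir)) write_scenario(scen, out_dir)
  scen
}

#' Write a scenario's FASTQ files and manifest to disk
#'
#' One FASTQ per (sample, species) cell, plus the manifest as TSV and JSON
#' and the per-sample metadata as TSV.
#'
#' @param scenario An `fmt_scenario`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_scenario <- function(scenario, out_dir) {
  stopifnot(inherits(scenario, "fmt_scenario"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(scenario$reads)) {
    for (sp in names(scenario$reads[[sid]])) {
      write_fastq(scenario$reads[[sid]][[sp]],
                  file.path(out_dir, sprintf("%s_%s.fastq", sid, sp)))
    }
  }
  man <- scenario$manifest
  write.table(man, file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write.table(scenario$metadata, file.path(out_dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (sp in names(scenario$references)) {
    write_fasta(
      stats::setNames(scenario$references[[sp]]$sequence, sp),
      file.path(out_dir, sprintf("ref_%s.fasta", sp))
    )
  }
  invisible(out_dir)
}

#' Pool several read sets into one
#'
#' Concatenates read sets, e.g. to emulate a donor whose longitudinal samples
#' are merged into a single sample before analysis.
#'
#' @param ... Read sets (or a single list of them).
#' @return A pooled `read_set`.
#' @export
pool_read_sets <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !is.data.frame(xs[[1]])) xs <- xs[[1]]
  xs <- lapply(xs, as_read_set)
  as_read_set(do.call(rbind, lapply(xs, function(x) x[, c("id", "seq", "qual")])))
}
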