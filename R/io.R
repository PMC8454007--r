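# File IO: FASTA/FASTQ through Biostrings, tables as plain TSV.

#' Read a FASTA file into a named character vector
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path Path to a 4-line-record FASTQ file (Phred+33).
#' @return A `read_set` data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # readQualityScaledDNAStringSet warns that it drops metadata columns the
  # FASTQ reader attaches internally; nothing of ours is lost
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  rs <- data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(Biostrings::quality(x)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  as_read_set(rs)
}

#' Write a read set to FASTQ (Phred+33)
#'
#' @param reads A `read_set` (see [as_read_set()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_read_set(reads)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}

#' Construct / validate a read set
#'
#' A read set is a plain data frame with character columns `id`, `seq` and
#' `qual` (Phred+33 quality string, same length as `seq`). Validation reports
#' the index of the first malformed record.
#'
#' @param x Data frame with columns `id`, `seq`, `qual`.
#' @return `x` with class `read_set` prepended.
#' @export
as_read_set <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "seq", "qual") %in% names(x)))
  bad <- which(nchar(x$seq) != nchar(x$qual))
  if (length(bad)) {
    stop("malformed FASTQ record at index ", bad[1],
         ": sequence and quality lengths differ", call. = FALSE)
  }
  if (!inherits(x, "read_set")) class(x) <- c("read_set", class(x))
  x
}

#' Write a per-species cut-off table as TSV
#'
#' Two columns: `species_id`, `cutoff_percent`. Duplicate species are
#' rejected so the table round-trips into the classifier unambiguously.
#'
#' @param tab Data frame with columns `species_id`, `cutoff_percent`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cutoff_table <- function(tab, path) {
  stopifnot(all(c("species_id", "cutoff_percent") %in% names(tab)))
  if (anyDuplicated(tab$species_id)) {
    stop("duplicate species in cut-off table: ",
         paste(unique(tab$species_id[duplicated(tab$species_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(tab$cutoff_percent <= 0 | tab$cutoff_percent >= 100)) {
    stop("cut-offs must lie strictly between 0 and 100", call. = FALSE)
  }
  write.table(tab[, c("species_id", "cutoff_percent")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-species cut-off table from TSV
#'
#' @param path Path to a TSV with columns `species_id`, `cutoff_percent`.
#' @return Data frame with those two columns.
#' @export
read_cutoff_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species_id", "cutoff_percent") %in% names(tab)))
  if (anyDuplicated(tab$species_id)) {
    stop("duplicate species in cut-off table", call. = FALSE)
  }
  tab
}

#' Read sample metadata from TSV
#'
#' Expected columns: `sample_id`, `subject_id`, `role` (donor, recipient or
#' segment), `timepoint_days`, `pre_fmt` (logical), `donor_link` (donor
#' subject id for recipients), `response` (R, NR or none) and optionally
#' `segment` (cecum, transverse or sigmoid).
#'
#' @param path Path to the metadata TSV.
#' @return Validated metadata data frame.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(md)
}

#' Validate a sample metadata table
#'
#' Checks the invariants the pairing schemes rely on: every recipient is
#' linked to a donor subject, timepoints are unique within a subject, and
#' recipients have an explicitly flagged pre-FMT sample.
#'
#' @param md Metadata data frame (see [read_metadata()]).
#' @return `md`, normalised (missing optional columns filled with NA).
#' @export
validate_metadata <- function(md) {
  need <- c("sample_id", "subject_id", "role")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  for (col in c("timepoint_days", "pre_fmt", "donor_link", "response", "segment")) {
    if (!col %in% names(md)) md[[col]] <- NA
  }
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  bad_role <- setdiff(unique(md$role), c("donor", "recipient", "segment"))
  if (length(bad_role)) stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  rec <- md[md$role == "recipient", , drop = FALSE]
  if (nrow(rec)) {
    unlinked <- unique(rec$subject_id[is.na(rec$donor_link) | rec$donor_link == ""])
    if (length(unlinked)) {
      stop("recipient(s) without linked donor: ", paste(unlinked, collapse = ", "))
    }
    tp <- rec[!is.na(rec$timepoint_days), , drop = FALSE]
    dup <- tp[duplicated(tp[, c("subject_id", "timepoint_days")]), "subject_id"]
    if (length(dup)) stop("duplicate timepoints for subject(s): ",
                          paste(unique(dup), collapse = ", "))
  }
  md
}
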