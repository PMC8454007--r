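# Tracking pipeline: pair samples (donor vs recipient, pre- vs post-FMT, or
# colon segment vs segment), score and classify every species x comparison
# cell, attribute post-FMT strains to donor / pre-FMT / neither, and
# summarize engraftment against therapy response.

#' Build a pairing scheme from sample metadata
#'
#' @param metadata Metadata data frame (see [read_metadata()]).
#' @param mode One of `donor_vs_recipient` (the linked donor sample against
#'   every recipient sample, pre-FMT included), `pre_vs_post` (each
#'   recipient's pre-FMT sample against each of their post-FMT samples), or
#'   `segment_pairwise` (cecum vs transverse, cecum vs sigmoid, transverse
#'   vs sigmoid within each subject).
#' @return Data frame of comparisons: `comparison_id`, `type` (donor, pre or
#'   segment), `sample_a` (reference sample), `sample_b`, `subject_id`,
#'   `timepoint_days` of `sample_b`.
#' @export
build_pairing_scheme <- function(metadata,
                                 mode = c("donor_vs_recipient", "pre_vs_post",
                                          "segment_pairwise")) {
  mode <- match.arg(mode)
  md <- validate_metadata(metadata)
  rows <- list()
  if (mode == "donor_vs_recipient") {
    rec <- md[md$role == "recipient", , drop = FALSE]
    for (i in seq_len(nrow(rec))) {
      donor_samples <- md$sample_id[md$role == "donor" &
                                      md$subject_id == rec$donor_link[i]]
      if (length(donor_samples) == 0) {
        stop("no donor sample for subject ", rec$donor_link[i], call. = FALSE)
      }
      if (length(donor_samples) > 1) {
        stop("donor ", rec$donor_link[i], " has multiple samples; pool them ",
             "into one sample first (see pool_read_sets/pool_pileups)",
             call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        type = "donor", sample_a = donor_samples, sample_b = rec$sample_id[i],
        subject_id = rec$subject_id[i], timepoint_days = rec$timepoint_days[i],
        stringsAsFactors = FALSE)
    }
  } else if (mode == "pre_vs_post") {
    rec <- md[md$role == "recipient", , drop = FALSE]
    for (subj in unique(rec$subject_id)) {
      sub <- rec[rec$subject_id == subj, , drop = FALSE]
      pre <- sub$sample_id[isTRUE_vec(sub$pre_fmt)]
      if (length(pre) == 0) {
        warning("recipient ", subj, " has no pre-FMT sample; skipped",
                call. = FALSE)
        next
      }
      post <- sub[!isTRUE_vec(sub$pre_fmt), , drop = FALSE]
      for (i in seq_len(nrow(post))) {
        rows[[length(rows) + 1L]] <- data.frame(
          type = "pre", sample_a = pre[1], sample_b = post$sample_id[i],
          subject_id = subj, timepoint_days = post$timepoint_days[i],
          stringsAsFactors = FALSE)
      }
    }
  } else {
    seg <- md[md$role == "segment", , drop = FALSE]
    seg_pairs <- list(c("cecum", "transverse"), c("cecum", "sigmoid"),
                      c("transverse", "sigmoid"))
    for (subj in unique(seg$subject_id)) {
      sub <- seg[seg$subject_id == subj, , drop = FALSE]
      for (pr in seg_pairs) {
        a <- sub$sample_id[sub$segment == pr[1]]
        b <- sub$sample_id[sub$segment == pr[2]]
        if (length(a) == 1 && length(b) == 1) {
          rows[[length(rows) + 1L]] <- data.frame(
            type = "segment", sample_a = a, sample_b = b,
            subject_id = subj, timepoint_days = NA_integer_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(type = character(), sample_a = character(),
                      sample_b = character(), subject_id = character(),
                      timepoint_days = integer(), stringsAsFactors = FALSE)
  }
  out$comparison_id <- if (nrow(out)) paste(out$sample_a, "vs", out$sample_b) else character()
  out[, c("comparison_id", "type", "sample_a", "sample_b", "subject_id",
          "timepoint_days")]
}

isTRUE_vec <- function(x) !is.na(x) & x == TRUE

#' Run the tracking analysis over a pairing scheme
#'
#' Scores and classifies every species x comparison cell (gate, WSS score,
#' cut-off call). When the scheme contains both donor and pre-FMT comparisons
#' for the same post-FMT sample, the donor rows additionally carry a four-way
#' attribution: `donor-related` when the donor pair is related (with
#' `both_related` flagged if the pre-FMT pair is related too),
#' `preFMT-related` when only the pre-FMT pair is related, `neither` when
#' both pairs are evaluable and unrelated, and `indeterminate` otherwise.
#' Cells for species without an established cut-off, or with a missing
#' profile, are indeterminate.
#'
#' @param profiles Nested list `profiles[[sample_id]][[species_id]]` of
#'   `strain_profile`s.
#' @param cutoffs Cut-off table (data frame `species_id`, `cutoff_percent`)
#'   or path to one.
#' @param scheme Pairing scheme from [build_pairing_scheme()]; to obtain
#'   attribution, rbind the `donor_vs_recipient` and `pre_vs_post` schemes.
#' @param species Species ids to evaluate; defaults to all species present
#'   in `profiles`.
#' @param ... Scoring parameters passed to [wss_score()].
#' @return A `tracking_matrix`: long data frame with one row per
#'   (species, comparison): scores, gating diagnostics, `call`,
#'   `attribution`, `both_related`, `reason`.
#' @export
run_tracking <- function(profiles, cutoffs, scheme, species = NULL, ...) {
  if (is.character(cutoffs)) cutoffs <- read_cutoff_table(cutoffs)
  species <- species %||%
    sort(unique(unlist(lapply(profiles, function(p) {
      if (inherits(p, "strain_profile")) p$species_id else names(p)
    }))))
  get_profile <- function(sample_id, sp) {
    p <- profiles[[sample_id]]
    if (is.null(p)) return(NULL)
    if (inherits(p, "strain_profile")) {
      if (identical(p$species_id, sp)) p else NULL
    } else p[[sp]]
  }
  rows <- list()
  for (sp in species) {
    cutoff <- cutoffs$cutoff_percent[cutoffs$species_id == sp]
    if (length(cutoff) == 0) cutoff <- NA_real_
    for (i in seq_len(nrow(scheme))) {
      pa <- get_profile(scheme$sample_a[i], sp)
      pb <- get_profile(scheme$sample_b[i], sp)
      if (is.null(pa) || is.null(pb)) {
        cell <- data.frame(
          species_id = sp, sample_a = scheme$sample_a[i],
          sample_b = scheme$sample_b[i], score_percent = NA_real_,
          evaluable = FALSE, windows_used = 0L,
          coverage_a = NA_real_, coverage_b = NA_real_,
          depth_a = NA_real_, depth_b = NA_real_,
          cutoff = cutoff, call = "indeterminate",
          reason = "missing profile", stringsAsFactors = FALSE)
      } else {
        cell <- classify_pair(wss_score(pa, pb, ...), cutoff)
      }
      cell$comparison_id <- scheme$comparison_id[i]
      cell$type <- scheme$type[i]
      cell$subject_id <- scheme$subject_id[i]
      cell$timepoint_days <- scheme$timepoint_days[i]
      rows[[length(rows) + 1L]] <- as.data.frame(cell)
    }
  }
  mat <- do.call(rbind, rows)
  mat$attribution <- "not-applicable"
  mat$both_related <- FALSE
  # attribution for donor rows that have a matching pre-FMT row
  is_donor <- mat$type == "donor"
  for (j in which(is_donor)) {
    k <- which(mat$type == "pre" & mat$species_id == mat$species_id[j] &
                 mat$sample_b == mat$sample_b[j])
    if (length(k) != 1) next
    donor_call <- mat$call[j]
    pre_call <- mat$call[k]
    if (donor_call == "related") {
      mat$attribution[j] <- "donor-related"
      mat$both_related[j] <- pre_call == "related"
    } else if (pre_call == "related") {
      mat$attribution[j] <- "preFMT-related"
    } else if (donor_call == "unrelated" && pre_call == "unrelated") {
      mat$attribution[j] <- "neither"
    } else {
      mat$attribution[j] <- "indeterminate"
    }
  }
  rownames(mat) <- NULL
  class(mat) <- c("tracking_matrix", "data.frame")
  mat
}

#' Summarize engraftment against therapy response
#'
#' Counts each recipient's donor-related / preFMT-related / neither /
#' indeterminate attributions, then cross-tabulates recipients by
#' "donor strain detected" (at least one species donor-related at at least
#' one post-FMT timepoint) against responder status (R vs NR) and reports a
#' two-sided Fisher exact test. Recipients without an R/NR label are
#' excluded from the 2x2.
#'
#' @param matrix A `tracking_matrix` containing attributed donor rows.
#' @param metadata Metadata with recipient `response` labels.
#' @return List with `per_recipient` (data frame of attribution counts and
#'   `donor_detected`), `table` (2x2 detected x responder), `fisher`
#'   (htest) and `notice` when no labeled recipients exist.
#' @export
summarize_response_concordance <- function(matrix, metadata) {
  md <- validate_metadata(metadata)
  rec <- unique(md[md$role == "recipient", c("subject_id", "response")])
  donor_rows <- matrix[matrix$type == "donor" &
                         matrix$attribution != "not-applicable", , drop = FALSE]
  if (nrow(donor_rows) == 0 || nrow(rec) == 0) {
    return(list(per_recipient = data.frame(), table = NULL, fisher = NULL,
                notice = "no attributed recipient cells"))
  }
  per <- do.call(rbind, lapply(split(donor_rows, donor_rows$subject_id),
    function(d) data.frame(
      subject_id = d$subject_id[1],
      n_donor_related = sum(d$attribution == "donor-related"),
      n_prefmt_related = sum(d$attribution == "preFMT-related"),
      n_neither = sum(d$attribution == "neither"),
      n_indeterminate = sum(d$attribution == "indeterminate"),
      stringsAsFactors = FALSE)))
  per$donor_detected <- per$n_donor_related > 0
  per <- merge(per, rec, by = "subject_id", all.x = TRUE, sort = TRUE)
  rownames(per) <- NULL
  labeled <- per[per$response %in% c("R", "NR"), , drop = FALSE]
  if (nrow(labeled) == 0) {
    return(list(per_recipient = per, table = NULL, fisher = NULL,
                notice = "no recipients with R/NR response labels"))
  }
  tab <- table(
    donor_detected = factor(labeled$donor_detected, levels = c(TRUE, FALSE)),
    responder = factor(labeled$response, levels = c("R", "NR")))
  ft <- stats::fisher.test(tab)
  list(per_recipient = per, table = tab, fisher = ft,
       odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Export a tracking matrix as long and wide TSV
#'
#' The long table has one row per (species, comparison) with score, call and
#' attribution; the wide table is the figure-style grid (species rows,
#' comparison columns, cell = call). Ordering is deterministic: species
#' alphabetical, comparisons by subject then timepoint.
#'
#' @param matrix A `tracking_matrix`.
#' @param path Output path for the long TSV; the wide grid goes to
#'   `<path minus extension>_wide.tsv`.
#' @return `path`, invisibly.
#' @export
export_matrix <- function(matrix, path) {
  ord <- order(matrix$species_id, matrix$subject_id, matrix$timepoint_days,
               matrix$comparison_id)
  long <- matrix[ord, c("species_id", "comparison_id", "type", "sample_a",
                        "sample_b", "subject_id", "timepoint_days",
                        "score_percent", "cutoff", "evaluable", "call",
                        "attribution", "both_related", "reason")]
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  comp <- unique(long[, c("comparison_id", "subject_id", "timepoint_days")])
  comp <- comp[order(comp$subject_id, comp$timepoint_days, comp$comparison_id), ]
  species <- sort(unique(long$species_id))
  wide <- matrix(NA_character_, nrow = length(species), ncol = nrow(comp),
                 dimnames = list(species, comp$comparison_id))
  for (i in seq_len(nrow(long))) {
    wide[long$species_id[i], long$comparison_id[i]] <- long$call[i]
  }
  wide_path <- sub("\\.tsv$", "", path)
  wide_path <- paste0(wide_path, "_wide.tsv")
  write.table(data.frame(species_id = rownames(wide), wide,
                         check.names = FALSE),
              wide_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a tracking matrix as a colored grid
#'
#' Mirrors the figure-style color coding: cells colored by call (or by
#' attribution for donor comparisons). Requires ggplot2.
#'
#' @param matrix A `tracking_matrix`.
#' @param fill `"call"` or `"attribution"`.
#' @return A ggplot object.
#' @export
plot_tracking_matrix <- function(matrix, fill = c("call", "attribution")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  fill <- match.arg(fill)
  df <- as.data.frame(matrix)
  df$fill_value <- df[[fill]]
  ggplot2::ggplot(df, ggplot2::aes(x = comparison_id, y = species_id,
                                   fill = fill_value)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(values = c(
      related = "#1b9e77", unrelated = "#d95f02", indeterminate = "white",
      `donor-related` = "#1b9e77", `preFMT-related` = "#7570b3",
      neither = "#d95f02", `not-applicable` = "grey85"), name = fill) +
    ggplot2::labs(x = "comparison", y = "species") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

utils::globalVariables(c("comparison_id", "species_id", "fill_value"))
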