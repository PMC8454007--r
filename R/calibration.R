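# Cut-off calibration: score labeled related/unrelated pairs and place a
# per-species threshold that separates the two classes, emulating how the
# published per-species cut-offs were established on paired HMP samples.

#' Score labeled sample pairs for calibration
#'
#' Same-subject longitudinal pairs are the related class; cross-subject
#' pairs are the unrelated class. Non-evaluable pairs are dropped (counted),
#' and a species with fewer than two evaluable pairs in either class is
#' flagged uncalibratable.
#'
#' @param profiles Named list: `profiles[[sample_id]]` is a `strain_profile`
#'   (single species) or a named list of profiles by species.
#' @param pairs Data frame with columns `sample_a`, `sample_b`, `label`
#'   (related/unrelated) and optionally `species_id` (required when profiles
#'   are nested by species).
#' @param ... Scoring parameters passed to [wss_score()].
#' @return List with `scores` (data frame: `species_id`, `sample_a`,
#'   `sample_b`, `score_percent`, `label`), `n_dropped` (non-evaluable pair
#'   count) and `uncalibratable` (character vector of species).
#' @export
score_labeled_pairs <- function(profiles, pairs, ...) {
  stopifnot(all(c("sample_a", "sample_b", "label") %in% names(pairs)))
  bad <- setdiff(unique(pairs$label), c("related", "unrelated"))
  if (length(bad)) stop("labels must be related/unrelated; got: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  get_profile <- function(sample_id, species_id) {
    p <- profiles[[sample_id]]
    if (is.null(p)) stop("no profile for sample ", sample_id, call. = FALSE)
    if (inherits(p, "strain_profile")) p else p[[species_id]]
  }
  rows <- vector("list", nrow(pairs))
  n_dropped <- 0L
  sp_seen <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sp <- if ("species_id" %in% names(pairs)) pairs$species_id[i] else NA_character_
    pa <- get_profile(pairs$sample_a[i], sp)
    pb <- get_profile(pairs$sample_b[i], sp)
    sp_seen[i] <- pa$species_id
    res <- wss_score(pa, pb, ...)
    if (!res$evaluable) { n_dropped <- n_dropped + 1L; next }
    rows[[i]] <- data.frame(
      species_id = res$species_id, sample_a = res$sample_a,
      sample_b = res$sample_b, score_percent = res$score_percent,
      label = pairs$label[i], stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(scores)) {
    scores <- data.frame(species_id = character(), sample_a = character(),
                         sample_b = character(), score_percent = numeric(),
                         label = character(), stringsAsFactors = FALSE)
  }
  uncal <- character()
  for (sp in unique(sp_seen)) {
    sub <- scores[scores$species_id == sp, , drop = FALSE]
    if (sum(sub$label == "related") < 2 || sum(sub$label == "unrelated") < 2) {
      uncal <- c(uncal, sp)
    }
  }
  list(scores = scores, n_dropped = n_dropped, uncalibratable = unique(uncal))
}

#' Fit a relatedness cut-off from labeled scores
#'
#' One-dimensional minimum-error threshold under the decision rule
#' "related iff score > cutoff". Candidate thresholds are the midpoints
#' between adjacent distinct observed scores (plus guards below the minimum
#' and above the maximum); among error-minimizing splits the one with the
#' widest gap between flanking scores is taken (then the lower cutoff). When
#' the classes are interleaved and no split removes all error, the global
#' error minimum is returned with a warning.
#'
#' @param scores Either the `scores` data frame from
#'   [score_labeled_pairs()] (single species) or a numeric vector of scores.
#' @param labels Character vector (related/unrelated) when `scores` is
#'   numeric.
#' @param method `"min_error"` (default) or `"youden"` (maximize
#'   sensitivity + specificity − 1; coincides with minimum error for
#'   balanced classes).
#' @return List with `cutoff_percent`, `training_error` (misclassification
#'   proportion), `n_misclassified`, `n_related`, `n_unrelated`.
#' @export
fit_cutoff <- function(scores, labels = NULL, method = c("min_error", "youden")) {
  method <- match.arg(method)
  if (is.data.frame(scores)) {
    labels <- scores$label
    scores <- scores$score_percent
  }
  stopifnot(length(scores) == length(labels), length(scores) > 0)
  is_rel <- labels == "related"
  if (!any(is_rel) || all(is_rel)) {
    stop("both classes must be present to fit a cut-off", call. = FALSE)
  }
  s <- sort(unique(scores))
  cand <- if (length(s) == 1) s else (s[-1] + s[-length(s)]) / 2
  gaps <- if (length(s) == 1) 0 else diff(s)
  # guards outside the observed range
  cand <- c(min(s) - 1, cand, max(s) + 1)
  gaps <- c(0, gaps, 0)
  n_rel <- sum(is_rel)
  n_unrel <- sum(!is_rel)
  obj <- vapply(cand, function(ct) {
    fn <- sum(is_rel & scores <= ct)      # related called unrelated
    fp <- sum(!is_rel & scores > ct)      # unrelated called related
    if (method == "min_error") fn + fp
    else fn / n_rel + fp / n_unrel        # 1 - (sens + spec - 1), up to affine
  }, 0)
  best <- which(obj == min(obj))
  best <- best[order(-gaps[best], cand[best])][1]
  cutoff <- cand[best]
  n_mis <- sum(is_rel & scores <= cutoff) + sum(!is_rel & scores > cutoff)
  if (n_mis > 0) {
    warning("classes are not separable; cut-off placed at the global ",
            "training-error minimum (", n_mis, " misclassified)", call. = FALSE)
  }
  list(cutoff_percent = cutoff, training_error = n_mis / length(scores),
       n_misclassified = n_mis, n_related = n_rel, n_unrelated = n_unrel)
}

#' Build a per-species cut-off table from fitted cut-offs
#'
#' @param fits Named list of [fit_cutoff()] results (names are species ids),
#'   or a data frame with `species_id` and `cutoff_percent`.
#' @param path Optional path; when given the table is also written as TSV.
#' @param provenance Free-text provenance note stored as an attribute.
#' @return Data frame with `species_id`, `cutoff_percent` (and
#'   `training_error` when available), attribute `provenance`.
#' @export
build_cutoff_table <- function(fits, path = NULL,
                               provenance = "synthetic calibration") {
  if (is.data.frame(fits)) {
    tab <- fits
  } else {
    stopifnot(length(fits) >= 1, !is.null(names(fits)))
    tab <- data.frame(
      species_id = names(fits),
      cutoff_percent = vapply(fits, `[[`, 0, "cutoff_percent"),
      training_error = vapply(fits, `[[`, 0, "training_error"),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(tab$species_id)) {
    stop("duplicate species in cut-off fits", call. = FALSE)
  }
  attr(tab, "provenance") <- c(note = provenance, date = format(Sys.Date()))
  if (!is.null(path)) write_cutoff_table(tab, path)
  tab
}

#' Simulate labeled calibration scores for one species
#'
#' Emulates a calibration set: related pairs are the same strain re-sequenced
#' twice (sequencing error only); unrelated pairs are two strains diverged at
#' `snvs_per_kb`. Each pair is scored through the full read → profile → WSS
#' route.
#'
#' @param ref A `reference_genome`.
#' @param n_related,n_unrelated Pairs per class.
#' @param snvs_per_kb Divergence of unrelated strains (SNVs per kb).
#' @param mean_depth,read_length,error_rate Read-simulation settings.
#' @param seed Integer seed.
#' @param ... Scoring parameters passed to [wss_score()].
#' @return Data frame of labeled scores (`species_id`, `score_percent`,
#'   `label`); attribute `n_dropped` counts non-evaluable pairs.
#' @export
simulate_calibration_scores <- function(ref, n_related = 20, n_unrelated = 20,
                                        snvs_per_kb = 1, mean_depth = 20,
                                        read_length = 100, error_rate = 0.01,
                                        seed = 1, ...) {
  stopifnot(inherits(ref, "reference_genome"))
  n_snvs <- as.integer(round(snvs_per_kb * ref$length / 1000))
  n_pairs <- n_related + n_unrelated
  seeds <- derive_seeds(seed, 2L + 4L * n_pairs)
  # related pairs resequence the same 0-SNV strain; unrelated pairs place the
  # full divergence between the two strains
  strain_a <- mutate_strain(ref, 0L, seeds[1], strain_id = "calib_a")
  strain_b <- mutate_strain(ref, n_snvs, seeds[2], strain_id = "calib_b")
  prof <- function(strain, s, id) {
    profile_reads(
      simulate_reads(strain, mean_depth = mean_depth, read_length = read_length,
                     error_rate = error_rate, seed = s, sample_id = id),
      ref, sample_id = id, run_qc = FALSE)
  }
  rows <- vector("list", n_pairs)
  n_dropped <- 0L
  k <- 3L
  for (i in seq_len(n_pairs)) {
    related <- i <= n_related
    pa <- prof(strain_a, seeds[k], sprintf("p%03d_a", i)); k <- k + 1L
    pb <- prof(if (related) strain_a else strain_b, seeds[k],
               sprintf("p%03d_b", i)); k <- k + 1L
    res <- wss_score(pa, pb, ...)
    if (!res$evaluable) { n_dropped <- n_dropped + 1L; next }
    rows[[i]] <- data.frame(
      species_id = ref$species_id, score_percent = res$score_percent,
      label = if (related) "related" else "unrelated",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  attr(out, "n_dropped") <- n_dropped
  out
}
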