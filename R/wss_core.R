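# Window-based SNV similarity: gate a sample pair on coverage/depth, score
# per-window consensus agreement, average across windows, and classify the
# pair against a per-species cut-off.

#' Gate a profile pair on coverage and depth
#'
#' A pair is evaluable only when BOTH samples exceed the coverage and depth
#' criteria, with strict inequality: coverage fraction > `min_coverage` and
#' mean depth > `min_depth`. Pairs failing the gate yield no score and are
#' reported as indeterminate (the figures' white boxes).
#'
#' @param profile_a,profile_b `strain_profile`s of the same species.
#' @param min_coverage Minimum coverage fraction (default 0.30, exclusive).
#' @param min_depth Minimum mean depth (default 3.5, exclusive).
#' @return List with `evaluable` (logical) and `diagnostics` (data frame of
#'   per-sample coverage fraction and mean depth).
#' @export
gate_pair <- function(profile_a, profile_b, min_coverage = 0.30,
                      min_depth = 3.5) {
  stopifnot(inherits(profile_a, "strain_profile"),
            inherits(profile_b, "strain_profile"))
  if (!identical(profile_a$species_id, profile_b$species_id)) {
    stop("profiles are for different species: ", profile_a$species_id,
         " vs ", profile_b$species_id, call. = FALSE)
  }
  diag <- data.frame(
    sample_id = c(profile_a$sample_id, profile_b$sample_id),
    coverage_fraction = c(profile_a$coverage_fraction, profile_b$coverage_fraction),
    mean_depth = c(profile_a$mean_depth, profile_b$mean_depth)
  )
  evaluable <- all(diag$coverage_fraction > min_coverage) &&
    all(diag$mean_depth > min_depth)
  list(evaluable = evaluable, diagnostics = diag)
}

#' Per-window co-coverage and agreement counts
#'
#' The reference is partitioned into consecutive non-overlapping windows
#' `[i*W, (i+1)*W)`. A window is emitted only when it holds at least
#' `min_sites_per_window` co-covered sites (sites with a consensus call in
#' both samples); `matching_sites` counts co-covered sites where the two
#' consensus alleles agree.
#'
#' @param profile_a,profile_b `strain_profile`s of the same species and
#'   reference length.
#' @param window_len Window length in bp (>= 100; default 1000).
#' @param min_sites_per_window Minimum co-covered sites per emitted window
#'   (>= 1; default 10).
#' @return Data frame with `window_index` (0-based), `co_covered_sites`,
#'   `matching_sites`.
#' @export
window_scores <- function(profile_a, profile_b, window_len = 1000,
                          min_sites_per_window = 10) {
  stopifnot(inherits(profile_a, "strain_profile"),
            inherits(profile_b, "strain_profile"),
            profile_a$L == profile_b$L)
  if (window_len < 100) stop("window_len must be >= 100", call. = FALSE)
  if (min_sites_per_window < 1) stop("min_sites_per_window must be >= 1", call. = FALSE)
  a <- profile_a$consensus
  b <- profile_b$consensus
  co <- which(!is.na(a) & !is.na(b))
  if (length(co) == 0) {
    return(data.frame(window_index = integer(), co_covered_sites = integer(),
                      matching_sites = integer()))
  }
  win <- (co - 1L) %/% as.integer(window_len)
  match_flag <- a[co] == b[co]
  co_n <- tapply(rep(1L, length(co)), win, sum)
  match_n <- tapply(as.integer(match_flag), win, sum)
  out <- data.frame(window_index = as.integer(names(co_n)),
                    co_covered_sites = as.integer(co_n),
                    matching_sites = as.integer(match_n))
  out <- out[out$co_covered_sites >= min_sites_per_window, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Window-based SNV similarity score for a sample pair
#'
#' After gating, the score is 100 times the mean over emitted windows of the
#' per-window fraction of co-covered sites whose consensus alleles agree
#' (windows are the averaging unit; a site-weighted variant — one global
#' ratio over all co-covered sites — is available via `site_weighted`). The
#' score is undefined (NA) when the pair fails the gate or no window is
#' emitted.
#'
#' @param profile_a,profile_b `strain_profile`s of the same species.
#' @param window_len,min_sites_per_window See [window_scores()].
#' @param min_coverage,min_depth See [gate_pair()].
#' @param site_weighted Weight windows by their co-covered sites (i.e. pool
#'   all sites) instead of averaging windows equally.
#' @return A `wss_result`: one-row data frame with `species_id`, `sample_a`,
#'   `sample_b`, `score_percent` (NA when not evaluable), `evaluable`,
#'   `windows_used`, and per-sample gating diagnostics
#'   (`coverage_a/b`, `depth_a/b`).
#' @export
wss_score <- function(profile_a, profile_b, window_len = 1000,
                      min_sites_per_window = 10, min_coverage = 0.30,
                      min_depth = 3.5, site_weighted = FALSE) {
  gate <- gate_pair(profile_a, profile_b, min_coverage, min_depth)
  score <- NA_real_
  n_win <- 0L
  if (gate$evaluable) {
    ws <- window_scores(profile_a, profile_b, window_len, min_sites_per_window)
    n_win <- nrow(ws)
    if (n_win > 0) {
      score <- if (site_weighted) {
        100 * sum(ws$matching_sites) / sum(ws$co_covered_sites)
      } else {
        100 * mean(ws$matching_sites / ws$co_covered_sites)
      }
    }
  }
  structure(
    data.frame(
      species_id = profile_a$species_id,
      sample_a = profile_a$sample_id, sample_b = profile_b$sample_id,
      score_percent = score,
      evaluable = gate$evaluable && n_win > 0,
      windows_used = n_win,
      coverage_a = gate$diagnostics$coverage_fraction[1],
      coverage_b = gate$diagnostics$coverage_fraction[2],
      depth_a = gate$diagnostics$mean_depth[1],
      depth_b = gate$diagnostics$mean_depth[2],
      stringsAsFactors = FALSE
    ),
    class = c("wss_result", "data.frame")
  )
}

#' Classify a scored pair against a species cut-off
#'
#' Related when the score strictly exceeds the cut-off, unrelated when it is
#' strictly below; a score exactly at the cut-off is conservatively called
#' unrelated. Non-evaluable results, and species without an established
#' cut-off, are indeterminate.
#'
#' @param result A `wss_result` row.
#' @param cutoff_percent The species' cut-off in (0, 100), or NA/missing
#'   when none is established.
#' @return A `pair_call`: one-row data frame with the result's fields plus
#'   `cutoff`, `call` (related/unrelated/indeterminate) and `reason`.
#' @export
classify_pair <- function(result, cutoff_percent = NA_real_) {
  stopifnot(inherits(result, "wss_result") || is.data.frame(result))
  if (length(cutoff_percent) == 0) cutoff_percent <- NA_real_
  if (!is.na(cutoff_percent) &&
      (cutoff_percent <= 0 || cutoff_percent >= 100)) {
    stop("cutoff_percent must lie strictly between 0 and 100", call. = FALSE)
  }
  if (is.na(cutoff_percent)) {
    call <- "indeterminate"
    reason <- "no established cut-off"
  } else if (!isTRUE(result$evaluable) || is.na(result$score_percent)) {
    call <- "indeterminate"
    reason <- "gating criteria not satisfied"
  } else if (result$score_percent > cutoff_percent) {
    call <- "related"
    reason <- ""
  } else {
    call <- "unrelated"
    reason <- ""
  }
  out <- cbind(as.data.frame(result), data.frame(
    cutoff = cutoff_percent, call = call, reason = reason,
    stringsAsFactors = FALSE))
  class(out) <- c("pair_call", "data.frame")
  out
}
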