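# End-to-end evaluation of synthetic FMT scenarios: profile every
# (sample, species) cell, calibrate cut-offs under the same simulation
# settings, run the tracking pipeline, and compare each cell's attribution
# with the manifest's ground truth.

#' Profile every cell of a scenario
#'
#' Runs QC (quality trim + length filter; no host screen, the simulations
#' are host-free) and the mapper/consensus caller on every (sample, species)
#' read set.
#'
#' @param scenario An `fmt_scenario`.
#' @param site_min_depth Per-site depth threshold for consensus calls.
#' @param run_qc Apply the QC pipeline before mapping.
#' @return Nested list `profiles[[sample_id]][[species_id]]`.
#' @export
scenario_profiles <- function(scenario, site_min_depth = 4, run_qc = TRUE) {
  stopifnot(inherits(scenario, "fmt_scenario"))
  profiles <- list()
  for (sid in names(scenario$reads)) {
    for (sp in names(scenario$reads[[sid]])) {
      profiles[[sid]][[sp]] <- profile_reads(
        scenario$reads[[sid]][[sp]], scenario$references[[sp]],
        sample_id = sid, site_min_depth = site_min_depth, run_qc = run_qc)
    }
  }
  profiles
}

#' Calibrate per-species cut-offs matching a scenario's settings
#'
#' Fits each species' cut-off from synthetic labeled pairs simulated under
#' the scenario's depth/error/divergence settings — the same route the
#' published per-species cut-offs took via labeled HMP pairs.
#'
#' @param scenario An `fmt_scenario`.
#' @param n_pairs Pairs per class per species.
#' @param seed Integer seed (independent of the scenario's).
#' @return Cut-off table data frame.
#' @export
calibrate_scenario_cutoffs <- function(scenario, n_pairs = 5, seed = 1) {
  stopifnot(inherits(scenario, "fmt_scenario"))
  p <- scenario$params
  seeds <- derive_seeds(seed, length(scenario$references))
  fits <- list()
  for (i in seq_along(scenario$references)) {
    ref <- scenario$references[[i]]
    sc <- simulate_calibration_scores(
      ref, n_related = n_pairs, n_unrelated = n_pairs,
      snvs_per_kb = p$snvs_per_kb,
      mean_depth = p$mean_depth, read_length = p$read_length,
      error_rate = p$error_rate, seed = seeds[i])
    fits[[ref$species_id]] <- fit_cutoff(sc)
  }
  build_cutoff_table(fits)
}

#' Ground-truth attribution for a scenario's post-FMT cells
#'
#' Derives, from the manifest, the attribution each evaluable post-FMT cell
#' should receive: `donor-related` when the cell's true strain is the donor
#' strain, `preFMT-related` when it is the recipient's pre-FMT strain, and
#' `neither` for a novel strain. Cells simulated below the coverage/depth
#' gate are expected `indeterminate`.
#'
#' @param scenario An `fmt_scenario`.
#' @param min_coverage,min_depth The gate thresholds cells are simulated
#'   against.
#' @return Data frame: `species_id`, `sample_id`, `truth_attribution`.
#' @export
scenario_truth <- function(scenario, min_coverage = 0.30, min_depth = 3.5) {
  man <- scenario$manifest
  post <- man[man$role == "recipient" & !man$pre_fmt, , drop = FALSE]
  truth <- ifelse(post$covered_fraction <= min_coverage |
                    post$mean_depth <= min_depth,
                  "indeterminate",
                  c(donor = "donor-related", recipient = "preFMT-related",
                    novel = "neither")[post$origin])
  data.frame(species_id = post$species_id, sample_id = post$sample_id,
             truth_attribution = unname(truth), stringsAsFactors = FALSE)
}

#' Run and evaluate one scenario end to end
#'
#' Profiles the scenario, runs the combined donor + pre-FMT tracking, and
#' scores the observed attributions against the manifest's ground truth.
#'
#' @param scenario An `fmt_scenario`.
#' @param cutoffs Cut-off table; calibrated from the scenario's settings via
#'   [calibrate_scenario_cutoffs()] when NULL.
#' @param site_min_depth Consensus site depth threshold.
#' @param ... Scoring parameters passed through to [run_tracking()].
#' @return List with `matrix` (the `tracking_matrix`), `cells` (per-cell
#'   observed vs truth), `accuracy` (fraction of gate-passing cells whose
#'   attribution matches truth), `n_evaluable`, and
#'   `low_coverage_indeterminate` (fraction of below-gate cells called
#'   indeterminate; NA when the scenario has none).
#' @export
evaluate_scenario <- function(scenario, cutoffs = NULL, site_min_depth = 4, ...) {
  if (is.null(cutoffs)) {
    cutoffs <- calibrate_scenario_cutoffs(scenario,
                                          seed = scenario$params$seed + 7919L)
  }
  profiles <- scenario_profiles(scenario, site_min_depth = site_min_depth)
  scheme <- rbind(
    build_pairing_scheme(scenario$metadata, "donor_vs_recipient"),
    build_pairing_scheme(scenario$metadata, "pre_vs_post"))
  mat <- run_tracking(profiles, cutoffs, scheme, ...)
  truth <- scenario_truth(scenario)
  donor_rows <- mat[mat$type == "donor" & mat$attribution != "not-applicable",
                    c("species_id", "sample_b", "attribution", "both_related")]
  cells <- merge(truth, donor_rows,
                 by.x = c("species_id", "sample_id"),
                 by.y = c("species_id", "sample_b"))
  expected_det <- cells$truth_attribution != "indeterminate"
  observed_det <- cells$attribution != "indeterminate"
  eval_cells <- cells[expected_det & observed_det, , drop = FALSE]
  accuracy <- if (nrow(eval_cells)) {
    mean(eval_cells$attribution == eval_cells$truth_attribution)
  } else NA_real_
  low <- cells[!expected_det, , drop = FALSE]
  low_ind <- if (nrow(low)) mean(low$attribution == "indeterminate") else NA_real_
  list(matrix = mat, cells = cells, accuracy = accuracy,
       n_evaluable = nrow(eval_cells), low_coverage_indeterminate = low_ind,
       cutoffs = cutoffs)
}
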