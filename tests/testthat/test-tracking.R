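fmt_metadata <- function() {
  data.frame(
    sample_id = c("D1", "R1_pre", "R1_p1", "R1_p2", "R1_p3"),
    subject_id = c("D1", rep("R1", 4)),
    role = c("donor", rep("recipient", 4)),
    timepoint_days = c(0L, 0L, 7L, 31L, 65L),
    pre_fmt = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    donor_link = c(NA, rep("D1", 4)),
    response = c("none", rep("R", 4)),
    stringsAsFactors = FALSE)
}

test_that("pairing schemes enumerate the figure-style comparisons", {
  md <- fmt_metadata()
  dvr <- build_pairing_scheme(md, "donor_vs_recipient")
  expect_equal(nrow(dvr), 4) # donor vs pre + 3 post
  expect_true(all(dvr$sample_a == "D1"))

  pvp <- build_pairing_scheme(md, "pre_vs_post")
  expect_equal(nrow(pvp), 3)
  expect_true(all(pvp$sample_a == "R1_pre"))

  seg <- expand.grid(subject = sprintf("S%d", 1:6),
                     segment = c("cecum", "transverse", "sigmoid"),
                     stringsAsFactors = FALSE)
  seg_md <- data.frame(
    sample_id = paste(seg$subject, seg$segment, sep = "_"),
    subject_id = seg$subject, role = "segment", segment = seg$segment,
    stringsAsFactors = FALSE)
  sps <- build_pairing_scheme(seg_md, "segment_pairwise")
  expect_equal(nrow(sps), 18) # 6 subjects x 3 segment pairs

  no_pre <- md[md$sample_id != "R1_pre", ]
  expect_warning(out <- build_pairing_scheme(no_pre, "pre_vs_post"),
                 "no pre-FMT")
  expect_equal(nrow(out), 0)

  bad <- md
  bad$donor_link[2] <- NA
  expect_error(build_pairing_scheme(bad, "donor_vs_recipient"),
               "without linked donor")
})

# profiles built directly: post-FMT samples equal to donor, pre, or neither
mk_tracking_fixture <- function(L = 6000) {
  donor <- random_profile(L, 1, seed = 1, species_id = "sp1",
                          sample_id = "D1", mean_depth = 10)
  pre <- perturb_profile(donor, n_flips = 60, seed = 2, sample_id = "R1_pre")
  novel <- perturb_profile(donor, n_flips = 120, seed = 3, sample_id = "x")
  profiles <- list(
    D1 = list(sp1 = donor),
    R1_pre = list(sp1 = pre),
    R1_p1 = list(sp1 = strain_profile(donor$consensus, "sp1", "R1_p1", 10)),
    R1_p2 = list(sp1 = strain_profile(pre$consensus, "sp1", "R1_p2", 10)),
    R1_p3 = list(sp1 = strain_profile(novel$consensus, "sp1", "R1_p3", 10)))
  cutoffs <- data.frame(species_id = "sp1", cutoff_percent = 99.5)
  md <- fmt_metadata()
  scheme <- rbind(build_pairing_scheme(md, "donor_vs_recipient"),
                  build_pairing_scheme(md, "pre_vs_post"))
  list(profiles = profiles, cutoffs = cutoffs, scheme = scheme, md = md)
}

test_that("tracking attributes post-FMT strains to donor, pre-FMT or neither", {
  fx <- mk_tracking_fixture()
  mat <- run_tracking(fx$profiles, fx$cutoffs, fx$scheme)
  donor_rows <- mat[mat$type == "donor", ]
  attr_of <- function(s) donor_rows$attribution[donor_rows$sample_b == s]
  expect_equal(attr_of("R1_p1"), "donor-related")
  expect_equal(attr_of("R1_p2"), "preFMT-related")
  expect_equal(attr_of("R1_p3"), "neither")
  # the pre-FMT sample itself gets no attribution
  expect_equal(attr_of("R1_pre"), "not-applicable")
  # attribution consistency: never simultaneously neither and related
  related_cells <- donor_rows$call == "related"
  expect_false(any(donor_rows$attribution[related_cells] == "neither"))
})

test_that("near-identical donor and pre-FMT strains set the both_related flag", {
  fx <- mk_tracking_fixture()
  donor_cons <- fx$profiles$D1$sp1$consensus
  fx$profiles$R1_pre$sp1 <- strain_profile(donor_cons, "sp1", "R1_pre", 10)
  fx$profiles$R1_p2$sp1 <- strain_profile(donor_cons, "sp1", "R1_p2", 10)
  mat <- run_tracking(fx$profiles, fx$cutoffs, fx$scheme)
  cell <- mat[mat$type == "donor" & mat$sample_b == "R1_p2", ]
  expect_equal(cell$attribution, "donor-related")
  expect_true(cell$both_related)
})

test_that("missing profiles and missing cut-offs yield indeterminate cells", {
  fx <- mk_tracking_fixture()
  fx$profiles$R1_p1 <- NULL
  mat <- run_tracking(fx$profiles, fx$cutoffs, fx$scheme)
  cell <- mat[mat$type == "donor" & mat$sample_b == "R1_p1", ]
  expect_equal(cell$call, "indeterminate")
  expect_match(cell$reason, "missing profile")

  fx2 <- mk_tracking_fixture()
  no_cut <- run_tracking(fx2$profiles, data.frame(species_id = character(),
                                                  cutoff_percent = numeric()),
                         fx2$scheme)
  expect_true(all(no_cut$call == "indeterminate"))
  expect_true(all(grepl("no established cut-off", no_cut$reason)))
})

test_that("adding another species leaves existing cells unchanged", {
  fx <- mk_tracking_fixture()
  mat1 <- run_tracking(fx$profiles, fx$cutoffs, fx$scheme)
  extra <- random_profile(6000, 1, seed = 9, species_id = "sp2", mean_depth = 10)
  profiles2 <- fx$profiles
  for (sid in names(profiles2)) {
    profiles2[[sid]]$sp2 <- strain_profile(extra$consensus, "sp2", sid, 10)
  }
  cutoffs2 <- rbind(fx$cutoffs, data.frame(species_id = "sp2",
                                           cutoff_percent = 99.5))
  mat2 <- run_tracking(profiles2, cutoffs2, fx$scheme)
  old <- mat2[mat2$species_id == "sp1", names(mat1)]
  rownames(old) <- NULL
  expect_equal(old, as.data.frame(mat1), ignore_attr = TRUE)
})

test_that("response concordance builds the 2x2 and Fisher test", {
  # perfectly concordant cohort: responders engrafted, non-responders not
  mk_matrix <- function(subjects, attributions) {
    do.call(rbind, lapply(seq_along(subjects), function(i) {
      data.frame(species_id = "sp1", sample_a = "D", sample_b = paste0("p", i),
                 type = "donor", subject_id = subjects[i],
                 attribution = attributions[i], call = "related",
                 stringsAsFactors = FALSE)
    }))
  }
  md <- data.frame(
    sample_id = paste0("p", 1:8), subject_id = paste0("S", 1:8),
    role = "recipient", timepoint_days = 7L, pre_fmt = FALSE,
    donor_link = "D", response = rep(c("R", "NR"), each = 4),
    stringsAsFactors = FALSE)
  mat <- mk_matrix(paste0("S", 1:8),
                   rep(c("donor-related", "neither"), each = 4))
  out <- summarize_response_concordance(mat, md)
  expect_equal(unname(out$table[1, 1]), 4)
  expect_equal(unname(out$table[2, 2]), 4)
  expect_true(is.infinite(out$odds_ratio))
  # closed-form Fisher p for a 4/0 vs 0/4 table, two-sided
  p_oracle <- sum(sapply(0:4, function(k) {
    p <- stats::dhyper(k, 4, 4, 4)
    if (p <= stats::dhyper(4, 4, 4, 4) + 1e-12) p else 0
  }))
  expect_equal(out$p_value, p_oracle, tolerance = 1e-10)

  empty <- summarize_response_concordance(mat[0, ], md)
  expect_match(empty$notice, "no attributed")
})

test_that("engraftment independent of response gives a near-null pooled odds ratio", {
  tab <- matrix(0, 2, 2)
  withr::with_seed(77, {
    for (s in 1:50) {
      n <- 20
      md <- data.frame(
        sample_id = paste0("p", 1:n), subject_id = paste0("S", 1:n),
        role = "recipient", timepoint_days = 7L, pre_fmt = FALSE,
        donor_link = "D", response = sample(c("R", "NR"), n, TRUE),
        stringsAsFactors = FALSE)
      attributions <- sample(c("donor-related", "neither"), n, TRUE)
      mat <- data.frame(species_id = "sp1", sample_a = "D",
                        sample_b = paste0("p", 1:n), type = "donor",
                        subject_id = paste0("S", 1:n),
                        attribution = attributions, call = "related",
                        stringsAsFactors = FALSE)
      out <- summarize_response_concordance(mat, md)
      if (!is.null(out$table)) tab <- tab + out$table
    }
  })
  pooled_or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_gt(pooled_or, 0.7)
  expect_lt(pooled_or, 1.4)
})

test_that("matrix export writes deterministic long and wide grids", {
  fx <- mk_tracking_fixture()
  extra <- random_profile(6000, 1, seed = 10, species_id = "sp2", mean_depth = 10)
  for (sid in names(fx$profiles)) {
    fx$profiles[[sid]]$sp2 <- strain_profile(extra$consensus, "sp2", sid, 10)
  }
  cutoffs <- rbind(fx$cutoffs, data.frame(species_id = "sp2",
                                          cutoff_percent = 99.5))
  scheme <- fx$scheme[fx$scheme$type == "donor" &
                        fx$scheme$sample_b %in% c("R1_p1", "R1_p2", "R1_p3"), ]
  mat <- run_tracking(fx$profiles, cutoffs, scheme)
  expect_equal(nrow(mat), 6) # 2 species x 3 comparisons

  d <- withr::local_tempdir()
  f1 <- file.path(d, "m1.tsv")
  f2 <- file.path(d, "m2.tsv")
  export_matrix(mat, f1)
  export_matrix(mat, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(file.path(d, "m1_wide.tsv")))

  back <- read.delim(f1, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 6)
  key <- function(df) paste(df$species_id, df$comparison_id)
  expect_setequal(paste(key(back), back$call), paste(key(mat), mat$call))
})

test_that("each scenario template is recovered end to end at small scale", {
  ref_cutoffs <- NULL
  for (tmpl in c("full_engraftment", "recipient_persistence",
                 "temporal_mosaic", "novel_strain",
                 "indeterminate_low_coverage")) {
    scen <- compose_scenario(tmpl, n_species = 2, genome_length = 20000,
                             mean_depth = 15, error_rate = 0.01, seed = 120)
    if (is.null(ref_cutoffs)) {
      ref_cutoffs <- calibrate_scenario_cutoffs(scen, n_pairs = 3, seed = 5)
    }
    ev <- evaluate_scenario(scen, cutoffs = ref_cutoffs)
    if (tmpl == "indeterminate_low_coverage") {
      expect_equal(ev$low_coverage_indeterminate, 1, info = tmpl)
    } else {
      expect_gt(ev$n_evaluable, 0)
      expect_equal(ev$accuracy, 1, info = tmpl)
    }
  }
})
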