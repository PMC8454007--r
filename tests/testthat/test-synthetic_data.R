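test_that("reference generation is seeded and hits its GC target", {
  r1 <- generate_reference("sp1", 10000, 0.5, seed = 1)
  r2 <- generate_reference("sp1", 10000, 0.5, seed = 1)
  expect_identical(r1$sequence, r2$sequence)
  expect_equal(nchar(r1$sequence), 10000)
  expect_true(grepl("^[ACGT]+$", r1$sequence))

  r3 <- generate_reference("sp1", 100000, 0.3, seed = 7)
  gc <- sum(strsplit(r3$sequence, "")[[1]] %in% c("G", "C")) / r3$length
  expect_gte(gc, 0.28)
  expect_lte(gc, 0.32)

  expect_error(generate_reference("sp1", -5, 0.5, seed = 1), "length_bp")
  expect_error(generate_reference("sp1", 10000, 1.2, seed = 1), "gc_fraction")
})

test_that("strain mutation places exactly the requested SNVs", {
  ref <- generate_reference("sp1", 100000, 0.5, seed = 3)
  s0 <- mutate_strain(ref, 0, seed = 5)
  expect_identical(s0$sequence, ref$sequence)
  expect_equal(nrow(s0$mutations), 0)

  s100 <- mutate_strain(ref, 100, seed = 5)
  expect_equal(hamming_chr(ref$sequence, s100$sequence), 100)
  expect_equal(nrow(s100$mutations), 100)
  expect_false(anyDuplicated(s100$mutations$pos) > 0)
  expect_true(all(s100$mutations$alt != s100$mutations$ref))

  s100b <- mutate_strain(ref, 100, seed = 5)
  expect_identical(s100$mutations, s100b$mutations)

  expect_error(mutate_strain(ref, ref$length + 1, seed = 1), "n_snvs")
})

test_that("read simulation controls coverage fraction and depth", {
  ref <- generate_reference("sp1", 50000, 0.5, seed = 11)
  st <- mutate_strain(ref, 50, seed = 12)

  full <- simulate_reads(st, mean_depth = 20, covered_fraction = 1,
                         read_length = 100, error_rate = 0, base_quality = 35,
                         seed = 3, sample_id = "s1")
  pf <- profile_reads(full, ref, run_qc = FALSE)
  expect_gt(pf$coverage_fraction, 0.95)
  expect_lt(abs(pf$mean_depth - 20) / 20, 0.15)

  part <- simulate_reads(st, mean_depth = 20, covered_fraction = 0.2,
                         read_length = 100, error_rate = 0, seed = 4,
                         sample_id = "s2")
  pp <- profile_reads(part, ref, run_qc = FALSE)
  expect_lte(pp$coverage_fraction, 0.25)

  # error-free reads match the strain exactly at their true positions
  truth <- attr(full, "truth")
  idx <- sample(nrow(full), 50)
  for (i in idx) {
    expect_identical(full$seq[i],
                     substr(st$sequence, truth$start[i] + 1,
                            truth$start[i] + 100))
  }

  expect_error(simulate_reads(st, 20, covered_fraction = 0, seed = 1),
               "covered_fraction")

  again <- simulate_reads(st, mean_depth = 20, covered_fraction = 1,
                          read_length = 100, error_rate = 0,
                          base_quality = 35, seed = 3, sample_id = "s1")
  expect_identical(full$seq, again$seq)
})

test_that("scenario templates encode their ground truth", {
  scen <- compose_scenario("full_engraftment", n_species = 2,
                           genome_length = 20000, mean_depth = 8,
                           error_rate = 0, seed = 21)
  man <- scen$manifest
  post <- man[man$role == "recipient" & !man$pre_fmt, ]
  expect_true(all(post$origin == "donor"))
  expect_true(all(grepl("_donor$", post$true_strain_id)))

  mosaic <- compose_scenario("temporal_mosaic", n_species = 1,
                             genome_length = 20000, mean_depth = 8,
                             error_rate = 0, seed = 22)
  mpost <- mosaic$manifest[mosaic$manifest$role == "recipient" &
                             !mosaic$manifest$pre_fmt, ]
  expect_true(any(mpost$origin == "donor"))
  expect_true(any(mpost$origin == "recipient"))

  novel <- compose_scenario("novel_strain", n_species = 1,
                            genome_length = 20000, mean_depth = 8,
                            error_rate = 0, seed = 23)
  st <- novel$strains[[1]]
  n_div <- round(novel$params$snvs_per_kb * 20000 / 1000)
  expect_gte(hamming_chr(st$novel$sequence, st$donor$sequence), n_div)
  expect_gte(hamming_chr(st$novel$sequence, st$recipient$sequence), n_div)

  low <- compose_scenario("indeterminate_low_coverage", n_species = 1,
                          genome_length = 20000, mean_depth = 8,
                          error_rate = 0, seed = 24)
  lpost <- low$manifest[low$manifest$role == "recipient" &
                          !low$manifest$pre_fmt, ]
  expect_true(all(lpost$covered_fraction <= 0.30))

  expect_error(compose_scenario("no_such_template", seed = 1),
               "full_engraftment.*temporal_mosaic")
})

test_that("every generated read set has exactly one manifest row", {
  scen <- compose_scenario("recipient_persistence", n_species = 2,
                           genome_length = 20000, mean_depth = 5,
                           error_rate = 0, seed = 31)
  emitted <- unlist(lapply(names(scen$reads), function(sid) {
    paste(sid, names(scen$reads[[sid]]))
  }))
  man_keys <- paste(scen$manifest$sample_id, scen$manifest$species_id)
  expect_setequal(emitted, man_keys)
  expect_false(anyDuplicated(man_keys) > 0)
})

test_that("scenarios are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  compose_scenario("temporal_mosaic", n_species = 1, genome_length = 20000,
                   mean_depth = 5, error_rate = 0.01, seed = 41, out_dir = d1)
  compose_scenario("temporal_mosaic", n_species = 1, genome_length = 20000,
                   mean_depth = 5, error_rate = 0.01, seed = 41, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("two-segment quality profiles drive the trimmer as designed", {
  ref <- generate_reference("sp1", 5000, 0.5, seed = 55)
  rs <- simulate_reads(
    ref, 3, 1, read_length = 150, error_rate = 0, seed = 56, sample_id = "s",
    quality_profile = list(head_q = 35, tail_q = 2, tail_start = 101))
  q <- utf8ToInt(rs$qual[1]) - 33L
  expect_equal(q[1:100], rep(35L, 100))
  expect_equal(q[101:150], rep(2L, 50))
  trimmed <- sliding_window_trim(rs)
  expect_true(all(nchar(trimmed$seq) == bf_trim_length(q)))
  expect_lt(bf_trim_length(q), 150)
})

test_that("profile divergence increases with strain SNV distance", {
  ref <- generate_reference("sp1", 20000, 0.5, seed = 51)
  mean_mismatch <- sapply(c(0, 50, 200), function(d) {
    mean(sapply(1:3, function(s) {
      st <- mutate_strain(ref, d, seed = 100 + s)
      p1 <- profile_reads(
        simulate_reads(ref, 10, 1, 100, 0, seed = 200 + s, sample_id = "a"),
        ref, run_qc = FALSE)
      p2 <- profile_reads(
        simulate_reads(st, 10, 1, 100, 0, seed = 300 + s, sample_id = "b"),
        ref, run_qc = FALSE)
      co <- !is.na(p1$consensus) & !is.na(p2$consensus)
      mean(p1$consensus[co] != p2$consensus[co])
    }))
  })
  expect_true(all(diff(mean_mismatch) >= 0))
})
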