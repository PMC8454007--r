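test_that("mapper places error-free reads at their true origin", {
  ref <- generate_reference("sp1", 30000, 0.5, seed = 61)
  st <- mutate_strain(ref, 30, seed = 62)
  rs <- simulate_reads(st, 10, 1, 100, 0, seed = 63, sample_id = "s")
  pile <- map_reads(rs, ref)
  truth <- attr(rs, "truth")$start
  placed <- pile$placements
  expect_gte(mean(!is.na(placed) & placed == truth), 0.99)

  empty <- as_read_set(data.frame(id = character(), seq = character(),
                                  qual = character()))
  p0 <- map_reads(empty, ref)
  expect_true(all(p0$counts == 0))

  other <- generate_reference("spX", 30000, 0.5, seed = 64)
  foreign <- simulate_reads(other, 2, 1, 100, 0, seed = 65, sample_id = "f")
  pf <- map_reads(foreign, ref)
  expect_lt(pf$n_placed / pf$n_reads, 0.01)

  long_read <- as_read_set(data.frame(
    id = "L", seq = random_dna(ref$length + 10, 66),
    qual = strrep("I", ref$length + 10), stringsAsFactors = FALSE))
  expect_warning(pl <- map_reads(long_read, ref), "longer than the reference")
  expect_equal(pl$n_too_long, 1)
})

test_that("pileup import converts coordinates and validates counts", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ref\tpos\tref_base\tdepth\tA\tC\tG\tT",
               "sp1\t1\tA\t5\t5\t0\t0\t0",
               "sp1\t3\tC\t4\t1\t3\t0\t0"), tsv)
  pile <- import_pileup(tsv, L = 10)
  expect_equal(pile$counts[1, "A"], c(A = 5L)) # file pos 1 -> row 1 (0-based 0)
  expect_equal(pileup_depth(pile), c(5L, 0L, 4L, rep(0L, 7)))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("ref\tpos\tref_base\tdepth\tA\tC\tG\tT", empty)
  expect_equal(sum(import_pileup(empty, L = 5)$counts), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ref\tpos\tref_base\tdepth\tA\tC\tG\tT",
               "sp1\t1\tA\t5\t5\t0\t0\t0",
               "sp1\t2\tC\t4\t1\t1\t0\t0"), bad)
  expect_error(import_pileup(bad), "line 3")
})

test_that("pileups round-trip through the TSV dialect", {
  ref <- generate_reference("sp1", 5000, 0.5, seed = 71)
  rs <- simulate_reads(ref, 6, 0.5, 100, 0.01, seed = 72, sample_id = "s")
  pile <- map_reads(rs, ref)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_pileup(pile, tsv, ref = ref)
  back <- import_pileup(tsv, L = ref$length)
  expect_equal(back$counts, pile$counts, ignore_attr = TRUE)
  expect_identical(back$species_id, "sp1")
})

test_that("consensus calling takes the majority with fixed tie order", {
  counts <- matrix(0L, nrow = 4, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[1, ] <- c(5L, 1L, 0L, 0L) # majority A
  counts[2, ] <- c(2L, 0L, 2L, 0L) # tie A/G -> A
  counts[3, ] <- c(1L, 1L, 1L, 0L) # depth 3 < 4 -> uncovered
  counts[4, ] <- c(0L, 0L, 1L, 4L) # majority T
  pile <- structure(list(species_id = "sp1", L = 4L, counts = counts),
                    class = "species_pileup")
  prof <- call_profile(pile, "s", site_min_depth = 4)
  expect_equal(prof$consensus, c(1L, 1L, NA_integer_, 4L))
  expect_equal(prof$coverage_fraction, 3 / 4)
  expect_error(call_profile(pile, "s", L = 0), "positive")
  expect_error(call_profile(pile, "s", site_min_depth = 0), "site_min_depth")
})

test_that("profiles of simulated reads recover the strain sequence", {
  ref <- generate_reference("sp1", 20000, 0.5, seed = 81)
  st <- mutate_strain(ref, 20, seed = 82)
  rs <- simulate_reads(st, 20, 1, 100, 0, seed = 83, sample_id = "s")
  prof <- profile_reads(rs, ref, run_qc = FALSE)
  expect_gt(prof$coverage_fraction, 0.95)
  expect_lt(abs(prof$mean_depth - 20) / 20, 0.15)
  truth <- seq_to_codes_chr(st$sequence)
  cov <- which(!is.na(prof$consensus))
  expect_gte(mean(prof$consensus[cov] == truth[cov]), 0.999)
})

test_that("coverage and depth diagnostics are monotone in the simulation dials", {
  ref <- generate_reference("sp1", 20000, 0.5, seed = 91)
  cov_out <- sapply(c(0.2, 0.5, 1.0), function(f) {
    profile_reads(simulate_reads(ref, 10, f, 100, 0, seed = 92, sample_id = "s"),
                  ref, run_qc = FALSE)$coverage_fraction
  })
  expect_true(all(diff(cov_out) > 0))
  depth_out <- sapply(c(6, 12, 24), function(d) {
    profile_reads(simulate_reads(ref, d, 1, 100, 0, seed = 93, sample_id = "s"),
                  ref, run_qc = FALSE)$mean_depth
  })
  expect_true(all(diff(depth_out) > 0))
})

test_that("strain profiles round-trip through TSV plus JSON sidecar", {
  ref <- generate_reference("sp1", 6000, 0.5, seed = 41)
  prof <- profile_reads(
    simulate_reads(ref, 8, 0.7, 100, 0.01, seed = 42, sample_id = "s"),
    ref, run_qc = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, tsv)
  back <- read_profile(tsv)
  expect_identical(back$consensus, prof$consensus)
  expect_equal(back$coverage_fraction, prof$coverage_fraction)
  expect_equal(back$mean_depth, prof$mean_depth)
  expect_identical(back$sample_id, "s")
})

test_that("donor pileup pooling adds counts position-wise", {
  ref <- generate_reference("sp1", 5000, 0.5, seed = 95)
  p1 <- map_reads(simulate_reads(ref, 3, 1, 100, 0, seed = 96, sample_id = "a"), ref)
  p2 <- map_reads(simulate_reads(ref, 3, 1, 100, 0, seed = 97, sample_id = "b"), ref)
  pooled <- pool_pileups(p1, p2)
  expect_equal(pooled$counts, p1$counts + p2$counts)
  other <- map_reads(simulate_reads(generate_reference("sp2", 5000, 0.5, seed = 98),
                                    3, 1, 100, 0, seed = 99, sample_id = "c"),
                     generate_reference("sp2", 5000, 0.5, seed = 98))
  expect_error(pool_pileups(p1, other), "share species")
})
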