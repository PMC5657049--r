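small_scenario <- function(...) {
  defaults <- list(n_families = 1, seeds_per_family = 8, family_length = 120,
                   divergence = 0.3, indel_rate = 0,
                   member_divergence = 0.05, fragment_mean_aa = 90,
                   fragment_sd_aa = 8, fragment_min_aa = 70,
                   fragment_max_aa = 110, read_length_nt = 76,
                   n_pairs = 50, error_rate = 0, rng_seed = 1)
  do.call(simulate_scenario, utils::modifyList(defaults, list(...)))
}

test_that("zero divergence and indel rate reproduce the ancestor", {
  fam <- simulate_family(small_scenario(divergence = 0, rng_seed = 5))
  expect_equal(length(unique(fam$msa$seqs)), 1L)
  expect_false(grepl("-", fam$msa$seqs[1]))
  # member at divergence 0.05 differs from (equal-length) seeds only by
  # substitutions
  expect_equal(nchar(fam$member_aa), nchar(fam$msa$seqs[1]))
})

test_that("mean pairwise seed identity matches the closed form", {
  # two rows diverged independently at rate p agree per site with
  # probability (1-p)^2 + p^2/19
  p <- 0.3
  expected <- (1 - p)^2 + p^2 / 19
  obs <- numeric(50)
  for (rep in 1:50) {
    fam <- simulate_family(small_scenario(seeds_per_family = 10,
                                          family_length = 200,
                                          fragment_mean_aa = 150,
                                          fragment_min_aa = 100,
                                          fragment_max_aa = 180,
                                          divergence = p,
                                          rng_seed = 1000 + rep))
    m <- do.call(rbind, strsplit(fam$msa$seqs, ""))
    pairs <- utils::combn(nrow(m), 2)
    obs[rep] <- mean(apply(pairs, 2, function(ij)
      mean(m[ij[1], ] == m[ij[2], ])))
  }
  expect_lt(abs(mean(obs) - expected), 0.05 * expected)
})

test_that("family simulation is deterministic under its seed", {
  a <- simulate_family(small_scenario(indel_rate = 0.05, rng_seed = 77))
  b <- simulate_family(small_scenario(indel_rate = 0.05, rng_seed = 77))
  expect_identical(a, b)
})

test_that("back-translation inverts to the member protein", {
  fam <- simulate_family(small_scenario(rng_seed = 6))
  tr <- six_frame_translate(fam$member_nt)
  expect_equal(tr$peptide[tr$frame == 1L], fam$member_aa)
})

test_that("error-free end1 maps exactly into the gene", {
  sc <- small_scenario(rng_seed = 8)
  fam <- simulate_family(sc)
  sim <- simulate_pairs(sc, fam$member_nt, n_pairs = 30)
  for (i in 1:30) {
    expect_true(grepl(sim$pairs$end1[i], fam$member_nt, fixed = TRUE))
    # FR orientation: end2 reverse-complemented lies on the gene too
    expect_true(grepl(reverse_complement(sim$pairs$end2[i]),
                      fam$member_nt, fixed = TRUE))
  }
})

test_that("true fragment lengths have the scenario mean (CLT bound)", {
  sc <- small_scenario(n_pairs = 5000, family_length = 250,
                       fragment_mean_aa = 150, fragment_sd_aa = 15,
                       fragment_min_aa = 66, fragment_max_aa = 240,
                       rng_seed = 9)
  fam <- simulate_family(sc)
  sim <- simulate_pairs(sc, fam$member_nt)
  m <- mean(sim$truth$true_fragment_aa)
  expect_lt(abs(m - 150), 3 * 15 / sqrt(5000) + 0.5)  # + integer rounding
  expect_true(all(sim$truth$true_fragment_aa >= 66))
  expect_true(all(sim$truth$true_fragment_aa <= 240))
})

test_that("truth covers every emitted pair exactly once; ids unique", {
  sc <- small_scenario(n_pairs = 40, rng_seed = 10)
  ds <- simulate_dataset(sc)
  expect_equal(sort(ds$truth$read_id), sort(ds$pairs$id))
  expect_false(anyDuplicated(ds$pairs$id) > 0)
})

test_that("pair simulation is deterministic and respects gene length", {
  sc <- small_scenario(rng_seed = 11)
  fam <- simulate_family(sc)
  a <- simulate_pairs(sc, fam$member_nt, n_pairs = 10)
  b <- simulate_pairs(sc, fam$member_nt, n_pairs = 10)
  expect_identical(a, b)
  expect_error(simulate_pairs(sc, strrep("ACG", 50)), "shorter")
})

test_that("a written dataset loads back through the package readers", {
  sc <- small_scenario(n_pairs = 10, rng_seed = 12)
  ds <- simulate_dataset(sc)
  dir <- withr::local_tempdir()
  write_sim_dataset(ds, dir)
  pairs <- read_paired_reads(file.path(dir, "reads_1.fastq"),
                             file.path(dir, "reads_2.fastq"))
  expect_equal(pairs$id, ds$pairs$id)
  expect_equal(pairs$end1, ds$pairs$end1)
  msa <- read_stockholm(file.path(dir, "families", "FAM01.sto"))
  expect_equal(msa$seqs, ds$msas$FAM01$seqs)
  truth <- read_truth_tsv(file.path(dir, "truth.tsv"))
  expect_equal(length(truth), 10L)
})
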