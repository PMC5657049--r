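make_msa <- function(seqs, ids = sprintf("s%d", seq_along(seqs)),
                     family_id = "F", rf = NULL) {
  shortpair:::new_seed_alignment(family_id, ids, seqs, rf = rf)
}

hit <- function(family, ms, me) {
  data.frame(read_id = "r", end = 1L, frame = 1L, family_id = family,
             model_start = ms, model_end = me, seq_start = 1L, seq_end = 1L,
             score = 10, evalue = 0.01, stringsAsFactors = FALSE)
}

test_that("coordinate conversion is the identity on ungapped rows", {
  msa <- make_msa(c("ACDEFGHIKL", "ACDEFGHIKL"))
  expect_equal(unname(model_span_to_seed_span(msa, 1:10, 1, 3, 10)),
               c(3, 10))
  # property: 200 random ungapped alignments, random spans
  set.seed(51)
  for (rep in 1:200) {
    L <- sample(5:40, 1)
    seqs <- replicate(sample(2:4, 1),
                      paste(sample(AA, L, replace = TRUE), collapse = ""))
    msa <- make_msa(seqs)
    a <- sort(sample.int(L, 2))
    sp <- model_span_to_seed_span(msa, seq_len(L), 1, a[1], a[2])
    expect_equal(unname(sp), a)
  }
})

test_that("gapped rows count only their own residues", {
  # column 3 is an insert (gap in row 1); map skips it
  msa <- make_msa(c("AC-EF", "ACDEF"))
  expect_equal(unname(model_span_to_seed_span(msa, c(1, 2, 4, 5), 1, 3, 4)),
               c(3, 4))
  expect_equal(unname(model_span_to_seed_span(msa, c(1, 2, 4, 5), 2, 3, 4)),
               c(4, 5))
})

test_that("spans gapped at both terminal columns are unanchored", {
  msa <- make_msa(c("--AAA", "CCAAA"))
  expect_null(model_span_to_seed_span(msa, 1:5, 1, 1, 2))
  expect_error(model_span_to_seed_span(msa, 1:5, 7, 1, 2), "out of range")
})

test_that("ungapped fragment length is z - w + 1", {
  msa <- make_msa(c(strrep("A", 60), strrep("A", 60)))
  fl <- estimate_fragment_length(msa, 1:60, hit("F", 1, 10), hit("F", 41, 50))
  expect_equal(fl, 50L)
})

test_that("per-seed averaging across an insert block rounds half up", {
  # seed A ungapped (60 residues); seed B carries a private 5-column insert
  # block between the two hit spans. Model span 1..50 -> 50 on A, 55 on B.
  sA <- paste0(strrep("A", 20), strrep("-", 5), strrep("A", 40))
  sB <- paste0(strrep("C", 20), strrep("C", 5), strrep("C", 40))
  msa <- make_msa(c(sA, sB))
  map <- c(1:20, 26:65)  # columns 21-25 are the insert block
  fl <- estimate_fragment_length(msa, map[1:60], hit("F", 1, 10),
                                 hit("F", 41, 50))
  expect_equal(fl, 53L)  # mean(c(50, 55)) = 52.5 -> 53
})

test_that("overlapping hits collapse to the outer span", {
  msa <- make_msa(c(strrep("A", 60), strrep("A", 60)))
  fl <- estimate_fragment_length(msa, 1:60, hit("F", 5, 40), hit("F", 10, 30))
  expect_equal(fl, 36L)  # hit1 span alone: 40 - 5 + 1
})

test_that("mismatched families and unanchored pairs error", {
  msa <- make_msa(c("ACDEF", "ACDEF"))
  expect_error(estimate_fragment_length(msa, 1:5, hit("F", 1, 2),
                                        hit("G", 3, 4)), "different famil")
  msa2 <- make_msa(c("--A--", "--A--"))
  expect_error(estimate_fragment_length(msa2, 1:5, hit("F", 1, 1),
                                        hit("F", 5, 5)), "anchors")
})

test_that("point-mass input gives a point distribution", {
  d <- build_distribution(rep(100L, 10), smoothing = 0)
  expect_equal(unname(d$probs["100"]), 1)
  expect_equal(d$support_min, 100L)
  expect_equal(d$support_max, 100L)
  expect_equal(fragment_probability(d, 100), 1)
  expect_equal(fragment_probability(d, 101), 0)  # no smoothing -> floor 0
})

test_that("histograms match the loop-coded oracle, smoothed and not", {
  set.seed(61)
  for (smoothing in c(0, 1, 2.5)) {
    lens <- sample(80:120, 500, replace = TRUE)
    d <- build_distribution(lens, smoothing = smoothing)
    expect_equal(d$probs, oracle_histogram(lens, smoothing),
                 tolerance = 1e-12)
    expect_equal(sum(d$probs), 1, tolerance = 1e-9)
  }
  # the two-point case: with smoothing 1 over 101 bins
  d <- build_distribution(c(100L, 200L), smoothing = 1)
  expect_equal(unname(fragment_probability(d, 150)), (1 / 101) / 3)
  expect_equal(unname(fragment_probability(d, 100)), (1 + 1 / 101) / 3)
  expect_true(fragment_probability(d, 500) > 0)  # floor outside support
  expect_error(build_distribution(integer(0)), "no fragment lengths")
})

test_that("outlier clipping drops lengths outside the range", {
  d <- build_distribution(c(rep(100L, 50), 1000L), smoothing = 0,
                          clip = c(66, 267))
  expect_equal(d$n_observations, 50L)
  expect_equal(d$support_max, 100L)
})

test_that("fragment distributions round-trip through TSV", {
  d <- build_distribution(sample(90:110, 200, replace = TRUE), smoothing = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fragdist_tsv(d, f)
  back <- read_fragdist_tsv(f)
  expect_equal(as.numeric(back$probs), as.numeric(d$probs))
  expect_equal(back$floor, d$floor)
  expect_equal(back$n_observations, d$n_observations)
})

test_that("unique-pair collection keeps exactly single-family pairs", {
  h <- rbind(hit("F1", 1, 5), hit("F1", 6, 9), hit("F2", 1, 5),
             hit("F1", 2, 6))
  h$read_id <- c("p1", "p1", "p2", "p2")
  h$end <- c(1L, 2L, 1L, 2L)
  # p1: end1 -> F1, end2 -> F1 (unique, same family) -> kept
  # p2: end1 -> F2, end2 -> F1 -> dropped
  u <- collect_unique_pairs(h)
  expect_equal(u$read_id, "p1")
  expect_equal(u$family_id, "F1")

  h2 <- h
  h2$read_id <- c("p3", "p3", "p3", "p4")
  h2$end <- c(1L, 1L, 2L, 1L)
  # p3: end1 hits two families -> excluded; p4 has no end2 -> excluded
  expect_equal(nrow(collect_unique_pairs(h2)), 0L)
})

test_that("low-divergence simulated hits are mostly collected as unique", {
  # single family: uniqueness only requires both ends to align
  sc <- simulate_scenario(n_families = 1, divergence = 0.2, indel_rate = 0,
                          member_divergence = 0.02, error_rate = 0,
                          n_pairs = 200, rng_seed = 71)
  ds <- simulate_dataset(sc)
  hmm <- calibrate_gumbel(build_from_msa(ds$msas[[1]]), 300, seed = 71)
  hits <- step1_scan(ds$pairs, list(hmm), run_config(seed = 71))
  u <- collect_unique_pairs(hits)
  expect_gte(nrow(u) / nrow(ds$pairs), 0.9)
  # agreement with a direct filtering oracle over the hit table
  both <- vapply(split(hits$end, hits$read_id),
                 function(e) length(unique(e)) == 2L, logical(1))
  fams <- vapply(split(hits$family_id, hits$read_id),
                 function(f) length(unique(f)) == 1L, logical(1))
  expect_setequal(u$read_id, names(both)[both & fams])
})
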