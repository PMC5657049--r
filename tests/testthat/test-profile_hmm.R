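make_msa <- function(seqs, ids = sprintf("s%d", seq_along(seqs)),
                     family_id = "F", rf = NULL) {
  shortpair:::new_seed_alignment(family_id, ids, seqs, rf = rf)
}

test_that("ungapped alignments make every column a match column", {
  hmm <- build_from_msa(make_msa(c("ACDEF", "ACDEF")))
  expect_equal(hmm$L, 5L)
  expect_equal(hmm$map_to_column, 1:5)
})

test_that("columns at gap fraction exactly 0.5 are not match columns", {
  hmm <- build_from_msa(make_msa(c("AC-EF", "ACDEF")))
  expect_equal(hmm$L, 4L)
  expect_equal(hmm$map_to_column, c(1L, 2L, 4L, 5L))
})

test_that("RF annotation overrides the gap-fraction rule", {
  hmm <- build_from_msa(make_msa(c("AC-EF", "ACDEF"), rf = "xx.xx"))
  expect_equal(hmm$map_to_column, c(1L, 2L, 4L, 5L))
  hmm2 <- build_from_msa(make_msa(c("AC-EF", "ACDEF"), rf = "xxxxx"))
  expect_equal(hmm2$L, 5L)
})

test_that("match emissions equal a separately coded count-and-normalize oracle", {
  seqs <- c("ACDEF", "ACDEY", "ACDEF", "GCDEF")
  hmm <- build_from_msa(make_msa(seqs))
  m <- do.call(rbind, strsplit(seqs, ""))
  for (k in 1:5) {
    cnt <- vapply(AA, function(a) sum(m[, k] == a), numeric(1))
    expect_equal(unname(hmm$match_emissions[k, ]),
                 unname((cnt + 1) / (sum(cnt) + 20)))
  }
  # all-identical column: P(A) = (n+1)/(n+20)
  expect_equal(unname(hmm$match_emissions[2, "C"]), 5 / 24)
})

test_that("emission and transition bundles are normalized on random alignments", {
  set.seed(21)
  for (rep in 1:5) {
    sc <- simulate_scenario(n_families = 1, family_length = 60,
                            fragment_mean_aa = 55, fragment_min_aa = 50,
                            fragment_max_aa = 58, indel_rate = 0.05,
                            rng_seed = 100 + rep)
    hmm <- build_from_msa(simulate_family(sc)$msa)
    expect_true(all(abs(rowSums(hmm$match_emissions) - 1) < 1e-9))
    expect_true(all(abs(rowSums(hmm$insert_emissions) - 1) < 1e-9))
    tr <- hmm$transitions
    expect_true(all(abs(rowSums(tr[, c("MM", "MI", "MD")]) - 1) < 1e-9))
    expect_true(all(abs(rowSums(tr[, c("IM", "II")]) - 1) < 1e-9))
    expect_true(all(abs(rowSums(tr[, c("DM", "DD")]) - 1) < 1e-9))
    expect_true(!is.unsorted(hmm$map_to_column, strictly = TRUE))
  }
})

test_that("excluding all rows errors; exclusion removes held-out members", {
  msa <- make_msa(c("ACDEF", "ACDEF", "GCDEF"))
  expect_error(build_from_msa(msa, exclude_ids = c("s1", "s2", "s3")),
               "excluded")
  hmm <- build_from_msa(msa, exclude_ids = "s3")
  expect_equal(unname(hmm$match_emissions[1, "G"]), 1 / 22)
})

test_that("consensus peptide aligns full-length with positive score", {
  hmm <- build_from_msa(make_msa(rep("ACDEFGHIK", 3)))
  hit <- viterbi_align(hmm, "ACDEFGHIK")
  expect_equal(hit$model_start, 1L)
  expect_equal(hit$model_end, 9L)
  expect_equal(hit$seq_start, 1L)
  expect_equal(hit$seq_end, 9L)
  expect_gt(hit$score, 0)
})

test_that("a lone stop codon can never align", {
  hmm <- build_from_msa(make_msa(rep("ACDEFGHIK", 3)))
  expect_null(viterbi_align(hmm, "*"))
  # and an alignment never crosses a stop: the local hit stays one side
  hit <- viterbi_align(hmm, "ACDE*GHIK")
  expect_true(hit$seq_end <= 4 || hit$seq_start >= 6)
})

test_that("Viterbi equals exhaustive path enumeration on random tiny instances", {
  set.seed(31)
  for (rep in 1:100) {
    L <- sample(2:6, 1)
    n <- sample(1:6, 1)
    hmm <- random_tiny_hmm(L)
    pep <- random_peptide(n)
    dp <- shortpair:::viterbi_score(hmm, pep)
    expect_equal(dp, oracle_viterbi(hmm, pep), tolerance = 1e-12,
                 info = sprintf("rep %d: L=%d pep=%s", rep, L, pep))
  }
})

test_that("residues that cannot join the local window leave the score alone", {
  hmm <- build_from_msa(make_msa(rep("ACDEFGHIK", 3)))
  base <- shortpair:::viterbi_score(hmm, "ACDEFGHIK")
  # '*' flanks cannot extend any path
  expect_equal(shortpair:::viterbi_score(hmm, "*ACDEFGHIK*"), base)
})

test_that("E-values follow the Gumbel closed form and its limits", {
  hmm <- build_from_msa(make_msa(rep("ACDEF", 2)))
  hmm$gumbel_mu <- 5
  hmm$gumbel_lambda <- 0.7
  expect_equal(evalue(hmm, 5, 1000), 1000)   # clipped at Z when s = mu
  expect_equal(evalue(hmm, 15, 1000), 1000 * exp(-7), tolerance = 1e-12)
  expect_equal(evalue(hmm, 1e6, 1000), 0)
  s <- seq(-5, 40, by = 0.5)
  expect_true(all(diff(evalue(hmm, s, 1000)) <= 0))         # monotone
  expect_equal(evalue(hmm, 20, 2000), 2 * evalue(hmm, 20, 1000))  # linear Z
})

test_that("uncalibrated models refuse to compute E-values", {
  hmm <- build_from_msa(make_msa(rep("ACDEF", 2)))
  expect_error(evalue(hmm, 10, 100), "calibrate")
})

test_that("Gumbel MLE recovers known parameters and is deterministic", {
  set.seed(41)
  x <- 4 - log(-log(runif(5000))) / 0.67  # Gumbel(mu = 4, lambda = 0.67)
  fit <- shortpair:::fit_gumbel(x)
  expect_lt(abs(fit["mu"] - 4), 0.2)
  expect_lt(abs(fit["lambda"] - 0.67), 0.05)

  hmm <- build_from_msa(make_msa(rep("ACDEFGHIKLMNPQRST", 3)))
  a <- calibrate_gumbel(hmm, 300, seed = 9)
  b <- calibrate_gumbel(hmm, 300, seed = 9)
  expect_identical(a$gumbel_mu, b$gumbel_mu)
  expect_identical(a$gumbel_lambda, b$gumbel_lambda)
  expect_error(calibrate_gumbel(hmm, 100, seed = 9), ">= 200")
})
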