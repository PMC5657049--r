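test_that("per-pair sensitivity follows |TP n C| / |TP|", {
  expect_equal(pair_sensitivity(c("A", "B"), c("A", "B")), 1)
  expect_equal(pair_sensitivity(c("A", "B"), c("A", "X")), 0.5)
  expect_equal(pair_sensitivity(c("A", "B"), character(0)), 0)
  expect_error(pair_sensitivity(character(0), "A"), "empty truth")
})

test_that("FP rate follows |C - TP| / |U - TP|, including the 3962 universe", {
  U <- sprintf("D%04d", 1:3962)
  expect_equal(pair_fp_rate("D0001", c("D0001", "D0002"), U), 1 / 3961)
  expect_equal(pair_fp_rate("A", "A", c("A", "B", "C")), 0)
  expect_equal(pair_fp_rate("A", c("B", "C"), c("A", "B", "C", "D", "E")),
               0.5)
  expect_error(pair_fp_rate(c("A", "B"), "A", c("A", "B")), "no true negatives")
})

test_that("F-score and PPV match hand-computed values", {
  expect_equal(unname(f_score_ppv(c("A", "B"), c("A", "B"))), c(1, 1))
  # sensitivity 0.5, PPV 1 -> F = 2/3
  expect_equal(unname(f_score_ppv(c("A", "B"), "A")), c(2 / 3, 1))
  expect_equal(unname(f_score_ppv("A", c("B", "C"))), c(0, 0))
  expect_equal(unname(f_score_ppv("A", character(0))), c(0, 0))
})

test_that("metric bounds and the F <= 2*min(sens, ppv) inequality hold", {
  set.seed(101)
  U <- sprintf("F%02d", 1:30)
  for (rep in 1:100) {
    TP <- sample(U, sample(1:5, 1))
    C <- sample(U, sample(0:8, 1))
    s <- pair_sensitivity(TP, C)
    fp <- pair_fp_rate(TP, C, U)
    f <- f_score_ppv(TP, C)
    expect_true(s >= 0 && s <= 1 && fp >= 0 && fp <= 1)
    expect_true(f["ppv"] >= 0 && f["ppv"] <= 1)
    expect_lte(f["f_score"], 2 * min(s, f["ppv"]) + 1e-12)
  }
})

test_that("dataset averaging equals an independent per-pair loop oracle", {
  set.seed(102)
  U <- sprintf("F%02d", 1:40)
  truth <- list()
  preds <- list()
  for (i in 1:200) {
    rid <- sprintf("p%03d", i)
    truth[[rid]] <- sample(U, sample(1:3, 1))
    preds[[rid]] <- sample(U, sample(0:5, 1))
  }
  got <- dataset_metrics(truth, preds, U)
  # oracle: plain accumulation loop
  acc <- c(0, 0, 0, 0)
  for (rid in names(truth)) {
    tp <- truth[[rid]]; C <- preds[[rid]]
    sens <- length(intersect(tp, C)) / length(tp)
    fpr <- length(setdiff(C, tp)) / (length(U) - length(tp))
    ppv <- if (length(C)) length(intersect(tp, C)) / length(C) else 0
    f <- if (sens + ppv > 0) 2 * sens * ppv / (sens + ppv) else 0
    acc <- acc + c(sens, fpr, f, ppv)
  }
  expect_equal(unname(got$mean), acc / length(truth), tolerance = 1e-12)
  expect_equal(got$n_excluded, 0L)
})

test_that("perfect and half-perfect datasets average as expected", {
  U <- c("A", "B", "C")
  truth <- list(p1 = "A", p2 = "B")
  perfect <- dataset_metrics(truth, list(p1 = "A", p2 = "B"), U)
  expect_equal(unname(perfect$mean), c(1, 0, 1, 1))
  half <- dataset_metrics(truth, list(p1 = "A", p2 = "C"), U)
  expect_equal(unname(half$mean["sensitivity"]), 0.5)
})

test_that("pairs with empty truth are excluded from averaging", {
  U <- c("A", "B")
  got <- dataset_metrics(list(p1 = "A", p2 = character(0)),
                         list(p1 = "A", p2 = "B"), U)
  expect_equal(got$n_excluded, 1L)
  expect_equal(nrow(got$per_pair), 1L)
})

test_that("tau sweep covers the 10-70% grid and E-value sweep is monotone", {
  set.seed(103)
  U <- sprintf("F%02d", 1:20)
  truth <- list()
  preds <- list()
  for (i in 1:50) {
    rid <- sprintf("p%03d", i)
    truth[[rid]] <- sample(U, 1)
    k <- sample(1:4, 1)
    p <- rexp(k)
    preds[[rid]] <- data.frame(family_id = sample(U, k),
                               posterior = p / sum(p),
                               evalue = 10^runif(k, -8, 1))
  }
  sw <- dataset_metrics(truth, preds, U, sweep = "tau")$sweep
  expect_equal(sw$threshold, seq(0.1, 0.7, by = 0.1))
  ev <- dataset_metrics(truth, preds, U, sweep = "evalue")$sweep
  # loosening the E-value cutoff never shrinks prediction sets:
  # FP rate and sensitivity are non-increasing as the cutoff tightens
  ord <- order(ev$threshold, decreasing = TRUE)
  expect_true(all(diff(ev$sensitivity[ord]) <= 1e-12))
  expect_true(all(diff(ev$fp_rate[ord]) <= 1e-12))
})

test_that("abundance distance is per-family absolute difference", {
  d <- abundance_distance(c(F1 = 10), c(F1 = 7))
  expect_equal(d$per_family$distance, 3)
  expect_equal(d$mean_distance, 3)
  ident <- abundance_distance(c(A = 5, B = 2), c(A = 5, B = 2))
  expect_true(all(ident$per_family$distance == 0))
  # family absent from predictions counts as 0
  d2 <- abundance_distance(c(A = 1), c(A = 1, B = 5))
  expect_equal(d2$per_family$distance[d2$per_family$family_id == "B"], 5)
})

test_that("abundance distance behaves as a metric per family", {
  set.seed(104)
  for (rep in 1:20) {
    fams <- sprintf("F%d", 1:6)
    x <- setNames(rpois(6, 20), fams)
    y <- setNames(rpois(6, 20), fams)
    z <- setNames(rpois(6, 20), fams)
    dxy <- abundance_distance(x, y)$per_family$distance
    dyx <- abundance_distance(y, x)$per_family$distance
    dxz <- abundance_distance(x, z)$per_family$distance
    dzy <- abundance_distance(z, y)$per_family$distance
    expect_equal(dxy, dyx)                        # symmetry
    expect_true(all(dxy <= dxz + dzy + 1e-12))    # triangle inequality
    expect_true(all(abundance_distance(x, x)$per_family$distance == 0))
  }
})
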