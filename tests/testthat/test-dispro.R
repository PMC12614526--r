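test_that("the drug-event table counts reports exactly once", {
  coh <- cohort_from_reports(
    drugs = list(c("D"), c("D"), character(0), c("X"), c("D")),
    shock = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  t <- build_contingency(coh, "D")
  expect_equal(unlist(t[, .(a, b, c, d)]), c(a = 2, b = 1, c = 1, d = 1))
  expect_equal(t$ntotal, 5)
  expect_equal(t$nexpected, 3 * 3 / 5)

  # permutation of the corpus leaves the table unchanged
  perm <- cohort_from_reports(
    drugs = list(c("D"), c("X"), c("D"), character(0), c("D")),
    shock = c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(as.data.frame(build_contingency(perm, "D")),
               as.data.frame(t), ignore_attr = TRUE)

  # drug present in every report empties the comparator cells
  all_in <- cohort_from_reports(
    drugs = list("D", c("D", "X"), "D"), shock = c(TRUE, FALSE, FALSE))
  t2 <- build_contingency(all_in, "D")
  expect_equal(unlist(t2[, .(c, d)]), c(c = 0, d = 0))

  # absent drug is flagged for downstream exclusion
  t3 <- build_contingency(coh, "NOPE")
  expect_true(attr(t3, "absent"))
  expect_equal(t3$a + t3$b, 0)

  # duplicate mentions of a drug in one report collapse
  dup <- cohort_from_reports(drugs = list(c("D", "D"), "X"),
                             shock = c(TRUE, FALSE))
  expect_equal(build_contingency(dup, "D")$a, 1)
})

test_that("all four statistics reproduce independently computed reference values", {
  t <- contingency(10, 90, 100, 9900)
  r <- ror_stats(t)
  expect_equal(r$ror, 11)
  expect_equal(r$ror_l95, 5.5595147, tolerance = 1e-6)
  expect_equal(r$ror_u95, 21.7644911, tolerance = 1e-6)

  p <- prr_stats(t)
  expect_equal(p$prr, 10)
  expect_equal(p$chi2, 74.4471685, tolerance = 1e-6)
  expect_equal(p$prr_l95, 5.3821543, tolerance = 1e-6)

  ic <- bcpnn_stats(t)
  expect_equal(t$nexpected, 1.0891089, tolerance = 1e-6)
  expect_equal(ic$ic, 2.7240994, tolerance = 1e-6)
  expect_equal(ic$ic025, 1.6469155, tolerance = 1e-6)
  expect_equal(ic$ic975, 3.4500600, tolerance = 1e-6)

  e <- ebgm_stats(t)
  expect_equal(e$ebgm, 9.1818182, tolerance = 1e-6)
  expect_equal(e$ebgm05, 5.1784708, tolerance = 1e-6)
})

test_that("balanced tables are exactly null for every method", {
  for (k in c(1, 5, 100)) {
    t <- contingency(k, k, k, k)
    expect_equal(ror_stats(t)$ror, 1)
    expect_equal(prr_stats(t)$prr, 1)
    expect_equal(prr_stats(t)$chi2, 0)
    expect_equal(ebgm_stats(t)$ebgm, 1)
    ic <- bcpnn_stats(t)
    expect_equal(ic$ic, 0)
    expect_lt(ic$ic025, 0)
    expect_gt(ic$ic975, 0)
  }
})

test_that("transposing exposure reciprocates the odds ratio", {
  set.seed(1)
  for (i in 1:50) {
    cells <- sample(1:500, 4, replace = TRUE)
    direct <- ror_stats(contingency(cells[1], cells[2], cells[3], cells[4]))$ror
    swapped <- ror_stats(contingency(cells[3], cells[4], cells[1], cells[2]))$ror
    expect_equal(direct * swapped, 1, tolerance = 1e-12)
  }
})

test_that("the geometric-mean statistic equals observed over expected", {
  set.seed(2)
  for (i in 1:50) {
    t <- contingency(sample(1:900, 1), sample(1:900, 1),
                     sample(1:900, 1), sample(1:900, 1))
    expect_equal(ebgm_stats(t)$ebgm, t$nobserved / t$nexpected,
                 tolerance = 1e-12)
  }
})

test_that("statistics increase with the target count in the sparse regime", {
  # with the background dominant (d >> a+b+c) and the target count not
  # exceeding either off-diagonal cell, adding target co-reports cannot
  # lower any of the four statistics (shrinkage measures lose monotonicity
  # outside this regime because the expected count grows with a too)
  set.seed(3)
  for (i in 1:20) {
    b <- sample(20:60, 1); c <- sample(20:60, 1); d <- 1e5
    a_grid <- 1:min(b, c)
    t <- contingency(a_grid, b, c, d)
    expect_false(is.unsorted(ror_stats(t)$ror))
    expect_false(is.unsorted(prr_stats(t)$prr))
    expect_false(is.unsorted(bcpnn_stats(t)$ic))
    expect_false(is.unsorted(ebgm_stats(t)$ebgm))
  }
})

test_that("interval bounds bracket their point estimates", {
  set.seed(4)
  cells <- matrix(sample(1:10000, 400, replace = TRUE), ncol = 4)
  t <- contingency(cells[, 1], cells[, 2], cells[, 3], cells[, 4])
  r <- cbind(ror_stats(t), prr_stats(t), bcpnn_stats(t), ebgm_stats(t))
  expect_true(all(r$ror_l95 <= r$ror & r$ror <= r$ror_u95))
  expect_true(all(r$prr_l95 <= r$prr & r$prr <= r$prr_u95))
  expect_true(all(r$ic025 < r$ic & r$ic < r$ic975))
  expect_true(all(r$ebgm05 <= r$ebgm))
})

test_that("zero cells yield explicit undefined results, never flags", {
  t <- contingency(0, 10, 5, 100)
  expect_true(is.na(ror_stats(t)$ror))
  expect_equal(ror_stats(t)$ror_note, "zero cell")
  s <- classify_signals(cbind(data.table(a = 0), ror_stats(t), prr_stats(t),
                              bcpnn_stats(t), ebgm_stats(t)))
  expect_equal(s$n_positive, 0L)
  expect_equal(s$tier, "none")
})

test_that("signal criteria apply their thresholds and the minimum-count rule", {
  # a = 2 with an enormous odds ratio still cannot flag
  t <- contingency(2, 1, 1, 10000)
  s <- classify_signals(cbind(t[, .(a)], ror_stats(t), prr_stats(t),
                              bcpnn_stats(t), ebgm_stats(t)), min_a = 3)
  expect_gt(s$ror, 100)
  expect_equal(s$n_positive, 0L)

  # boundary: lower bound at 0.99 is not a signal however large the point
  s2 <- classify_signals(data.table(
    a = 50, ror = 1.5, ror_l95 = 0.99, prr = 1.5, chi2 = 2,
    ic025 = -0.1, ebgm05 = 1))
  expect_false(s2$ror_pos)
  expect_equal(s2$tier, "none")

  # tier labels by number of positive methods
  s3 <- classify_signals(data.table(
    a = c(50, 50, 50, 50),
    ror = c(5, 5, 5, 0.5), ror_l95 = c(2, 2, 2, 0.2),
    prr = c(5, 5, 1, 1), chi2 = c(50, 50, 1, 1),
    ic025 = c(1, 1, 1, -1), ebgm05 = c(3, 1, 1, 1)))
  expect_equal(s3$tier, c("four_method", "three_method", "weak", "none"))
  expect_equal(s3$n_positive, c(4L, 3L, 2L, 0L))
})

test_that("the drug screen orders by case count with alphabetical ties", {
  coh <- cohort_from_reports(
    drugs = c(rep(list(c("ZETA")), 6), rep(list(c("ALPHA")), 6),
              rep(list(c("MID")), 8), rep(list("BG"), 30)),
    shock = c(rep(TRUE, 4), rep(FALSE, 2),    # ZETA: a=4
              rep(TRUE, 4), rep(FALSE, 2),    # ALPHA: a=4
              rep(TRUE, 6), rep(FALSE, 2),    # MID: a=6
              rep(FALSE, 30)))
  sig <- screen_signals(coh, min_a = 3)
  expect_equal(sig$drug[1:3], c("MID", "ALPHA", "ZETA"))
  expect_equal(sig$a[1:3], c(6, 4, 4))
  # drugs under the minimum count are excluded but still counted as tests
  expect_false("BG" %in% sig$drug)
  expect_equal(attr(sig, "n_tests"), 4L)
  # cells add up to the corpus size for every row
  expect_true(all(rowSums(sig[, .(a, b, c, d)]) == nrow(coh$cases)))
})

test_that("screening an empty cohort yields an empty result", {
  empty <- cohort_from_reports(list(), logical(0))
  expect_equal(nrow(screen_signals(empty)), 0L)
})
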