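test_that("PPA with exact intervals reproduces published-style table rows", {
  r <- ppa(31, 38)
  expect_equal(round(r$percent, 1), 81.6)
  expect_equal(round(r$lower_pct, 1), 65.7)
  expect_equal(round(r$upper_pct, 1), 92.3)

  # 3/3 bin: lower bound has the closed form 100 * 0.025^(1/3)
  r33 <- ppa(3, 3)
  expect_equal(r33$percent, 100)
  expect_equal(r33$upper_pct, 100)
  expect_equal(r33$lower_pct, 100 * 0.025^(1 / 3), tolerance = 1e-10)
  expect_equal(round(r33$lower_pct, 1), 29.2)

  # 0/10: upper bound closed form 100 * (1 - 0.025^(1/10))
  r0 <- ppa(0, 10)
  expect_equal(r0$lower_pct, 0)
  expect_equal(r0$upper_pct, 100 * (1 - 0.025^(1 / 10)), tolerance = 1e-10)
  expect_equal(round(r0$upper_pct, 1), 30.8)

  expect_error(ppa(1, 0), "n")
  expect_error(ppa(5, 3), "x")
})

test_that("exact intervals agree with binom.test across a grid", {
  for (n in c(3, 10, 38, 76)) for (x in unique(c(0, 1, n %/% 2, n))) {
    ours <- ppa(x, n)
    oracle <- 100 * binom.test(x, n)$conf.int
    expect_equal(c(ours$lower_pct, ours$upper_pct), as.numeric(oracle),
                 tolerance = 1e-10)
  }
})

test_that("exact interval coverage reaches the nominal level in simulation", {
  set.seed(1)
  xs <- rbinom(2000, 38, 0.8)
  cover <- vapply(xs, function(x) {
    r <- ppa(x, 38)
    r$lower_pct <= 80 && 80 <= r$upper_pct
  }, logical(1))
  expect_gte(mean(cover), 0.95)
})

test_that("diagnostic odds ratio matches the published value and hand corrections", {
  d <- diagnostic_odds_ratio(list(a = 31, b = 7, c = 6, d = 32))
  expect_equal(d$dor, 992 / 42, tolerance = 1e-12)
  expect_equal(round(d$dor, 1), 23.6)
  expect_equal(round(d$lower, 1), 7.1)
  expect_equal(round(d$upper, 1), 78.2)

  expect_equal(diagnostic_odds_ratio(list(a = 5, b = 5, c = 5, d = 5))$dor, 1)

  corr <- diagnostic_odds_ratio(list(a = 5, b = 0, c = 1, d = 5))
  expect_true(corr$corrected)
  expect_equal(corr$dor, (5.5 * 5.5) / (0.5 * 1.5), tolerance = 1e-12)

  expect_error(diagnostic_odds_ratio(list(a = 0, b = 0, c = 0, d = 0)),
               "all-zero")
})

test_that("DOR is invariant to double swaps and inverted by row swaps", {
  t0 <- list(a = 31, b = 7, c = 6, d = 32)
  both <- list(a = 32, b = 6, c = 7, d = 31)   # rows and columns swapped
  rows <- list(a = 6, b = 32, c = 31, d = 7)   # rows swapped only
  expect_equal(diagnostic_odds_ratio(both)$dor,
               diagnostic_odds_ratio(t0)$dor)
  expect_equal(diagnostic_odds_ratio(rows)$dor,
               1 / diagnostic_odds_ratio(t0)$dor)
})

test_that("Fisher exact p values match enumeration over fixed margins", {
  expect_equal(round(fisher_exact_2x2(matrix(c(31, 7, 32, 6), 2,
                                             byrow = TRUE)), 3), 1.000)
  expect_equal(fisher_exact_2x2(matrix(c(4, 6, 4, 6), 2)), 1)

  # enumeration oracle: sum of hypergeometric masses <= observed mass
  fisher_enum <- function(m) {
    r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
    as <- max(0, c1 - (n - r1)):min(r1, c1)
    mass <- dhyper(as, r1, n - r1, c1)
    obs <- dhyper(m[1, 1], r1, n - r1, c1)
    sum(mass[mass <= obs + 1e-12])
  }
  m55 <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(fisher_enum(m55), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(m55), 2 / 252, tolerance = 1e-9)
  set.seed(6)
  for (i in 1:10) {
    m <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_2x2(m), fisher_enum(m), tolerance = 1e-9)
  }
})

test_that("AUC equals the Mann-Whitney pair-counting statistic", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(F, F, F, T, T, T))$auc, 1)
  expect_equal(roc_auc(rep(5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)

  set.seed(3)
  s <- round(rnorm(20), 1)  # rounding forces some ties
  lab <- rep(c(TRUE, FALSE), each = 10)
  brute <- mean(outer(s[lab], s[!lab],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(roc_auc(s, lab)$auc, brute, tolerance = 1e-12)

  # antisymmetry under score negation
  expect_equal(roc_auc(-s, lab)$auc, 1 - roc_auc(s, lab)$auc)

  skip_if_not_installed("pROC")
  expect_equal(roc_auc(s, lab)$auc,
               as.numeric(pROC::auc(pROC::roc(lab, s, quiet = TRUE))))
  expect_error(roc_auc(s, rep(TRUE, 20)), "both classes")
})

test_that("stratified PPA reproduces a necrosis-style attribute table", {
  # bins with 39, 19, 15, 3 specimens and 32, 16, 12, 3 agreements
  ns <- c(39, 19, 15, 3); xs <- c(32, 16, 12, 3)
  lo <- c(0, 10, 20, 30)
  records <- data.frame(necrosis_pct = unlist(mapply(
    function(n, l) l + seq(0.5, 9.5, length.out = n), ns, lo)))
  correct <- unlist(mapply(function(n, x) c(rep(TRUE, x),
                                            rep(FALSE, n - x)), ns, xs))
  tab <- stratified_ppa(correct, records, "necrosis_pct",
                        breaks = c(0, 10, 20, 30, 40))
  expect_equal(tab$n, ns)
  expect_equal(round(tab$percent, 1), c(82.1, 84.2, 80.0, 100))

  # a single all-covering bin equals the overall PPA
  one <- stratified_ppa(correct, records, "necrosis_pct",
                        breaks = c(0, 40))
  expect_equal(one$percent, ppa(sum(xs), sum(ns))$percent)

  expect_error(stratified_ppa(correct, records, "necrosis_pct",
                              breaks = c(0, 20)), "outside all bins")
})

test_that("metastatic-style subgroup row reproduces its exact interval", {
  r <- ppa(21, 26)
  expect_equal(round(c(r$percent, r$lower_pct, r$upper_pct), 1),
               c(80.8, 60.6, 93.4))
})

test_that("performance_summary assembles consistent tables from calls", {
  calls <- c(rep("HNSCC", 31), rep("LUNG_SCC", 7),
             rep("LUNG_SCC", 32), rep("HNSCC", 6))
  truth <- rep(c("HNSCC", "LUNG_SCC"), each = 38)
  reports <- data.frame(specimen_id = seq_along(calls),
                        ss_hnscc = ifelse(calls == "HNSCC", 90, 10),
                        ss_lung = ifelse(calls == "HNSCC", 10, 90),
                        call = calls, stringsAsFactors = FALSE)
  perf <- performance_summary(reports, truth)
  expect_equal(perf$agreement$a, 31)
  expect_equal(perf$agreement$d, 32)
  expect_equal(round(perf$table$percent, 1), c(81.6, 84.2, 82.9))
  expect_equal(round(perf$dor$dor, 1), 23.6)
  expect_equal(round(perf$fisher_p, 3), 1.000)
})
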