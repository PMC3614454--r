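test_that("training rejects degenerate inputs", {
  s <- small_standardized()
  lab <- s$cohort$metadata$class_label
  expect_error(train_nested_cv(s$std, rep("HNSCC", length(lab))),
               "both classes")
  few <- c(1:3, 31:33)  # three specimens per class
  expect_error(train_nested_cv(s$std[, few], lab[few],
                               cv_spec(outer_folds = 5)), "too few")
  expect_error(train_nested_cv(s$std, rep("squamous", length(lab))),
               "labels")
})

test_that("training is deterministic given data and seed", {
  s <- small_standardized()
  lab <- s$cohort$metadata$class_label
  m1 <- train_nested_cv(s$std, lab, cv_spec(n_features = 25), seed = 4)
  m2 <- train_nested_cv(s$std, lab, cv_spec(n_features = 25), seed = 4)
  expect_identical(m1$probes, m2$probes)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$cv$outer_accuracy, m2$cv$outer_accuracy)
})

test_that("planted markers drive near-perfect outer-fold accuracy and recovery", {
  s <- small_standardized()
  m <- small_model()
  expect_gte(m$cv$outer_accuracy, 0.95)
  rk <- rank_markers(m, s$std, s$cohort$metadata$class_label, top = 20)
  expect_equal(rk$rank, 1:20)
  expect_true(all(diff(rk$importance) <= 1e-12))
  truth <- setNames(s$cohort$truth$role, s$cohort$truth$probe_id)
  hits <- sum(truth[rk$probe_id] != "null" &
              rk$direction == truth[rk$probe_id])
  expect_gte(hits, 18)
})

test_that("pure-noise data yields chance-level outer accuracy (no leakage)", {
  co <- generate_cohort(generator_config(
    n_probes = 300, n_specimens_per_class = 100, marker_effect = 0,
    qc_failure_rate = 0, seed = 2))
  std <- standardize_matrix(co$expression, fit_reference(co$expression))
  m <- train_nested_cv(std, co$metadata$class_label,
                       cv_spec(n_features = c(25, 50, 100)), seed = 2)
  expect_gte(m$cv$outer_accuracy, 0.4)
  expect_lte(m$cv$outer_accuracy, 0.6)
})

test_that("similarity scores sum to 100 and the call follows the higher score", {
  s <- small_standardized()
  reports <- score_matrix(small_model(), s$std)
  expect_true(all(abs(reports$ss_hnscc + reports$ss_lung - 100) < 0.05))
  expect_true(all(reports$ss_hnscc >= 0 & reports$ss_hnscc <= 100))
  decided <- reports$call != "indeterminate"
  expect_true(all(ifelse(reports$call[decided] == "HNSCC",
                         reports$ss_hnscc > reports$ss_lung,
                         reports$ss_lung > reports$ss_hnscc)[decided]))
})

test_that("strongly planted specimens score above 90 for their class", {
  s <- small_standardized()
  m <- small_model()
  lab <- s$cohort$metadata$class_label
  lung1 <- s$std[, which(lab == "LUNG_SCC")[1]]
  hn1 <- s$std[, which(lab == "HNSCC")[1]]
  expect_gt(score_specimen(m, lung1)$ss_lung, 90)
  expect_gt(score_specimen(m, hn1)$ss_hnscc, 90)
})

test_that("raising a lung-up marker never decreases the lung score", {
  s <- small_standardized()
  m <- small_model()
  truth <- setNames(s$cohort$truth$role, s$cohort$truth$probe_id)
  lungup <- intersect(m$probes[truth[m$probes] == "lung-up" &
                               m$coefficients < 0], m$probes)
  skip_if(length(lungup) == 0)
  probe <- lungup[1]
  x <- s$std[, 1]
  prev <- -Inf
  for (delta in c(0, 0.5, 1, 2, 4)) {
    x2 <- x; x2[probe] <- x2[probe] + delta
    ss <- score_specimen(m, x2)$ss_lung
    expect_gte(ss, prev - 1e-9)
    prev <- ss
  }
})

test_that("score_specimen reports missing selected probes by name", {
  s <- small_standardized()
  m <- small_model()
  x <- s$std[, 1]
  drop <- m$probes[1:2]
  expect_error(score_specimen(m, x[setdiff(names(x), drop)]),
               paste(drop, collapse = ", "), fixed = TRUE)
})

test_that("marker direction labels flip when class labels are swapped", {
  s <- small_standardized()
  m <- small_model()
  lab <- s$cohort$metadata$class_label
  swapped <- ifelse(lab == "HNSCC", "LUNG_SCC", "HNSCC")
  rk <- rank_markers(m, s$std, lab)
  rk_sw <- rank_markers(m, s$std, swapped)
  expect_identical(rk$probe_id, rk_sw$probe_id)
  expect_true(all(rk$direction != rk_sw$direction))
})

test_that("reports render both scores to one decimal and name the likelier tissue", {
  hn <- render_report(make_report(71.1))
  expect_true(any(grepl("71.1", hn, fixed = TRUE)))
  expect_true(any(grepl("28.9", hn, fixed = TRUE)))
  expect_true(any(grepl("Head & neck", hn)))

  tie <- render_report(make_report(50))
  expect_true(any(grepl("indeterminate", tie)))

  lung <- render_report(make_report(0))
  expect_true(any(grepl("Similarity Score, lung SCC: 100.0", lung,
                        fixed = TRUE)))
  expect_true(any(grepl("Lung squamous", lung)))
})

test_that("a trained model survives its text round trip with identical scores", {
  s <- small_standardized()
  m <- small_model()
  prefix <- file.path(withr::local_tempdir(), "mdl")
  write_model(m, prefix)
  back <- read_model(prefix)
  orig <- score_matrix(m, s$std)
  again <- score_matrix(back, s$std)
  expect_equal(again$ss_hnscc, orig$ss_hnscc, tolerance = 1e-10)
  expect_identical(again$call, orig$call)
})
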