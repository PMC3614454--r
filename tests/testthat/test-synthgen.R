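test_that("invalid generator configurations name the offending field", {
  expect_error(generator_config(qc_failure_rate = 1.5), "qc_failure_rate")
  expect_error(generator_config(site_effect_sd = -1), "site_effect_sd")
  expect_error(generator_config(n_probes = 10, n_markers_lung = 8,
                                n_markers_hn = 8), "n_probes")
  expect_error(generator_config(n_specimens_per_class = 0),
               "n_specimens_per_class")
})

test_that("zero-effect, zero-noise configuration collapses to identical specimens", {
  co <- generate_cohort(generator_config(
    n_probes = 50, n_specimens_per_class = 4, marker_effect = 0,
    site_effect_sd = 0, ffpe_noise_sd = 0, specimen_baseline_sd = 0,
    qc_failure_rate = 0, seed = 1))
  expect_true(all(co$expression == co$expression[, 1]))
  expect_true(all(co$expression > 0))
})

test_that("cohorts are deterministic given config and seed", {
  cfg <- generator_config(n_probes = 120, n_specimens_per_class = 8,
                          seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
})

test_that("cohort structure is internally consistent", {
  co <- default_cohort()
  expect_identical(colnames(co$expression), co$metadata$specimen_id)
  expect_identical(rownames(co$expression), co$truth$probe_id)
  expect_true(all(co$expression > 0))
  expect_equal(sum(co$truth$role == "lung-up"), 12)
  expect_equal(sum(co$truth$role == "hn-up"), 8)
  expect_true(all(co$metadata$tumor_content_pct >= 60))
})

test_that("planted QC failures hit exactly round(rate * n) specimens", {
  co <- default_cohort()  # 80 specimens at 5%
  expect_equal(sum(co$metadata$qc_planted), 4)
  expect_setequal(unique(co$metadata$qc_artifact),
                  c("none", "dark_signal", "dark_block"))
})

test_that("planted markers separate with the planted sign at n = 100 per class", {
  co <- generate_cohort(generator_config(n_specimens_per_class = 100,
                                         qc_failure_rate = 0, seed = 1))
  lg <- log2(co$expression)
  lung <- co$metadata$class_label == "LUNG_SCC"
  mk <- co$truth$role != "null"
  d <- rowMeans(lg[mk, lung]) - rowMeans(lg[mk, !lung])
  ok <- ifelse(co$truth$role[mk] == "lung-up", d > 0, d < 0)
  expect_gte(mean(ok), 0.99)
})

test_that("null probes give approximately standard-normal t statistics", {
  co <- generate_cohort(generator_config(n_specimens_per_class = 100,
                                         qc_failure_rate = 0, seed = 1))
  y <- co$metadata$class_label == "HNSCC"
  lg <- log2(co$expression)
  nul <- co$truth$role == "null"
  tt <- apply(lg[nul, ], 1, function(v)
    stats::t.test(v[y], v[!y])$statistic)
  expect_gte(mean(abs(tt) > 1.96), 0.03)
  expect_lte(mean(abs(tt) > 1.96), 0.07)
})

test_that("replicate sections share signal and differ only by within-block noise", {
  co <- generate_cohort(generator_config(n_probes = 80,
                                         n_specimens_per_class = 8,
                                         qc_failure_rate = 0, seed = 5))
  expect_error(generate_replicate_sections(co, 1, 0.1), "n_sections")

  exact <- generate_replicate_sections(co, 3, 0, seed = 5)
  expect_equal(ncol(exact$expression), 48)
  expect_equal(length(unique(exact$metadata$block_id)), 16)
  for (bl in unique(exact$metadata$block_id)) {
    cols <- exact$expression[, exact$metadata$block_id == bl, drop = FALSE]
    expect_equal(max(abs(cols - cols[, 1])), 0)
  }

  noisy <- generate_replicate_sections(co, 3, 0.2, seed = 5)
  expect_false(any(noisy$expression[, 1] == noisy$expression[, 2]))
  # sections of a block stay far closer than unrelated specimens
  d_within <- mean(abs(log2(noisy$expression[, 1]) -
                       log2(noisy$expression[, 2])))
  d_between <- mean(abs(log2(noisy$expression[, 1]) -
                        log2(noisy$expression[, 4])))
  expect_lt(d_within, d_between)
})

test_that("cohort artifacts survive a text round trip", {
  co <- generate_cohort(generator_config(n_probes = 30,
                                         n_specimens_per_class = 3,
                                         qc_failure_rate = 0, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(back, co$expression, tolerance = 1e-12)
  md <- read.csv(file.path(dir, "metadata.csv"))
  expect_equal(md$specimen_id, co$metadata$specimen_id)
})
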