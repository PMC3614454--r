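# Shared fixtures, generated in code and memoized so expensive objects
# are built once per test run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# default-condition cohort: 80 specimens, 2000 probes, 5% planted QC failures
default_cohort <- function() memo("default_cohort",
  generate_cohort(generator_config(seed = 3)))

# small clean planted cohort + frozen reference + standardized matrix
small_standardized <- function() memo("small_std", {
  co <- generate_cohort(generator_config(
    n_probes = 300, n_markers_lung = 12, n_markers_hn = 8,
    n_specimens_per_class = 30, qc_failure_rate = 0, seed = 7))
  ref <- fit_reference(co$expression)
  list(cohort = co,
       ref = ref,
       std = standardize_matrix(co$expression, ref))
})

# nested-CV model trained on the small planted cohort
small_model <- function() memo("small_model", {
  s <- small_standardized()
  train_nested_cv(s$std, s$cohort$metadata$class_label,
                  cv_spec(n_features = c(25, 50)), seed = 7)
})

make_report <- function(ss_hnscc, specimen_id = NA_character_) {
  r_hn <- squamdx:::round_half_up(ss_hnscc, 1)
  r_lu <- squamdx:::round_half_up(100 - ss_hnscc, 1)
  call <- if (r_hn > r_lu) "HNSCC" else if (r_lu > r_hn) "LUNG_SCC"
          else "indeterminate"
  structure(list(specimen_id = specimen_id, ss_hnscc = ss_hnscc,
                 ss_lung = 100 - ss_hnscc, call = call),
            class = "similarity_report")
}
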