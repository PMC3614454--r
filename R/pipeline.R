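#' Default pipeline configuration
#'
#' Nested list with a `paths` block (all artifact locations under
#' `output_dir`), a `generator` block ([generator_config()] arguments),
#' a `classifier` block ([cv_spec()] arguments), a `design` block
#' ([design_spec()] arguments plus `true_ppa` and `n_reps` for the
#' operating-characteristics command), a `reproducibility` block
#' (`n_sections`, `within_block_sd`), and a master `seed`.
#'
#' @param output_dir directory receiving all artifacts.
#' @param seed master seed.
#' @return Configuration list.
#' @export
default_config <- function(output_dir = "squamdx_out", seed = 1) {
  list(
    paths = list(output_dir = output_dir),
    generator = list(),
    classifier = list(),
    design = list(true_ppa = 0.95, n_reps = 2000),
    reproducibility = list(n_sections = 3, within_block_sd = 0.15),
    seed = as.integer(seed),
    verbose = FALSE
  )
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config))
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("malformed config", call. = FALSE)
  base <- default_config()
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- utils::modifyList(base[[nm]], config[[nm]])
    else base[[nm]] <- config[[nm]]
  }
  base
}

artifact_header <- function(config, stage) {
  # hash only the scientific parameters, not artifact locations, so the
  # same analysis rerun elsewhere stamps identically
  hashed <- config[setdiff(names(config), c("paths", "verbose"))]
  sprintf("# squamdx %s | stage=%s | seed=%d | config_md5=%s",
          as.character(utils::packageVersion("squamdx")), stage,
          config$seed, config_hash(hashed))
}

write_artifact <- function(df, path, config, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(artifact_header(config, stage), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_artifact <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

pipe_path <- function(config, name) file.path(config$paths$output_dir, name)

pipe_log <- function(config, ...) if (isTRUE(config$verbose)) message(...)

#' Run one stage of the analysis pipeline
#'
#' Orchestrates the package's stages over plain-text artifacts in the
#' configured output directory. Subcommands:
#' \describe{
#'   \item{simulate}{generate a synthetic cohort; writes
#'     `expression.tsv`, `metadata.csv`, `truth.csv`.}
#'   \item{qc}{entry + array QC for every specimen; writes
#'     `qc_results.csv`.}
#'   \item{standardize}{fit the frozen reference on QC-passing specimens
#'     and standardize them; writes `reference.tsv`,
#'     `standardized.tsv`.}
#'   \item{train}{nested-CV training on standardized QC-passing
#'     specimens; writes the coefficients/JSON model pair.}
#'   \item{score}{similarity reports for all standardized specimens;
#'     writes `reports.csv`.}
#'   \item{validate}{performance tables (per-class/overall PPA with
#'     exact CIs, Fisher comparison, DOR, AUC, attribute-stratified
#'     PPA); refuses specimens that failed QC; writes
#'     `performance.csv`, `performance_by_attribute.csv`,
#'     `performance_stats.json`.}
#'   \item{design-oc}{operating characteristics of the adaptive design;
#'     writes `design_oc.csv`.}
#'   \item{reproduce}{replicate-section reproducibility study
#'     (concordance, kappa, %CV); writes `reproducibility.csv`.}
#' }
#' Every artifact carries a header line with the package version, stage,
#' seed and config hash, so reruns with the same seed are bit-identical
#' apart from nothing (no timestamps are written).
#'
#' @param subcommand one of the stage names above.
#' @param config configuration list, or path to a YAML/JSON file;
#'   merged over [default_config()].
#' @param seed optional master-seed override.
#' @return Invisibly, a named vector of artifact paths written.
#' @export
run_pipeline <- function(subcommand = c("simulate", "qc", "standardize",
                                        "train", "score", "validate",
                                        "design-oc", "reproduce"),
                         config = default_config(), seed = NULL) {
  subcommand <- match.arg(subcommand)
  config <- read_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(config$paths$output_dir, recursive = TRUE,
             showWarnings = FALSE)
  stage_fun <- switch(subcommand,
    "simulate" = stage_simulate, "qc" = stage_qc,
    "standardize" = stage_standardize, "train" = stage_train,
    "score" = stage_score, "validate" = stage_validate,
    "design-oc" = stage_design_oc, "reproduce" = stage_reproduce)
  tryCatch(stage_fun(config),
           error = function(e) stop("stage '", subcommand, "': ",
                                    conditionMessage(e), call. = FALSE))
}

load_cohort_artifacts <- function(config) {
  list(expression = read_expression(pipe_path(config, "expression.tsv")),
       metadata = utils::read.csv(pipe_path(config, "metadata.csv"),
                                  stringsAsFactors = FALSE))
}

stage_simulate <- function(config) {
  gen <- do.call(generator_config,
                 utils::modifyList(config$generator,
                                   list(seed = config$seed)))
  cohort <- generate_cohort(gen)
  paths <- write_cohort(cohort, config$paths$output_dir)
  pipe_log(config, "simulate: ", ncol(cohort$expression), " specimens, ",
           nrow(cohort$expression), " probes")
  invisible(paths)
}

stage_qc <- function(config) {
  cohort <- load_cohort_artifacts(config)
  qc <- qc_cohort(cohort, verbose = isTRUE(config$verbose))
  path <- pipe_path(config, "qc_results.csv")
  write_artifact(qc, path, config, "qc")
  pipe_log(config, sprintf("qc: %d/%d specimens passed all criteria (%.1f%%)",
                           sum(qc$qc_pass), nrow(qc),
                           100 * mean(qc$qc_pass)))
  invisible(c(qc_results = path))
}

passing_specimens <- function(config) {
  qc <- read_artifact(pipe_path(config, "qc_results.csv"))
  qc$specimen_id[qc$qc_pass]
}

stage_standardize <- function(config) {
  cohort <- load_cohort_artifacts(config)
  keep <- intersect(colnames(cohort$expression), passing_specimens(config))
  if (length(keep) < 2)
    stop("fewer than 2 QC-passing specimens to standardize")
  expr <- cohort$expression[, keep, drop = FALSE]
  ref <- fit_reference(expr)
  std <- standardize_matrix(expr, ref)
  ref_path <- pipe_path(config, "reference.tsv")
  std_path <- pipe_path(config, "standardized.tsv")
  write_reference(ref, ref_path)
  write_expression(std, std_path)
  pipe_log(config, "standardize: ", length(keep), " specimens")
  invisible(c(reference = ref_path, standardized = std_path))
}

stage_train <- function(config) {
  std <- read_expression(pipe_path(config, "standardized.tsv"))
  md <- utils::read.csv(pipe_path(config, "metadata.csv"),
                        stringsAsFactors = FALSE)
  labels <- md$class_label[match(colnames(std), md$specimen_id)]
  spec <- do.call(cv_spec, config$classifier)
  model <- train_nested_cv(std, labels, spec, seed = config$seed)
  paths <- write_model(model, pipe_path(config, "classifier"))
  pipe_log(config, sprintf("train: outer-CV accuracy %.3f over %d probes",
                           model$cv$outer_accuracy, length(model$probes)))
  invisible(paths)
}

stage_score <- function(config) {
  std <- read_expression(pipe_path(config, "standardized.tsv"))
  model <- read_model(pipe_path(config, "classifier"))
  reports <- score_matrix(model, std)
  path <- pipe_path(config, "reports.csv")
  write_artifact(reports, path, config, "score")
  invisible(c(reports = path))
}

stage_validate <- function(config) {
  reports <- read_artifact(pipe_path(config, "reports.csv"))
  md <- utils::read.csv(pipe_path(config, "metadata.csv"),
                        stringsAsFactors = FALSE)
  keep <- intersect(reports$specimen_id, passing_specimens(config))
  if (length(keep) == 0)
    stop("no QC-passing specimens available for validation")
  reports <- reports[match(keep, reports$specimen_id), ]
  md <- md[match(keep, md$specimen_id), ]
  perf <- performance_summary(reports, md$class_label)
  correct <- reports$call == md$class_label
  strata <- rbind(
    cbind(attribute = "necrosis_pct",
          stratified_ppa(correct, md, "necrosis_pct",
                         breaks = c(0, 10, 20, 30, 40))),
    cbind(attribute = "tumor_content_pct",
          stratified_ppa(correct, md, "tumor_content_pct",
                         breaks = c(60, 70, 80, 90, 100), right = TRUE)),
    cbind(attribute = "grade", stratified_ppa(correct, md, "grade")))
  p1 <- pipe_path(config, "performance.csv")
  p2 <- pipe_path(config, "performance_by_attribute.csv")
  p3 <- pipe_path(config, "performance_stats.json")
  write_artifact(perf$table, p1, config, "validate")
  write_artifact(strata, p2, config, "validate")
  writeLines(jsonlite::toJSON(list(
    fisher_p = perf$fisher_p, dor = perf$dor, auc = perf$auc,
    agreement = unclass(perf$agreement), seed = config$seed),
    auto_unbox = TRUE, digits = NA), p3)
  pipe_log(config, sprintf("validate: overall agreement %.1f%%, AUC %.3f",
                           perf$table$percent[3], perf$auc))
  invisible(c(performance = p1, by_attribute = p2, stats = p3))
}

stage_design_oc <- function(config) {
  dn <- config$design
  spec_args <- dn[setdiff(names(dn), c("true_ppa", "n_reps"))]
  design <- do.call(design_spec,
                    utils::modifyList(spec_args, list(seed = config$seed)))
  oc <- simulate_operating_characteristics(design, dn$true_ppa,
                                           dn$n_reps, seed = config$seed)
  df <- data.frame(true_ppa = paste(rep_len(dn$true_ppa, 2),
                                    collapse = "/"),
                   acceptance_rate = oc$acceptance_rate,
                   futility_rate = oc$futility_rate,
                   fail_rate = oc$fail_rate,
                   expected_n_per_class = oc$expected_n_per_class,
                   n_reps = oc$n_reps)
  path <- pipe_path(config, "design_oc.csv")
  write_artifact(df, path, config, "design-oc")
  invisible(c(design_oc = path))
}

stage_reproduce <- function(config) {
  cohort <- load_cohort_artifacts(config)
  keep <- intersect(colnames(cohort$expression), passing_specimens(config))
  expr <- cohort$expression[, keep, drop = FALSE]
  md <- cohort$metadata[match(keep, cohort$metadata$specimen_id), ]
  base <- structure(list(expression = expr, metadata = md,
                         truth = NULL,
                         config = do.call(generator_config,
                                          utils::modifyList(
                                            config$generator,
                                            list(seed = config$seed)))),
                    class = "syn_cohort")
  rp <- config$reproducibility
  sections <- generate_replicate_sections(base, rp$n_sections,
                                          rp$within_block_sd,
                                          seed = config$seed)
  ref <- read_reference(pipe_path(config, "reference.tsv"))
  std <- standardize_matrix(sections$expression, ref)
  model <- read_model(pipe_path(config, "classifier"))
  reports <- score_matrix(model, std)
  tab <- reproducibility_table(reports, sections$metadata$block_id,
                               paste0("section_",
                                      sections$metadata$section_id))
  # %CV of the similarity score for the known diagnosis
  lbl <- sections$metadata$class_label
  ss_known <- ifelse(lbl == "HNSCC", reports$ss_hnscc, reports$ss_lung)
  cv <- similarity_cv(ss_known, sections$metadata$block_id)
  out <- rbind(tab$pairs,
               data.frame(comparison = "overall",
                          n_pairs = tab$overall$denominator,
                          concordant = tab$overall$numerator,
                          percent = tab$overall$percent,
                          lower_pct = tab$overall$lower_pct,
                          upper_pct = tab$overall$upper_pct,
                          kappa = NA_real_))
  out$median_cv_pct <- cv$median_cv_pct
  path <- pipe_path(config, "reproducibility.csv")
  write_artifact(out, path, config, "reproduce")
  pipe_log(config, sprintf("reproduce: overall concordance %.1f%%, median %%CV %.2f",
                           tab$overall$percent, cv$median_cv_pct))
  invisible(c(reproducibility = path))
}
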