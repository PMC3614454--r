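#' Specimen entry gating
#'
#' Applies the assay's specimen-entry requirements: at least 60% tumor
#' content (intra-tumoral stroma included), a minimum total RNA yield of
#' 30 ng at a concentration of at least 9.5 ng/ul with an A260/A280 ratio
#' of at least 1.0, and at least 2.5 ug of labeled cDNA. All thresholds
#' are inclusive. Each violated rule is reported once.
#'
#' @param record a list or one-row data frame with fields
#'   `tumor_content_pct`, `rna_yield_ng`, `rna_conc_ng_per_ul`,
#'   `a260_a280`, `cdna_yield_ug` (and optionally `specimen_id`).
#' @return A list of class `qc_result` with `entry_pass` and
#'   `failure_reasons`.
#' @examples
#' check_specimen_entry(list(tumor_content_pct = 75, rna_yield_ng = 100,
#'   rna_conc_ng_per_ul = 20, a260_a280 = 1.9, cdna_yield_ug = 5))$entry_pass
#' @export
check_specimen_entry <- function(record) {
  record <- as.list(record)
  needed <- c("tumor_content_pct", "rna_yield_ng", "rna_conc_ng_per_ul",
              "a260_a280", "cdna_yield_ug")
  for (f in needed) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop("missing specimen field: '", f, "'", call. = FALSE)
  }
  rules <- c(
    tumor_content_below_60pct = record$tumor_content_pct < 60,
    rna_yield_below_30ng = record$rna_yield_ng < 30,
    rna_concentration_below_9.5ng_per_ul = record$rna_conc_ng_per_ul < 9.5,
    a260_a280_below_1.0 = record$a260_a280 < 1.0,
    cdna_yield_below_2.5ug = record$cdna_yield_ug < 2.5
  )
  structure(list(
    specimen_id = record$specimen_id %||% NA_character_,
    entry_pass = !any(rules),
    failure_reasons = names(rules)[rules]
  ), class = "qc_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Microarray data-quality metrics
#'
#' Computes the three array quality metrics and applies the gating
#' thresholds: Overall Signal >= 10, Percent Present >= 5, Regional
#' Discontinuity <= 0.84. The metric formulas in the cited prior work are
#' not public; the package uses documented threshold-compatible proxies:
#' \itemize{
#'   \item overall signal: median intensity divided by a background
#'     estimate (the 2.5th percentile of intensities);
#'   \item percent present: percent of probes brighter than twice
#'     background;
#'   \item regional discontinuity: probes laid out row-major on a square
#'     grid partitioned 4 x 4; the maximum absolute difference between a
#'     block's mean log2 intensity and the global mean log2 intensity.
#' }
#'
#' @param intensities strictly positive raw intensity vector, one value
#'   per probe.
#' @param grid optional probe layout as returned by the internal grid
#'   builder (data frame with a `block` column); defaults to the
#'   row-major square grid for `length(intensities)` probes.
#' @return A list of class `qc_result` with `overall_signal`,
#'   `percent_present`, `regional_discontinuity`, `array_pass`, and
#'   `failure_reasons`.
#' @export
compute_array_qc <- function(intensities, grid = NULL) {
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("data error: intensities must be strictly positive", call. = FALSE)
  if (is.null(grid)) grid <- probe_grid(length(intensities))
  if (nrow(grid) != length(intensities))
    stop("data error: grid layout does not cover all probes", call. = FALSE)
  bg <- unname(stats::quantile(intensities, 0.025))
  overall_signal <- stats::median(intensities) / bg
  percent_present <- 100 * mean(intensities > 2 * bg)
  lg <- log2(intensities)
  block_means <- tapply(lg, grid$block, mean)
  regional_discontinuity <- max(abs(block_means - mean(lg)))
  rules <- c(
    overall_signal_below_10 = overall_signal < 10,
    percent_present_below_5 = percent_present < 5,
    regional_discontinuity_above_0.84 = regional_discontinuity > 0.84
  )
  structure(list(
    overall_signal = overall_signal,
    percent_present = percent_present,
    regional_discontinuity = unname(regional_discontinuity),
    array_pass = !any(rules),
    failure_reasons = names(rules)[rules]
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("QC result", if (!is.null(x$specimen_id) && !is.na(x$specimen_id))
    paste0("[", x$specimen_id, "]"), "\n")
  for (f in c("overall_signal", "percent_present", "regional_discontinuity"))
    if (!is.null(x[[f]])) cat(sprintf("  %s: %.3f\n", f, x[[f]]))
  for (f in c("entry_pass", "array_pass"))
    if (!is.null(x[[f]])) cat(" ", f, ":", x[[f]], "\n")
  if (length(x$failure_reasons))
    cat("  reasons:", paste(x$failure_reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Run entry and array QC over a whole cohort
#'
#' Applies [check_specimen_entry()] to every metadata record and
#' [compute_array_qc()] to every expression column, returning one row per
#' specimen. Specimens failing either gate must be excluded from
#' standardization, classification and performance tables; downstream
#' pipeline stages enforce this.
#'
#' @param cohort a `syn_cohort`, or any list with `expression` (probes x
#'   specimens matrix) and `metadata` (data frame keyed by
#'   `specimen_id`).
#' @param verbose log one line per failing specimen.
#' @return Data frame with the three array metrics, `entry_pass`,
#'   `array_pass`, `qc_pass` (both), and semicolon-joined
#'   `failure_reasons`.
#' @export
qc_cohort <- function(cohort, verbose = FALSE) {
  expr <- cohort$expression
  md <- cohort$metadata
  stopifnot(identical(colnames(expr), md$specimen_id))
  grid <- probe_grid(nrow(expr))
  rows <- lapply(seq_len(ncol(expr)), function(j) {
    entry <- check_specimen_entry(md[j, , drop = FALSE])
    array <- compute_array_qc(expr[, j], grid)
    reasons <- c(entry$failure_reasons, array$failure_reasons)
    if (verbose && length(reasons))
      message("QC fail ", md$specimen_id[j], ": ",
              paste(reasons, collapse = "; "))
    data.frame(specimen_id = md$specimen_id[j],
               overall_signal = array$overall_signal,
               percent_present = array$percent_present,
               regional_discontinuity = array$regional_discontinuity,
               entry_pass = entry$entry_pass,
               array_pass = array$array_pass,
               qc_pass = entry$entry_pass && array$array_pass,
               failure_reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
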