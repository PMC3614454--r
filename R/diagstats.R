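#' Positive percent agreement with exact (Clopper-Pearson) interval
#'
#' PPA is the percent of test calls agreeing with the known clinical
#' diagnosis. The confidence interval is the exact equal-tailed
#' Clopper-Pearson interval obtained from Beta quantiles, the method
#' consistent with published performance tables for this class of test
#' (a 3-of-3 bin yields a lower bound of `100 * 0.025^(1/3) = 29.2`).
#'
#' @param x number of agreements.
#' @param n total specimens (>= 1).
#' @param level confidence level.
#' @return A one-row data frame of class `proportion_ci`: `numerator`,
#'   `denominator`, `percent`, `lower_pct`, `upper_pct`, `level`.
#' @examples
#' ppa(31, 38)  # 81.6% [65.7, 92.3]
#' @export
ppa <- function(x, n, level = 0.95) {
  stopifnot_scalar(n, "n", min = 1, integer = TRUE)
  stopifnot_scalar(x, "x", min = 0, max = n, integer = TRUE)
  stopifnot_scalar(level, "level", min = 0, max = 1)
  a <- (1 - level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  structure(data.frame(numerator = x, denominator = n,
                       percent = 100 * x / n,
                       lower_pct = 100 * lower, upper_pct = 100 * upper,
                       level = level),
            class = c("proportion_ci", "data.frame"))
}

#' Build a 2x2 agreement table of test call versus known diagnosis
#'
#' Cell layout: `a` = HNSCC called HNSCC, `b` = HNSCC called lung SCC,
#' `c` = lung SCC called HNSCC, `d` = lung SCC called lung SCC.
#'
#' @param calls character vector of test calls.
#' @param truth character vector of known diagnoses, same length.
#' @return A list of class `agreement_table` with counts `a`, `b`, `c`,
#'   `d`.
#' @export
agreement_table <- function(calls, truth) {
  stopifnot(length(calls) == length(truth))
  structure(list(
    a = sum(truth == "HNSCC" & calls == "HNSCC"),
    b = sum(truth == "HNSCC" & calls == "LUNG_SCC"),
    c = sum(truth == "LUNG_SCC" & calls == "HNSCC"),
    d = sum(truth == "LUNG_SCC" & calls == "LUNG_SCC")
  ), class = "agreement_table")
}

as_agreement_table <- function(table) {
  if (inherits(table, "agreement_table")) return(table)
  if (is.matrix(table) && all(dim(table) == 2))
    return(structure(list(a = table[1, 1], b = table[1, 2],
                          c = table[2, 1], d = table[2, 2]),
                     class = "agreement_table"))
  if (is.list(table) && all(c("a", "b", "c", "d") %in% names(table)))
    return(structure(table[c("a", "b", "c", "d")],
                     class = "agreement_table"))
  stop("not a 2x2 agreement table", call. = FALSE)
}

#' Diagnostic odds ratio with log-method confidence interval
#'
#' `DOR = (a * d) / (b * c)`, the odds of a correct HNSCC call times the
#' odds of a correct lung SCC call; a single-number summary of
#' discrimination. The interval is the standard log method,
#' `exp(ln DOR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is
#' zero, 0.5 is added to every cell (Haldane-Anscombe correction) before
#' computation; the result is flagged.
#'
#' @param table an `agreement_table`, 2x2 matrix, or list with `a`-`d`.
#' @param level confidence level.
#' @return List: `dor`, `lower`, `upper`, `level`, `corrected`.
#' @examples
#' diagnostic_odds_ratio(list(a = 31, b = 7, c = 6, d = 32))  # 23.6
#' @export
diagnostic_odds_ratio <- function(table, level = 0.95) {
  t2 <- as_agreement_table(table)
  cells <- as.numeric(t2[c("a", "b", "c", "d")])
  if (any(cells < 0)) stop("counts must be non-negative", call. = FALSE)
  if (all(cells == 0)) stop("all-zero agreement table", call. = FALSE)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  dor <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / cells))
  list(dor = dor, lower = exp(log(dor) - z * se),
       upper = exp(log(dor) + z * se), level = level,
       corrected = corrected)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p value under the small-table convention: the sum of
#' hypergeometric probabilities of all tables (with the observed
#' margins) no more probable than the observed one. Thin wrapper around
#' [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative counts (or an
#'   `agreement_table`).
#' @return Two-sided p value.
#' @export
fisher_exact_2x2 <- function(table) {
  t2 <- as_agreement_table(table)
  m <- matrix(as.numeric(t2[c("a", "b", "c", "d")]), 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' ROC curve and area under the curve
#'
#' Sweeps every threshold of the per-specimen score for one class (the
#' similarity score for the positive class), forming the ROC curve, and
#' computes the AUC by the trapezoidal rule — equivalently the
#' Mann-Whitney probability that a random positive scores above a random
#' negative, ties counting half.
#'
#' @param scores numeric score for the positive class, one per specimen.
#' @param labels logical or two-level vector; `TRUE` (or `"HNSCC"`)
#'   marks the positive class.
#' @param positive value of `labels` treated as positive.
#' @return List: `auc` and `curve` (data frame of `threshold`, `tpr`,
#'   `fpr`).
#' @export
roc_auc <- function(scores, labels, positive = "HNSCC") {
  pos <- if (is.logical(labels)) labels else labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = th,
    tpr = vapply(th, function(t) mean(scores[pos] >= t), 0),
    fpr = vapply(th, function(t) mean(scores[!pos] >= t), 0))
  list(auc = auc, curve = curve)
}

#' Stratified positive percent agreement (performance-by-attribute table)
#'
#' Splits specimens into bins of a metadata attribute and reports the
#' PPA with its exact interval inside each bin, the layout used to report
#' performance by specimen age, tumor content, necrosis, patient age,
#' grade or stage. Empty bins are reported with zero counts rather than
#' dropped.
#'
#' @param correct logical vector: did the test call agree with the known
#'   diagnosis?
#' @param records metadata data frame, one row per element of `correct`.
#' @param attribute column of `records` to stratify on.
#' @param breaks numeric bin edges (passed to [cut()]) for a numeric
#'   attribute; ignored when the attribute is categorical, whose levels
#'   become the bins.
#' @param right should numeric bins be right-closed?
#' @param include.lowest include the lowest edge in the first bin?
#' @param level confidence level.
#' @return Data frame: one row per bin with `bin`, `n`, `agreements`,
#'   `percent`, `lower_pct`, `upper_pct`.
#' @export
stratified_ppa <- function(correct, records, attribute, breaks = NULL,
                           right = FALSE, include.lowest = TRUE,
                           level = 0.95) {
  stopifnot(length(correct) == nrow(records))
  values <- records[[attribute]]
  if (is.null(values)) stop("unknown attribute: '", attribute, "'",
                            call. = FALSE)
  bin <- if (is.numeric(values) && !is.null(breaks))
    cut(values, breaks = breaks, right = right,
        include.lowest = include.lowest)
  else factor(values)
  if (anyNA(bin))
    stop("record outside all bins for attribute '", attribute, "'",
         call. = FALSE)
  out <- lapply(levels(bin), function(b) {
    sel <- bin == b
    n <- sum(sel)
    if (n == 0)
      return(data.frame(bin = b, n = 0L, agreements = 0L,
                        percent = NA_real_, lower_pct = NA_real_,
                        upper_pct = NA_real_))
    ci <- ppa(sum(correct[sel]), n, level)
    data.frame(bin = b, n = n, agreements = ci$numerator,
               percent = ci$percent, lower_pct = ci$lower_pct,
               upper_pct = ci$upper_pct)
  })
  do.call(rbind, out)
}

#' Summarize classifier performance against known diagnoses
#'
#' Produces the overall accuracy table: per-class PPA with exact
#' intervals, overall agreement, the Fisher exact comparison of the two
#' class non-agreement rates, the diagnostic odds ratio, and the AUC of
#' the HNSCC similarity score.
#'
#' @param reports data frame from [score_matrix()].
#' @param truth known class labels, parallel to `reports`.
#' @param level confidence level.
#' @return List: `table` (per-class and overall rows), `fisher_p`,
#'   `dor`, `auc`, `agreement` (the 2x2 table).
#' @export
performance_summary <- function(reports, truth, level = 0.95) {
  stopifnot(nrow(reports) == length(truth))
  tab <- agreement_table(reports$call, truth)
  rows <- rbind(
    cbind(group = "HNSCC", ppa(tab$a, tab$a + tab$b, level)),
    cbind(group = "LUNG_SCC", ppa(tab$d, tab$c + tab$d, level)),
    cbind(group = "overall",
          ppa(tab$a + tab$d, tab$a + tab$b + tab$c + tab$d, level)))
  # Fisher compares the two per-class agreement rates:
  # rows = known class, columns = (agreement, non-agreement)
  fisher_rows <- matrix(c(tab$a, tab$b, tab$d, tab$c), 2, byrow = TRUE)
  list(table = rows,
       fisher_p = fisher_exact_2x2(fisher_rows),
       dor = diagnostic_odds_ratio(tab, level),
       auc = roc_auc(reports$ss_hnscc, truth)$auc,
       agreement = tab)
}
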