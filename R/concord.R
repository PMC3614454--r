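#' Build a pair set of test calls for reproducibility analysis
#'
#' Pairs the calls made on two members of each unit (two adjacent
#' sections of a tissue block, or the same section processed at two
#' laboratories). Units with a missing call in either member — e.g. a
#' section that failed QC — are excluded, which is why reproducibility
#' denominators can be smaller than the number of blocks.
#'
#' @param unit_id unit (block/specimen) identifiers, no duplicates.
#' @param call_a,call_b calls (`"HNSCC"`/`"LUNG_SCC"`, `NA` = missing).
#' @param label optional label for the comparison (e.g.
#'   `"site 1 vs site 2"`).
#' @return A data frame of class `call_pairs` with attribute `label`.
#' @export
call_pairs <- function(unit_id, call_a, call_b, label = NULL) {
  stopifnot(length(unit_id) == length(call_a),
            length(call_a) == length(call_b))
  if (anyDuplicated(unit_id))
    stop("unit repeated within a pair set", call. = FALSE)
  keep <- !is.na(call_a) & !is.na(call_b)
  out <- data.frame(unit_id = unit_id[keep],
                    call_a = as.character(call_a[keep]),
                    call_b = as.character(call_b[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "label") <- label
  class(out) <- c("call_pairs", "data.frame")
  out
}

#' Pairwise concordance of test calls
#'
#' Fraction of units whose two calls match, with the exact
#' (Clopper-Pearson) interval used throughout the package's proportion
#' reporting.
#'
#' @param pairs a [call_pairs()] data frame (>= 1 pair).
#' @param level confidence level.
#' @return A `proportion_ci` row (see [ppa()]).
#' @export
pairwise_concordance <- function(pairs, level = 0.95) {
  if (nrow(pairs) < 1) stop("empty pair set", call. = FALSE)
  ppa(sum(pairs$call_a == pairs$call_b), nrow(pairs), level)
}

#' Cohen's kappa for paired categorical calls
#'
#' Chance-corrected agreement
#' `kappa = (p_obs - p_exp) / (1 - p_exp)`, with the expected agreement
#' `p_exp` computed from the two call margins. The confidence interval
#' uses the large-sample standard error
#' `sqrt(p_obs (1 - p_obs) / (n (1 - p_exp)^2))`. When both raters make
#' a single identical call throughout (`p_exp = 1`), kappa is undefined
#' and the result is flagged rather than returned as a number.
#'
#' @param pairs a [call_pairs()] data frame (>= 2 pairs).
#' @param level confidence level.
#' @return List: `kappa`, `lower`, `upper`, `p_obs`, `p_exp`, `n`,
#'   `undefined`.
#' @export
cohens_kappa <- function(pairs, level = 0.95) {
  if (nrow(pairs) < 2) stop("need at least 2 pairs", call. = FALSE)
  lev <- sort(unique(c(pairs$call_a, pairs$call_b)))
  a <- factor(pairs$call_a, levels = lev)
  b <- factor(pairs$call_b, levels = lev)
  n <- nrow(pairs)
  p_obs <- mean(a == b)
  p_exp <- sum((table(a) / n) * (table(b) / n))
  if (p_exp >= 1 - 1e-12)
    return(list(kappa = NA_real_, lower = NA_real_, upper = NA_real_,
                p_obs = p_obs, p_exp = p_exp, n = n, undefined = TRUE))
  kappa <- (p_obs - p_exp) / (1 - p_exp)
  se <- sqrt(p_obs * (1 - p_obs) / (n * (1 - p_exp)^2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(kappa = kappa,
       lower = max(-1, kappa - z * se),
       upper = min(1, kappa + z * se),
       p_obs = p_obs, p_exp = unname(p_exp), n = n, undefined = FALSE)
}

#' Percent coefficient of variation of replicate similarity scores
#'
#' For each tissue block with replicate sections, the %CV of the
#' similarity score for the known diagnosis is `100 * sd / mean` (sample
#' standard deviation); the summary across blocks is the median. Blocks
#' with a zero mean are flagged undefined and excluded from the median.
#'
#' @param scores numeric similarity scores of the replicates.
#' @param block block identifier for each score; every block must have
#'   at least 2 replicates.
#' @return List: `per_block` (data frame of `block`, `n`, `mean`, `sd`,
#'   `cv_pct`, `undefined`) and `median_cv_pct`.
#' @export
similarity_cv <- function(scores, block) {
  stopifnot(length(scores) == length(block))
  counts <- table(block)
  if (any(counts < 2))
    stop("every block needs at least 2 replicate scores", call. = FALSE)
  per_block <- do.call(rbind, lapply(names(counts), function(bl) {
    s <- scores[block == bl]
    m <- mean(s)
    undef <- m == 0
    data.frame(block = bl, n = length(s), mean = m, sd = stats::sd(s),
               cv_pct = if (undef) NA_real_ else 100 * stats::sd(s) / m,
               undefined = undef, stringsAsFactors = FALSE)
  }))
  list(per_block = per_block,
       median_cv_pct = stats::median(per_block$cv_pct, na.rm = TRUE))
}

#' Reproducibility table for replicate sections
#'
#' Given calls (and similarity scores) for sections of the same blocks
#' processed in one run or at several sites, builds the pairwise
#' concordance rows — one per section/site pair plus a pooled overall
#' row — together with kappa per pair, in the layout of a
#' reproducibility table.
#'
#' @param reports data frame from [score_matrix()] with columns
#'   `ss_hnscc`, `call`.
#' @param block block identifier per report row.
#' @param section section or site identifier per report row.
#' @param level confidence level.
#' @return List: `pairs` (data frame with one row per section pair:
#'   concordant counts, percent, CI, kappa) and `overall` (pooled
#'   `proportion_ci`).
#' @export
reproducibility_table <- function(reports, block, section, level = 0.95) {
  stopifnot(nrow(reports) == length(block),
            length(block) == length(section))
  secs <- sort(unique(section))
  combos <- utils::combn(secs, 2, simplify = FALSE)
  blocks <- unique(block)
  get_calls <- function(s) {
    idx <- match(paste(blocks, s), paste(block, section))
    reports$call[idx]
  }
  rows <- list(); pooled_match <- 0L; pooled_n <- 0L
  for (cmb in combos) {
    pr <- call_pairs(blocks, get_calls(cmb[1]), get_calls(cmb[2]),
                     label = paste(cmb[1], "vs", cmb[2]))
    cc <- pairwise_concordance(pr, level)
    kp <- if (nrow(pr) >= 2) cohens_kappa(pr, level)
          else list(kappa = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = attr(pr, "label"), n_pairs = cc$denominator,
      concordant = cc$numerator, percent = cc$percent,
      lower_pct = cc$lower_pct, upper_pct = cc$upper_pct,
      kappa = kp$kappa, stringsAsFactors = FALSE)
    pooled_match <- pooled_match + cc$numerator
    pooled_n <- pooled_n + cc$denominator
  }
  list(pairs = do.call(rbind, rows),
       overall = ppa(pooled_match, pooled_n, level))
}
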