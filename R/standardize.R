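#' Fit a frozen reference distribution for quantile standardization
#'
#' The assay's standardization step maps each incoming specimen's probe
#' intensities onto a fixed reference distribution so that technical
#' (site/batch) variation is removed before classification. The reference
#' is frozen at training time — quantile `k` is the mean across training
#' specimens of each specimen's `k`-th smallest log2 intensity — so a
#' single clinical specimen can be standardized at test time without
#' access to any cohort.
#'
#' @param training probes x specimens matrix of raw positive intensities
#'   (at least two specimens).
#' @return An object of class `ref_dist`: sorted log2 reference quantiles
#'   plus the probe identifier order.
#' @export
fit_reference <- function(training) {
  if (!is.matrix(training) || ncol(training) < 2)
    stop("reference fitting needs at least 2 specimens", call. = FALSE)
  if (any(training <= 0)) stop("intensities must be strictly positive",
                               call. = FALSE)
  q <- rowMeans(apply(log2(training), 2, sort))
  structure(list(quantiles = q, probe_ids = rownames(training)),
            class = "ref_dist")
}

#' Standardize a specimen against a frozen reference
#'
#' Rank-transforms the specimen's log2 intensities and substitutes the
#' reference quantiles (single-specimen quantile normalization). Ties
#' share the mean of the reference quantiles their ranks span, so the map
#' is deterministic. Output is on the log2 scale. Standardizing an
#' already-standardized specimen against the same reference is a no-op.
#'
#' @param specimen raw positive intensity vector (or a log2-scale vector
#'   with `log2_input = TRUE`), same length and probe order as the
#'   reference.
#' @param ref a [fit_reference()] object.
#' @param log2_input is `specimen` already on the log2 scale?
#' @return Standardized log2 vector, names preserved.
#' @export
apply_standardization <- function(specimen, ref, log2_input = FALSE) {
  stopifnot(inherits(ref, "ref_dist"))
  if (length(specimen) != length(ref$quantiles))
    stop("specimen length ", length(specimen),
         " does not match reference length ", length(ref$quantiles),
         call. = FALSE)
  x <- if (log2_input) specimen else {
    if (any(specimen <= 0)) stop("intensities must be strictly positive",
                                 call. = FALSE)
    log2(specimen)
  }
  q <- sort(ref$quantiles)
  lo <- rank(x, ties.method = "min")
  hi <- rank(x, ties.method = "max")
  cs <- c(0, cumsum(q))
  out <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  names(out) <- names(specimen)
  out
}

#' Standardize every specimen of an expression matrix
#'
#' @param x probes x specimens matrix of raw positive intensities.
#' @param ref a [fit_reference()] object.
#' @return Matrix of standardized log2 values, dimnames preserved.
#' @export
standardize_matrix <- function(x, ref) {
  out <- apply(x, 2, apply_standardization, ref = ref)
  dimnames(out) <- dimnames(x)
  out
}

#' Read / write a reference distribution as TSV
#'
#' Stored as two tab-delimited columns, `rank` and `log2_quantile`, so a
#' frozen reference can be versioned alongside a trained model.
#'
#' @param ref a `ref_dist`.
#' @param path file path.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "ref_dist"))
  utils::write.table(
    data.frame(rank = seq_along(ref$quantiles),
               log2_quantile = ref$quantiles),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  df <- utils::read.delim(path)
  structure(list(quantiles = df$log2_quantile, probe_ids = NULL),
            class = "ref_dist")
}
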