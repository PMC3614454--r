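#' Cross-validation specification for classifier training
#'
#' @param outer_folds,inner_folds stratified fold counts for the outer
#'   (performance-estimation) and inner (hyperparameter-selection) loops.
#' @param n_features candidate counts of top-ranked probes (by absolute
#'   two-sample t statistic) offered to the inner loop.
#' @param alpha elastic-net mixing parameter passed to glmnet (0 = ridge).
#' @param nlambda length of the regularization path searched.
#' @return A list of class `cv_spec`.
#' @export
cv_spec <- function(outer_folds = 5, inner_folds = 5,
                    n_features = c(25, 50, 100, 200),
                    alpha = 0, nlambda = 30) {
  stopifnot_scalar(outer_folds, "outer_folds", min = 2, integer = TRUE)
  stopifnot_scalar(inner_folds, "inner_folds", min = 2, integer = TRUE)
  stopifnot(is.numeric(n_features), all(n_features >= 1))
  stopifnot_scalar(alpha, "alpha", min = 0, max = 1)
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 n_features = as.integer(sort(unique(n_features))),
                 alpha = alpha, nlambda = as.integer(nlambda)),
            class = "cv_spec")
}

# Stratified fold assignment: within each class, specimens are shuffled
# and dealt round-robin, so fold class balance is as even as possible.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })
  fold
}

# Pooled-variance two-sample t statistic per probe (columns of X),
# comparing y == positive class against the rest. Vectorized.
feature_t_stats <- function(X, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  m0 <- colMeans(X[y == 0, , drop = FALSE])
  v1 <- colSums(sweep(X[y == 1, , drop = FALSE], 2, m1)^2)
  v0 <- colSums(sweep(X[y == 0, , drop = FALSE], 2, m0)^2)
  sp <- sqrt((v1 + v0) / (n1 + n0 - 2))
  (m1 - m0) / (sp * sqrt(1 / n1 + 1 / n0) + 1e-12)
}

# Inner loop: pick (feature count, lambda) minimizing inner-CV binomial
# deviance. Feature ranking is redone on the training data only.
select_hyperparams <- function(X, y, spec, seed) {
  foldid <- stratified_folds(y, spec$inner_folds, seed)
  tt <- abs(feature_t_stats(X, y))
  best <- NULL
  for (k in pmin(spec$n_features, ncol(X))) {
    feats <- order(tt, decreasing = TRUE)[seq_len(k)]
    cvfit <- glmnet::cv.glmnet(X[, feats, drop = FALSE], y,
                               family = "binomial",
                               type.measure = "deviance",
                               alpha = spec$alpha, nlambda = spec$nlambda,
                               foldid = foldid, standardize = TRUE)
    score <- min(cvfit$cvm)
    if (is.null(best) || score < best$score)
      best <- list(score = score, n_features = k,
                   lambda = cvfit$lambda.min, features = feats)
  }
  best
}

fit_penalized <- function(X, y, spec, hyper) {
  fit <- glmnet::glmnet(X[, hyper$features, drop = FALSE], y,
                        family = "binomial", alpha = spec$alpha,
                        standardize = TRUE)
  beta <- as.numeric(stats::predict(fit, s = hyper$lambda,
                                    type = "coefficients",
                                    exact = FALSE))
  list(intercept = beta[1],
       coefficients = stats::setNames(beta[-1],
                                      colnames(X)[hyper$features]))
}

#' Train the two-class similarity-score classifier by nested CV
#'
#' Fits a regularized logistic model on standardized expression with a
#' nested cross-validation protocol: the inner loop selects the feature
#' count (top probes by absolute t statistic, ranked within the training
#' data only) and the regularization strength; the outer loop provides an
#' unbiased accuracy estimate from specimens never seen by the inner
#' selection. The final model is refit on all specimens with the selected
#' hyperparameters, and a monotone (Platt) calibration is fit on the
#' pooled outer-fold held-out predictions so that the reported scores are
#' interpretable as class probabilities.
#'
#' @param x probes x specimens matrix of standardized log2 expression.
#' @param labels per-specimen class labels, `"HNSCC"` or `"LUNG_SCC"`;
#'   HNSCC is the positive class.
#' @param spec a [cv_spec()].
#' @param seed integer seed controlling all fold assignments.
#' @return An object of class `sq_model` with elements `probes`,
#'   `coefficients`, `intercept`, `calibration` (logit-scale intercept
#'   and non-negative slope), `hyper`, `cv` (outer-fold accuracy estimate
#'   and per-specimen held-out predictions), and `seed`.
#' @export
train_nested_cv <- function(x, labels, spec = cv_spec(), seed = 1) {
  labels <- as.character(labels)
  if (!all(labels %in% CLASS_LEVELS))
    stop("labels must be one of: ", paste(CLASS_LEVELS, collapse = ", "),
         call. = FALSE)
  y <- as.integer(labels == "HNSCC")
  if (length(unique(y)) < 2)
    stop("both classes must be present in the training data", call. = FALSE)
  if (min(table(y)) < spec$outer_folds)
    stop("too few specimens per class for ", spec$outer_folds,
         "-fold outer cross-validation", call. = FALSE)
  X <- t(x)

  outer <- stratified_folds(y, spec$outer_folds, substream_seed(seed, 11))
  heldout_p <- rep(NA_real_, length(y))
  for (f in seq_len(spec$outer_folds)) {
    tr <- outer != f
    hyper <- select_hyperparams(X[tr, , drop = FALSE], y[tr], spec,
                                substream_seed(seed, 20 + f))
    fit <- fit_penalized(X[tr, , drop = FALSE], y[tr], spec, hyper)
    eta <- fit$intercept +
      X[!tr, names(fit$coefficients), drop = FALSE] %*% fit$coefficients
    heldout_p[!tr] <- stats::plogis(as.numeric(eta))
  }
  heldout_call <- ifelse(heldout_p > 0.5, 1L, 0L)
  outer_accuracy <- mean(heldout_call == y)

  hyper <- select_hyperparams(X, y, spec, substream_seed(seed, 12))
  fit <- fit_penalized(X, y, spec, hyper)
  calibration <- fit_platt(heldout_p, y)

  structure(list(
    probes = names(fit$coefficients),
    coefficients = fit$coefficients,
    intercept = fit$intercept,
    calibration = calibration,
    hyper = list(n_features = hyper$n_features, lambda = hyper$lambda,
                 alpha = spec$alpha),
    cv = list(outer_folds = spec$outer_folds,
              inner_folds = spec$inner_folds,
              outer_accuracy = outer_accuracy,
              heldout = data.frame(specimen_id = colnames(x),
                                   label = labels,
                                   p_hnscc = heldout_p,
                                   stringsAsFactors = FALSE)),
    class_levels = CLASS_LEVELS,
    seed = as.integer(seed)
  ), class = "sq_model")
}

# Platt scaling: logistic regression of the outcome on the raw logit.
# The slope is clamped at zero so the calibration map is monotone
# non-decreasing even in degenerate fits.
fit_platt <- function(p_raw, y) {
  eps <- 1e-6
  z <- stats::qlogis(pmin(pmax(p_raw, eps), 1 - eps))
  co <- tryCatch(
    stats::coef(suppressWarnings(
      stats::glm(y ~ z, family = stats::binomial()))),
    error = function(e) c(0, 1))
  if (anyNA(co)) co <- c(0, 1)
  list(intercept = unname(co[1]), slope = max(0, unname(co[2])))
}

apply_calibration <- function(p_raw, calibration) {
  eps <- 1e-6
  z <- stats::qlogis(pmin(pmax(p_raw, eps), 1 - eps))
  stats::plogis(calibration$intercept + calibration$slope * z)
}

#' @export
print.sq_model <- function(x, ...) {
  cat("Two-class squamous origin classifier\n")
  cat("  probes selected:", length(x$probes),
      " (lambda =", signif(x$hyper$lambda, 3), ")\n")
  cat(sprintf("  outer-CV accuracy: %.3f\n", x$cv$outer_accuracy))
  invisible(x)
}

#' Score a specimen: two similarity scores summing to 100
#'
#' Applies the trained model to one standardized specimen and reports
#' the pair of similarity scores. The HNSCC score is 100 times the
#' calibrated probability that the specimen's expression profile matches
#' HNSCC; the lung SCC score is its complement, so the two scores always
#' add up to 100. The call names the class with the strictly higher score
#' at the reporting precision of one decimal; an exact tie at that
#' precision is reported as indeterminate.
#'
#' @param model an `sq_model`.
#' @param specimen named standardized log2 vector covering (at least) all
#'   selected probes.
#' @param specimen_id optional identifier carried into the report.
#' @return A list of class `similarity_report` with `ss_hnscc`,
#'   `ss_lung`, and `call`.
#' @export
score_specimen <- function(model, specimen, specimen_id = NULL) {
  stopifnot(inherits(model, "sq_model"))
  missing <- setdiff(model$probes, names(specimen))
  if (length(missing))
    stop("specimen is missing selected probes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  eta <- model$intercept +
    sum(model$coefficients * specimen[model$probes])
  p <- apply_calibration(stats::plogis(eta), model$calibration)
  ss_hnscc <- 100 * p
  ss_lung <- 100 - ss_hnscc
  r_hn <- round_half_up(ss_hnscc, 1)
  r_lu <- round_half_up(ss_lung, 1)
  call <- if (r_hn > r_lu) "HNSCC" else if (r_lu > r_hn) "LUNG_SCC"
          else "indeterminate"
  structure(list(specimen_id = specimen_id %||% NA_character_,
                 ss_hnscc = ss_hnscc, ss_lung = ss_lung, call = call),
            class = "similarity_report")
}

#' Score every specimen of a standardized matrix
#'
#' @param model an `sq_model`.
#' @param x probes x specimens standardized matrix.
#' @return Data frame: `specimen_id`, `ss_hnscc`, `ss_lung`, `call`.
#' @export
score_matrix <- function(model, x) {
  reports <- lapply(colnames(x), function(id)
    score_specimen(model, x[, id], id))
  data.frame(specimen_id = vapply(reports, `[[`, "", "specimen_id"),
             ss_hnscc = vapply(reports, `[[`, 0, "ss_hnscc"),
             ss_lung = vapply(reports, `[[`, 0, "ss_lung"),
             call = vapply(reports, `[[`, "", "call"),
             stringsAsFactors = FALSE)
}

#' Rank the model's markers with tissue-direction labels
#'
#' Orders the selected probes by importance (absolute coefficient scaled
#' by the probe's standard deviation in the supplied data) and labels
#' each with the tissue type in which its expression is higher: `lung-up`
#' if the lung SCC class mean exceeds the HNSCC class mean, `hn-up`
#' otherwise.
#'
#' @param model a trained `sq_model`.
#' @param x probes x specimens standardized matrix.
#' @param labels per-specimen class labels.
#' @param top number of markers to return (default all selected probes).
#' @return Data frame: `rank` (contiguous from 1), `probe_id`,
#'   `direction`, `importance` (non-increasing).
#' @export
rank_markers <- function(model, x, labels, top = Inf) {
  stopifnot(inherits(model, "sq_model"))
  if (is.null(model$coefficients) || !length(model$probes))
    stop("model has no trained coefficients", call. = FALSE)
  labels <- as.character(labels)
  sub <- x[model$probes, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  importance <- abs(model$coefficients) * sds
  diff <- rowMeans(sub[, labels == "LUNG_SCC", drop = FALSE]) -
    rowMeans(sub[, labels == "HNSCC", drop = FALSE])
  ord <- order(importance, decreasing = TRUE)
  n <- min(length(ord), top)
  data.frame(rank = seq_len(n),
             probe_id = model$probes[ord[seq_len(n)]],
             direction = ifelse(diff[ord[seq_len(n)]] > 0,
                                "lung-up", "hn-up"),
             importance = unname(importance[ord[seq_len(n)]]),
             stringsAsFactors = FALSE)
}

#' Render a similarity report as human-readable text
#'
#' Both scores are printed to one decimal and the higher-scoring tissue
#' is named as the more likely tissue of origin.
#'
#' @param report a `similarity_report`.
#' @return Character vector of report lines (invisibly printed by the
#'   `print` method).
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "similarity_report"))
  hn <- round_half_up(report$ss_hnscc, 1)
  lu <- round_half_up(report$ss_lung, 1)
  id <- report$specimen_id
  header <- if (is.na(id)) "Tissue-of-origin similarity report"
            else sprintf("Tissue-of-origin similarity report — %s", id)
  verdict <- switch(report$call,
    HNSCC = sprintf(
      "Head & neck squamous cell carcinoma (Similarity Score %.1f) is the more likely tissue of origin.", hn),
    LUNG_SCC = sprintf(
      "Lung squamous cell carcinoma (Similarity Score %.1f) is the more likely tissue of origin.", lu),
    "The two Similarity Scores are equal; the tissue of origin is indeterminate.")
  c(header,
    sprintf("  Similarity Score, HNSCC:    %.1f", hn),
    sprintf("  Similarity Score, lung SCC: %.1f", lu),
    paste0("  ", verdict))
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Read / write a trained model as plain text
#'
#' Coefficients go to a tab-delimited file (`probe_id`, `coefficient`);
#' intercept, calibration, hyperparameters and seed go to a JSON header
#' next to it.
#'
#' @param model an `sq_model`.
#' @param prefix path prefix; writes `<prefix>_coefficients.tsv` and
#'   `<prefix>_model.json`.
#' @export
write_model <- function(model, prefix) {
  stopifnot(inherits(model, "sq_model"))
  coef_path <- paste0(prefix, "_coefficients.tsv")
  json_path <- paste0(prefix, "_model.json")
  utils::write.table(
    data.frame(probe_id = model$probes,
               coefficient = unname(model$coefficients)),
    coef_path, sep = "\t", quote = FALSE, row.names = FALSE)
  header <- list(intercept = model$intercept,
                 calibration = model$calibration,
                 hyper = model$hyper,
                 outer_accuracy = model$cv$outer_accuracy,
                 class_levels = model$class_levels,
                 seed = model$seed)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA),
             json_path)
  invisible(c(coefficients = coef_path, header = json_path))
}

#' @rdname write_model
#' @export
read_model <- function(prefix) {
  coefs <- utils::read.delim(paste0(prefix, "_coefficients.tsv"))
  header <- jsonlite::fromJSON(paste0(prefix, "_model.json"))
  structure(list(
    probes = coefs$probe_id,
    coefficients = stats::setNames(coefs$coefficient, coefs$probe_id),
    intercept = header$intercept,
    calibration = header$calibration,
    hyper = header$hyper,
    cv = list(outer_accuracy = header$outer_accuracy),
    class_levels = header$class_levels,
    seed = header$seed
  ), class = "sq_model")
}
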