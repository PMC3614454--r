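#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated two-class FFPE
#' microarray cohort: HNSCC and lung SCC specimens with overlapping global
#' expression, a set of directional marker probes (lung-up markers such as
#' the surfactant proteins, HN-up markers such as the keratins), additive
#' site batch shifts across independent processing laboratories, FFPE
#' measurement noise, and a configurable rate of planted quality-control
#' failures.
#'
#' Intensities follow a log-normal model: probe intensity is normal on the
#' log2 scale — grand mean, plus a fixed per-probe effect, plus a
#' per-specimen baseline, plus the class shift on marker probes, plus a
#' per-site scalar batch shift, plus FFPE noise — and is exponentiated to
#' the raw scale, so raw intensities are strictly positive.
#'
#' @param n_probes number of probes on the array.
#' @param n_markers_lung,n_markers_hn number of planted lung-up / HN-up
#'   marker probes. Defaults 12 and 8 mirror the directional split among
#'   a squamous-origin panel's top markers (surfactant-type lung markers
#'   outnumbering keratin-type head & neck markers).
#' @param marker_effect class shift, in log2 units, added to a marker
#'   probe in specimens of its "up" class.
#' @param n_specimens_per_class specimens simulated per class.
#' @param n_sites number of processing laboratories.
#' @param site_effect_sd standard deviation of the per-site scalar batch
#'   shift (log2 units).
#' @param ffpe_noise_sd standard deviation of per-measurement FFPE noise
#'   (log2 units).
#' @param qc_failure_rate fraction of specimens planted with a
#'   QC-breaking artifact; the planted count is `round(rate * n)`.
#' @param replicate_sections number of adjacent sections per block kept
#'   in the base cohort (replicates are usually added afterwards with
#'   [generate_replicate_sections()]).
#' @param seed master seed; all internal random sub-streams are derived
#'   from it by fixed offsets.
#' @param baseline_log2_mean,probe_effect_sd,specimen_baseline_sd
#'   nuisance-scale parameters of the log-normal model (log2 units).
#' @return An object of class `generator_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
generator_config <- function(n_probes = 2000,
                             n_markers_lung = 12,
                             n_markers_hn = 8,
                             marker_effect = 2,
                             n_specimens_per_class = 40,
                             n_sites = 3,
                             site_effect_sd = 0.5,
                             ffpe_noise_sd = 0.5,
                             qc_failure_rate = 0.05,
                             replicate_sections = 1,
                             seed = 1,
                             baseline_log2_mean = 8,
                             probe_effect_sd = 2,
                             specimen_baseline_sd = 0.5) {
  stopifnot_scalar(n_probes, "n_probes", min = 1, integer = TRUE)
  stopifnot_scalar(n_markers_lung, "n_markers_lung", min = 0, integer = TRUE)
  stopifnot_scalar(n_markers_hn, "n_markers_hn", min = 0, integer = TRUE)
  stopifnot_scalar(marker_effect, "marker_effect", min = 0)
  stopifnot_scalar(n_specimens_per_class, "n_specimens_per_class",
                   min = 1, integer = TRUE)
  stopifnot_scalar(n_sites, "n_sites", min = 1, integer = TRUE)
  stopifnot_scalar(site_effect_sd, "site_effect_sd", min = 0)
  stopifnot_scalar(ffpe_noise_sd, "ffpe_noise_sd", min = 0)
  stopifnot_scalar(qc_failure_rate, "qc_failure_rate", min = 0, max = 1)
  stopifnot_scalar(replicate_sections, "replicate_sections", min = 1,
                   integer = TRUE)
  stopifnot_scalar(seed, "seed", integer = TRUE)
  stopifnot_scalar(baseline_log2_mean, "baseline_log2_mean")
  stopifnot_scalar(probe_effect_sd, "probe_effect_sd", min = 0)
  stopifnot_scalar(specimen_baseline_sd, "specimen_baseline_sd", min = 0)
  if (n_markers_lung + n_markers_hn > n_probes)
    stop("configuration error: 'n_markers_lung' + 'n_markers_hn' exceeds ",
         "'n_probes'", call. = FALSE)
  structure(list(
    n_probes = as.integer(n_probes),
    n_markers_lung = as.integer(n_markers_lung),
    n_markers_hn = as.integer(n_markers_hn),
    marker_effect = marker_effect,
    n_specimens_per_class = as.integer(n_specimens_per_class),
    n_sites = as.integer(n_sites),
    site_effect_sd = site_effect_sd,
    ffpe_noise_sd = ffpe_noise_sd,
    qc_failure_rate = qc_failure_rate,
    replicate_sections = as.integer(replicate_sections),
    seed = as.integer(seed),
    baseline_log2_mean = baseline_log2_mean,
    probe_effect_sd = probe_effect_sd,
    specimen_baseline_sd = specimen_baseline_sd
  ), class = "generator_config")
}

# Row-major square grid layout for the array, plus the 4 x 4 block
# partition used by the regional-discontinuity metric and by the planted
# dark-block artifact.
probe_grid <- function(n_probes) {
  side <- ceiling(sqrt(n_probes))
  idx <- seq_len(n_probes) - 1L
  row <- idx %/% side + 1L
  col <- idx %% side + 1L
  band <- function(pos) pmin(4L, ceiling(pos / (side / 4)))
  data.frame(probe_index = idx + 1L, row = row, col = col,
             block = (band(row) - 1L) * 4L + band(col))
}

# Metadata attribute draws. Bin frequencies follow the attribute mix of a
# 76-specimen squamous validation cohort (specimen age, tumor and necrotic
# content, patient age, grade, stage, metastatic fraction); they are
# defaults, not contracts.
sample_metadata <- function(n, class_label, site_ids) {
  spec_age_bin <- sample(c(0, 1, 2, 3, 4), n, replace = TRUE,
                         prob = c(37, 8, 8, 12, 11) / 76)
  tumor_bin <- sample(1:4, n, replace = TRUE, prob = c(7, 19, 28, 22) / 76)
  tumor_lo <- c(90, 80, 70, 60)[tumor_bin]
  necr_bin <- sample(1:4, n, replace = TRUE, prob = c(39, 19, 15, 3) / 76)
  necr_lo <- c(0, 10, 20, 30)[necr_bin]
  page_bin <- sample(1:4, n, replace = TRUE, prob = c(16, 25, 25, 10) / 76)
  page_lo <- c(40, 50, 60, 70)[page_bin]
  grade <- sample(c("G1", "G2", "G3", "GX"), n, replace = TRUE,
                  prob = c(4, 10, 56, 6) / 76)
  stage <- sample(c("I-II", "III-IV", "unknown"), n, replace = TRUE,
                  prob = c(16, 17, 43) / 76)
  metastatic <- runif(n) < 26 / 76
  site_primary <- ifelse(class_label == "HNSCC",
                         sample(c("larynx", "oral_cavity", "nasopharynx",
                                  "oropharynx"), n, replace = TRUE),
                         "lung")
  site_met <- sample(c("lymph_node", "brain", "abdominal_wall", "dermal"),
                     n, replace = TRUE, prob = c(21, 2, 2, 1) / 26)
  data.frame(
    class_label = class_label,
    tumor_content_pct = tumor_lo + runif(n) * 10,
    necrosis_pct = necr_lo + runif(n) * 10,
    rna_yield_ng = runif(n, 50, 500),
    rna_conc_ng_per_ul = runif(n, 9.5, 50),
    a260_a280 = runif(n, 1.56, 2.60),
    cdna_yield_ug = runif(n, 2.5, 10),
    biopsy_site = ifelse(metastatic, site_met, site_primary),
    metastatic = metastatic,
    grade = grade,
    stage = stage,
    patient_age_years = page_lo + runif(n) * ifelse(page_lo == 70, 15, 10),
    specimen_age_years = spec_age_bin + runif(n),
    processing_site_id = site_ids,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic two-class FFPE expression cohort
#'
#' Simulates raw (strictly positive) probe intensities and specimen
#' metadata under the model described in [generator_config()]. Marker
#' probes carry the configured class shift with the planted direction;
#' `round(qc_failure_rate * n)` specimens are planted with one of two
#' QC-breaking artifacts: a globally dark signal (the log2 dynamic range
#' compressed toward background, driving the overall-signal metric below
#' threshold) or a dark spatial block (one 4 x 4 grid block dimmed,
#' driving regional discontinuity above threshold).
#'
#' @param config a [generator_config()].
#' @return An object of class `syn_cohort`: a list with
#'   \describe{
#'     \item{expression}{numeric matrix, probes x specimens, raw scale;}
#'     \item{metadata}{one row per specimen (class label, entry-criteria
#'       fields, processing site, block/section identifiers, and the
#'       planted QC artifact flags used only by test harnesses);}
#'     \item{truth}{one row per probe: marker role
#'       (`lung-up`/`hn-up`/`null`) and planted effect size;}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' cohort <- generate_cohort(generator_config(n_probes = 100,
#'   n_specimens_per_class = 5, seed = 7))
#' dim(cohort$expression)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  p <- config$n_probes
  n <- 2L * config$n_specimens_per_class
  probe_ids <- sprintf("probe_%04d", seq_len(p))
  specimen_ids <- sprintf("spec_%03d", seq_len(n))
  class_label <- rep(CLASS_LEVELS, each = config$n_specimens_per_class)

  # marker roles: first lung-up, then hn-up, remainder null
  role <- rep("null", p)
  if (config$n_markers_lung > 0) role[seq_len(config$n_markers_lung)] <- "lung-up"
  if (config$n_markers_hn > 0)
    role[config$n_markers_lung + seq_len(config$n_markers_hn)] <- "hn-up"
  effect <- ifelse(role == "null", 0, config$marker_effect)

  probe_effect <- with_seed(substream_seed(config$seed, 1),
                            rnorm(p, 0, config$probe_effect_sd))
  site_shift <- with_seed(substream_seed(config$seed, 2),
                          rnorm(config$n_sites, 0, config$site_effect_sd))
  site_of <- with_seed(substream_seed(config$seed, 3),
                       sample(rep_len(seq_len(config$n_sites), n)))
  baseline <- with_seed(substream_seed(config$seed, 4),
                        rnorm(n, 0, config$specimen_baseline_sd))
  noise <- with_seed(substream_seed(config$seed, 5),
                     matrix(rnorm(p * n, 0, config$ffpe_noise_sd), p, n))

  log2x <- config$baseline_log2_mean + probe_effect + noise +
    rep(baseline + site_shift[site_of], each = p)
  class_shift <- outer(effect * (role == "lung-up"),
                       as.numeric(class_label == "LUNG_SCC")) +
    outer(effect * (role == "hn-up"), as.numeric(class_label == "HNSCC"))
  log2x <- log2x + class_shift

  # plant QC artifacts
  n_fail <- round_half_up(config$qc_failure_rate * n)
  planted <- with_seed(substream_seed(config$seed, 6),
                       sample(n, n_fail))
  artifact <- rep("none", n)
  if (n_fail > 0) {
    artifact[planted] <- rep_len(c("dark_signal", "dark_block"), n_fail)
    grid <- probe_grid(p)
    dark_blocks <- with_seed(substream_seed(config$seed, 7),
                             sample(16L, n_fail, replace = TRUE))
    for (k in seq_len(n_fail)) {
      j <- planted[k]
      if (artifact[j] == "dark_signal") {
        # compress the dynamic range toward the specimen median: the
        # median/background ratio collapses below the signal threshold
        ctr <- median(log2x[, j])
        log2x[, j] <- ctr + 0.35 * (log2x[, j] - ctr)
      } else {
        sel <- grid$block == dark_blocks[k]
        log2x[sel, j] <- log2x[sel, j] - 4
      }
    }
  }

  metadata <- with_seed(substream_seed(config$seed, 8),
                        sample_metadata(n, class_label, site_of))
  metadata <- cbind(specimen_id = specimen_ids, metadata,
                    section_id = 1L,
                    block_id = sprintf("block_%03d", seq_len(n)),
                    qc_planted = artifact != "none",
                    qc_artifact = artifact,
                    stringsAsFactors = FALSE)
  rownames(metadata) <- NULL

  expression <- 2^log2x
  dimnames(expression) <- list(probe_ids, specimen_ids)
  structure(list(
    expression = expression,
    metadata = metadata,
    truth = data.frame(probe_id = probe_ids, role = role, effect = effect,
                       stringsAsFactors = FALSE),
    config = config
  ), class = "syn_cohort")
}

#' @export
print.syn_cohort <- function(x, ...) {
  cat("Synthetic squamous-carcinoma cohort\n")
  cat("  probes:    ", nrow(x$expression), "\n")
  cat("  specimens: ", ncol(x$expression), " (",
      paste(table(x$metadata$class_label), collapse = " / "), ")\n", sep = "")
  cat("  planted markers:", sum(x$truth$role != "null"),
      " planted QC failures:", sum(x$metadata$qc_planted), "\n")
  invisible(x)
}

#' Expand a cohort into adjacent replicate sections
#'
#' Emulates cutting adjacent thin sections from each FFPE tissue block:
#' every specimen yields `n_sections` correlated copies that share its
#' biological signal and differ by within-block measurement noise on the
#' log2 scale. Section and block identifiers are recorded so downstream
#' reproducibility analyses can pair sections of a block.
#'
#' @param cohort a `syn_cohort`.
#' @param n_sections sections per block (>= 2).
#' @param within_block_sd log2-scale noise between adjacent sections;
#'   `0` makes all sections of a block identical.
#' @param seed integer seed.
#' @return A `syn_cohort` whose expression has one column per section and
#'   whose metadata carries `section_id` and the originating `block_id`.
#' @export
generate_replicate_sections <- function(cohort, n_sections, within_block_sd,
                                        seed = cohort$config$seed) {
  stopifnot(inherits(cohort, "syn_cohort"))
  stopifnot_scalar(n_sections, "n_sections", min = 2, integer = TRUE)
  stopifnot_scalar(within_block_sd, "within_block_sd", min = 0)
  p <- nrow(cohort$expression)
  n <- ncol(cohort$expression)
  signal <- log2(cohort$expression)
  idx <- rep(seq_len(n), each = n_sections)
  log2x <- signal[, idx, drop = FALSE] +
    with_seed(substream_seed(seed, 9),
              matrix(rnorm(p * n * n_sections, 0, within_block_sd),
                     p, n * n_sections))
  metadata <- cohort$metadata[idx, , drop = FALSE]
  metadata$section_id <- rep(seq_len(n_sections), times = n)
  metadata$specimen_id <- paste0(metadata$block_id, "_s",
                                 metadata$section_id)
  rownames(metadata) <- NULL
  expression <- 2^log2x
  dimnames(expression) <- list(rownames(cohort$expression),
                               metadata$specimen_id)
  structure(list(expression = expression, metadata = metadata,
                 truth = cohort$truth, config = cohort$config),
            class = "syn_cohort")
}

#' Write a cohort's artifacts as plain text
#'
#' Expression goes to a tab-delimited matrix (`probe_id` then one column
#' per specimen), metadata to CSV, and the probe-level truth table
#' (marker role and planted effect; test-harness use only) to CSV.
#'
#' @param cohort a `syn_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "syn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.csv"))
  write_expression(cohort$expression, paths[["expression"]])
  utils::write.csv(cohort$metadata, paths[["metadata"]], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}

#' Read / write a probes-x-specimens expression matrix as TSV
#'
#' The interchange format is tab-delimited text with a `probe_id` header
#' column followed by one column per specimen; missing values are
#' forbidden.
#'
#' @param x numeric matrix with probe rownames and specimen colnames.
#' @param path file path.
#' @return `write_expression` returns `path` invisibly; `read_expression`
#'   returns the matrix.
#' @export
write_expression <- function(x, path) {
  stopifnot(is.matrix(x), !anyNA(x))
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (anyNA(df)) stop("expression matrix contains missing values")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}
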