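#' @keywords internal
"_PACKAGE"

# Class labels used throughout: the two squamous carcinoma origins.
CLASS_LEVELS <- c("HNSCC", "LUNG_SCC")

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the
#' caller's RNG state afterwards, so package functions are deterministic
#' without clobbering the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a sub-stream seed from a master seed by a fixed offset, kept
# within the 32-bit integer range.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 10007 * offset) %% .Machine$integer.max)
}

# Round half away from zero (table-style rounding, so 0.5 -> 1).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf,
                             integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("configuration error: '", name, "' must be a single number",
         call. = FALSE)
  if (integer && x != floor(x))
    stop("configuration error: '", name, "' must be an integer",
         call. = FALSE)
  if (x < min || x > max)
    stop("configuration error: '", name, "' must be in [", min, ", ",
         max, "]", call. = FALSE)
  invisible(x)
}

# md5 of the canonical JSON serialization of a config list; used to stamp
# pipeline artifacts so reruns are identifiable.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tf)
  unname(tools::md5sum(tf))
}
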