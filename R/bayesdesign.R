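#' Bayesian adaptive validation design specification
#'
#' Encodes the group-sequential acceptance design used to validate the
#' test: per-class Beta-binomial posteriors for the positive percent
#' agreement (PPA), interim analyses ("looks") at fixed fractions of the
#' maximum sample size, acceptance when every class's posterior mean PPA
#' is at least 0.80 and the lower bound of its 95% equal-tailed credible
#' interval is at least 0.65, and futility stopping when the predictive
#' probability of eventual success falls below 0.05.
#'
#' @param n_max maximum specimens per class.
#' @param look_fractions strictly increasing fractions of `n_max` at
#'   which looks occur; the last must be 1. Per-class look sizes are
#'   rounded half-up.
#' @param prior Beta prior shape pair `(alpha, beta)` used for every
#'   class.
#' @param mean_threshold minimum posterior mean PPA for acceptance.
#' @param lower_threshold minimum lower credible bound for acceptance.
#' @param credible_level credible level of the equal-tailed interval.
#' @param futility_threshold stop for futility when the predictive
#'   probability of success falls below this.
#' @param pps_draws Monte Carlo draws used when exact enumeration of the
#'   predictive probability is infeasible.
#' @param seed integer seed for Monte Carlo paths.
#' @return A list of class `design_spec`; `look_n` holds the per-class
#'   look sample sizes.
#' @export
design_spec <- function(n_max = 50, look_fractions = c(0.5, 0.75, 1),
                        prior = c(1, 1), mean_threshold = 0.80,
                        lower_threshold = 0.65, credible_level = 0.95,
                        futility_threshold = 0.05, pps_draws = 10000,
                        seed = 1) {
  stopifnot_scalar(n_max, "n_max", min = 1, integer = TRUE)
  if (!is.numeric(look_fractions) || length(look_fractions) < 1 ||
      any(diff(look_fractions) <= 0) ||
      utils::tail(look_fractions, 1) != 1 || any(look_fractions <= 0))
    stop("configuration error: 'look_fractions' must be strictly ",
         "increasing with last element 1", call. = FALSE)
  stopifnot(is.numeric(prior), length(prior) == 2, all(prior > 0))
  stopifnot_scalar(mean_threshold, "mean_threshold", min = 0, max = 1)
  stopifnot_scalar(lower_threshold, "lower_threshold", min = 0, max = 1)
  stopifnot_scalar(credible_level, "credible_level", min = 0, max = 1)
  stopifnot_scalar(futility_threshold, "futility_threshold",
                   min = 0, max = 1)
  stopifnot_scalar(pps_draws, "pps_draws", min = 1, integer = TRUE)
  structure(list(
    n_max = as.integer(n_max),
    look_fractions = look_fractions,
    look_n = as.integer(round_half_up(look_fractions * n_max)),
    prior = as.numeric(prior),
    mean_threshold = mean_threshold,
    lower_threshold = lower_threshold,
    credible_level = credible_level,
    futility_threshold = futility_threshold,
    pps_draws = as.integer(pps_draws),
    seed = as.integer(seed)
  ), class = "design_spec")
}

#' Beta posterior summary of a class's PPA
#'
#' With `x` agreements in `n` specimens and a `Beta(alpha, beta)` prior,
#' the PPA posterior is `Beta(x + alpha, n - x + beta)`; the summary
#' reports its mean and equal-tailed credible bounds.
#'
#' @param x agreements (0 <= x <= n).
#' @param n specimens.
#' @param prior Beta shape pair.
#' @param level credible level.
#' @return A list of class `posterior_summary`: `successes`, `n`,
#'   `mean`, `lower`, `upper`, `prior`, `level`.
#' @examples
#' posterior_ppa(31, 38)  # mean 0.800
#' @export
posterior_ppa <- function(x, n, prior = c(1, 1), level = 0.95) {
  stopifnot_scalar(n, "n", min = 0, integer = TRUE)
  stopifnot_scalar(x, "x", min = 0, max = n, integer = TRUE)
  a <- x + prior[1]; b <- n - x + prior[2]
  tail <- (1 - level) / 2
  structure(list(successes = x, n = n,
                 mean = a / (a + b),
                 lower = stats::qbeta(tail, a, b),
                 upper = stats::qbeta(1 - tail, a, b),
                 prior = prior, level = level),
            class = "posterior_summary")
}

# Does (x, n) meet both acceptance thresholds?
meets_acceptance <- function(x, n, design) {
  a <- x + design$prior[1]; b <- n - x + design$prior[2]
  mean_ok <- a / (a + b) >= design$mean_threshold
  lower_ok <- stats::qbeta((1 - design$credible_level) / 2, a, b) >=
    design$lower_threshold
  mean_ok & lower_ok
}

# Smallest success count meeting acceptance at sample size n (NA if none;
# acceptance is monotone in x at fixed n).
acceptance_min_successes <- function(n, design) {
  ok <- meets_acceptance(0:n, n, design)
  if (!any(ok)) return(NA_integer_)
  as.integer(min(which(ok)) - 1L)
}

# P(final success count >= smin | x successes of n so far), under the
# Beta-binomial posterior predictive for the remaining n_max - n.
bb_tail <- function(x, n, design) {
  m <- design$n_max - n
  smin <- acceptance_min_successes(design$n_max, design)
  if (is.na(smin)) return(0)
  need <- smin - x
  if (need <= 0) return(1)
  if (need > m) return(0)
  y <- 0:m
  a <- x + design$prior[1]; b <- n - x + design$prior[2]
  pr <- exp(lchoose(m, y) + lbeta(a + y, b + m - y) - lbeta(a, b))
  sum(pr[y >= need])
}

#' Predictive probability of success at the maximum sample size
#'
#' The probability, under the current per-class Beta posteriors and the
#' Beta-binomial posterior-predictive distribution of the remaining
#' outcomes, that every class will meet both acceptance thresholds at
#' the final look. Computed by exact enumeration over the remaining
#' success counts when the per-class remainder is at most 200, otherwise
#' by seeded Monte Carlo.
#'
#' @param x_by_class agreements so far, one per class.
#' @param n_current current per-class sample size (< `n_max`).
#' @param design a [design_spec()].
#' @param method `"auto"` (enumeration when feasible), `"exact"`, or
#'   `"mc"`.
#' @return Probability in `[0, 1]`.
#' @export
predictive_probability_of_success <- function(x_by_class, n_current,
                                              design,
                                              method = c("auto", "exact",
                                                         "mc")) {
  method <- match.arg(method)
  stopifnot_scalar(n_current, "n_current", min = 0, integer = TRUE)
  if (n_current >= design$n_max)
    stop("n_current must be smaller than the design maximum ",
         design$n_max, call. = FALSE)
  stopifnot(all(x_by_class >= 0), all(x_by_class <= n_current))
  m <- design$n_max - n_current
  use_exact <- method == "exact" || (method == "auto" && m <= 200)
  if (use_exact)
    return(prod(vapply(x_by_class, bb_tail, 0, n = n_current,
                       design = design)))
  smin <- acceptance_min_successes(design$n_max, design)
  if (is.na(smin)) return(0)
  with_seed(design$seed, {
    ok <- rep(TRUE, design$pps_draws)
    for (x in x_by_class) {
      p <- stats::rbeta(design$pps_draws, x + design$prior[1],
                        n_current - x + design$prior[2])
      y <- stats::rbinom(design$pps_draws, m, p)
      ok <- ok & (x + y >= smin)
    }
    mean(ok)
  })
}

#' Evaluate one interim analysis (look) of the adaptive design
#'
#' Accepts when every class meets both thresholds (posterior mean PPA
#' and lower credible bound); otherwise computes the predictive
#' probability of success and stops for futility when it falls below the
#' design threshold; otherwise continues. At the final look the decision
#' is accept or fail — there is no continuation.
#'
#' @param x_by_class per-class agreements at this look.
#' @param n_by_class per-class sample sizes; must match the look
#'   schedule.
#' @param look look index (1-based).
#' @param design a [design_spec()].
#' @return A list of class `look_decision`: `look`, `posteriors` (one
#'   [posterior_ppa()] summary per class), `decision` (`"accept"`,
#'   `"continue"`, `"stop_futility"`, or `"fail"`), and `pps` (when
#'   computed).
#' @examples
#' evaluate_look(c(HNSCC = 31, LUNG_SCC = 32), c(38, 38), look = 2,
#'               design_spec())$decision  # "accept"
#' @export
evaluate_look <- function(x_by_class, n_by_class, look, design) {
  stopifnot(inherits(design, "design_spec"))
  if (!(look %in% seq_along(design$look_n)))
    stop("look index ", look, " outside the design schedule", call. = FALSE)
  if (!all(n_by_class == design$look_n[look]))
    stop("per-class sample sizes ", paste(n_by_class, collapse = ", "),
         " do not match the look-", look, " schedule (",
         design$look_n[look], " per class)", call. = FALSE)
  posteriors <- mapply(posterior_ppa, x_by_class, n_by_class,
                       MoreArgs = list(prior = design$prior,
                                       level = design$credible_level),
                       SIMPLIFY = FALSE)
  final <- look == length(design$look_n)
  all_pass <- all(meets_acceptance(x_by_class, n_by_class[1], design))
  pps <- NA_real_
  decision <- if (all_pass) "accept"
  else if (final) "fail"
  else {
    pps <- predictive_probability_of_success(x_by_class, n_by_class[1],
                                             design)
    if (pps < design$futility_threshold) "stop_futility" else "continue"
  }
  structure(list(look = look, posteriors = posteriors,
                 decision = decision, pps = pps),
            class = "look_decision")
}

#' @export
print.look_decision <- function(x, ...) {
  cat("Look", x$look, "decision:", x$decision, "\n")
  for (i in seq_along(x$posteriors)) {
    p <- x$posteriors[[i]]
    cat(sprintf("  class %s: %d/%d, posterior mean %.3f, %g%% CrI [%.3f, %.3f]\n",
                names(x$posteriors)[i] %||% i, p$successes, p$n,
                p$mean, 100 * p$level, p$lower, p$upper))
  }
  if (!is.na(x$pps))
    cat(sprintf("  predictive probability of success: %.4f\n", x$pps))
  invisible(x)
}

#' Simulate the design's operating characteristics
#'
#' Draws per-class binomial data at each look under given true PPA
#' values, applies the look decisions (early acceptance, futility stop,
#' final accept/fail), and aggregates acceptance and futility rates, the
#' expected per-class sample size, and the distribution of stopping
#' looks. The simulation is vectorized over replicates but uses the same
#' acceptance boundaries and predictive-probability function as
#' [evaluate_look()], tabulated over all reachable success counts.
#'
#' @param design a [design_spec()].
#' @param true_ppa_by_class true per-class PPA (recycled to two classes
#'   if scalar).
#' @param n_reps simulation replicates.
#' @param seed integer seed.
#' @return List: `acceptance_rate`, `futility_rate`, `fail_rate`,
#'   `expected_n_per_class`, `look_stop` (data frame of per-look stop
#'   counts by reason), `n_reps`.
#' @export
simulate_operating_characteristics <- function(design, true_ppa_by_class,
                                               n_reps, seed = design$seed) {
  stopifnot(inherits(design, "design_spec"))
  stopifnot_scalar(n_reps, "n_reps", min = 1, integer = TRUE)
  p_true <- rep_len(true_ppa_by_class, 2)
  looks <- design$look_n
  L <- length(looks)
  amin <- vapply(looks, acceptance_min_successes, integer(1),
                 design = design)
  # pps lookup per non-final look: value for every possible x
  pps_tab <- lapply(seq_len(max(L - 1, 0)), function(l)
    vapply(0:looks[l], bb_tail, 0, n = looks[l], design = design))

  with_seed(seed, {
    x1 <- x2 <- integer(n_reps)
    status <- rep("active", n_reps)
    stop_look <- rep(NA_integer_, n_reps)
    nprev <- 0L
    for (l in seq_len(L)) {
      inc <- looks[l] - nprev
      active <- status == "active"
      x1[active] <- x1[active] + stats::rbinom(sum(active), inc, p_true[1])
      x2[active] <- x2[active] + stats::rbinom(sum(active), inc, p_true[2])
      pass <- active & !is.na(amin[l]) & x1 >= amin[l] & x2 >= amin[l]
      status[pass] <- "accept"; stop_look[pass] <- l
      active <- status == "active"
      if (l < L) {
        pps <- pps_tab[[l]][x1 + 1] * pps_tab[[l]][x2 + 1]
        fut <- active & pps < design$futility_threshold
        status[fut] <- "stop_futility"; stop_look[fut] <- l
      } else {
        status[active] <- "fail"; stop_look[active] <- l
      }
      nprev <- looks[l]
    }
    look_stop <- as.data.frame(table(look = factor(stop_look,
                                                   levels = seq_len(L)),
                                     reason = factor(status)),
                               responseName = "count")
    list(acceptance_rate = mean(status == "accept"),
         futility_rate = mean(status == "stop_futility"),
         fail_rate = mean(status == "fail"),
         expected_n_per_class = mean(looks[stop_look]),
         look_stop = look_stop,
         n_reps = n_reps)
  })
}
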