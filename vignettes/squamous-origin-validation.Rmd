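---
title: "Methods: a similarity-score classifier for squamous tissue-of-origin and its Bayesian adaptive validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: squamous tissue-of-origin classification and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Squamous cell carcinomas arising in the head & neck (HNSCC) and in the
lung (lung SCC) are frequently indistinguishable by histology and by the
common squamous immunomarkers, yet the two diagnoses imply opposite
management for a patient presenting with a lung nodule after head & neck
cancer: a second lung primary is aggressively resectable, a metastasis is
not. A gene-expression classifier on FFPE tissue can resolve the
differential. `squamdx` implements the full analysis chain of such a
test — quality gating, standardization, a calibrated two-class
similarity-score classifier, exact diagnostic-accuracy statistics, a
Bayesian adaptive acceptance design, and reproducibility analytics — with
a synthetic-cohort generator standing in for the proprietary assay data,
so that every stage is exercised by tests that need no external download.

# The synthetic cohort generator

`generate_cohort()` draws log2 intensities as

$$\log_2 X_{ij} = \mu_0 + a_i + b_j + s_{\ell(j)} +
  \Delta_i\,[\text{class}(j)\ \text{matches marker direction}\ i] +
  \varepsilon_{ij},$$

with fixed per-probe effects $a_i \sim N(0, 2^2)$, per-specimen baselines
$b_j \sim N(0, 0.5^2)$, a scalar batch shift $s_\ell \sim N(0, 0.5^2)$
for each of 3 processing laboratories, FFPE noise
$\varepsilon_{ij} \sim N(0, 0.5^2)$, and a planted class shift
$\Delta_i$ (default 2 log2 units) on marker probes. Intensities are
exponentiated, so they are strictly positive (a log-normal model, the
simplest family matching raw microarray intensities). Defaults: 2000
probes; 12 lung-up and 8 HN-up markers, mirroring the directional split
seen among the top markers of squamous-origin panels, where
surfactant-type lung markers outnumber keratin-type head & neck markers;
40 specimens per class, giving the 80-specimen scale of a clinical
validation run.

Two QC-breaking artifacts are planted in `round(rate × n)` specimens
(default rate 5%, hence 4 of 80): a *globally dark* array, realized by
compressing the log2 dynamic range toward the specimen median by a factor
0.35, which collapses the median-to-background ratio; and a *dark
block*, one cell of the 4 × 4 spatial partition dimmed by 4 log2 units.
Metadata attributes (tumor and necrotic content, grade, stage, patient
and specimen age, biopsy site, metastatic status) are drawn from bin
frequencies shaped like a 76-specimen squamous validation cohort so that
stratified reporting is exercised; the frequencies are defaults, not
contracts. A single master seed drives fixed-offset sub-streams for probe
effects, site shifts, noise, artifact placement and metadata, so a cohort
is a pure function of its configuration.

What the generator does *not* emulate: probe sequence effects, scanner
physics, intensity-dependent (heteroscedastic) noise, correlated gene
modules, or class-overlapping marker distributions. Passing tests
therefore demonstrate that the pipeline's logic and statistics are
correct under a controlled model, not that the classifier would attain
any particular accuracy on real tumors.

# Quality control

Entry gating applies the assay's specimen rules with inclusive
thresholds exactly as printed on test requisitions of this kind: tumor
content ≥ 60%, RNA yield ≥ 30 ng at concentration ≥ 9.5 ng/µl,
A260/A280 ≥ 1.0, labeled cDNA ≥ 2.5 µg. Each violated rule is reported
once, so a failing specimen's record is auditable.

The three array metrics are gated at Overall Signal ≥ 10, Percent
Present ≥ 5 and Regional Discontinuity ≤ 0.84. Their original formulas
live in proprietary prior work; the package uses documented,
threshold-compatible proxies — median/background ratio (background =
2.5th intensity percentile), percent of probes above twice background,
and the maximum deviation of a 4 × 4 grid block's mean log2 intensity
from the global mean. These proxies preserve the *gating logic*, which is
what the validation analysis depends on. Two numerical consequences are
worth knowing: the metrics are invariant under uniform multiplicative
brightening (a gain change does not alter pass/fail), and the
regional-discontinuity proxy needs enough probes per block
(≈ 50 or more) for a clean array's block means to sit safely inside the
0.84 band; tiny toy arrays can fail it spuriously.

# Standardization

The clinical workflow standardizes one specimen at a time, so cohort-wise
normalization is not an option. `fit_reference()` freezes a reference
distribution at training time — quantile $k$ is the mean across training
specimens of the $k$-th smallest log2 intensity — and
`apply_standardization()` rank-transforms a specimen and substitutes the
reference quantiles, with ties sharing the mean of the spanned
quantiles. This removes any monotone specimen-level distortion, in
particular additive log2 batch shifts, exactly; it is idempotent; and all
standardized specimens share the same sorted values by construction. The
tie rule makes the map deterministic.

# The classifier

The published description of tests in this family states only that
selected probe sets and coefficients combine into two similarity scores;
a regularized linear model with a logistic link is the minimal family
matching that description and is what the package fits. Training uses
nested cross-validation (default 5 × 5, stratified): the inner loop picks
the feature count (top probes by absolute two-sample t statistic,
re-ranked inside each training split) and the ridge penalty by inner-CV
binomial deviance via `glmnet`; the outer loop supplies an accuracy
estimate from specimens never touched by selection — on pure-noise data
this estimate sits at chance level, which the suite checks explicitly.
The final model is refit on all data with the selected hyperparameters.

Scores must be interpretable as probabilities, so the raw model output is
passed through a monotone Platt calibration fit on the pooled outer-fold
held-out predictions (the only predictions that are honest about
generalization). The slope is clamped non-negative so the calibration map
is monotone non-decreasing even in degenerate fits. The HNSCC similarity
score is 100 × the calibrated probability and the lung SCC score is its
complement: the pair sums to 100 identically. Reporting precision is one
decimal; a tie at that precision — both scores 50.0 — is reported as
indeterminate, since no tie-break rule is defined for such reports.
Marker ranking orders selected probes by |coefficient| × SD and labels
each with the class whose mean expression is higher, reproducing the
"tissue type with higher expression" layout of published marker tables.

# Diagnostic statistics

All proportions (per-class and overall PPA, stratified PPA, concordance)
carry exact equal-tailed Clopper-Pearson intervals from Beta quantiles.
The choice is deliberate: it is the only standard method whose 3-of-3 bin
reproduces a lower bound of $100 \times 0.025^{1/3} = 29.2$, the value
such tables print. Percents are reported to one decimal, rounding half
up. The diagnostic odds ratio is $(a d)/(b c)$ on the
call-versus-diagnosis table with the log-method interval; a zero cell
triggers the Haldane-Anscombe 0.5 correction, flagged in the result. The
Fisher exact comparison of per-class agreement rates uses the standard
"probability mass ≤ observed" two-sided convention via
`stats::fisher.test`, verified in the suite against hypergeometric
enumeration. AUC is computed by Mann-Whitney rank counting (ties count
half), verified against brute-force pair counting and `pROC`.

# The Bayesian adaptive validation design

The primary endpoint is the per-class PPA under a Beta-binomial model.
With prior $\text{Beta}(\alpha, \beta)$ and $x$ agreements in $n$, the
posterior is $\text{Beta}(x+\alpha,\, n-x+\beta)$. The design accepts
when *both* classes satisfy posterior mean ≥ 0.80 and 2.5th posterior
percentile ≥ 0.65. The per-class reading (rather than criteria on the
class average) follows the published phrasing that both cancer types
exceeded the thresholds, and is the stricter of the two readings.

Looks occur at 1/2, 3/4 and 1 of the per-class maximum, rounded half-up.
The published study's design supplement is not available, so the package
fixes defaults that reproduce its visible structure: maximum 50 per
class, making Look 2 equal 38 per class — matching a 76-specimen second
look — with flat Beta(1, 1) priors and equal-tailed intervals. Under
these defaults the acceptance boundaries are 21/25, 31/38 and 41/50
agreements, and the observed-style interim data (31/38, 32/38) accept at
Look 2 with posterior means 0.800 and 0.825.

At a non-final look that misses acceptance, the predictive probability of
success (PPS) is the probability, under the Beta-binomial
posterior-predictive distribution of the remaining outcomes, that the
final look accepts; since acceptance at fixed $n$ is monotone in $x$, the
per-class PPS is a Beta-binomial tail above the final boundary, and the
two classes multiply. PPS is computed by exact enumeration whenever at
most 200 specimens per class remain (always, under the defaults), and by
seeded Monte Carlo otherwise; the two routes are cross-checked within
Monte-Carlo error in the suite. PPS < 0.05 stops for futility. The final
look admits only accept or fail.

`simulate_operating_characteristics()` vectorizes this design over
replicates, tabulating the same acceptance boundaries and the same PPS
function it would use at a single look. At 10,000 replicates the default
design's simulated acceptance rate is bounded by 5% when the true
per-class PPA is 0.65 and exceeds 98% when it is 0.95 — the type-I and
power targets such designs are built to — and `scripts/acceptance.R`
recomputes both rates from scratch at that replicate count in seconds.

# Reproducibility analytics

Adjacent-section replicates (`generate_replicate_sections()`) share a
block's signal and differ by within-block log2 noise (default 0.15 in the
pipeline's `reproduce` stage — small against a planted effect of 2, so
synthetic concordance runs near 100%, higher than the ~90% of real
inter-laboratory studies; the synthetic model has no section-to-section
tumor heterogeneity). Concordance over pairs of sections or sites uses
the same exact intervals as PPA; blocks with a missing call in either
member are excluded, which is how real studies end up with denominators
smaller than their block counts. Cohen's kappa uses marginal-frequency
expected agreement with the simple large-sample variance
$p_o(1-p_o)/(n(1-p_e)^2)$ — the published kappa CI method for such
tables is rarely stated, and this is the common default — and a
degenerate table (both raters constant and identical) returns a flagged
undefined result rather than a number. The %CV of replicate similarity
scores uses the sample (n − 1) standard deviation; the median across
blocks is the summary.

# Numerical and design choices

* **Seeds.** Every stochastic function takes a seed and restores the
  caller's RNG state; sub-streams derive from the master seed by fixed
  offsets, so artifacts are bit-stable across reruns and machines.
* **Rounding.** Table-style rounding is half-up (82.85 → 82.9), applied
  only at the reporting layer; all statistics are computed at full
  precision.
* **Degenerate inputs.** Single-class training data, empty pair sets,
  all-zero agreement tables, zero-mean CV blocks and out-of-schedule
  looks raise immediate, named errors rather than propagating NaN.
* **Problem sizes.** The test suite runs its heaviest checks at 2000
  probes and 100 specimens per class (classifier recovery) and 10,000
  replicates (design operating characteristics); both complete in
  seconds to a couple of minutes on a single core, which is the scale a
  reviewer can rerun casually.

# Limitations

The standardization and classifier are principled stand-ins for
unpublished proprietary algorithms: quantile normalization to a frozen
reference, and ridge logistic regression with calibrated outputs. They
reproduce the *published structure* (single-specimen operation, two
scores summing to 100, nested-CV honesty) but not the original
coefficients, probe list, or clinical accuracy. Likewise the array QC
metrics are threshold-compatible proxies, and the adaptive design's
maximum sample size and priors are stated defaults consistent with the
visible look structure, not recovered values. Conclusions from this
package about real specimens require real validation data.
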