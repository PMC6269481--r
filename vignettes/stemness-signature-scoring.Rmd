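---
title: "Rank-based stemness signature scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based stemness signature scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemscore)
```

# The problem

Embryonal tumors such as neuroblastoma can retain gene-regulatory
programs of embryonic stem cells (ESCs), and the strength of such a
program in an individual tumor is a candidate marker of aggressiveness
and therapy resistance.  `stemscore` quantifies that program from bulk
expression data with a per-sample rank statistic, links it to patient
outcome, and extends it from the miRNA compartment (where ESC programs
are sharply defined — the miR-302/367 cluster up, the let-7 family down)
to a correlated mRNA signature that is amenable to functional
enrichment analysis.

This vignette explains each model, its assumptions, the tunable
parameters, and the numerical choices made where the design was
genuinely open.

# The rank-sum signature score

For each sample, expression values of all $G$ measured features are
converted to within-sample ranks, rank 1 for the lowest-expressed
feature, midranks for ties.  For a directional signature with up-set $U$
and down-set $D$, the score of sample $j$ is

$$S_j \;=\; \frac{1}{G}\,\overline{r}_{U,j} \;-\; \frac{1}{G}\,\overline{r}_{D,j},$$

where $\overline{r}_{U,j}$ is the mean rank of the up members present in
the matrix.  An empty direction contributes zero.

Three choices here deserve comment:

* **Subtraction of the down-member term.**  With a two-direction
  signature, a plain sum of signature-member ranks would reward high
  expression of members that are expected *low* in the ESC state.
  Up-minus-down is the only convention under which "high score =
  ESC-like", which is the orientation all survival readouts in this
  package assume.
* **Means and the $1/G$ normalization.**  Dividing by $G$ and averaging
  within each direction makes scores comparable across matrices of
  different size and signatures with unequal up/down counts; scores lie
  in $(-1, 1)$.  Since all downstream uses are rank-based (median split,
  Spearman correlations), any affine rescaling of the score would leave
  every downstream result unchanged — the normalization is purely for
  interpretability.
* **Invariance.**  Only within-sample ranks enter, so the score is
  exactly invariant to strictly increasing transforms applied per sample
  (log bases, quantile maps, platform-monotone distortions), and each
  sample's score does not depend on any other sample.  Both properties
  are enforced by tests.

**Coverage guard.**  Scoring requires at least `min_coverage` (default
0.5) of each nonempty direction to be present among the matrix features;
below that the score is considered unreliable and scoring errors out
naming the missing members, rather than silently computing a score from
a sliver of the signature.  Missing expression values are rejected at
load: the rank transform is undefined on missing data and no imputation
rule is part of this method.

**Median dichotomization.**  Groups are `high` (score strictly above the
cohort median) versus `low`.  Samples exactly at the median go to `low`
— a deterministic tie-break; an exactly equal split is impossible for
odd $n$ or tied medians.  A cohort of identical scores has no
informative split and errors.

# Consensus signature construction

Published ESC differential-expression lists disagree; the consensus rule
keeps feature $f$ as "up" when at least `min_support` sources list it as
up (symmetrically for "down"), counting each source once regardless of
within-source duplicates.  A feature reaching the threshold in *both*
directions is contradictory across the literature; it is excluded and
reported in a conflict attribute rather than assigned a direction
arbitrarily.  One corner case follows from this rule: a feature
conflict-excluded at a low threshold can re-enter at a higher threshold
if only one of its directions keeps sufficient support — so "raising the
threshold only shrinks the signature" holds exactly only when sources
are direction-consistent.  An empty consensus (nothing reaches support)
is an error, because an empty signature cannot score anything.

# Derived mRNA signature

Genes are ranked by the Pearson correlation of their expression with the
miRNA score across the cohort; the derived signature is the top `n`
(default 500) genes, all required to have strictly positive correlation
— the derived signature marks genes co-expressed with the stemness
program, so it is all-"up" by construction and a cohort without enough
positively correlated genes is an error, not a shorter list.  Ties at
the boundary are broken lexicographically (C locale) for determinism.
Zero-variance genes have no defined correlation and are excluded with a
report.  "Protein-coding" filtering is the caller's responsibility: the
package takes whatever gene universe the input matrix provides and
bundles no genome annotation.

# Survival analysis

* **Kaplan–Meier curves** use the product-limit estimator with the
  standard convention that subjects censored at an event time remain in
  the risk set at that time.  Fitting is delegated to
  `survival::survfit`; the container retains per-event-time risk sets,
  event counts, survival and Greenwood variance.
* **Landmark survival** intervals use the log-log (complementary
  log-log) transform of the Greenwood variance, which respects $[0,1]$
  and yields the asymmetric intervals appropriate for survival
  fractions near the boundaries; at $\hat S = 0$ or $1$ the transform
  degenerates and the interval collapses to the point estimate.
  Evaluation beyond the last follow-up carries the estimate forward
  with an explicit extrapolation flag and warning.
* **Log-rank test** (via `survival::survdiff`): observed versus
  hypergeometric-expected events summed over distinct event times,
  tie-corrected variance, $\chi^2_1$ reference.  Tests verify the
  statistic against an independently coded per-event-time 2×2
  evaluation, label-swap and monotone-time invariance, and type-I
  calibration on null cohorts.
* **Outcome-restricted logistic regression.**  Because censored
  short-follow-up patients provide no binary outcome, the logistic model
  uses only patients who died of disease or survived event-free for at
  least `min_followup` (default 3) years.  The fit is standard IRLS
  (tolerance $10^{-8}$, at most 100 iterations) with Wald per-covariate
  p-values — the convention matching per-covariate odds-ratio-plus-p
  reporting.  The score can enter dichotomized (high-group indicator,
  the default) or continuous; both are exposed because either reading is
  defensible for a "median cut-off" model.  Quasi-complete separation is
  flagged (any standardized coefficient beyond 15, or IRLS
  non-convergence) and the fit is returned with `converged = FALSE`
  rather than silently reporting astronomical odds ratios.

No Cox model is provided: the survival claims this workflow makes are
the KM/log-rank stratification and the restricted logistic model, and
adding a semi-parametric hazard model would change the estimand.  No
multiplicity correction is applied across subgroup analyses.

# Enrichment statistics

The pre-ranked enrichment score walks the ranked list with increments
$|s_g|^w / \sum_{set}|s_g|^w$ at set members and decrements
$1/(N - n_{hit})$ otherwise; ES is the maximum deviation of the running
sum.  `weight_exponent` defaults to 1 (the published GSEA default);
0 reduces ES to the classic Kolmogorov–Smirnov statistic.  Ties in the
ranking statistic keep their list position — the ranked input order is
authoritative.  Implementation detail: the extremum of the running sum
can only occur immediately after a hit or immediately before one, so ES
is evaluated at $O(n_{hit})$ candidate positions; tests compare against
a full cumulative-sum brute force and against `fgsea`'s statistic.

The null is gene-permutation (random same-size sets from the ranked
list), the appropriate null when the ranking arrives precomputed, as it
does here (correlation- or t-statistic-ranked lists).  NES divides ES by
the mean absolute null ES of matching sign.  Permutation p-values use
the add-one convention $(k+1)/(m+1)$ over same-sign nulls, which is
exactly rank-uniform under the null and can never report zero (its floor
is $1/(n_{perm}+1)$); the plain fraction-with-floor alternative is
measurably conservative at these permutation counts.  FDR q-values use
the sign-stratified NES-ratio procedure: within each sign, the fraction
of pooled normalized null NES at least as extreme divided by the
fraction of observed NES at least as extreme, clipped to $[0,1]$.

Gene-list overlap uses the one-sided (enrichment) hypergeometric tail;
the odds ratio is the plain 2×2 cross-ratio $ad/bc$ (not the
conditional-MLE estimate `fisher.test` reports), with the Haldane 0.5
correction applied to the odds ratio only when a cell is zero, and
flagged.  Group comparisons are Welch's t or the Mann–Whitney rank-sum
test with tie-corrected normal approximation, both two-sided.

# The synthetic cohort generator

Real miRNA/mRNA cohorts with outcome cannot ship with a package, and
cohort-level results depend on them; validation therefore runs on
synthetic cohorts whose generating truth is known.  A single latent
"stemness" factor $s_i \sim N(0,1)$ drives everything:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 200 | cohort size, matching the scale of a large tumor series |
| `n_mirna` / `n_up` / `n_down` | 400 / 33 / 27 | miRNA features; member counts equal the packaged signature's column sizes, so that signature applies to synthetic cohorts unchanged |
| `n_mrna` / `n_driver_genes` | 10000 / 500 | coding-gene compartment and planted positively loaded drivers (the derived-signature size) |
| `effect_size` | 1.0 | expression shift per latent s.d. (log-scale units); a clear but noisy single-gene signal (signal-to-noise 1) |
| `noise_sd` | 1.0 | residual expression s.d. |
| `hazard_log_ratio` | 0.7 | log hazard ratio per latent s.d. — a strong prognostic factor (HR $\approx$ 2 per s.d.) |
| `baseline_hazard` | 0.1 /year | exponential baseline; with 10-year uniform censoring this yields roughly 35–40% observed events |
| `censoring_horizon` | 10 years | administrative censoring, pediatric-cohort follow-up scale |
| `amp_intercept`, `amp_slope` | −2, 1.5 | amplification logit: $\approx$ 15–20% amplified, strongly enriched at high factor values |

Up members have mean $+\beta s_i$, down members $-\beta s_i$,
background features mean 0, all with independent Gaussian noise on a
log-like scale.  Because the scorer consumes only within-sample ranks,
any monotone-equivalent generative family would produce identical
downstream behavior; Gaussian-additive is the simplest faithful choice.
Survival is exponential with hazard $\lambda_0 e^{\delta s_i}$ under
independent uniform censoring — the minimal proportional-hazards model
with closed-form marginal event rates.  The clinical table also needs
stage and age covariates, which the generator's core model does not
define; they are filled with a mildly factor-associated stage-4 label
(logit $-0.5 + 0.5 s_i$, reflecting that high-stage disease is enriched
for the aggressive phenotype) and an independent Bernoulli(0.6) age
indicator, chosen once as cohort-realistic.  The planted mRNA drivers
are all positively loaded, matching the all-"up" character of the
derived signature.

What the generator deliberately does **not** emulate: platform- or
batch-specific noise, probe effects, miRNA–target regulatory coupling
between the two matrices, non-proportional hazards, or informative
censoring.  Passing parameter-recovery tests therefore demonstrates
correctness of the statistical machinery under the stated model, not
robustness to the artifacts of real microarray/RNA-seq cohorts — and
published cohort-level numbers (specific odds ratios or survival
percentages) are properties of real patient data that synthetic cohorts
are not expected to reproduce.

```{r recovery, eval = FALSE}
cohort <- simulate_cohort(simulation_config(seed = 1))
scores <- signature_score(cohort$mirna, esc_mirna_signature())
cor(scores$score, cohort$truth$latent, method = "spearman")
ranked <- correlate_genes_with_score(cohort$mrna, scores)
truth_recovery_report(cohort, derive_top_signature(ranked, 500))$precision
```

# Validation design and problem sizes

The test suite validates by dual routes wherever possible: every
nontrivial statistic is checked against an independently coded oracle
(counting-based midranks for the score, full cumulative running sums and
`fgsea` for ES, explicit `choose()` tails for the hypergeometric,
per-event-time 2×2 tables for the log-rank, the closed-form 2×2 odds
ratio for the logistic fit), plus closed-form toys and
parameter-recovery runs.  Monte-Carlo checks use fixed seeds and these
problem sizes, chosen to keep each property measurable with comfortable
margins: 100 random instances for the scoring and enrichment oracles;
2000 null cohorts of $n = 100$ for log-rank type-I calibration and 200
cohorts of $n = 200$ for power; 2000 trials of 200 permutations each for
null uniformity of the permutation p (at 500 trials the empirical-CDF
noise alone, median Kolmogorov distance 0.037, would dominate the
0.05 acceptance bound); exhaustive universes up to 30 for the
hypergeometric tail.  Calibration-style simulations reuse the default
miRNA compartment but shrink the mRNA block, which plays no role in the
quantities under test.

# Known limitations

* Identifier matching is verbatim (case-sensitive, whitespace-trimmed);
  no miRNA alias or annotation-version harmonization is attempted, so
  signatures and matrices must share a naming convention.
* The rank-sum score weights all signature members equally; a member
  whose direction is wrong for a given tumor subtype dilutes rather than
  flips the score.
* The gene-permutation enrichment null ignores inter-gene correlation
  and is anti-conservative for strongly co-expressed sets — a known
  property of pre-ranked GSEA, relevant when interpreting small FDR
  values for sets derived from the same cohort being tested.
* The logistic stage models a binary outcome on a restricted subset;
  it discards censoring-time information by design and is not a
  substitute for a hazard model.
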