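# stemscore

Rank-based stemness signature scoring and survival stratification for
tumor expression cohorts.

High-risk embryonal tumors such as neuroblastoma are thought to retain
regulatory programs of embryonic stem cells (ESCs), and the strength of
such a program in an individual tumor carries prognostic information.
`stemscore` implements the complete in-silico workflow for quantifying
that program from bulk expression data:

1. **Consensus signature construction** — combine directional gene lists
   from several publications into one up/down signature by
   minimum-support voting (a feature must be listed, in a consistent
   direction, by at least *k* sources).
2. **Rank-sum signature scoring** — the central statistic.  For sample
   *j* with per-sample expression ranks *r(f, j)* over all *G* measured
   features (rank 1 = lowest expression, midranks for ties), the score of
   a signature with up-set *U* and down-set *D* is

   ```
   S_j = mean_{f in U} r(f,j) / G  -  mean_{f in D} r(f,j) / G
   ```

   so `S_j` lies in (−1, 1), is invariant to any strictly increasing
   per-sample transform of the data (hence comparable across platforms
   and normalizations), and is high when a sample expresses the up
   members high and the down members low.
3. **Survival stratification** — median dichotomization of the score,
   Kaplan–Meier product-limit curves per group, the two-group log-rank
   test, landmark survival with log-log Greenwood confidence intervals,
   and a multivariate logistic regression of death-of-disease (on the
   outcome-restricted subset of patients who died or survived ≥ 3 years)
   adjusting for the classical risk covariates (MYCN amplification,
   stage 4, age at diagnosis).
4. **Correlated mRNA signature derivation** — rank all coding genes by
   Pearson correlation of their expression with the miRNA score and take
   the top *N* (default 500) positively correlated genes as a derived
   all-"up" mRNA signature.
5. **Gene-set enrichment** — pre-ranked weighted Kolmogorov–Smirnov
   enrichment (GSEA-style ES/NES) with a gene-permutation null,
   exactly-uniform permutation p-values and sign-stratified NES-ratio
   FDR, plus one-sided Fisher/hypergeometric gene-list overlap tests and
   Welch-t / Mann–Whitney group comparisons.
6. **Synthetic cohorts with ground truth** — a latent-factor generator
   (directional miRNA members, planted mRNA drivers, proportional-hazards
   survival, amplification label) so every stage is validated by
   parameter recovery rather than by unavailable patient data.

The package ships the 60-member directional ESC miRNA signature
(33 up-regulated members, including the complete miR-302/367 cluster, and
27 down-regulated members, including the let-7 family) as
`esc_mirna_signature()`.

## File formats

All inputs are UTF-8, tab-separated text; one packaged example of each
lives in `inst/extdata/`:

| artifact | format | example |
|---|---|---|
| expression matrix | features × samples TSV, first column feature ids, header row sample ids (use `transpose = TRUE` for the other orientation) | `example_mirna_matrix.tsv` |
| directional signature | 2 columns: `feature_id`, `direction` (`up`/`down`) | `esc_mirna_signature.tsv` |
| clinical table | 6 columns: `sample_id`, `os_time` (years), `os_event` (0/1), `mycn_amplified`, `stage4`, `age_ge_1y` (empty = missing) | `example_clinical.tsv` |
| gene sets | standard GMT (`name`, description, members…) | `example_sets.gmt` |

Readers are strict: duplicate identifiers, missing or non-numeric
expression cells, negative survival times and malformed direction tokens
are load errors, never silently repaired.

## Worked example

```r
library(stemscore)

cohort <- simulate_cohort(simulation_config(seed = 1))  # 200 samples
sig <- esc_mirna_signature()
scores <- signature_score(cohort$mirna, sig)
scores
#> Signature scores for 200 samples (33 up / 27 down members used)
#> sample_001 sample_002 sample_003 sample_004 sample_005 sample_006
#> -0.3754461  0.1622054 -0.5665825  0.6916162  0.1694108 -0.5004882

report <- survival_report(scores, cohort$clinical,
                          covariates = c("mycn_amplified", "stage4", "age_ge_1y"))
report$logrank
#> Log-rank test: chi2 = 15.8 on 1 df, p = 7.026e-05
report$logistic
#> Logistic fit on 155 subjects (0 excluded)
#>                   coef     OR      p
#> (Intercept)    -0.2572 0.7732 0.4554
#> score           1.2224 3.3955 0.0012
#> mycn_amplified  0.4291 1.5359 0.3797
#> stage4          0.0001 1.0001 0.9998
#> age_ge_1y      -0.7526 0.4711 0.0350

ranked <- correlate_genes_with_score(cohort$mrna, scores)
mrna_sig <- derive_top_signature(ranked, n = 500, name = "esc_mrna_signature")
truth_recovery_report(cohort, mrna_sig)$precision
#> [1] 1
```

Patients in the high-score half of this cohort have 51.1% five-year
overall survival (CI 39.2–61.7%) against 73.4% (62.1–81.8%) in the
low-score half; the log-rank test rejects equality (p = 7.0e-05), and in
the outcome-restricted logistic model the median-dichotomized score
carries an odds ratio of 3.40 (p = 0.0012) for death of disease,
independent of the amplification, stage and age covariates.  The derived
top-500 mRNA signature recovers the 500 planted driver genes with
precision 1.0.

The same workflow runs from the shell via the thin dispatcher in
`inst/exec/stemscore` (`consensus`, `score`, `survive`, `derive`,
`enrich`, `simulate`, `demo`, `run`), or end-to-end in R via
`run_pipeline()` on a YAML config (see `?run_pipeline`;
`stemscore_demo()` runs simulate → score → survive → derive → enrich on
defaults and writes a reproducible `manifest.json`).

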