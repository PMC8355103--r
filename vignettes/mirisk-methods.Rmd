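---
title: "Methods: serum miRNA risk scores for colorectal cancer risk prediction"
author: "mirisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum miRNA risk scores for colorectal cancer risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirisk)
```

# The problem

Circulating microRNAs measured in serum collected years before a
colorectal cancer (CRC) diagnosis may stratify risk better than
established tools. This package implements, as reusable and tested
components, the full analysis chain needed to derive a logistic
miRNA-panel risk score ("miR-score") from qPCR quantification-cycle
(Cq) data and to benchmark it against a point-based environmental risk
score (ERS) and a 140-SNP polygenic risk score (PRS): quality control,
reference-gene selection and normalization, sequencing-phase candidate
discovery, score construction, quintile-stratified association, and
optimism-corrected predictive performance.

Because the motivating cohort data are under restricted access, the
package ships a synthetic-cohort generator whose defaults emulate the
study conditions (a prospective case-cohort design with 198 incident
cases and 178 controls on a 41-miRNA panel), so that every downstream
stage is exercised end to end without any download. Published worked
numbers that are fully determined by printed inputs — the quintile
odds-ratio contrasts from their case/control counts, the frozen
7-miRNA score equation, the Holm-corrected p-value column — are used
as exact oracles in the test suite.

# qPCR quality control

Cq is the PCR cycle at which fluorescence crosses threshold; each cycle
is a doubling, so Cq is natively log2-scaled and *lower* Cq means
*higher* abundance. An undetected reaction is represented as an
explicit missing value (`NA`), never as a sentinel Cq such as 40, so
that sentinels can never leak into means.

The QC stages run in pipeline order (`run_qc()`):

1. **Spike-in monitoring** (warn only). UniSp2/UniSp4 monitor RNA
   extraction, UniSp6 the reverse-transcription step. Per-spike-in mean
   and SD are reported and samples deviating by more than 3 SD (the
   conventional laboratory rule, configurable) are flagged.
2. **Hemolysis exclusion.** miR-451a is enriched in red blood cells
   while miR-23a is stable in serum, so red-cell lysis lowers the Cq of
   miR-451a. A sample is hemolysed when
   `Cq(miR-23a) - Cq(miR-451a) > 7` cycles (strict). We use the Cq
   *difference*: the hemolysis literature defines this marker contrast
   as a delta-Cq, and a ratio of Cq values would be unit-dependent. A
   sample with either marker undetected cannot be evaluated and is
   excluded with its own reason code.
3. **Per-measurement validity.** A measurement is invalid when
   `Cq > 37` or when it lies within 5 cycles of the assay's no-template
   negative control (an undetected control counts as no contamination
   evidence). Invalid measurements become `NA`.
4. **Detectability.** Candidates detected (`Cq < 40`, strict) in at
   least 99% of retained samples form the *informative* set. The
   validity cap at 37 and the detectability limit at 40 are distinct
   instrument-grade rules and are kept as two separate configurable
   stages.
5. **Completeness.** Samples missing any normalizer or informative
   miRNA are excluded; the exclusion log gives one primary reason per
   sample, and the per-reason counts partition the input exactly
   (`n_input = n_retained + sum of exclusions`), which the tests check
   together with idempotence of the whole pass.

# Normalizer selection and delta-Cq normalization

Candidate reference miRNAs are ranked with the NormFinder model: a
variance-components decomposition of log-scale expression into a
systematic between-group bias and a within-group variance per assay.
For group $g$ (sizes $n_g$, $a$ assays), each group's matrix is
double-centred (per-sample and per-assay means removed). The raw
residual variance $S_{ig}$ of assay $i$ is corrected for the coupling
that per-sample centring induces between assays:

$$\hat\sigma^2_{ig} = \max\!\Big(0,\; \big(S_{ig} - \bar S_g/(a-1)\big)\,\frac{a}{a-2}\Big).$$

Group biases $d_{ig}$ (the assay's group mean relative to the group
grand mean, centred across groups) are shrunk towards zero with the
empirical-Bayes factor $\hat\gamma^2/(\hat\gamma^2 +
\hat\sigma^2_{ig}/n_g)$, where $\hat\gamma^2$ is a method-of-moments
estimate of the variance of true biases. The stability value of an
assay is the across-group mean of $|\tilde d_{ig}| +
\sqrt{\mathrm{Var}(\tilde d_{ig})}$; lower is more stable. For a
combination of $k$ assays the shrunk biases are averaged before taking
the absolute value, so biases of opposite sign cancel — a combination
can be more stable than any member, which is why `select_normalizers()`
performs an exhaustive search over all size-$k$ subsets
($\binom{38}{3} = 8{,}436$ at panel scale, cheap and exact) rather than
a greedy one. Ties are broken lexicographically by assay id. The
default $k = 3$ follows the three-normalizer design of the motivating
study; whether $k$ should itself be compared is left as a configuration
knob. The test suite checks the implementation against an independent
loop-based evaluation of the same formulas and verifies that a planted
stable trio among 38 assays is recovered in at least 95% of 200
designed replicates.

Normalized expression is
`expr[s, t] = mean(Cq[s, normalizers]) - Cq[s, t]`. The sign convention
makes up-regulation positive and `2^expr` exactly the 2^-dCt relative
quantity; the transform is invariant to per-sample additive Cq offsets
(global efficiency shifts), which the tests assert.

# Sequencing-phase candidate discovery

The discovery stage reduces a genome-wide miRNA count matrix to a
candidate list using three published filters: FDR < 0.05
(Benjamini-Hochberg), TMM-scaled mean > 10 in at least one group, and
|log2 fold change| > 1 — all strict inequalities.

* **TMM factors** (`tmm_factors()`) follow the trimmed-mean-of-M-values
  recipe: reference column by the 75th-percentile rule, M and A values
  over doubly expressed features, two-sided trimming of 30% on M and 5%
  on A, inverse-approximate-variance weighting, and rescaling to
  geometric mean 1. The tests require agreement with edgeR's
  `calcNormFactors` to 1e-8 as an independent oracle.
* **The two-group test** (`de_test()`) keeps the structure of the exact
  negative-binomial test but deliberately replaces the
  conditional-maximum-likelihood dispersion machinery with a single
  common method-of-moments dispersion on TMM-scaled counts; the
  conditional exact test on the per-group sums is then evaluated in
  full, with the two-sided p-value summing all splits as or less likely
  than the observed one. With a zero moment estimate the test falls
  back to the Poisson (binomial-conditional) form with a warning.
  Under a simulated Poisson null the p-values are approximately uniform
  (KS check in the suite); planted four-fold changes are detected with
  fold-change estimates near truth.
* **Fold changes** use a 0.5 pseudo-count on TMM-scaled group means to
  avoid infinities (configurable). "TMM > 10" is interpreted as the
  group *mean* of scaled counts (the group median is a configurable
  alternative; the choice is not determined by the published wording).

# Risk scores

**miR-score.** An unpenalised maximum-likelihood logistic regression of
case status on the informative-miRNA expression panel
(`fit_mir_score()`); the score is the *linear predictor* (log-odds), no
link transform. Convergence requires a relative log-likelihood change
below 1e-10 within 100 iterations; complete or quasi-complete
separation raises an explicit error advising penalisation. The
published 7-miRNA equation (intercept 0.1899) is shipped as a frozen,
versioned JSON artifact (`load_mir_score_model()`), decoupling
derivation from application so the printed coefficients are testable
without data. The frozen coefficients are applied to expression values
under this package's sign convention, which is recorded inside the
artifact.

**ERS.** Integer points summed over age bracket (0-4), sex (0/1),
first-degree family history (0/1), BMI bracket (0-2) and smoking
pack-years bracket (0/2/4); range 0-12, piecewise constant with
breakpoints exactly at {55, 60, 65, 70} years, {25, 30} kg/m² and
{0, 30} pack-years (grid-checked in the tests). BMI stands in for waist
circumference, following the modification used in the motivating
cohort. Missing family history and pack-years are imputed by chained
equations (`impute_ers_missing()`): a logistic conditional model for
the binary variable and a linear one for pack-years, cycled for a fixed
10 iterations, with each missing value drawn from the fitted predictive
distribution (Bernoulli, or a normal draw truncated at zero). We use
plain predictive-distribution draws rather than predictive-mean
matching for implementation transparency; `m` datasets can be drawn and
the first is the default analysis set. Everything is seed-reproducible.

**PRS.** The weighted sum of risk-allele dosages,
$\sum_i w_i \, d_i$ with $d_i \in [0, 2]$, with strict id matching and
range validation. The published 140-SNP weight list is an external
resource; the synthetic generator records its true simulated weights in
the same `snp_weights.tsv` interface.

**Combinations.** Combined predictors (ERS + PRS, ERS + miR-score, ...)
are logistic refits of case status on the component scores — the
standard choice where no combination method is stated — and the
combination is refit inside every bootstrap resample so the optimism
correction remains honest. Collinear components are rejected by a
condition-number guard.

# Association and evaluation

**Quintiles.** Risk categories use the 20/40/60/80 percentiles of the
*control* score distribution (linear interpolation of order statistics,
`stats::quantile` type 7 — a rule that must be pinned for
reproducibility and is configurable among the common definitions), with
right-closed bins, so a score exactly at a threshold falls in the lower
bin. Odds ratios come from logistic regression with the middle quintile
as reference; model 1 is unadjusted, model 2 adds age (continuous — the
natural default where the published adjustment scale is unstated) and
sex. Wald 95% CIs and two-sided Wald p-values are used throughout the
association module because they reproduce the published table
arithmetic exactly from the printed counts; `or_from_2x2()` provides
the closed form, which equals the unadjusted logistic contrast to 1e-8
(asserted in the suite). Display rounding is 2 decimals for ORs/CIs and
3 for AUC/Brier; full precision is kept internally.

**AUC and Brier.** AUC is the Mann-Whitney U statistic scaled (mid-rank
tie handling), with the DeLong variance method for the 95% CI. The
Brier score is the mean squared difference between predicted
probability and outcome.

**.632+ bootstrap.** With apparent loss `err_app` (fit and evaluate on
the full data) and leave-one-out bootstrap loss `err1`,

```
R = clip((err1 - err_app) / (gamma - err_app), 0, 1)
w = 0.632 / (1 - 0.368 R)
corrected = (1 - w) err_app + w min(err1, gamma)
```

Resampling is simple (unstratified) with replacement of all n samples,
the cited method's default; a stratified option exists. Two adaptations
are needed for AUC, which has no per-sample loss: the out-of-bag AUC of
each replicate is computed on its full out-of-bag set and averaged over
replicates (pooling per-sample losses is ill-defined for a rank
statistic), and the no-information rate is `gamma = 0.5`. For Brier,
per-sample squared errors are averaged over the resamples excluding
each sample and `gamma` is the all-pairs mean squared error of the
full-data predictions. Replicates whose resample contains one class
(or, for AUC, whose out-of-bag set does) are skipped and counted; more
than 10% skipped is an error. AUC results are reported as `1 - loss`.
Because of the `min(err1, gamma)` truncation, the corrected AUC cannot
be dragged below chance by pessimistic out-of-bag estimates, which is
exactly the behaviour the null simulation in the test suite verifies
(apparent AUC visibly above 0.5, corrected within 0.05 of 0.5 at
n = 200, B = 200).

**Follow-up subgroups.** `followup_subgroup()` retains cases with
`t_min < time-to-diagnosis <= t_max` and all controls, so the windows
(0, 3] and (3, Inf) partition the cases exactly.

**Deregulation.** Per-miRNA fold change is the ratio of group means of
`2^expr`; the two-sided Mann-Whitney test is exact when both groups
have at most 25 samples and no ties (verified against full enumeration
at 3-vs-3), normal-approximated with continuity correction otherwise;
Holm's step-down correction is applied across the panel. Spearman
correlations use average-rank ties; a constant miRNA yields a flagged
`NA`, never a silent 0.

# The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws, per subject: age (normal, mean 65, SD 7,
truncated to the 50-75 recruitment range), sex (55% male), family
history (12%), BMI (normal 27.5, SD 4), pack-years (55% ever-smokers
with a gamma distribution, mean 18), and 140 SNP dosages
(binomial(2, f) with frequencies uniform on 0.05-0.5). Case status
follows an additive logistic model on centred covariates and dosages
(per-SNP log odds normal with SD 0.08, covariate effects of plausible
epidemiological size), and subjects are rejection-sampled to the
configured case/control margins, as in a case-cohort design with fixed
sampling margins. Assay baselines are uniform on Cq 22-34 (the
detectable range with headroom below 40), candidate noise SD is 1
cycle, and the three planted normalizers have SD 0.15 and no group
shift.

Informative miRNAs receive their configured case/control shift as a
case-conditional location shift on the Cq scale, which pins the
injected delta-Cq exactly (the recovery tests exploit this); after
collapsing, this is equivalent to a latent-liability contribution.
Default shifts are the log2 of fold changes between about 0.6 and 1.5
— the magnitude range typical of serum miRNA case-control studies —
with signs matching the direction pattern of the published panel.
Hemolysed samples (default fraction 10/376) have miR-451a lowered until
the marker difference exceeds 7 by 0.5-3 cycles. Spike-ins use the
published summary means and SDs. Undetected measurements default to 5%
of filler-candidate values, missing completely at random (an optional
Cq-dependent mechanism concentrates dropout near the detection limit);
dropout is confined to the low-abundance filler assays so that the 99%
detectability contract of the informative set is reproducible by
design. Time to diagnosis is uniform on 0-14 years for cases (median 7,
matching a 14-year follow-up).

The generator deliberately does **not** simulate raw sequencing reads,
linkage disequilibrium between SNPs, longitudinal miRNA trajectories,
plate/batch effects, or correlated miRNA co-regulation beyond what the
shared case status induces. Passing tests on synthetic cohorts
therefore demonstrate that the *computational pipeline* is correct and
well calibrated under its stated model — not that the biological effect
sizes of any real cohort are reproduced.

# Numerical choices and problem sizes

Strictness of every threshold follows the published wording (hemolysis
`> 7`, validity `<= 37`, detectability `< 40`, filters `<`/`>`).
Logistic fits use epsilon 1e-10 and at most 100 iterations; quantile
rule type 7; subset-search ties lexicographic; TMM trims 0.30/0.05 with
a 0.5 pseudo-count on fold changes; imputation runs 10 chained cycles.
The test suite sizes its simulations for tight statistical power at
interactive runtimes: coefficient recovery at n = 5,000, coverage and
imputation checks over 100-200 replicates, the null .632+ check at
n = 200 with B = 200, normalizer recovery over 200 replicates of a
25-per-group design, and the null p-value check over 1,000 features;
the default cohort itself is the study-scale 376 samples. The analysis
scripts use B = 200 bootstrap replicates; for publication-grade numbers
B = 1000 (the default of `bootstrap_632plus()`) is recommended.

# Known limitations

* The NB exact test's single moment dispersion is a deliberate
  simplification; genuinely heterogeneous dispersions will make it
  conservative for stable features and liberal for volatile ones.
* Imputation draws ignore parameter uncertainty (no posterior draw of
  the conditional-model coefficients), which narrows between-imputation
  variability relative to fully Bayesian chained equations.
* The NormFinder bias components are panel-relative: with many shifted
  assays on a small panel, unshifted assays acquire small apparent
  biases, and bias cancellation can favour combinations that include a
  weakly shifted assay. This is a property of the model, not a defect
  of the search.
* `auc()`'s DeLong CI is undefined for degenerate (constant) scores and
  is reported as `NA`.
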