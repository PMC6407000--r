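---
title: "Methods: from raw Ct values to a validated prognostic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw Ct values to a validated prognostic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`miRsurv` operationalizes a complete analysis of circulating-miRNA qPCR
panels against right-censored survival endpoints, the kind of analysis run
on histotype-stratified early-stage NSCLC cohorts. This vignette documents
the statistical model at each stage, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## 1. Normalization model

Raw Ct values confound biology with technical recovery. Two corrections are
applied in sequence.

**Spike-in centring.** The exogenous spike-in (cel-miR-39) is added at
extraction in fixed quantity, so its Ct measures per-sample technical
recovery. For patient $j$ the deviation of the spike-in Ct from its cohort
mean is subtracted from every well. The operation needs at least two
patients (a cohort mean); offsets sum to zero by construction. We also
re-centre the spike-in Ct itself so the operation is idempotent — the
underlying convention (should a twice-centred plate change?) is not forced
by the chemistry, and idempotence makes pipeline restarts safe.

**Reference-gene selection.** Endogenous references are chosen by a
model-based stability score in the NormFinder tradition. On the candidate
genes with complete (detected) profiles, the additive model

$$\mathrm{Ct}_{gj} = \mu_g + s_j + \varepsilon_{gj}$$

is fitted by row/column means; the stability of gene $g$ is the standard
deviation of $\hat\varepsilon_{gj}$ across patients, with the small-sample
factor $G/(G-1)$ applied to the variance ($G$ = number of candidates). The
two smallest scores (ties broken lexicographically by gene id) become the
references. The original grouped (intra/inter-group) variant is available
behind the `groups` argument but is not the default: an ungrouped residual
SD is fully reproducible, oracle-testable, and captures the operational
meaning of "most stable = least variation beyond the sample effect". In the
two-cohort design the ranking is run per histotype, so SCC and ADC can (and
typically do) select different reference pairs.

**Reference subtraction.** Expression is reported as
$-\Delta\mathrm{Ct}_{gj} = -(\mathrm{Ct}_{gj} - \tfrac12(\mathrm{Ct}_{r_1 j}
+ \mathrm{Ct}_{r_2 j}))$, a relative log2-abundance scale (higher = more
expressed). The references (and the housekeeping snRNA wells) are excluded
from all downstream statistics. Two invariances characterize the
normalization and are enforced by tests at $10^{-9}$: adding a constant to
*every* well of one patient (targets, references and spike-in) leaves the
output unchanged, as does a global constant shift.

## 2. Missing data

Wells that never cross the fluorescence threshold ("undetermined") are
below-detection observations, not random gaps.

* **Exclusion**: targets undetermined in strictly more than 50% of patients
  are dropped (the strict inequality matters: a gene missing in exactly
  half is retained). On an 84-target panel this typically removes a
  low-abundance block; the generator plants 14 such targets by default so
  the arithmetic $84 - 14 - 2 = 68$ of the screening family is exercised.
* **Outcome-associated missingness**: before imputing, each gene's
  undetermined status is cross-tabulated against the event indicator;
  Fisher's exact test is used when any expected cell count is 5 or below,
  otherwise Pearson's chi-square without continuity correction. Degenerate
  margins are reported as not applicable rather than tested.
* **Imputation**: remaining masked wells are filled by K-nearest-neighbour
  imputation on the spike-in-centred Ct scale, within histotype, *before*
  reference subtraction — this keeps reference selection a function of
  complete data only. Distances between patients are root-mean-square Ct
  differences over the genes observed in both, so patients with different
  missingness patterns remain comparable; each cell takes the unweighted
  mean of the $k = 5$ nearest donors. $k$, the distance, and the
  unweighted mean are package decisions (the analysis tradition leaves
  them unstated); all are configurable, and imputed values always lie
  inside the observed range of the gene.

## 3. Univariate screening

Each miRNA (and each clinical covariate) is screened with a single-covariate
Cox model: Efron tie handling, Wald 95% CIs and two-sided Wald p-values —
the CI shape matches the symmetric-on-log intervals such tables publish.
Monotone-likelihood fits (e.g. perfect separation) are flagged rows with an
infinite upper bound, not errors. Categorical covariates expand against
fixed reference levels (stage I, female, never-smoker, no treatment); stage
is 3-level (I/II/IIIA) by default with substage labels collapsed on input.

Multiplicity over the miRNA family (never the clinical covariates) is
controlled by Benjamini–Hochberg at level $\delta = 0.05$: with $m$ tests
the $j$-th smallest p-value is compared against $(j/m)\,\delta$ and all
tests up to the largest passing rank are rejected. The implementation
accepts $m$ larger than the number of supplied p-values so that decisions
can be reproduced from a published table of only the smallest p-values.
Kaplan–Meier medians use the earliest-crossing convention (the first time
the curve drops to 0.5 or below; never reached → `NA`) with log-log
Greenwood intervals, and median follow-up is the median time at risk of the
censored patients (reverse-of-events convention).

## 4. The combined elastic-net Cox model

The multivariable model maximizes the penalized Cox partial likelihood

$$\ell(\beta) - \lambda \sum_{g \in \text{miRNA}}
  \left[\alpha\,|\beta_g| + \tfrac{1-\alpha}{2}\,\beta_g^2\right],
\qquad \alpha = 0.5,$$

with clinical covariates (default: the stage dummies) carrying penalty
factor 0 — no shrinkage — and miRNAs penalty factor 1. Elastic net rather
than lasso because miRNA expression is correlated; $\alpha = 0.5$ balances
selection against shrinkage among correlated candidates. miRNA columns are
standardized internally so the penalty acts on comparable scales, and
coefficients are reported back on the $-\Delta\mathrm{Ct}$ scale;
unpenalized columns are untouched.

Path and cap: `glmnet` computes a geometric path of 100 lambdas down to
$0.01\,\lambda_{\max}$; the path is truncated at the first lambda whose
count of nonzero *penalized* coefficients would exceed `max_selected = 5`
(path truncation, the standard device in penalized-path software, rather
than post-hoc deletion). The cap reflects the low event counts of such
cohorts; clinical covariates never count against it — the cap is read as a
cap on selected biomarkers, since the unpenalized covariates are in the
model by design. Lambda is then chosen on the admissible path by 10-fold
cross-validated partial-likelihood deviance in the Verweij–van Houwelingen
form, computed by the package itself (Breslow ties, matching `glmnet`'s
internal convention), with folds stratified by event status and derived
deterministically from the seed. The minimum-deviance lambda is used — no
1-SE rule — because the selection cap already provides the parsimony a 1-SE
rule would add.

The prognostic index of a patient is the linear predictor
$PI = x^\top\hat\beta$; only ranks and contrasts of $PI$ are used
downstream, so no baseline hazard is estimated.

## 5. Validation engine

Internal validation follows the resampling scheme for cross-validated
survival classifiers:

* **LOOCV prognostic indices.** For each patient the *entire* modelling
  procedure — standardization, path construction, fold assignment, lambda
  selection — is refit on the other $n-1$ patients (re-seeded
  deterministically from `(seed, i)`), and the held-out patient is scored
  by that model. Nothing from the held-out patient leaks into the fit that
  scores them.
* **Risk groups.** Patients are split at the median cross-validated index;
  ties at the median and the extra patient at odd $n$ go to the low-risk
  group. Cross-validated KM curves and the log-rank chi-square follow.
* **Time-dependent ROC.** Cumulative-case / dynamic-control ROC at a
  landmark $t^*$ (default 24 months — the two-year relapse horizon that
  dominates clinical reporting in this setting; configurable), with
  inverse-probability-of-censoring weights from the KM estimate of the
  censoring distribution evaluated at $T^-$ for cases and $t^*$ for
  controls. The AUC is the weighted probabilistic index with ties counted
  one half; it satisfies $AUC(PI) + AUC(-PI) = 1$ exactly.
* **Permutation tests.** (i) The *separation* test shuffles the
  correspondence between the (time, event) pairs and the joint
  (miRNA, clinical) rows — stage stays with the miRNAs; the alternative
  reading, shuffling stage along with the outcomes, is exposed behind a
  flag since the underlying convention is genuinely ambiguous. (ii) The
  *added-value* test reassigns only the miRNA rows, keeping outcomes and
  clinical covariates together, testing whether survival and covariates
  are independent of the miRNAs. In both, the **full pipeline including
  LOOCV and inner tuning is rerun for every permutation** — this is the
  honest version of the procedure and its dominant cost. P-values use the
  $(1 + \#\{\text{perm} \ge \text{obs}\})/(B+1)$ convention, never exactly
  zero; failed permutations are skipped with the denominator adjusted. The
  AUC-versus-0.5 test is two-sided (on $|AUC - 0.5|$); the added-value
  comparisons are one-sided.

A practical note observable in the engine's output: leave-one-out linear
predictors carry a systematic jackknife anti-correlation (excluding a
high-risk patient shifts the refitted coefficients), so the permutation
null of the cross-validated log-rank statistic is *not* a $\chi^2_1$ and
can sit surprisingly high. This is precisely why the permutation reference
distribution — with the same LOOCV artifact built in — is used instead of
an asymptotic one, and why the added-value log-rank test has visibly lower
power than the added-value AUC test in our power checks.

## 6. The synthetic cohort generator

`simulate_cohort()` emulates the structure the analysis assumes, with
defaults set once to a squamous-cell-like cohort: $n = 83$; stage I/II/IIIA
probabilities $(0.506, 0.325, 0.169)$; stage log-hazards $(0.60, 1.23)$
against stage I; Weibull baseline (shape 1.1, scale 48 months) giving a
median DFS near two years; uniform accrual censoring on $(0, 160)$ months
capped administratively at 170, giving event fractions near 0.7; an 84 + 6
panel with 14 planted low-abundance targets (>50% undetermined at the
Ct = 35 detection limit), two designated near-noise-free stable targets
(the reference candidates), and three prognostic miRNAs with log-hazards
(−0.5, −0.4, 0.3) per $-\Delta\mathrm{Ct}$ unit, inside the univariate
hazard-ratio range (≈0.6–1.4) such panels report. Latent expression is
gene + sample + well noise; Ct is an affine map of $-x$ plus the per-sample
technical offset that the spike-in records (noiselessly — a simplification);
overall-survival event times are the DFS times plus an exponential
post-progression gap (mean 24 months) under shared censoring, since the
tradition treats the endpoints independently and publishes no generating
model.

What it does **not** emulate: amplification-efficiency differences,
plate/batch effects, informative censoring, correlated miRNA blocks beyond
the shared sample effect, or the real cohorts' marginal covariate
distributions beyond stage frequencies. Passing tests on these cohorts
therefore demonstrate the *statistical machinery* — not that any particular
biological signal exists.

## 7. Numerical choices, problem sizes and limitations

* Breslow tie handling inside the penalized fit and its CV deviance
  (matching `glmnet`); Efron in the univariate screen (less biased, and
  the univariate fitter never has to match `glmnet`).
* Degenerate inputs fail loudly and early: constant covariates, all-equal
  cross-validated indices, undefined log-rank configurations, masked
  reference genes, genes observed in fewer than $k$ patients.
* All resampling seeds derive from one master seed through a string-hash
  scheme (`derive_seed()`), so serial and parallel execution, and package
  versus reference-loop implementations, agree bit for bit.
* The test suite exercises the permutation engine at reduced problem sizes
  chosen for a single-CPU run: null calibration with $n = 20$, 3 miRNAs,
  $B = 19$ and 30 replicates (rejection within 3 Monte-Carlo SEs of the
  nominal level, mean p near ½), and added-value power at $n = 80$,
  $|\beta| = 1$, $B = 19$ over 5 seeds. A definitive analysis run uses
  $B = 1000$; on an 83-patient, 68-miRNA cohort with inner 10-fold tuning
  that is on the order of $B \times n$ penalized path fits and is best run
  once, not inside a test suite.
* Known limitations: no amplification-efficiency correction or standard
  curves; no multiple or model-based imputation; no k-fold (non-LOO)
  validation variant; no confidence bands for the cross-validated AUC
  beyond the permutation p-value; no competing-risks analysis.
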