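---
title: "Methods: swarm-optimized TEP-score classification of platelet spliced RNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swarm-optimized TEP-score classification of platelet spliced RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepscore)
```

## The problem

Tumor-educated platelets (TEPs) carry spliced mRNA repertoires that shift in
the presence of a tumor. Counting only intron-spanning (spliced-junction)
reads excludes cell-free DNA contamination, so a transcripts × samples
matrix of spliced-junction counts is the molecular input of the whole
pipeline. The statistical task is to decide, from such a profile, whether a
blood sample comes from a patient with active sarcoma or from a control
(healthy donors pooled with former patients who have been cancer-free for
years), and to do so with a disciplined train/evaluate/validate split so the
reported performance is honest.

`tepscore` implements this as a single fitting function, `tep_fit()`,
returning a classed object with the usual `print`/`summary`/`coef`/
`predict`/`plot` methods, over modular building blocks that are all exported
and individually tested.

## Model and procedure

**Normalization.** Counts are transformed to
$\log_2(10^6 \cdot c_{ts} / N_s + 1)$ where $N_s$ is the total spliced reads
of sample $s$. The pseudocount of 1 maps zeros to exactly 0 and keeps the
transform invertible. A deliberate design choice: protocol-style latent-
factor corrections are replaced by this fully specified transform, and depth
effects are instead controlled by the swarm-tuned library-size correlation
filter below. Before normalization, transcripts with fewer than 30 total
reads, or expressed in fewer than 3 samples, are dropped (defaults of
`run_config()`; both thresholds are explicit, logged stand-ins — coverage
filtering is always protocol-specific).

**Differential statistics.** Each transcript is tested by fixed-effects
one-way ANOVA of normalized expression against the class label. With two
groups the F statistic equals the squared pooled-variance t statistic with
$p$ from $F(1, n-2)$; this identity is asserted against `stats::aov` and a
from-scratch pooled-t oracle in the tests. Constant transcripts are assigned
$F = 0, p = 1$ so the statistic is total. Benjamini–Hochberg adjustment is
delegated to `stats::p.adjust` and cross-checked against a brute-force
step-up implementation. Selection uses the strict inequality $q <$
threshold, with the deterministic ranking $q$, then $p$, then transcript id.

**Panel selection and the four hyperparameters.** A biomarker panel is
built from the training series only, by the pipeline: library-size
correlation filter (keep transcripts whose Pearson correlation with log2
library size lies in $[\ell, 1]$; zero-variance transcripts get $r = 0$) →
ANOVA + BH on the survivors → $q < f$ → absolute point-biserial label
correlation $\ge c$ → take the top $k$ ranked transcripts. The four numbers
$(\ell, f, c, k)$ are exactly the dimensions the swarm searches, within the
published ranges $\ell \in [-0.1, 1]$, $f \in [10^{-5}, 1]$,
$c \in [0.5, 1]$, $k \in [200, \text{all detected}]$ (the upper bound on $k$
is capped at run time by the detected-transcript count, and tests use
smaller lower bounds on toy cohorts via `run_config(bounds = ...)`).

**Classifier and TEP-score.** Panel transcripts are z-scaled by their
training mean/sd (the frozen "normalization reference" of the locked
panel) and classified by an RBF-kernel SVM with $C = 1$ and
$\gamma = 1/|panel|$ — fixed rather than swarm-tuned, keeping the search
space exactly the four panel dimensions. Probabilities come from a Platt
sigmoid $P(\text{sarcoma}\mid d) = 1/(1 + e^{ad + b})$ fitted by Newton
iterations on the training decision values with Platt's smoothed targets.
Doing the calibration in-package (rather than using the SVM library's
internal cross-validated variant) makes scoring a deterministic function of
the stored panel: decision values are computed directly from the stored
support vectors, so a panel restored from its JSON artifact scores
bit-identically, and repeated builds hash identically. The tests verify the
manual decision path against the SVM library's own decision values.

**Swarm optimization.** Standard inertia-weight PSO: velocity
$v \leftarrow \omega v + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x)$,
position clamped to the bounds, $\omega = 0.72$, $c_1 = c_2 = 1.49$, zero
initial velocities — conventional constriction-style constants, exposed in
`run_config()`, since the optimizer's own constants are not part of the
published search space. The ranked-count dimension flies as a continuous
value and is rounded at evaluation. One particle is pinned to a documented
default $(\ell, f, c, k) = (-0.1, 0.05, 0.5, \min(1000, \text{all}))$, which
guarantees the swarm never returns something worse than the default
pipeline. Fitness is the evaluation-series AUC of the training-built panel;
parameter settings that leave no transcript standing yield a "degenerate"
panel scored at chance (0.5) instead of an error, so the swarm can traverse
bad regions. Ties in the global best keep the earliest incumbent in
(iteration, particle) order. The default budget is 100 particles × 10
iterations (1000 evaluated particles); the clustering variant defaults to
200 × 12, following the published per-iteration settings even though the
source text's "1200 particles in total" is arithmetically inconsistent with
them.

**Locking and leakage.** `pso_optimize()` receives only training and
evaluation samples (it errors on overlap); the winning panel is rebuilt on
the training series and locked. `tep_score()` refuses to score validation
or unspecified samples with an unlocked panel. Because validation data
never reach the optimizer, deleting the validation series must leave the
locked panel byte-identical — asserted as a test on the panel hash.

**Performance reporting.** AUC uses the Mann–Whitney pair-counting
definition via mid-ranks (ties count ½), verified against trapezoidal ROC
integration, explicit pair enumeration and pROC. Confidence intervals are
class-stratified percentile bootstrap (default 2000 resamples, seeded); the
method is a package choice — the CI construction behind published TEP
intervals is not specified in the protocol family. Cross-tables apply the
documented tie rule (score exactly at the cutoff → sarcoma, the
high-sensitivity direction) and report whole-percent rates for display
while retaining full precision internally.

**Controls.** The shuffled-label control permutes training + evaluation
class labels, re-runs the entire optimization, and scores the untouched
validation series — a permutation null for the whole pipeline. The
shuffled-training control re-draws the training/evaluation split with
labels intact — a split-robustness check, interpreted this way because the
published figure reports it at near-nominal AUC, far from the label-shuffle
null. Both allow a reduced particle budget for tractability, which is
recorded in the run configuration.

**Clustering.** Samples are clustered on row-Z-scored expression with
distance $1 - r$ (Pearson, between sample columns) and complete linkage,
cut at $k = 2$; cluster–class association uses the two-sided Fisher exact
test (the association test behind published clustering p-values is unnamed;
Fisher is our documented choice, verified against full fixed-margin
enumeration). `pso_cluster_panel()` swarm-tunes the FDR threshold alone,
with fitness $-\log_{10} p$ mapped monotonically into $[0, 1)$.

## The synthetic-cohort generator

No cohort of this kind is publicly deposited, so the generator is a
first-class module. It emulates: ~3,799 detected spliced transcripts; 57
sarcoma and 103 control samples of which 38 are flagged former-sarcoma;
stratified training/evaluation/validation series of 55/52/53 samples
(largest-remainder apportionment within each class, seeded); log-normal
library sizes; heavy-tailed (log-normal) baseline abundances; gamma-Poisson
(negative-binomial) counts with $\mathrm{var} = \mu + \alpha\mu^2$; a
planted signature of transcripts shifted by $\pm$`effect_log2fc` (constant
magnitude, random sign, split symmetrically between the groups); and
age/gender effects on a disjoint 10% transcript subset. Defaults are the
study conditions above plus invented-but-fixed noise parameters:
`n_de = 400`, `effect_log2fc = 1.5`, dispersion $\alpha = 0.2$ (a typical
bulk RNA-seq overdispersion), library sizes log-normal with median $10^6$
and sdlog 0.4, `confounder_strength = 0.5`.

Matching is emulated, not implemented: ages are drawn from the same
distribution in both classes and gender independently of class, and a
balance report is emitted — the study states matching as a design fact, not
a procedure. Former-sarcoma controls are statistically identical to healthy
controls; the flag exists for reporting strata only, consistent with the
observation that former patients classify as controls. All randomness flows
from one integer seed through a deterministic string-keyed seed-derivation
scheme (`derive_seed`), so stages are independently reproducible.

What passing tests on these cohorts do **not** show: robustness to
batch/plate effects, isoform-level structure, count zero-inflation beyond
NB, or real biological correlation structure between transcripts (planted
effects are independent across transcripts). Real-data performance claims
are outside what the generator can support.

## Numerical choices and degenerate inputs

- Zero-variance transcripts: $r = 0$ in both correlation filters; $F = 0,
  p = 1$ in ANOVA; all-zero rows after Z-scoring. Every statistic is total.
- Degenerate panels (no survivors, or an unfittable SVM) are flagged and
  scored at chance rather than erroring.
- LOOCV folds that collapse a class below 2 samples score 0.5 and are
  flagged; panel selection is repeated inside every fold, so the held-out
  sample touches no selection step.
- Platt fitting uses smoothed targets, which keeps the Newton solve finite
  even on separable training data.
- Tie-breaks are deterministic everywhere (ranking: $q$, $p$, id; swarm
  global best: earliest found; classification: cutoff ties → sarcoma).
- `hclust` complete linkage guarantees non-decreasing merge heights;
  asserted in tests.

## Problem sizes in the test and acceptance runs

The tests exercise toy cohorts of 150–1,500 transcripts and 16–80 samples
with small swarm budgets (4–10 particles, 1–3 iterations), which keeps the
full suite around ten seconds while still running every stage end to end.
The acceptance script uses 4,000-transcript null and planted cohorts
(30 + 30 samples) for calibration and recovery checks, 50 label shuffles at
a reduced budget for the permutation control, and one study-scale cohort at
the full published budget (3,799 transcripts, 57 + 103 samples, 100
particles × 10 iterations). These sizes are the package's own choices for
routine reproducibility; all of them are parameters, not limits.

## Known limitations

- The coverage-filter thresholds and the normalization are explicit
  stand-ins for protocol steps whose published description is incomplete;
  they are logged and configurable but not reconstructions.
- ANOVA runs on normalized values without age/gender covariates —
  confounding is controlled by the matched design (and emulated as such in
  the generator), not by modeling.
- The SVM hyperparameters behind published TEP panels are not public; C and
  γ are fixed by convention here.
- No multiclass (histologic-subtype) classification, no >2-cluster
  analyses, no read-level simulation.
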