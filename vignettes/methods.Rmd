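---
title: "Methods: multimodal prediction of AUD remission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal prediction of AUD remission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remitpredict)
```

# The problem

remitpredict models a longitudinal case–control design: individuals who all
meet criteria for alcohol use disorder (AUD) at a baseline visit are
re-assessed years later and divided into a *continued* group (still meeting
criteria) and a *remitted* group (no longer meeting criteria). The question
is whether baseline measurements — resting-state EEG functional
connectivity, polygenic risk scores (PRS), demographics and medication
intake — predict which group a person will end up in. Because the clinical
datasets this design needs are access-restricted, the package pairs every
analysis stage with a synthetic-cohort generator whose ground truth is
recorded, so the whole pipeline can be validated end to end on data with
known answers.

# EEG functional connectivity

## Estimator

Connectivity between two regions of interest (ROIs) is the band-averaged
magnitude-squared coherence (MSC)

$$C_{ij}(f) \;=\; \frac{|S_{ij}(f)|^2}{S_{ii}(f)\,S_{jj}(f)} \in [0, 1],$$

with auto- and cross-spectra estimated by Welch averaging: the recording is
cut into 2-second segments with 50% overlap, each segment is demeaned,
Hann-tapered and Fourier-transformed, and periodograms are averaged across
segments. Per-bin MSC is then averaged over the bins falling in each band's
half-open interval: theta [4, 8), alpha [8, 12), beta [12, 30) and gamma
[30, 60) Hz. Half-open intervals keep adjacent bands disjoint. The
per-bin-then-average order (rather than coherence of band-averaged spectra)
was chosen for robustness to the number of in-band bins.

Settings that matter, with defaults:

* `segment_length = 2` s — sets the frequency resolution (0.5 Hz); at the
  default sampling rate of 256 Hz a 4-minute recording yields 239 segments.
* `overlap = 0.5`, `window = "hann"` — standard Welch choices; both
  configurable.

Two biases are worth knowing. First, the estimator has a positive
small-sample bias for independent signals of roughly $1/K$ for $K$
segments; tests assert the bias floor stays below 0.05 at the default
geometry and decreases monotonically with $K$. Second, band-averaged MSC of
a *band-limited* shared component is biased slightly low because the bins at
the band edges mix in-band signal with out-of-band noise through the taper's
spectral leakage; at the defaults this is about 0.02–0.03 in absolute MSC.
The estimator itself was cross-checked against an independent Welch
implementation on fixed signals (values frozen in the test suite at six
decimals).

With 68 Desikan–Killiany regions and four bands the feature block has
$4 \times \binom{68}{2} = 9112$ features named `ROIa-ROIb@band`.

## Synthetic construction

For a pair with target band MSC $m$, the generator builds

$$x = \alpha s + \sqrt{1 - \alpha^2}\, e_1, \qquad
  y = \alpha s + \sqrt{1 - \alpha^2}\, e_2,$$

where $e_1, e_2$ are unit-variance white noise and $s$ is band-limited noise
whose in-band power spectral density equals the white noise's. In the band,
$S_{xy} = \alpha^2 S_s$ and $S_{xx} = S_{yy} = \alpha^2 S_s +
(1-\alpha^2) S_e = S_e$, so the theoretical band MSC is $\alpha^4$ and the
generator uses $\alpha = m^{1/4}$. At $m = 1$ the channels are identical in
the band and the estimator returns exactly 1. Each ROI may take part in at
most one planted effect so targets stay exact; effect magnitudes differ by
outcome group, which is what makes connectivity predictive downstream.

# Genetics

## Polygenic risk scores

PRS are built by the classical clumping-and-thresholding procedure:

1. **Clumping** (`clump()`): greedily take the genome-wide most significant
   unclumped SNP as an index, retain it, and remove every unclumped SNP on
   the same chromosome within ±500 kb whose reference-panel dosage
   $r^2 \ge 0.25$ with the index. Ties on p are broken by (chromosome,
   position, id) so results are deterministic. The boundary is inclusive,
   matching common tooling. Tests replay this definition with an
   independent brute-force implementation on a thousand random instances.
2. **Scoring** (`prs_scores()`): at threshold $t$, a subject's raw score is
   $\sum_{\text{SNP}: p < t} \mathrm{sign}(\beta)\,(-\log_{10} p)\,d$
   over retained SNPs, with $d$ the effect-allele dosage. The weight's
   magnitude is the negative log p-value; the sign of the discovery beta is
   applied because a signless weight would discard effect direction and
   make the score's direction meaningless. Log base 10 is a pure
   convention — any base differs by a global factor that standardization
   removes. The threshold family is the nine standard cutoffs from 1e-4 to
   0.5 (strict inequality, per the usual "p < t" notation). Missing dosages
   are mean-imputed per SNP so score scales stay comparable.
3. **Standardization** (`standardize_prs()`): columns are Z-scored
   (denominator $n-1$); constant columns become 0 with a warning.

Genotype QC is out of scope; inputs are assumed quality-controlled.

## Ancestry

Genetic ancestry is assigned from genotype PCA: dosages are centred by twice
the allele frequency and scaled by $\sqrt{2f(1-f)}$, the subject covariance
is eigendecomposed, and coordinates are eigenvectors scaled by the square
root of their eigenvalues (so axes carry their share of variance — this
matters for the clustering step). Signs follow a fixed convention
(largest-magnitude entry positive). Two-group assignment is k-means on the
first two PCs with deterministic k-means++ seeding; clusters are named by
the majority of self-reported ancestry, ties resolved toward the larger
cluster, and poorly separated clusterings (between-cluster sum of squares
below half the total) are flagged — the threshold-vs-clustering choice was
open, and clustering was picked because it needs no externally calibrated
PC cutoffs.

## Synthetic genotypes

Null SNPs are laid out in LD blocks. Within a block, all SNPs share one
allele frequency drawn uniformly from [0.1, 0.5] and an equicorrelated
latent-Gaussian haplotype structure whose correlation is calibrated by root
finding (through the thresholded-Gaussian allele correlation) so that the
dosage $r^2$ matches the requested `block_r2` exactly in expectation;
sharing the frequency inside a block is what makes the target attainable
after thresholding. Blocks span well under 500 kb and sit 2 Mb apart so
clumping behaviour is fully controlled. Causal SNPs are appended as
independent loci whose dosage distribution is drawn conditionally on the
outcome label through a logistic model with the stated per-dosage log-odds
(intercept solved so the marginal remission rate is one half, matching the
balanced design). The discovery summary statistics give causal SNPs small
p-values with the stated sign; null SNPs get uniform p-values. A reference
panel is drawn independently from the same LD process. Family structure and
recombination maps are deliberately not modelled: clumping behaviour, not
population-genetic realism, is the object under test.

# Cohort assembly

Feature tables are plain tibbles with reserved metadata columns
(`subject_id`, `label`, `sex`, `ancestry`, `ancestry_genetic`, `age`);
every other column is a feature whose modality travels in its name prefix
(`eeg_`, `prs_`, `dem_`, `med_`), which survives any dplyr manipulation.
Demographics are binary indicators (married, employed) plus eight
medication flags (sleep, anxiety, headaches, birth control, depression,
energy, steroids, other).

Stratification filters to one sex × ancestry cell, using either
self-reported or genetically assigned ancestry, and restricts the feature
columns to a selected set. Age matching is greedy nearest-neighbour 1:1
matching without replacement under a 2-year caliper (candidate pairs
ordered by age difference, ties by subject id): the published design states
group-level age matching without an algorithm, and greedy pairwise matching
is the simplest deterministic procedure that guarantees the group-mean age
difference is bounded by the caliper. Missingness is handled by listwise
deletion over the *selected* features only, so a subject missing EEG data
still contributes to PRS-only models. Z-normalization supports fit-and-
transform as well as transform-with-given-statistics; the latter is what
the leakage-free CV mode uses inside training folds.

# Classification protocol

## Feature selection

The LASSO is run on the binary label with squared-error loss (the label
coded 0/1 as the response), solved by cyclic coordinate descent over 100
log-spaced penalties from $\lambda_{\max} = \max_j |x_j^\top (y - \bar y)|/n$
down to $10^{-3}\lambda_{\max}$. Gaussian rather than logistic LASSO is the
canonical reading of "regression of the label"; the selected-set behaviour
is very similar and the downstream SVM only consumes the support. The
penalty is chosen by 10-fold CV at the loss minimum (no 1-SE rule), ties
broken toward the larger penalty. Numerically, the CV path runs at the
solver's default tolerance while the returned coefficients come from a
warm-started refit truncated at the selected penalty with a $10^{-12}$
threshold, so Karush–Kuhn–Tucker residuals are below $10^{-6}$ without
paying for high-precision solutions at penalties that are never selected.
An empty selection is signalled distinctly; evaluation falls back to all
features with a warning, which on null data simply reproduces chance.

## SVM and evaluation

The classifier is a soft-margin linear SVM, optimized by randomized dual
coordinate descent on the hinge loss — the standard algorithm for linear
SVMs, which stays fast at large cost values where SMO-style solvers stall
on non-separable data. The bias is an augmented constant feature (value 10),
so it carries a weak penalty of its own; the trainer is cross-checked
against an SMO implementation in the test suite (decision-sign agreement
and weight cosine on fixtures) and its solutions are verified as local
minima of the primal objective against a thousand random perturbations.
The cost parameter is tuned by
stratified 5-fold inner CV over 10 log-spaced values in $[10^{-3}, 10^3]$
(ties toward the smaller, more regularized cost) and the model refit at the
winner. Decision scores $w \cdot x + b$ are oriented so larger values
favour the remitted class; sensitivity is the true-positive rate on
remitted, specificity the true-negative rate on continued, and the AUC is
computed from score ranks with half credit for ties (the Mann–Whitney
statistic), verified against exhaustive pairwise counting.

Evaluation is shuffled, stratified 10-fold CV repeated 10 times, in two
modes:

* **paper_faithful** (default): Z-normalization and LASSO selection run
  once on the whole stratum before CV, reproducing the published order of
  operations. Because selection has seen the test folds, accuracy on null
  data is optimistically biased — the package demonstrates this bias
  explicitly (see the leakage check below).
* **nested**: scaling statistics and the selection are refit inside every
  training fold; estimates are leakage-free.

Both modes exist because reproducing a published protocol and estimating
generalization honestly are different goals; results carry their mode, and
the README states the caveat. Summaries report mean ± SD of each metric
across the repeat means. Stratified folds are used even though the groups
are balanced by construction — they guard small strata at no cost. A final
normalize–select–train fit on the full stratum supplies the reported
feature weights and ranks (ordered by absolute weight, ties by name);
nested runs additionally record each feature's selection frequency across
folds. A stratified 70:30 holdout (`holdout_evaluate()`) is available as a
confirmatory check for larger strata. Model comparison is a paired t test
on per-repeat mean accuracies; repeat-level pairing reuses subjects, so the
test is anti-conservative and its output carries that caveat — it is a
declared stand-in, not a reconstruction of any published procedure.

# Synthetic cohort defaults and what they do (not) emulate

Defaults mirror the study conditions: balanced groups, 68 ROIs at 256 Hz
for 240 s, age drawn for both groups from one truncated normal
(mean 30.7, SD 9.4, ≥ 18 years, matching the reported cohort ages), 60%
male, 65% European ancestry (the cohort's ancestry split is not reported;
this is a plausible choice for a US-based study and only affects stratum
sizes). Covariate base rates (married 0.5, employed 0.6, each medication
0.15) are realistic round numbers; each covariate's group difference is
controlled by a log-odds-of-remission parameter realized exactly as an odds
ratio between group-conditional rates. No effect-size scale is published
for any modality, so synthetic defaults are chosen for testability, not
realism.

The generator emulates: band-limited pairwise coherence structure differing
by outcome, LD-blocked genotypes with label-linked causal SNPs and matching
summary statistics, and label-linked binary covariates. It does *not*
emulate volume conduction or artifacts (signals are source-level by
construction), family structure, admixture, or realistic recombination.
Passing tests therefore validate the pipeline's statistical machinery —
estimator calibration, selection, evaluation, leakage behaviour — not
clinical effect sizes on real EEG or genotype data.

Label-first generation (draw the balanced outcome, then modalities
conditional on it) was preferred over a latent-liability model because it
matches the balanced case–control framing and makes every effect size
directly controllable.

# Numerical and design notes

* All randomness flows through one master seed; per-modality streams are
  derived by hashing a stream label, so any modality can be regenerated
  independently and full runs are byte-reproducible.
* The published feature count for 68 ROIs × 4 bands is 9221, which does not
  equal $4\binom{68}{2} = 9112$; the package follows the stated
  construction, hence 9112.
* A published PRS feature total of 1162 is not reconstructible from 47
  phenotypes × 9 thresholds = 423; the PRS module therefore takes any named
  set of summary-statistics tables and makes no attempt to reproduce that
  count.
* Welch spectral settings (2 s, 50% overlap, Hann) are declared defaults,
  not inferred ones: the source protocol's estimator settings are not
  public.
* Degenerate inputs fail loudly: constant channels and NaN samples are
  errors naming the ROI; recordings shorter than one segment report the
  minimum duration; monomorphic SNPs cannot clump others ($r^2$ defined 0,
  with a warning) and are dropped from PCA with a count.
* Problem sizes in the validation suite (e.g. 50 subjects per coherence
  target, a 400-subject recovery cohort with 5008 features, null cohorts of
  100–200 subjects) were chosen as the smallest sizes at which the checked
  properties have comfortable statistical margins.
* Null-calibration checks average over several independent label-permuted
  cohorts: a single 200-subject cohort's cross-validated accuracy carries
  roughly 3.5 percentage points of binomial noise, so the cohort-averaged
  mean is the quantity a tight chance-level band can sensibly bound.

# A worked example

```{r example, eval = FALSE}
library(remitpredict)

truth <- cohort_truth(
  n_per_group = 60,
  coherence_effects = tibble::tibble(
    roi_i = 1L, roi_j = 5L, band = "theta",
    msc_continued = 0.15, msc_remitted = 0.55),
  causal_snps = tibble::tibble(snp = "rs_example", log_odds = 0.5),
  covariate_effects = c(married = -0.6),
  seed = 42)

cohort <- generate_cohort(truth, n_rois = 8, duration = 60,
                          n_snps = 60, n_blocks = 10)

eeg <- coherence_features(cohort$signals)
prs <- compute_prs(cohort$genotypes, list(pheno = cohort$summary_stats),
                   cohort$reference)
tbl <- build_feature_table(list(eeg, prs), cohort$subjects)

stratum <- tbl |>
  stratify("male", "EA", features = c("EEG", "PRS", "marital")) |>
  complete_cases() |>
  age_match(caliper = 2)

res <- repeated_cv_evaluate(stratum, mode = "nested", seed = 7)
glance(res)
render_feature_report(res)
```

# Known limitations

* The paper_faithful mode is intentionally optimistic on high-dimensional
  data; never report it without the nested counterpart.
* The model-comparison t test is anti-conservative (repeat-level pairing).
* PRS portability across ancestries, LD-aware scoring methods, imputation,
  and source reconstruction from scalp EEG are out of scope.
* Synthetic effect sizes are arbitrary; absolute accuracies on synthetic
  cohorts say nothing about attainable accuracy on clinical data.
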