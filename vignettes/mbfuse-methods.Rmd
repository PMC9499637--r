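---
title: "Methods: multi-block PLS-DA fusion of paired microbiome and metabolome tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-block PLS-DA fusion of paired microbiome and metabolome tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbfuse)
```

# The analysis problem

`mbfuse` implements an integrated workflow for cohorts where each stool
sample carries two measurements — a 16S rRNA amplicon count table (taxa) and
an NMR metabolite concentration table — plus a clinical table with group
labels (e.g. patients at type-1-diabetes onset, their siblings, and healthy
controls) and disease markers (anti-GAD, IAA, IA-2, HbA1c, cholesterol,
insulin need, blood pH, age, c-peptide). The scientific questions it serves
are: do the groups differ ecologically (diversity, ordination, PERMANOVA)?
which individual taxa or metabolites differ (univariate scans with
multiplicity control)? and, centrally, how well can a classifier tell the
groups apart when both omic blocks are modelled jointly, and which features
drive that classification (multi-block PLS-DA with repeated double
cross-validation and VIP-based biomarker selection)?

# Preprocessing

**Feature filtering.** Taxa are removed when their total count across the
dataset is below 1% of the grand total, or when they are present (non-zero)
in fewer than 25% of the samples. Both comparisons are inclusive (`>=`
survives). The 1% rule is read as *per-feature total over the dataset grand
total*: a per-sample reading would remove essentially every feature in
realistic data, so the dataset-level reading is the only workable one; both
thresholds are arguments of `filterFeatures()`, not constants.

**Cumulative sum scaling (CSS).** Counts are normalized by dividing each
sample by the sum of its counts up to a chosen quantile of its *non-zero*
counts (zeros are excluded from the quantile, matching the reference
implementation of the method), then multiplying by a fixed scale (1000).
This attenuates the influence of a few dominant taxa relative to
total-sum scaling. The reference quantile is chosen data-adaptively by
`cssReferenceQuantile()`: scanning the grid 0.05, 0.10, ..., 0.95, it
returns the smallest level at which the median relative deviation of the
per-sample cumulative sums from their across-sample median exceeds 0.1; if
the criterion never triggers (e.g. all samples identical) it falls back to
0.5 with a warning. The procedure is deterministic.

**Which tables feed which stage.** Alpha diversity (Shannon, Simpson,
bias-corrected Chao1) is computed on *unnormalized* counts, because richness
estimators need raw singleton/doubleton counts. Beta diversity
(Bray-Curtis) and the univariate taxa scans run on relative abundances; the
chemometric stages run on CSS-normalized counts. Shannon defaults to log
base 2 (the convention of the common ecology toolkits); the base is an
argument.

# Ecology

Bray-Curtis distances, principal coordinate analysis (Gower double-centering
of $-d^2/2$; axes with non-positive eigenvalues are dropped from the
coordinates but all eigenvalues are reported), and PERMANOVA. The PERMANOVA
pseudo-F is computed from total and within-group sums of squared distances;
significance comes from label permutation with the add-one estimator
$p = (1 + \#\{F_\pi \ge F\})/(1 + n_\pi)$, switching automatically to exact
full enumeration of the distinct label assignments whenever there are at
most `nPerm` of them. UniFrac distances are out of scope: they require a
phylogenetic tree this package does not construct.

# Clinical profiling

The nine clinical variables are autoscaled (column mean 0, SD 1, $n-1$
denominator) and decomposed by SVD-based PCA; rows with any missing value
among the nine variables are dropped with a logged count (the simplest
auditable rule). Pairwise Pearson correlations use pairwise-complete
deletion. Patients are stratified by the standard cut-offs: blood pH
severity strata (normal $\ge 7.32$, moderate $[7.10, 7.32)$, severe
$< 7.10$), the binary pH split at 7.32 (the boundary belongs to the
"$\ge$" side), and anti-GAD $> 1$ U/mL (the boundary value 1 is "low").

# The chemometric core

**PLS-DA.** Binary classification uses NIPALS PLS1 on a single centered 0/1
class indicator. Per component: $w_a \propto X^\top y$ (unit norm),
$t_a = X w_a$, then $X$ and $y$ are deflated. The regression vector is
$b = W (P^\top W)^{-1} q$, and a new sample is assigned to the positive
class iff its continuous prediction is $\ge 0.5$; ties at exactly 0.5 go to
the positive class. The 0.5 rule is a package decision — the dummy coding
and assignment rule are otherwise arbitrary. Multi-class coding is out of
scope; all study contrasts are two-class. Component signs in PCA are fixed
by forcing the largest-magnitude loading entry positive, so refits are
byte-identical.

**VIP.** Variable importance in projection:
$\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a (w_{ja}/\lVert w_a\rVert)^2
/ \sum_a \mathrm{SSY}_a}$, where $\mathrm{SSY}_a$ is the response sum of
squares explained by component $a$. The squared VIPs sum to $p$ by
construction, so VIP > 1 marks an above-average contribution; the selection
threshold is 1.15.

**Low-level fusion.** Each block is autoscaled, divided by its Frobenius
norm ($\lVert X\rVert_F = \sqrt{\sum_{jk} x_{jk}^2}$) to level out the
blocks' contributions, and the blocks are concatenated row-wise
(samples stay rows). Multiplying a raw block by any $c > 0$ leaves the
fused matrix unchanged. A standard PLS-DA is then fitted on the
concatenated matrix.

**Repeated double cross-validation (rDCV).** Per repetition: a stratified
outer split (default 5 folds) estimates performance; inside each outer
training partition a stratified inner CV (default 5 folds) selects the
number of components minimizing the pooled inner misclassification error,
ties going to the smallest model. All preprocessing — per-block autoscaling
and Frobenius scaling — is estimated on the training partition of the fold
at hand and applied frozen to held-out rows, so test data never influence
preprocessing, model-size selection, or the fit (this is audited by a test
in which a label-revealing column present only in test folds must not lift
accuracy above chance). Figures of merit (accuracy, sensitivity,
specificity, in percent) are computed per repeat from the pooled
out-of-fold predictions and reported as mean ± SD over repeats. Per repeat,
a VIP vector is recorded from a refit on all samples at the repeat's median
chosen component count (half-integer medians round down, consistent with
the smallest-model tie rule); whether VIPs should come from per-fold models
or a refit is an open design choice, and the refit was chosen because it
yields one well-defined VIP per feature and repeat. Defaults: 5 outer
folds, 5 inner folds, 20 repeats, at most 10 components — values chosen as
conventional for cohorts of one to two hundred samples.

**Biomarker rule.** A feature is *selected* when its VIP reaches the
threshold (default 1.15) in at least half of the repeats (the consistency
fraction is configurable); selected features are then *confirmed* by
Mann-Whitney tests with Bonferroni correction at 0.05 — the two-stage rule.
The ecology-wide univariate scans instead use Kruskal-Wallis with
Benjamini-Hochberg FDR (flagging on the conjunction raw $p \le 0.05$ and
FDR $\le 0.1$); the two multiplicity regimes are deliberately kept
distinct, matching how each is used.

**Permutation testing.** The null distribution of each figure of merit is
built by permuting labels (default 1000 times) and repeating the rDCV
computation at a reduced repeat count (default 1). Every permutation
reuses the outer-fold structure derived from the unpermuted labels so that
the test isolates label exchangeability. $p = (1 + \#\{\text{null} \ge
\text{obs}\})/(1 + n_\pi)$ per metric, bounded below by $1/(n_\pi+1)$.

# The synthetic study generator

`generateStudy()` draws bundles with the statistical structure the analysis
assumes, so every stage is testable without cohort data. Its defaults *are*
the emulated study conditions and are not tuned per analysis:

* three groups of 52 / 17 / 57 samples;
* per-sample library sizes log-normal with mean 75,154 reads and CV 0.3
  (the CV is a modelling choice — only the mean depth is an observed
  condition);
* counts are Dirichlet-multinomial: a rank-abundance-ordered baseline
  composition (normalized log-normal weights, SD 1.5 on the log scale) is
  modified per group by planted log2 fold changes and renormalized, and
  each sample's composition is a Dirichlet draw around its group
  composition with total concentration 200. The Dirichlet-multinomial
  (rather than plain multinomial) gives the overdispersion characteristic
  of 16S tables; the concentration is exposed as a parameter;
* 37 metabolites with log-normal marginals; planted group shifts act on
  the log scale in SD units; each planted taxon-metabolite link blends the
  metabolite's standardized log value with the linked taxon's standardized
  CSS-normalized log abundance, weight $r$ against $\sqrt{1-r^2}$
  independent noise, hitting the target Pearson correlation in expectation
  *on the log scale* (the scale the analysis works on). The default link
  plants $r = -0.68$;
* a clinical table drawn through a Gaussian copula with a target
  correlation matrix (defaults plant $r = 0.33$ between insulin need and
  HbA1c, $-0.33$ between insulin need and blood pH, $-0.36$ between
  anti-GAD and HbA1c). Marginals are parameterized from the cohort means
  and SDs of a pediatric T1D-onset population; no distributional detail
  beyond mean ± SD is available for them, so the families (normal,
  truncated normal, log-normal) are modelling choices. Blood pH is a
  two-component normal mixture at 7.18 (SD 0.08) and 7.38 (SD 0.04) with
  weights 0.54/0.46, reproducing the below/at-or-above-7.32 strata
  proportions that the pH-based stratification exploits. Monotone marginal
  transforms attenuate Pearson correlations slightly relative to the
  latent targets; with the default marginals the attenuation is under
  0.04, well inside the tolerances the tests use;
* one master seed expands into independent per-table substreams, so
  regenerating one table never perturbs the others.

What the generator does **not** emulate: sequencing reads and their error
structure, chimeras, NMR spectra, longitudinal sampling, and sibling-pair
genetic structure beyond a shared group-level composition effect. Passing
tests on these bundles therefore demonstrate the correctness and
calibration of the *statistical machinery* under the declared generative
model — not that the pipeline recovers biology from real cohorts.

# Numerical choices and degenerate inputs

* Autoscaling uses the two-pass algorithm so constant columns give exact
  zeros; zero-variance columns are dropped (fold-locally inside CV) with a
  warning, and an all-constant matrix is an error.
* NIPALS stops with an error when a requested component exceeds the rank of
  the training matrix; inside cross-validation the component count is
  truncated to what the fold supports instead.
* A cross-validation training fold that loses one class entirely (possible
  only under permuted labels) falls back to majority-class prediction.
* All-identical values give Kruskal-Wallis H = 0, p = 1 by convention.
* Mann-Whitney uses the exact null when $n_x + n_y \le 12$ with no ties,
  otherwise the tie-corrected normal approximation.
* Permutation p values use the add-one estimator and can never be 0.

# Problem sizes used by the test-suite simulations

The suite exercises the stack at deliberately modest sizes — e.g. null
calibration on 40 + 40 samples with 150 taxa over 200 replicates at 99
permutations each, and signal recovery with 10 features shifted by 1.5 SD
among 200 at 60 + 60 samples — sizes at which the calibration and power
properties under test are already stable and a full run stays comfortable
on a laptop.

# Known limitations

* Two-class PLS-DA only; no OPLS-DA, kernel or sparse variants, and no
  mid/high-level fusion or block-weight optimization.
* UniFrac, rarefaction, PERMDISP and zero-inflated count models are out of
  scope.
* The clinical copula controls latent (normal-scale) correlations; extreme
  marginal skew would attenuate observed Pearson correlations, so planted
  values are only guaranteed near the defaults' moderate skew.
* Dense tables only; no sparse BIOM-HDF5 input.
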