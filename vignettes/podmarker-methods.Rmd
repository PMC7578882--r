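---
title: "Methods: microbial marker discovery and POD classification"
author: "podmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbial marker discovery and POD classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podmarker)
```

# Scope

`podmarker` implements the analysis arc common to case-control gut-microbiome
marker studies: profile community diversity, screen OTUs for differential
abundance, score effect sizes LEfSe-style, select a minimal optimal marker
set with a random forest and repeated cross-validation, score every sample
with a probability-of-disease (POD) index, evaluate the classifier by
ROC/AUC on held-out cohorts, and correlate marker abundances with clinical
indicators.  Everything downstream of the OTU count table is in scope;
read-level processing (merging, chimera removal, OTU clustering, taxonomy
assignment) is upstream of the package and out of scope.

Because real cohorts of this kind are deposited as raw sequence archives
and are not redistributable at package scale, the package ships a
synthetic-cohort generator with recorded ground truth.  All tests and the
acceptance script run end-to-end on generated cohorts.

# The data model

An `otu_table` is a samples x OTUs matrix of non-negative integer read
counts with unique ids; `sample_metadata` carries a two-level group label
(case/control), a cohort tag (discovery/validation/independent) and numeric
clinical indicators with missing values allowed.  TSV I/O is lossless and
orientation is always *declared* (`samples_in = "columns"` by default, the
common OTUs-in-rows amplicon convention), never guessed; BIOM-JSON v1.0 is
supported through the biomformat package.

Relative abundance is `count / library size` with no pseudocount, so rows
sum to exactly 1.  Rarefaction subsamples without replacement
(hypergeometric, via `vegan::rrarefy`) to a common depth, drops samples
below the depth with a warning naming them, and is fully seeded.  Whether
diversity is computed on rarefied or raw counts is a user choice; the
pipeline default is rarefied (to the minimum library size), because the
richness estimators below are depth-sensitive.

# Diversity

Alpha diversity per sample:

* observed OTUs: number of taxa with count > 0;
* Shannon entropy \(H = -\sum_i p_i \ln p_i\) over positive proportions —
  natural log by default so a uniform community of \(S\) taxa has
  \(H = \ln S\); a `base` argument switches conventions;
* Chao1, in the bias-corrected form
  \(S_{obs} + F_1(F_1 - 1) / (2 (F_2 + 1))\) with \(F_k\) the number of
  taxa seen \(k\) times — finite even without doubletons;
* ACE with the standard rare/abundant threshold of 10 (configurable):
  abundant taxa counted directly, rare taxa estimated through the sample
  coverage \(C = 1 - F_1/N_{rare}\) and the squared coefficient of
  variation \(\gamma^2\); when every rare taxon is a singleton the coverage
  is 0 and the estimator falls back to bias-corrected Chao1.

These estimators are implemented directly from their classical definitions
so that the degenerate branches (no rare taxa, zero coverage, `N_rare = 1`)
are explicit; the test suite cross-checks them against `vegan::estimateR`
on non-degenerate vectors and against independent brute-force evaluations
of the formulas on 1000 random vectors.

Beta diversity is Bray-Curtis,
\(BC(x, y) = 1 - 2\sum_i \min(x_i, y_i) / (\sum x + \sum y)\), on relative
abundances (via `vegan::vegdist`), ordinated by classical PCoA
(double-centred Gower matrix eigendecomposition via `stats::cmdscale`).
Negative eigenvalues are reported but their axes dropped, and the
proportion explained is taken relative to the sum of positive eigenvalues.
Covariance PCA on relative abundances is provided as a second ordination;
NMDS is deliberately not implemented — an iterative stress minimiser adds
nothing to the package's testable claims beyond what PCoA provides.

Group-overlap (Venn) accounting calls an OTU present in a group when its
summed count there is at least `presence_min` (default 1, since no
published counting rule is standard); shared, per-group-unique and total
counts follow by set algebra.

# Differential abundance

The screen is the two-sided Mann-Whitney/Wilcoxon rank-sum test per
feature (`stats::wilcox.test`): exact enumeration for small tie-free
groups, otherwise the midrank, tie-corrected normal approximation without
continuity correction — chosen so that the two-group case agrees
algebraically (to 1e-9) with the Kruskal-Wallis chi-squared test.  A
feature with identical values in both groups gets p = 1.

**No multiple-testing correction is applied by default.**  This mirrors
the practice of the biomarker-screen literature this package emulates,
where selection uses raw p < 0.05; it inflates the family-wise error and
is documented here prominently for that reason.  A Benjamini-Hochberg
option (`adjust = "BH"`) is available.

The LEfSe-style effect size is reimplemented for the single-factor,
two-class design (no subclass structure): Kruskal-Wallis prescreen at
p < 0.05, then, per feature, abundances scaled so each sample sums to 1e6
(the LEfSe convention), bootstrap resampling within groups (30 resamples,
seeded, as in canonical LEfSe), the absolute difference of group means
along the per-feature discriminant averaged over bootstraps, and the score
reported as log10 of that difference floored at 1 for any non-zero effect
(zero-variance features score 0).  A feature passes at the conventional
double threshold: KW p < 0.05 and score >= 2.  With a single feature and
two classes the LDA direction is the feature axis itself, so the
"difference along the discriminant" reduces to the scaled group-mean
difference; this is the simplification the two-class case admits.

Taxonomy aggregation sums counts over OTUs sharing a rank label; OTUs
unassigned at the rank are pooled under `<nearest assigned parent>_norank`
and OTUs absent from the map under `unclassified_norank`, so column sums
are conserved at every rank.

# Marker selection

The selection procedure is deliberately faithful to the two-stage design
it reproduces:

1. Wilcoxon screen at raw p < 0.05 on the discovery cohort's relative
   abundances (unrarefied by default).
2. A random forest on the screened features with all parameters default
   except `importance = TRUE` (500 trees); features ranked by mean
   decrease in accuracy, ties broken by column order.
3. Five trials of stratified fivefold cross-validation over the nested
   prefixes of that ranking.  "Error" is the misclassification rate pooled
   over held-out folds (the source procedure leaves this undefined;
   pooling is the `rfcv`-style convention and is robust to imbalanced
   groups, which is also why folds are stratified).  Each trial draws a
   fresh fold partition, shared across prefix sizes within the trial.
4. The minimum-error-plus-SD rule: cutoff = minimal mean error + the
   between-trial SD at the minimising size (ties to the smallest size);
   candidates are sizes with mean error strictly below the cutoff; the
   smallest candidate wins.  When the SD at the minimum is zero the
   comparison relaxes to "at or below" — otherwise the minimum itself
   would be excluded and the rule degenerate.

Two caveats are intentional and documented rather than hidden.  First, the
importance ranking is computed once on the full discovery cohort and *not*
recomputed inside cross-validation folds; the error curve therefore
carries selection leakage and is an optimistic estimate.  This is faithful
to the two-stage procedure being reproduced; the transport evaluation on
independent cohorts (below) is the honest measure.  Second, the rule is a
parsimony rule: when one or two features already attain the minimal error,
it stops there.  On small, clean cohorts the chosen set is genuinely
smaller than the planted set — visible on the shipped worked example,
where 3 of 5 planted markers are chosen and all chosen markers are
planted.

A further property of compositional data is worth knowing when judging
"false" positives: planting a multiplicative effect on a few percent of
community mass shifts the *relative* abundance of every other OTU through
renormalisation, so on strong-effect cohorts some non-planted OTUs are
genuinely differentially abundant in relative terms and may legitimately
enter the screen and the marker set.

# POD classification and evaluation

The final model is a random forest restricted to the chosen markers.  The
POD index of a sample is the fraction of trees voting for the case class;
the literal case/control vote *ratio* is available behind a flag but is
unbounded (infinite when no tree votes control) and induces the same
ordering, so ROC/AUC results are identical — the fraction is the default
for that reason.

ROC/AUC uses pROC (the field's standard): the empirical ROC over all
distinct thresholds with case as the positive class; the AUC equals the
normalised Mann-Whitney statistic with ties counted one half (verified in
the tests against exhaustive pair counting to 1e-12); the 95% CI is
DeLong's by default, with a seeded bootstrap option.  Cohort evaluation
refuses any cohort sharing sample ids with the training set and reports,
per cohort, the scores, the ROC with CI, and a Wilcoxon p for the
case-control difference in POD.

# Clinical correlation

Marker abundances are correlated with clinical indicators by midrank
Spearman correlation, pairwise-complete over missing clinical values, with
the number of complete pairs recorded per cell; cells with fewer than 3
complete pairs are flagged `NA` rather than raising.  The "partial"
variant (rank-regress both variables on a *stated* covariate set and
correlate residuals, p from a t reference with reduced degrees of freedom)
is provided but off by default: published "partial Spearman" analyses of
this kind rarely state their adjustment set, and plain Spearman is the
reproducible default.

# The synthetic cohort generator

The generator is the package's test bed and defines the study conditions;
its defaults are fixed, not tuning knobs.

* **Population.** A log-normal base profile: per-OTU log abundances
  \(N(0, 2)\) over 100 OTUs, softmax-normalised — a realistically uneven
  community spanning roughly four orders of magnitude.  The planted
  differential set (5 OTUs by default) is drawn from the 65-90% abundance
  quantile window: abundant enough that an effect is observable at
  realistic sequencing depth, below the dominant taxa so renormalisation
  barely distorts the nominal fold change.  Half the planted OTUs are
  enriched in cases (profile multiplied by \(2^{\mathrm{lfc}}\), default
  lfc = 3), half in controls (divided), then the case profile is
  renormalised.  The base profile and planted set are drawn from
  `spec$seed` alone, so cohorts drawn from one spec share their ground
  truth and differ only in sampled individuals — this is what makes
  "independent cohort from the same population" meaningful.
* **Samples.** Library sizes log-normal(log 1e4, 0.5); composition per
  sample Dirichlet with concentration 50 around the group profile
  (moderate compositional overdispersion: rare taxa are present-or-absent
  across samples, as in real 16S data); counts a single multinomial draw
  of the library size, so row totals equal the drawn library sizes
  exactly.
* **Sparsity.** The target marginal zero fraction (default 0.6, chosen at
  the model's natural zero rate under the defaults) is reached by per-cell
  dropout applied to the Dirichlet weights before the multinomial draw.
  The natural zero fraction is computed analytically per cohort from the
  beta-binomial zero probability, and the dropout rate solves for the
  target; a target more than 0.25 below the natural rate is diagnosed as
  infeasible (the margin absorbs draw-to-draw variability of the
  heavy-tailed profile).
* **Clinical covariates.** Six indicators (SCr, BUN, eGFR, ALB, Hb,
  phosphate) drawn normal around realistic healthy baselines with
  group shifts in SD units (defaults +3, +2, -3, -1, -1.5, +1 for cases,
  the directions kidney disease moves them).  They depend on the counts
  only through the group label; correlation-structure realism between
  taxa and chemistry is out of scope.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: taxon-specific biology, phylogenetic signal,
batch and site effects beyond a simple log-normal profile perturbation
(`site_log_sd`), longitudinal structure, and abundance-correlated clinical
chemistry.

The fixed worked example (`spike_worked_example()`) is a 20-sample x
30-OTU cohort with 5 planted markers at lfc = 2, regenerated
deterministically from a hard-coded spec; its discovery output is pinned
in the regression tests.

# Numerical and design choices

* All stochastic stages take explicit seeds; a single master seed is split
  into stage sub-streams by the documented rule
  `derive_seed(seed, k) = (seed + 999983 k) mod (2^31 - 1) + 1`, so any
  stage can be reproduced in isolation.  Seeded functions restore the
  caller's RNG state.
* Ties: importance ranking breaks ties by column order; the error-curve
  argmin resolves ties to the smallest size; rank tests use midranks with
  tie corrections; AUC counts ties one half.
* Degenerate inputs are handled explicitly and tested: all-zero samples
  are an error for normalisation and Bray-Curtis; constant features get
  p = 1 (Wilcoxon, KW) and effect 0 (LDA score); zero coverage falls back
  to Chao1; `n < 3` complete pairs flags a correlation cell as
  not-computable.
* Type-I calibration of the screen is asserted over *testable* features: a
  sparse null cohort contains OTUs observed in no sample, for which no
  test exists (p = 1 by construction); including them mechanically
  deflates the raw rejection fraction below the nominal level.  The raw
  fraction is additionally checked to be non-anticonservative.
* DeLong CI coverage is checked on binormal scores (cases N(1,1),
  controls N(0,1), true AUC = 0.760) at n = 50+50 with 2000 replicates,
  keeping the Monte Carlo error of the coverage estimate (~0.5%) well
  inside the 2.5% assertion band.  A closed-form true AUC is used because
  the "true" AUC of a generator-trained classifier is not available
  analytically.
* Simulation sizes throughout the suite (20-seed recovery/transport runs,
  200-replicate null calibration, 60-replicate calibration sweeps) were
  chosen to keep Monte Carlo error comfortably inside each assertion band
  while the full suite runs in minutes on one CPU.

# The pipeline and its interface

`run_pipeline()` executes the whole workflow from a config list or
YAML/JSON file — generate or load cohorts, rarefy, diversity + ordination
+ overlap, screen + effect sizes (+ per-rank aggregation when a taxonomy
is given), marker discovery on the discovery cohort, POD training,
evaluation on discovery (resubstitution), validation and independent
cohorts, and marker-clinical correlation — writing every stage result as
TSV/JSON plus a `manifest.json` with the effective config, derived stage
seeds, input hashes and per-stage status.  Outputs are byte-identical for
identical config and seed; on stage failure, partial outputs are kept and
the manifest records the failure point before the error is re-raised.

The package's functions are the primary interface; a thin command-line
wrapper over `run_pipeline()` ships in `inst/scripts/podmarker-pipeline.R`
for shell use.  For synthetic runs the validation cohort is an independent
draw from the discovery population and the independent cohort adds a
log-normal site perturbation (`site_log_sd`, default 0.3) to emulate a
second recruitment site.

# Known limitations

* The error curve inherits selection leakage by design (see above); use
  the held-out cohort evaluations for honest performance.
* The LEfSe reimplementation covers only the two-class, single-factor
  design; no cladogram, no subclass stratification.
* No phylogeny-aware distances (no tree in the data model).
* POD is a vote share, not a calibrated probability; no decision cutoff
  is chosen.
* Raw p-value selection (no multiplicity control) is a faithful-
  reproduction choice, not a statistical recommendation.
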