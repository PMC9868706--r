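---
title: "Chemotype discovery and chemomarker screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemotype discovery and chemomarker screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(chemotyper)
```

chemotyper re-implements, as a reusable and tested pipeline, the analysis
chain used to classify plant germplasm collections into *chemotypes* —
intraspecific classes distinguished by metabolite composition — from
untargeted GC-MS/LC-MS feature tables, and to link the discriminating
metabolites (*chemomarkers*) to morphological traits. This vignette
explains each model, the parameters that matter, the numerical choices,
and what the synthetic validation data can and cannot show.

## The data model

The universal currency is a `feature_table`: a sample × feature intensity
matrix plus per-sample metadata (biological vs pooled-QC role, injection
order, collection, replicate, platform) and per-feature annotation.
Intensities are non-negative instrument units; empty cells are missing
(undetected) values, while zeros are treated as measured. Morphology
lives in a separate collection × trait table restricted to a fixed
13-trait vocabulary (LL leaf length, LTWR length/width ratio, LDH/LDW/LDN
dentation height/width/number, LW width, LA area, CRV chlorophyll
reference value, LP perimeter, LT thickness, SL stipe length, SLFW/SLDW
specific fresh/dry weight); its loader rejects unknown columns and
missing cells rather than imputing silently.

## Preprocessing

The conditioning chain mirrors standard untargeted-metabolomics practice:

1. **Detection filter.** Features missing in ≥ 80% of *biological*
   samples are removed (inclusive boundary; QC samples never count).
2. **KNN imputation** (`k = 10`). A missing cell becomes the mean of the
   feature over the k nearest samples; sample–sample distance is
   Euclidean over features observed in both, normalized by the
   shared-feature count so samples with different missingness patterns
   stay comparable.
3. **QC-anchored drift correction.** Per feature, a regressor of QC
   intensity on injection order is fitted on QC samples only — random
   forest (500 trees, nodesize 5), LOESS (span 0.75, degree 2, direct
   surface so run edges extrapolate), or radial-kernel SVR (epsilon
   0.1) — and every sample is divided by the fitted value normalized to
   the QC median. Factors are clipped to [0.1, 10] to prevent blow-ups at
   run edges. `select_correction()` runs all three and keeps the method
   whose *reserved fraction* (share of features with corrected QC RSD
   below the platform threshold: 0.50 for GC-MS, 0.30 for LC-MS) is
   highest among those reaching 0.70, with ties preferring RF, then
   LOESS, then SVR.
4. **Optional replicate-outlier screening.** Within each collection, the
   replicates farthest from the collection centroid in the global top-2
   PC plane are dropped; collections with too few replicates are kept
   intact with a warning. This step is off by default (`n_outlier_remove
   = 0`) because three-replicate designs cannot spare three outliers.
5. **Log standardization and averaging.** log10, per-feature autoscaling
   over biological samples, replicate averaging within collection, QC
   samples dropped. Log base and unit-variance scaling are conventions;
   both live behind the function boundary.

## Chemotype discovery

**Gap statistic.** For each candidate k, the within-cluster dispersion of
the best of 10 seeded K-means restarts is compared against B = 50 uniform
reference draws over the data's bounding box;
`gap(k) = mean_b log W_kb − log W_k` with simulation error
`s_k = sd_b √(1 + 1/B)`, and the selected k is the smallest k with
`gap(k) ≥ gap(k+1) − s_{k+1}` (ties toward smaller k). This stopping rule
is deliberately conservative: it returns k = 1 on structureless data,
which is exactly the generator's no-signal regime.

**Self-organizing map.** A 7 × 7 rectangular SOM is trained for 100
epochs of sequential best-matching-unit updates. The Gaussian
neighbourhood is truncated at the current radius, which decays linearly
from `max(rows, cols)/2` to 0.5 — so the final phase is winner-only and
the codebook can converge — while the learning rate decays 0.5 → 0.01.
The codebook is initialized deterministically on the top-2 PC plane;
only the per-epoch presentation order is random. After each epoch the
quantization error (mean sample→BMU distance) and topographic error
(fraction of samples whose two best nodes are not 4-adjacent) are
recorded, and the returned codebook is the epoch snapshot minimizing
`qe + te` (equal weights, configurable) — our fixed-iteration reading of
"minimum quantization and topology error" as a termination criterion.
Nodes become chemotypes by average-linkage hierarchical clustering of the
codebook vectors cut at k (the standard two-stage SOM practice; the
original analysis does not state how its 49 nodes became 4 groups), and
collections inherit their BMU's group. Chemotype labels are numbered by
descending group size — a convention, since the original I–IV ordering
rule is unknowable from its non-monotone group sizes.

**Adjudication.** Competing classifications (SOM vs K-means across k)
are scored by a random-forest discriminant protocol: stratified 75/25
split, 1,000 trees, out-of-bag training accuracy, independent-set
accuracy, and macro one-vs-rest AUC, averaged over repeated seeded
splits (20 by default; the packaged end-to-end runs use 5, which already
stabilizes the comparison at our problem sizes). The winner maximizes
the mean of training and independent accuracy.

## OPLS-DA and the chemomarker screen

Each chemotype is contrasted one-vs-rest with an orthogonal-projection
PLS discriminant model: orthogonal components (X-variation uncorrelated
with the class) are stripped first, then a single predictive component is
fitted. R²Y(cum) is the explained class variance; Q²(cum) is
`1 − PRESS/TSS` over stratified 7-fold cross-validation (the convention
of the field's commercial tool); with zero orthogonal components the
model reduces exactly to PLS1, which the tests exploit as an oracle.
Permutation validation refits on shuffled class labels and reports
empirical p-values `(1 + #{permuted ≥ observed})/(n_perm + 1)`.

VIP follows the classical definition — squared component weights weighted
by the class variance each component explains, scaled so Σ VIP² equals
the number of features. Orthogonal components explain zero class
variance by construction, so they influence VIP only through the
orthogonal filtering of the predictive weights. We considered weighting
orthogonal components by the X-variance they remove, but that ranks
class-*uncorrelated* structure above the discriminative features and
defeats a VIP ≥ 2 marker screen; the classical form keeps both the
normalization identity and the PLS1 limit.

A feature is a **chemomarker** of a chemotype iff it jointly passes four
criteria: VIP ≥ 2 (inclusive), two-sided pooled-variance Student's t-test
p < 0.05, |log2 FC| > 0.5 with FC the linear-scale group/rest mean ratio,
and SE-scaled random-forest mean decrease accuracy ≥ 2. The literal
raw-ratio reading of the fold-change rule ("FC > 0.5") excludes almost
nothing and contradicts the existence of down-regulated markers, so the
two-sided log2 form is the default and the raw rule is a config flag.
MDA is computed one-vs-rest per chemotype with 1,000 trees; the ≥ 2
threshold is only meaningful for the SE-scaled (z-like) importance, which
is what `randomForest::importance(type = 1, scale = TRUE)` reports. No
multiple-testing correction is applied — the joint criterion is already
far stricter than p < 0.05 alone — and a BH-adjusted column can be added
downstream if desired. Because the rest-group mean of chemotype c is
inflated by the other chemotypes' markers, one-vs-rest screening
re-detects those as *down*-markers of c; this is real structure (it is
why exclusivity analysis exists), and the recovery metrics treat it as
such: sensitivity counts planted (chemotype, feature, up) triples
recovered exactly, precision counts a screened record as correct when
its feature is planted for some chemotype with a direction consistent
with that planting.

## Trait linkage

Metabolite co-expression modules use an unsigned weighted network:
adjacency `|cor|^β`, topological-overlap similarity, average-linkage
clustering on 1 − TOM, static cut at height 0.99, clusters below 10
features discarded to module 0 ("grey"). The static cut is a
deterministic simplification of dynamic tree cut; deviation from the
original study's "nine modules / 601 metabolites" is expected and
unavoidable without its raw data. The soft power β is the smallest one
whose scale-free fit reaches 0.8 — but only among powers whose mean
connectivity stays ≥ 1. The floor matters: block-structured metabolite
data is *not* scale-free at low powers, and chasing the fit alone drives
β so high that the network is empty and the static cut can find nothing,
while moderate powers recover planted blocks perfectly. Each module's
eigenmetabolite is the first PC of its standardized submatrix, unit
variance, sign oriented to positive mean loading so correlation signs
are reproducible; modules are named by the conventional size-ordered
colour sequence (turquoise, blue, brown, …).

Module–trait links are Pearson correlations (two-sided p) between
eigenmetabolites and traits. A chemotype's *morphological marker* is
found by locating the module holding most of its up-regulated
chemomarkers and taking that module's most strongly correlated trait
(max |r| with p < 0.05). Trait predictability is the out-of-fold R² of a
nested-CV LASSO (outer 10 folds; inner `cv.glmnet` with the 1-SE rule),
which can be negative and is never clamped; per-module random-forest
regression reports %IncMSE. Trait differences across chemotypes use
one-way ANOVA with Tukey HSD.

## The synthetic-data generator

`generate_dataset()` plants everything the pipeline is supposed to find.
On the natural-log scale, a biological intensity is

baseline + marker effect + module effect + drift + replicate noise,

with per-feature log-normal baselines (location ln 10⁵, scale 1),
chemotype markers shifted by `log2fc·ln 2`, module features loading
`√ρ` on a shared collection-level Gaussian factor (so the planted
intra-module correlation is ρ), smooth injection-order drift (monotone
trend + low-frequency random walk, mean factor exactly 1 per feature),
and i.i.d. Gaussian replicate noise. QC samples are the pooled mean of
the expected biological profiles — zero chemotype signal by
construction — with technical noise only. Missingness is half MCAR, half
preferential in the lowest-intensity decile, mimicking abundance-linked
MS dropouts. Traits are `coef × module factor + noise`; the default
links modules 1–4 to LL, CRV, LDH and LT with coefficient 0.75 against
unit noise, a true correlation of 0.6.

Default study conditions: 160 collections × 3 replicates, 600 features,
4 chemotypes of 60/50/30/20 collections, 25 up-markers per chemotype at
|log2FC| = 1, drift amplitude 0.2, 15% missing, QC opening the run and
recurring after every 10 biological injections. Free parameters were set
on realism grounds: biological replicate noise sd 0.25 in ln units
(≈ 25% CV, typical for plant material), QC technical noise sd 0.10
(≈ 10% CV). The module latent-factor scale defaults to 0.1 so that the
planted chemotypes are the *primary* variance structure — an early draft
used 0.5, at which the five 40-feature module directions carried more
standardized variance than the chemotype separations and clustering
recovered modules instead of chemotypes, contradicting the generator's
design intent (with markers off the matrix is meant to have no cluster
structure at all). Module-focused studies raise `module_sd` to 0.5, at
which the realized collection-level intra-module correlation is ≈ 0.66
for ρ = 0.7.

What passing on this generator does *not* show: real metabolomes have
heavy-tailed intensity distributions, correlated drift across features,
batch boundaries, adduct/isotope redundancy, and annotation error — none
of which are simulated. Recovery here validates the statistical
machinery, not instrument-level robustness.

## Validation problem sizes and numerical choices

The test suite's heavier checks run at deliberately chosen sizes: the
end-to-end run at the full default conditions above; gap-statistic
calibration on four unit-sd Gaussian blobs with centres placed uniformly
at random in 3-D under a ≥ 6σ pairwise-separation constraint (symmetric
2-D lattices make the gap curve locally flat at small k, where the 1-SE
stopping rule stalls by design; the asymmetric random layout is the
generic case); drift-correction stability on a near-noise-free zero-drift
table (QC technical CV 1%) plus an exactly-flat identity check, because
under realistic technical noise a max-relative-change bound measures
regressor variance rather than invented drift; and LASSO calibration
(signal fraction 0.5 across 10 of 50 features) at n = 300 collections,
where the 1-SE rule's ≈ 0.15 R² shrinkage cost still leaves the
out-of-fold R² centred near 0.42.

Other numerical conventions: drift factors clipped to [0.1, 10];
features whose QC values are all missing pass through uncorrected and
flagged; zero-pooled-variance t-tests report p = 1 with a flag; constant
features standardize to 0 rather than NaN; stage seeds derive from the
global seed by a stable integer hash (`stage_seed()`), so every stage is
individually reproducible and below 2³¹.

## Known limitations

- The SOM uses rectangular 4-connected topology only; no hexagonal or
  toroidal grids, no growing maps.
- Module detection uses a static cut, not dynamic tree cut, and does not
  merge modules by eigenmetabolite similarity.
- OPLS-DA is binary one-vs-rest; there is no multi-class OPLS.
- Drift correction addresses injection-order drift within a run, not
  batch effects across instrument batches.
- Headline numbers from the original leaf study (Table-1 accuracies,
  1,100 annotated metabolites, 103 markers, module counts) depend on its
  deposited raw spectra and annotation-database versions and are not
  reproducible from synthetic data; the pipeline validates the methods'
  behaviour, and its reports are analogues, not reproductions.
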