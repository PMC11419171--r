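---
title: "Sub-phenotype clustering and cluster-stratified association: methods"
author: "endoclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-phenotype clustering and cluster-stratified association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoclust)
```

## The problem

Endometriosis is clinically heterogeneous: patients present with pain
syndromes, uterine comorbidities, pregnancy complications, cardiometabolic
disease, or hardly any coded history at all. When all cases are pooled into a
single case-control phenotype, genetic effects that act in only one clinical
subgroup are diluted. `endoclust` implements the alternative analysis end to
end: derive sub-phenotype clusters from binary ICD-derived clinical features
in a large EHR cohort, characterize the clusters, transfer the cluster labels
into genotyped cohorts with a nearest-neighbour classifier, and run
cluster-stratified candidate-locus association with a random-effects
meta-analysis across ancestry strata, against a pooled positive control and a
size-preserving randomized negative control.

Because the EHR-linked biobanks this style of analysis runs on are
access-controlled, the package ships a synthetic cohort generator with
planted subtypes and subtype-specific genetic effects. Every stage of the
pipeline is exercised and tested against that generator; nothing requires a
data download.

## Case definition and features

Case status is ICD-defined: any billing code with canonical prefix `617`
(ICD-9) or `N80` (ICD-10) in a female subject. Codes are canonicalized by
uppercasing and stripping dots, and all matching is prefix matching on the
canonical form, so `N80.1`, `N801` and site-truncated variants behave
identically.

The default feature catalog has 39 binary features in four groups: 9
anatomical lesion-site subtypes (the `617.x`/`N80.x` codes themselves), 14
comorbidities, 8 symptoms and 8 pregnancy-related phenotypes. Features are
ever/never flags with no date logic. Before clustering, the anatomical
subtypes are removed (they are reserved for cluster characterization), and
the remaining features are kept only if their prevalence among cases is at
least 5% (closed threshold). With the default catalog and realistic
prevalences this yields a 17-feature clustering input. Since supplementary
code lists differ between sites, the catalog is a plain data frame with a
YAML round trip (`read_feature_catalog()` / `write_feature_catalog()`) and
every prefix is user-overridable.

## Clustering model

The core model is spectral clustering of the binary case x feature matrix:

1. **Affinity.** A symmetrized k-nearest-neighbour connectivity graph under
   Manhattan distance (on 0/1 vectors Manhattan equals the Hamming count, so
   the same metric serves the silhouette and the KNN transfer). All
   points tied with the k-th neighbour distance are included, which keeps
   the graph invariant to row order — exact distance ties are the norm, not
   the exception, on 17 binary features. The default neighbourhood is 25:
   with clusters in the hundreds of subjects, a 10-neighbour graph proved
   too sparse for a stable eigenstructure (recovery of planted subtypes
   straddled ARI 0.9), while 25 neighbours gives stable recovery without
   blurring cluster boundaries; the value is a configuration default, not a
   tuned constant per dataset.
2. **Embedding.** The symmetric normalized Laplacian of the affinity is
   decomposed; the K eigenvectors of smallest eigenvalue (computed densely
   for small n, otherwise by Lanczos iteration on the sparse normalized
   affinity) form the K-dimensional embedding, rows normalized to unit
   length. The Lanczos start vector is drawn under a fixed seed, so results
   are bit-reproducible.
3. **Assignment.** Cluster labels come from column-pivoted QR on the
   embedding: K maximally independent rows act as cluster representatives,
   the embedding is rotated onto them, and each subject takes the dominant
   column. This is deterministic and handles the eigenvector rotation
   ambiguity that plain k-means in eigenspace is sensitive to; a seeded
   k-means fallback covers the rare ill-conditioned case.

Three baselines run alongside: k-means (k-means++ initialisation, 10
restarts, best SSE kept), hierarchical agglomerative clustering (average
linkage on Manhattan distance by default; Ward on Euclidean), and DBSCAN
(noise labelled `-1` and excluded from all metrics; an `eps` with no core
points yields zero clusters rather than an error).

### Model selection

`model_sweep()` scores every (method, K) for K = 2–20 by default with three
metrics: mean Manhattan silhouette, distortion (within-cluster sum of
squared Euclidean errors about the centroid), and evenness — the fractional
difference between largest and smallest cluster sizes, `(max - min)/n`,
minimized at balanced clusterings.

`select_model()` codifies the empirical procedure: methods whose inferred
cluster count explodes past a bound (default 20) are excluded — this is
DBSCAN's characteristic failure mode on noisy binary data — and survivors
are ranked by mean evenness, which is what removes strongly unbalanced
hierarchical solutions. The selected K is the first *prominent* strict
interior local minimum of distortion over the K grid; prominence requires
the dip below both neighbours to be at least 5% of the curve's total range.
The prominence requirement exists because distortion on a feature matrix is
near-monotone decreasing in K, so sampling jitter routinely creates
one-point dips an unqualified rule would latch onto; a "clear" minimum has
to stand out from that jitter. When no method shows one — the usual case on
the synthetic cohorts, whose distortion curves flatten smoothly past the
true K — the rule falls back to the (method, K) with maximal silhouette,
which on planted five-subtype data selects K = 5 essentially always.

## Cluster characterization

Every (feature, cluster) pair is tested cluster-vs-rest with the pooled
two-proportion z-test; `z^2` equals the Pearson chi-square of the 2x2 table
(an identity the tests verify to 1e-10), and no continuity correction is
applied. Pooled proportions of 0 or 1 make the statistic undefined; such
rows are flagged degenerate instead of silently zeroed. Significance is
Bonferroni-corrected over all feature x cluster tests at family-wise 0.05 —
a deliberately conservative default, configurable. Anatomical lesion-site
flags and any chart-review-style variables enter through the same code path
as extra binary columns.

## Label transfer

A K-nearest-neighbour classifier (default k = 3, Manhattan distance) trained
on the derivation cohort's 17 features and cluster labels assigns cluster
phenotypes to cases in genotyped cohorts. Binary features make exact ties
common, so the tie rules are explicit: the neighbour set includes all
training points tied with the k-th distance; a tied vote falls back to the
single nearest neighbour's label; residual exact ties break toward the
smallest cluster label. Together these make the assignment invariant to
training row order. Test subjects missing a feature column are an error, not
an imputation — absent codes are zeros upstream by construction.

## Association model

Within each ancestry x dataset stratum, cases are the cluster's members and
controls are all non-endometriosis females of the stratum. The per-variant
test is a covariate-adjusted logistic score test: the null model
`case ~ age + PC1..PC4` is fitted once per phenotype and stratum, and each
dosage is tested via its efficient score. This preserves the statistical
intent of mixed-model score tests used at biobank scale while omitting the
genetic relatedness matrix, which the synthetic cohorts do not have; the
omission is a deliberate scope decision, as is skipping saddlepoint
correction (case:control imbalances here are mild, and the null calibration
is verified directly by simulation). Effect sizes are reported from the full
logistic fit (Wald beta and SE) by default, or from the one-step
approximation `U/V` for large scans. Genetic PCs are computed per stratum
from the centered, allele-frequency-standardized dosage matrix; when the
variant panel is no larger than the number of requested PCs, PCs are
omitted rather than letting the basis re-encode the tested dosages.
Missing dosages are mean-imputed per variant; variants monomorphic after
imputation are skipped with a recorded reason; quasi-separation is flagged
while the score p-value remains valid.

Candidate loci are expanded to tag SNPs from a reference dosage panel:
same chromosome, distance strictly under 0.5 Mb, squared Pearson dosage
correlation strictly above 0.1; `r^2` is allele-flip invariant, and a lead
monomorphic in the reference is emitted lead-only with a warning.

## Meta-analysis and controls

Per-stratum effects are combined by DerSimonian–Laird random-effects
meta-analysis — the canonical moment estimator, chosen because multiple
genetic ancestry groups make between-stratum heterogeneity the expectation,
not the exception. Whenever `Q <= k - 1`, `tau^2` truncates to zero and the
result equals the fixed-effect inverse-variance meta exactly (tested as an
oracle identity). A single stratum passes through unchanged.

The positive control pools cases from all clusters and runs the identical
machinery, providing the baseline for the central comparison: does a
cluster phenotype, despite its smaller case count, associate more strongly
than overall disease at loci whose effects are subtype-specific? The
negative control permutes the multiset of cluster labels uniformly at
random across cases, independently within each dataset, so every
negative-control cluster preserves the real per-dataset case counts
exactly; any signal surviving that scrambling reflects pooled (diluted)
effects or chance, not subtype structure.

Locus-level significance is the minimum p over a lead and its tags with no
per-locus multiplicity adjustment, compared strictly against the Bonferroni
threshold 0.05/39 (39 candidate loci by default) and the genome-wide 5e-8.

## The synthetic generator

`simulate_cohort()` draws a case-control cohort with K latent subtypes.
Cases of subtype k draw each binary feature from `Bernoulli(p[j,k])`;
controls from baseline `p0[j]`. The default configuration plants five
subtypes shaped after the sub-phenotypes seen in real EHR cohorts — pain
comorbidities, uterine disorders, pregnancy complications, cardiometabolic
comorbidities, and a pelvic-pain symptom subtype — each owning 3–4 of the
17 clustering features at prevalence 0.8 against a 0.05 background. The 13
other non-anatomical catalog features sit at 0.02 so the 5% case-prevalence
filter reproduces the 39 → 17 feature selection; anatomical lesion codes are
emitted for cases only, enriched in selected subtypes for the
characterization stage to find.

Genotypes are retrospective: controls draw `Binomial(2, maf)`
(Hardy–Weinberg), and subtype-k cases draw dosage g with probability
proportional to `HWE(g) * exp(beta_k * g)`. Case-conditional sampling
guarantees the configured case counts exactly — matching case-control
ascertainment — and has a closed-form expected case allele frequency
(`sum (g/2) HWE(g) OR^g / sum HWE(g) OR^g`), which the tests verify against
Monte-Carlo draws. Ancestry strata (default AFR 0.3 / EUR 0.7) can carry
per-stratum allele frequencies to exercise meta-analytic heterogeneity.
ICD emission inverts feature extraction: each positive flag emits the
feature's first ICD-9 or ICD-10 prefix with probability `icd_sensitivity`
(default 1, making extraction an exact round trip), and cases additionally
emit a bare `617`/`N80` stem that defines case status without touching any
anatomical feature.

What the generator does *not* emulate, and what passing tests therefore do
not establish about real data: features are conditionally independent given
the subtype (real comorbidity codes are correlated within patients), there
is no relatedness or cryptic kinship, no longitudinal structure or coding
drift, no imputation dosage uncertainty, and LD is only present where the
variant specification plants it.

## Problem sizes and determinism

The test-suite study conditions are: 5 subtypes x 500 cases for recovery
and transfer checks (held-out cohort of equal size), 150 cases per subtype
x 10 replicates for the K-selection sweep, 2,000 null variants at 1,000
cases / 5,000 controls for calibration, 100 replicates for effect-size
recovery and for the stratified-power comparison (OR 1.5 confined to one of
five equal subtypes, two ancestry strata), and 30 replicates of a 39-locus
null panel for the negative-control calibration. These sizes put every
Monte-Carlo check comfortably inside its tolerance while keeping a full run
on one CPU in minutes.

Every stochastic step takes an explicit seed and restores the caller's RNG
state; identical configuration and seed give byte-identical artifacts,
including the sparse eigensolver. The pipeline driver writes a manifest
with stage order, seed and MD5 hashes of all artifacts.

## Known limitations

The score test relies on the normal approximation; at extreme case:control
imbalance or very rare variants a saddlepoint-corrected tail would be more
accurate. The DerSimonian–Laird estimator is noisy with very few strata
(k = 2 is common here); it is reported with `Q`, `tau^2` and `I^2` so users
can judge. Spectral recovery on the synthetic conditions runs close to the
generator's Bayes limit (ARI ~0.93), so small parameter changes move the
recovery number more than implementation quality does. The evenness metric
ignores all but the extreme cluster sizes by design.
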