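---
title: "Methods: multi-criteria species identification and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-criteria species identification and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures behind `shearid`, the
assumptions they make, the parameters that matter, and the design choices
taken where the methodology left room. The running system is a pair of
recently diverged shearwaters (Yelkouan, YS; Balearic, BS) identified from
bycatch carcasses, but every component is generic for two-group
integrative identification.

## The consensus model

Each bird is scored under four independent criteria: plumage colouration
(a categorical field call), sex-standardized linear biometrics, feather
stable isotopes, and an aligned mtDNA control-region fragment. The three
quantitative criteria are clustered (below) and the clusters anchored to
species through reference birds of known origin. A bird's consensus
species is the species called identically by at least `min_agree` (default
3) of the four criteria; doubtful plumage and missing data abstain, and
abstentions never count as agreement. The rationale is that species
divergence is not expressed simultaneously in all traits — any single
criterion can be fooled (introgressed mtDNA, whitish BS plumage,
overlapping biometrics) but three independent failures on the same bird
are unlikely. The abstention rule is the only reading of the published
bookkeeping consistent with its per-criterion accuracies: accuracy is the
fraction of *assigned* birds whose criterion call equals the consensus,
with abstentions counting as incorrect, rounded to integer percent.

An extension cohort without genetic data is assigned by a stricter rule:
plumage and the two discriminant functions (biometric, isotopic) must
agree unanimously; any disagreement or doubtful plumage yields unknown.

## Per-criterion clustering

**Distances.** Biometrics are standardized by the translation method
(subtract each sex's mean per trait) to remove sexual size dimorphism,
then compared by Euclidean distance on the raw mm scale — no variance
scaling, matching the source methodology; wing length consequently
carries the largest share of the distance. Isotope profiles (δ15N, δ13C
of P1 and R6, all in permil) use plain Euclidean distance. Sequence
dissimilarity is `sqrt(1 - identity)` with valid sites restricted to
positions where both sequences carry an unambiguous A/C/G/T; gaps *and*
IUPAC ambiguity codes are excluded pairwise (pairwise rather than global
deletion — the fragment is a homologous aligned region and the source
workflow confirms variable sites by chromatogram inspection, implying
clean calls). No multiple-hit correction is applied: the statistic is an
identity, not an evolutionary distance.

**PAM.** Partitioning around medoids minimizes the summed dissimilarity
of points to their cluster medoid. Tiny instances
(`choose(n, k) <= 1500`) are solved exactly by enumerating every medoid
subset (ties to the lexicographically smallest subset); larger instances
use the classic deterministic local search — greedy BUILD seeding
followed by best-improving SWAP exchanges, all ties to the lowest index.
The exact route exists because the local search (like any PAM
implementation) can miss the global optimum by a fraction of a percent on
small instances, and at that scale exact minimization is free. All
randomness in the pipeline therefore lives in the bootstrap, never in the
clustering itself.

**Cluster number and stability.** The cluster count is chosen by maximum
average silhouette width over `k_range` (default 2–6, ties to the
smallest k); the pipeline then clusters at a fixed `k = 2` (the
biological hypothesis) while logging the silhouette estimate. Stability
is the mean, over bootstrap resamples, of the best Jaccard match between
each original cluster and the reclustered resample, computed on the
distinct resampled points; 0.75 is the conventional stability floor.
The default is 100 resamples for desk-scale runs (the study-scale setting
is 10000); resamples with fewer than k+1 distinct points are redrawn.
Shape clustering is always computed and reported but never enters the
consensus — in the source design its clusters fail the stability floor.

**Ordination.** Classical (Torgerson) MDS via the double-centred Gram
matrix. Genetic distances are made Euclidean beforehand by adding the
Cailliez constant c\* — the largest real eigenvalue of the 2n×2n block
matrix `[[0, 2*D1], [-I, -4*D2]]`, `D1 = -J D^2 J/2`, `D2 = -J D J/2` —
to every off-diagonal entry, which is the smallest such constant.

## Geometric morphometrics

Configurations are 13 points in 2-D: 10 fixed landmarks and 3
semilandmarks on the outline of the superior unguicorn between landmarks
1 and 10 (curve order 1, 11, 12, 13, 10). Centroid size is
`sqrt(sum of squared distances to the centroid)` in mm; size analyses use
log10(CS) (the published magnitudes ≈1.78 correspond to a ≈60 mm CS).

GPA centres each configuration, scales it to unit centroid size, and
rotates it (proper rotations only — all photographs show the right bill
side, so reflections are disallowed) onto an iteratively updated mean.
Semilandmarks slide along the chord tangent between their outline
neighbours to the position nearest the corresponding mean point
(`t = u . (mean - x)`, the minimum Procrustes distance criterion); chord
tangents are the standard choice with only three semilandmarks between
two anchors. Sliding interleaves with re-superimposition until joint
convergence. Two numerical points deserve note:

* *Convergence target.* The tangential position of slid points is a
  neutral direction: configurations can creep along the outline
  indefinitely with vanishing effect on fit, so the mean shape never
  stabilizes to tight tolerance. With sliding, iteration therefore stops
  when the total Procrustes sum of squares improves by less than
  `slide_tol` (default 1e-4, relative) per iteration — in practice ~5
  iterations, with the objective within 0.01% of its limit. Plain GPA
  converges on the mean shape itself (tol 1e-8).
* *Degrees of freedom.* Relative warps are the principal components of
  the mean-centred aligned coordinates with uniform and non-uniform
  variation weighted equally (bending-energy weight 0). Residuals are
  first projected orthogonally to the directions superimposition and
  sliding have removed — two translations, scale (along the mean),
  rotation (the mean rotated 90°) and, when slid, the outline tangent at
  each semilandmark of the mean — so k landmarks with s slid
  semilandmarks yield exactly 2k−4−s non-zero eigenvalues (19 for the
  default configuration), the standard accounting for semilandmark use.

## Discriminant functions

Two-group linear discriminants with equal priors and pooled within-group
covariance (divisor n−2), expressed as Fisher classification functions
(`c_g = S^-1 mu_g`, constant `-mu_g' S^-1 mu_g / 2 + log prior_g`);
classification by the larger score equals minimal Mahalanobis distance
under equal priors. Validation is jackknife (leave-one-out refitting) plus
a stratified train/test split: default 80% of each group for training, and
the published explicit counts (40 YS / 50 BS) — which follow no single
rounding rule — available as a configuration field. No automatic stepwise
selection is performed by default; the published biometric function is
implied to use two variables, but the selection procedure is unstated, so
the package fits the full function and leaves variable choice to the
user.

## Isotope statistics and temporal variance

Species differences per isotope variable use a two-sample t test, pooled
when Levene's test (one-way ANOVA on absolute deviations from group
means) accepts homoscedasticity at 0.05, Welch otherwise — both variants
are always reported, with the gated one marked — against a Bonferroni
threshold of 0.05/4 = 0.0125. A summary-statistic mode recomputes t and
df from printed means/SDs/n; printed one-decimal SDs limit the
reproduction of Welch df to a few percent. Biometric species/sex effects
use a two-way MANOVA (Wilks' Λ with Type III hypothesis matrices, Rao's F
approximation, multivariate partial η² = 1 − Λ^(1/s)); log centroid size
uses a Type III two-way ANOVA. Normality checks report both the naive KS
p-value and the Lilliefors-corrected one (estimated parameters), the
latter via the standard analytic approximation. Measurement
repeatability is the two-way consistency intra-class correlation for
single measures.

Temporal stability of the isotope data is assessed by partitioning each
variable into species, moult-year and residual variance with crossed
random effects fit by REML. Moult year derives from the collection date:
March–June collections carry previous-year feathers, October–November
same-year; other months are unresolvable and excluded rather than
guessed, since only those two windows are defined by the moult phenology.
No species×year interaction is fit by default (only the two main random
effects are named in the source design); an interaction option exists.
Treating a 2-level classification variable as random follows the source
analysis; with 2 levels the component is estimated from essentially one
contrast, which shapes how recovery can be tested (below).

## The synthetic cohort generator

`sim_params()` encodes the study conditions: species-by-sex multivariate
normal biometrics with the published means/SDs; isotope means/SDs per
species and feather with additive year effects; two mtDNA haplogroups at
2.5% fixed divergence (round(0.025×293) = 7 sites) with Poisson(1)
private substitutions per bird; a 9/13 introgression probability for a
designated hybridizing-colony subpopulation; a 13-point bill template
with a dorso-ventral thickness offset for BS and log10 centroid-size
distributions per species and sex; a 10% doubtful-plumage rate; cohort
sizes of 41 YS + 62 BS bycatch, 10 YS references and one ringed BS
reference. Choices the source leaves open, fixed once here:

* *Biometric correlations* are unpublished; the default is 0.4 among the
  three bill variables and 0.2 elsewhere, configurable.
* *Year-effect SD* defaults to one third of the species mean difference
  per variable, which reproduces the documented ordering (species
  variance dominating year variance) without making years negligible.
* *Moult-year span* is 2002–2007 for the main cohort and 2008–2011 for
  the extension cohort, the spans of the two published datasets; with
  fewer year levels the realized year variance is too noisy for the
  species>year ordering to be a per-seed property.
* *Substitution model* is uniform site choice with equal exchange
  probabilities — sufficient for identity-distance clustering; no
  transition bias, no coalescent structure.
* *Within-species haplotype diversity* is unpublished; the Poisson mean
  of 1 private substitution per bird is an assumption.
* The *bill template* is a hand-digitized plausible outline; its absolute
  geometry is arbitrary, only the depth contrast between species matters.

What the generator does **not** emulate: geographic structure within
species (the major suspected cause of the unstable published shape
clusters), colony-level biometric variation, measurement error structure
beyond isotropic noise, plumage wear, and baseline isotopic drift beyond
additive year shifts. Passing tests therefore demonstrate that the
machinery recovers structure under the published parameter regime, not
that real specimens behave this simply.

## Reference anchoring in the pipeline

The strict anchoring rule labels each cluster by the majority species of
its reference birds, errors on conflicts, and fills a reference-free
cluster by elimination. On noisy synthetic cohorts a stray reference can
occasionally cross clusters; the pipeline then re-anchors on the majority
cluster of the best-represented reference species (the other cluster by
elimination), logging the event — the same logic the source applied with
ten YS references and a single ringed BS.

## Test and acceptance problem sizes

The packaged tests run the full pipeline on cohorts of 113+65 birds with
100 bootstrap resamples, GPA on 30–60 configurations, brute-force PAM
oracles at n ≤ 12, a refined grid-search oracle for sliding, bisection
oracles for the Cailliez constant on 50 random matrices, and 10-seed REML
recovery at 2×8×30 observations. Because a 2-level random factor is
estimated from one contrast, the REML recovery simulation rescales the
drawn species and year effects so their realized variance equals the
nominal component (a conditional parameter-recovery design); without
conditioning, the estimate's sampling distribution at 2 levels is too
wide for any fixed-seed bound to be meaningful. The whole suite completes
in a few minutes on one core.

## Known limitations

* Two groups only, by design, throughout (LDA, anchoring, consensus).
* The identity distance ignores multiple hits; it is not an evolutionary
  distance and should not be compared across loci.
* Chord-tangent sliding is first-order; with dense semilandmark curves a
  spline tangent or bending-energy criterion would be preferable.
* Consensus treats criteria as exchangeable votes; no weighting by
  per-criterion reliability is attempted, and no hybrid category is
  assigned even when plumage/nuclear and mitochondrial criteria disagree
  in the introgression-typical direction.
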