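# shearid

Integrative species identification for recently diverged seabirds.

## The problem

The Balearic shearwater (*Puffinus mauretanicus*, "BS") and the Yelkouan
shearwater (*P. yelkouan*, "YS") are sister taxa that diverged recently
enough to overlap in plumage, body size and mtDNA (2.2–2.9% control-region
divergence, with maternal introgression where they hybridize). Both are
bycaught in large numbers by Mediterranean longliners, and conservation
assessment requires assigning each carcass to a species even though no
single trait is diagnostic. `shearid` implements the integrative solution:
score every bird under four independent criteria — plumage colouration,
linear biometrics, feather stable isotopes (δ15N and δ13C of the first
primary P1 and sixth rectrix R6), and an aligned 293-bp mtDNA
control-region fragment — and accept a species only when at least three
criteria agree. It is aimed at anyone combining weakly diagnostic
characters into a defensible joint species call: bycatch monitoring
programs, museum collections, integrative-taxonomy studies.

## What the package computes

* **Per-criterion clustering.** Each quantitative criterion is reduced to a
  dissimilarity matrix — sex-standardized biometrics (each trait minus its
  sex mean) and isotope profiles under Euclidean distance; sequences under
  the identity distance d(i,j) = sqrt(1 − identity(i,j)) with pairwise
  deletion of gaps/ambiguities, made Euclidean by the Cailliez additive
  constant c\*. Partitioning around medoids (PAM) clusters each matrix; the
  cluster number is chosen by maximum average silhouette width
  s(i) = (b(i)−a(i))/max(a(i),b(i)); cluster reality is assessed by
  bootstrap resampling with the mean Jaccard coefficient per cluster
  (≥ 0.75 = stable); classical MDS provides ordination coordinates.
* **Reference anchoring and consensus.** Clusters are mapped to species via
  birds of known origin; per-bird calls are combined by the ≥3-of-4 rule
  (doubtful plumage and missing criteria abstain), with pattern-table
  bookkeeping and per-criterion accuracy.
* **Geometric morphometrics of bill shape.** Generalized Procrustes
  Analysis of 13-point configurations (10 landmarks, 3 semilandmarks slid
  along the upper-bill outline by the minimum Procrustes distance
  criterion), centroid size CS = sqrt(Σᵢ‖xᵢ−x̄‖²), and relative warps with
  exactly 2k−4−s non-zero eigenvalues.
* **Discriminant extension.** Equal-prior Fisher linear discriminant
  functions (cᵍ = Σ̂⁻¹μᵍ, constant −½μᵍᵀΣ̂⁻¹μᵍ + ln πᵍ) fit on the
  consensus-assigned birds, validated by jackknife (leave-one-out) and a
  stratified 80/20 split, then applied with plumage under a strict
  three-way agreement rule to later cohorts lacking genetic data.
* **Temporal stability.** REML variance components of each isotope variable
  with species and moult year (March–June collections → previous year,
  October–November → same year) as crossed random effects.
* **Statistics.** Type III two-way (M)ANOVA with partial η², Levene-gated
  pooled/Welch t tests with Bonferroni threshold, KS/Lilliefors normality,
  intra-class correlation for measurement repeatability.
* **Synthetic cohorts.** `simulate_cohort()` generates bird tables, aligned
  sequences and landmark configurations with the published study structure
  (species-by-sex biometric distributions, species/feather isotope
  distributions with moult-year effects, two mtDNA haplogroups with
  configurable introgression, two-species bill-shape populations), so the
  full pipeline is testable without specimens.

## Worked example

Feeding the published cross-criteria pattern table (117 birds: 107 bycatch
plus 10 reference Yelkouans) through the consensus machinery:

```r
library(shearid)
birds <- expand_patterns(bycatch_pattern_counts())
asg   <- consensus_assign(birds[, 1:4])
head(tabulate_patterns(asg), 4)
#>    plumage biometrics genetics isotopes consensus count percent
#> 6       BS         BS       BS       BS        BS    52    44.4
#> 12      YS         YS       YS       YS        YS    40    34.2
#> 5  abstain         YS       YS       YS        YS     4     3.4
#> 9       BS         YS       BS       BS        BS     4     3.4
criterion_accuracy(asg)
#>    plumage biometrics   genetics   isotopes
#>         95         94         96         97
sum(asg$consensus == "unknown")
#> [1] 4
```

44.4% of birds are unanimous BS and 34.2% unanimous YS; four birds have
fewer than three agreeing criteria and stay unknown; stable isotopes are
the most accurate single criterion (97% of the 113 assigned birds).

A synthetic cohort runs the same machinery end to end:

```r
co  <- simulate_cohort(seed = 42)
d   <- apply_cailliez(identity_distance(co$alignment))
estimate_k(d, 2:5)$k
#> [1] 2
bootstrap_stability(d, 2, runs = 100, seed = 42)$jaccard
#> [1] 1 1
```

The genetic criterion finds two clusters with perfect bootstrap stability
(mean Jaccard 1.0 for both). `run_pipeline(pipeline_config(seed = ...))`
executes every stage and writes a report bundle (cluster tables, MDS
coordinates, stability, assignments, discriminant coefficients, variance
components, JSON summary).

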