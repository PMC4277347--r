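Package: shearid
Title: Integrative Species Identification for Recently Diverged Seabirds
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-criteria species identification for pairs of recently
    diverged taxa, built around the Yelkouan/Balearic shearwater problem:
    per-criterion k-medoids clustering with bootstrap Jaccard stability,
    reference-anchored cluster labelling, >=3-of-4 consensus species
    assignment, equal-prior linear discriminant functions with jackknife
    cross-validation, geometric morphometrics of bill shape (Generalized
    Procrustes Analysis with sliding semilandmarks and relative warps),
    identity-based mtDNA distances with the Cailliez additive constant,
    species-difference statistics, and REML variance partitioning of feather
    stable-isotope values into species, moult-year and residual components.
    Includes a synthetic cohort generator so the whole pipeline is testable
    without specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    MASS,
    car,
    jsonlite,
    lme4,
    nortest,
    stats,
    utils,
    withr
Suggests:
    cluster,
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
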