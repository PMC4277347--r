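#' Pipeline configuration
#'
#' Collects the tunable parameters of the integrative identification
#' pipeline with the study-scale defaults: silhouette search over k = 2..6
#' followed by clustering at the fixed k, 100 bootstrap resamples for
#' stability (the study-scale setting is 10000), the 0.75 Jaccard
#' stability threshold, and the at-least-3-of-4 consensus rule.
#'
#' @param k_range Candidate cluster numbers for the silhouette search.
#' @param fix_k Cluster number used for the per-criterion partitions
#'   (default 2; the silhouette estimate is logged alongside).
#' @param bootstrap_runs Bootstrap resamples per criterion.
#' @param stability_threshold Mean-Jaccard threshold for a stable cluster.
#' @param consensus_min_agree Minimum agreeing criteria for a consensus
#'   species (must not exceed the 4 criteria).
#' @param seed Master RNG seed (default 20141226); every stochastic stage
#'   derives its own seed from it.
#' @param train_counts Named per-group training sizes for the discriminant
#'   split, or `NULL` for 80% per group.
#' @param params Generator parameters ([sim_params()]) used when the
#'   pipeline simulates its cohorts.
#' @param simulate_dataset2 Also simulate and assign an extension cohort
#'   (no genetic criterion) via the discriminant functions.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(k_range = 2:6, fix_k = 2L, bootstrap_runs = 100L,
                            stability_threshold = 0.75,
                            consensus_min_agree = 3L, seed = 20141226L,
                            train_counts = NULL, params = sim_params(),
                            simulate_dataset2 = TRUE) {
  if (consensus_min_agree > 4L)
    stop_ctx("consensus_min_agree exceeds the number of criteria (4)")
  if (stability_threshold < 0 || stability_threshold > 1)
    stop_ctx("stability_threshold must lie in [0, 1]")
  stopifnot(is_count(bootstrap_runs), bootstrap_runs >= 1)
  structure(list(k_range = k_range, fix_k = as.integer(fix_k),
                 bootstrap_runs = as.integer(bootstrap_runs),
                 stability_threshold = stability_threshold,
                 consensus_min_agree = as.integer(consensus_min_agree),
                 seed = as.integer(seed), train_counts = train_counts,
                 params = params, simulate_dataset2 = simulate_dataset2),
            class = "pipeline_config")
}

# Cluster one criterion: silhouette k estimate, PAM at the fixed k,
# bootstrap stability, MDS coordinates.
cluster_criterion <- function(d, config, seed) {
  est <- estimate_k(d, config$k_range)
  fit <- pam_cluster(d, config$fix_k)
  boot <- bootstrap_stability(d, config$fix_k, runs = config$bootstrap_runs,
                              seed = seed, threshold = config$stability_threshold)
  mds <- classical_mds(d, dims = 2L)
  list(estimated_k = est$k, silhouette_by_k = est$avg_silhouette, fit = fit,
       stability = boot, mds = mds)
}

# Translate cluster labels into species calls via the reference anchoring.
# When the strict per-cluster majority rule conflicts (a stray reference in
# the wrong cluster), fall back to anchoring on the references of the
# best-represented species only -- the other cluster follows by elimination,
# as in the original design with 10 YS references and a single ringed BS.
species_calls <- function(fit, references) {
  anchor <- tryCatch(
    anchor_clusters(fit$labels, references),
    error = function(e) {
      sp_counts <- table(references)
      major_sp <- names(sp_counts)[which.max(sp_counts)]
      message("anchoring conflict (", conditionMessage(e),
              "); re-anchoring on the majority cluster of the ", major_sp,
              " references")
      refs_sp <- references[references == major_sp]
      in_cl <- table(fit$labels[names(fit$labels) %in% names(refs_sp)])
      home <- names(in_cl)[which.max(in_cl)]
      cl <- as.character(sort(unique(fit$labels)))
      stats::setNames(ifelse(cl == home, major_sp,
                             setdiff(species_levels(), major_sp)), cl)
    })
  stats::setNames(anchor[as.character(fit$labels)], names(fit$labels))
}

#' Run the integrative identification pipeline
#'
#' Executes the full analysis on a cohort: per-criterion clustering
#' (sex-standardized biometrics, stable isotopes, Cailliez-corrected mtDNA
#' identity distances, and relative-warp bill shape) with silhouette-based
#' k estimation, bootstrap Jaccard stability and MDS coordinates;
#' reference-anchored species calls; the >=3-of-4 consensus assignment with
#' pattern bookkeeping and per-criterion accuracies; equal-prior
#' discriminant functions (biometric and isotopic) with jackknife and
#' train/test validation, applied with the three-way agreement rule to an
#' extension cohort; species-difference statistics; and REML variance
#' partitioning of the isotope variables into species, moult-year and
#' residual components. Shape clustering is reported but never enters the
#' consensus (in the study design its clusters fail the stability
#' threshold).
#'
#' @param config A [pipeline_config()].
#' @param inputs `NULL` to simulate the cohorts from `config$params`, or a
#'   list with `birds` (bird table path or data frame), `fasta` (alignment
#'   path or `alignment`), `tps` (landmark path or list), and optionally
#'   `birds2` for the extension cohort.
#' @param out_dir Directory for the report bundle (created if needed), or
#'   `NULL` to skip writing.
#' @return A list of class `pipeline_result` with elements `birds`,
#'   `clusters`, `calls`, `assignments`, `patterns`, `accuracy`, `dfa`,
#'   `dataset2`, `varcomp`, `stats`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL,
                         out_dir = NULL) {
  seed <- config$seed
  message("pipeline: master seed ", seed)

  if (is.null(inputs)) {
    message("stage simulate: cohort from sim_params (seed ", seed, ")")
    cohort <- simulate_cohort(config$params, seed = seed)
    birds <- cohort$birds
    aln <- cohort$alignment
    lms <- cohort$landmarks
    birds2 <- if (isTRUE(config$simulate_dataset2))
      simulate_dataset2_cohort(config$params, seed = derive_seed(seed, 9000L))
  } else {
    birds <- if (is.character(inputs$birds)) read_bird_table(inputs$birds)
             else validate_bird_table(inputs$birds)
    aln <- if (is.character(inputs$fasta)) read_fasta_alignment(inputs$fasta)
           else inputs$fasta
    lms <- if (is.character(inputs$tps)) read_tps(inputs$tps) else inputs$tps
    birds2 <- inputs$birds2
    if (is.character(birds2)) birds2 <- read_bird_table(birds2)
  }
  n <- nrow(birds)
  if (n < 10L) stop_ctx("pipeline needs a cohort of >= 10 birds")
  references <- stats::setNames(
    ifelse(birds$source == "reference_ys", "YS", "BS"),
    birds$id)[grepl("^reference_", birds$source)]
  if (!length(references)) stop_ctx("no reference birds in the cohort")

  clusters <- list()
  calls <- matrix("abstain", n, 4,
                  dimnames = list(birds$id,
                                  c("plumage", "biometrics", "genetics", "isotopes")))
  plum <- birds$plumage_call
  calls[, "plumage"] <- ifelse(plum %in% species_levels(), plum, "abstain")

  # biometrics: translation-standardized, Euclidean
  bio_ok <- stats::complete.cases(birds[biometric_names()]) &
    birds$sex %in% c("male", "female")
  message("stage cluster/biometrics: n = ", sum(bio_ok),
          " (seed ", derive_seed(seed, 1L), ")")
  xb <- sex_standardize(as.matrix(birds[bio_ok, biometric_names()]),
                        birds$sex[bio_ok])
  rownames(xb) <- birds$id[bio_ok]
  clusters$biometrics <- cluster_criterion(to_dist_matrix(xb), config,
                                           derive_seed(seed, 1L))
  calls[names(species_calls(clusters$biometrics$fit, references)),
        "biometrics"] <-
    species_calls(clusters$biometrics$fit, references)

  # isotopes: Euclidean on the four delta values
  iso_ok <- stats::complete.cases(birds[isotope_names()])
  message("stage cluster/isotopes: n = ", sum(iso_ok),
          " (seed ", derive_seed(seed, 2L), ")")
  xi <- as.matrix(birds[iso_ok, isotope_names()])
  rownames(xi) <- birds$id[iso_ok]
  clusters$isotopes <- cluster_criterion(to_dist_matrix(xi), config,
                                         derive_seed(seed, 2L))
  calls[names(species_calls(clusters$isotopes$fit, references)), "isotopes"] <-
    species_calls(clusters$isotopes$fit, references)

  # genetics: identity distance + Cailliez correction
  if (!is.null(aln)) {
    ids <- intersect(birds$id, names(aln))
    message("stage cluster/genetics: n = ", length(ids),
            " (seed ", derive_seed(seed, 3L), ")")
    dg <- apply_cailliez(identity_distance(as_alignment(aln[ids])))
    clusters$genetics <- cluster_criterion(dg, config, derive_seed(seed, 3L))
    calls[names(species_calls(clusters$genetics$fit, references)), "genetics"] <-
      species_calls(clusters$genetics$fit, references)
  }

  # shape: GPA + sliding + relative warps; reported, never in the consensus
  if (length(lms) >= 10L) {
    message("stage cluster/shape: n = ", length(lms),
            " (seed ", derive_seed(seed, 4L), ")")
    gpa <- gpa_align(lms)
    rw <- relative_warps(gpa)
    xs <- rw$scores[, seq_len(rw$n_nonzero), drop = FALSE]
    rownames(xs) <- gpa$ids
    clusters$shape <- cluster_criterion(to_dist_matrix(xs), config,
                                        derive_seed(seed, 4L))
    clusters$shape$gpa <- gpa
    clusters$shape$warps <- rw
  }

  message("stage consensus: min_agree = ", config$consensus_min_agree)
  assignments <- consensus_assign(calls, min_agree = config$consensus_min_agree)
  assignments <- cbind(id = birds$id, assignments)
  patterns <- tabulate_patterns(assignments)
  accuracy <- criterion_accuracy(assignments)

  # discriminant functions on the consensus-assigned birds
  known <- assignments$consensus != "unknown"
  dfa <- list()
  for (crit in c("biometrics", "isotopes")) {
    feats <- if (crit == "biometrics") biometric_names() else isotope_names()
    ok <- known & stats::complete.cases(birds[feats])
    x <- as.matrix(birds[ok, feats])
    grp <- factor(assignments$consensus[ok], levels = species_levels())
    split <- split_train_test(grp, counts = config$train_counts,
                              seed = derive_seed(seed, 10L + match(crit, c("biometrics", "isotopes"))))
    fit <- fit_lda(x[split$train, , drop = FALSE], grp[split$train])
    test_pred <- predict(fit, x[split$test, , drop = FALSE])
    full_fit <- fit_lda(x, grp)
    loo <- jackknife_cv(x, grp)
    message("stage dfa/", crit, ": train ", length(split$train), ", test ",
            length(split$test), ", LOO accuracy ", round(100 * loo$overall), "%")
    dfa[[crit]] <- list(
      model = full_fit, train_model = fit, split = split,
      test_accuracy = mean(test_pred == as.character(grp[split$test])),
      loo = loo,
      predict_all = stats::setNames(predict(full_fit, x), birds$id[ok]))
  }

  # extension cohort: plumage + the two DFAs, strict agreement
  dataset2 <- NULL
  if (!is.null(birds2) && nrow(birds2) > 0) {
    message("stage dataset2: n = ", nrow(birds2))
    b2 <- birds2
    bio2 <- predict(dfa$biometrics$model, as.matrix(b2[biometric_names()]))
    iso2 <- predict(dfa$isotopes$model, as.matrix(b2[isotope_names()]))
    d2 <- assign_dataset2(b2$plumage_call, bio2, iso2)
    dataset2 <- data.frame(id = b2$id, plumage = b2$plumage_call,
                           biometric_dfa = bio2, isotope_dfa = iso2,
                           assigned = d2, stringsAsFactors = FALSE)
  }

  # temporal variance partitioning over both cohorts
  message("stage varcomp: REML species/year components")
  vc_birds <- rbind(
    data.frame(species = assignments$consensus,
               year = assign_moult_year(birds$collection_date),
               birds[isotope_names()])[known, ],
    if (!is.null(dataset2)) {
      keep <- dataset2$assigned != "unknown"
      data.frame(species = dataset2$assigned[keep],
                 year = assign_moult_year(birds2$collection_date[keep]),
                 birds2[keep, isotope_names()])
    })
  vc_birds <- vc_birds[!is.na(vc_birds$year), ]
  varcomp <- do.call(rbind, lapply(isotope_names(), function(v) {
    vc <- reml_varcomp(vc_birds[[v]], vc_birds$species, vc_birds$year)
    data.frame(variable = v, component = names(vc$components),
               variance = unname(vc$components),
               percent = unname(vc$percent), converged = vc$converged)
  }))

  # species-difference statistics on the assigned birds
  message("stage stats: species-difference tests")
  stats_out <- species_stats(birds, assignments)

  result <- structure(
    list(birds = birds, clusters = clusters, calls = calls,
         assignments = assignments, patterns = patterns, accuracy = accuracy,
         dfa = dfa, dataset2 = dataset2, varcomp = varcomp,
         stats = stats_out, config = config),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_report(result, out_dir)
  invisible(result)
}

# Extension cohort generator: later years, no references, no genetics use.
simulate_dataset2_cohort <- function(params, seed) {
  p2 <- params
  p2$cohort <- list(ys_male = 10L, ys_female = 11L, bs_male = 22L,
                    bs_female = 22L, refs_ys = 0L, refs_bs = 0L,
                    menorca_n = 0L)
  p2$years <- 2008:2011
  co <- simulate_cohort(p2, seed = seed)
  birds <- co$birds
  if (nrow(birds)) birds$id <- sub("^B", "D2_", birds$id)
  birds
}

# MANOVA on the six biometric variables, two-way ANOVA-style t tests for
# the isotopes with the Levene heteroscedasticity gate (both variants
# always reported, the gated one marked).
species_stats <- function(birds, assignments) {
  known <- assignments$consensus != "unknown"
  sp <- assignments$consensus[known]
  sex <- birds$sex[known]
  out <- list()
  ok <- stats::complete.cases(birds[known, biometric_names()]) &
    sex %in% c("male", "female")
  if (sum(ok) > 10L && length(unique(sp[ok])) == 2L)
    out$biometrics_manova <- manova_wilks(
      as.matrix(birds[known, ][ok, biometric_names()]), sp[ok], sex[ok])
  iso_rows <- lapply(isotope_names(), function(v) {
    x <- birds[[v]][known]
    keep <- !is.na(x)
    lev <- levene_test(x[keep], sp[keep])
    pooled <- two_sample_t(x[keep & sp == "YS"], x[keep & sp == "BS"], "pooled")
    welch <- two_sample_t(x[keep & sp == "YS"], x[keep & sp == "BS"], "welch")
    used <- if (lev$p < 0.05) "welch" else "pooled"
    sel <- if (used == "welch") welch else pooled
    data.frame(variable = v, levene_F = lev$F, levene_p = lev$p,
               variant = used, t = sel$t, df = sel$df, p = sel$p,
               t_pooled = pooled$t, df_pooled = pooled$df,
               t_welch = welch$t, df_welch = welch$df,
               bonferroni_alpha = bonferroni_threshold(0.05, 4))
  })
  out$isotope_tests <- do.call(rbind, iso_rows)
  out
}

# Write the report bundle: delimited tables plus a machine-readable JSON
# summary. Output is a pure function of (inputs, config, seed) -- no
# timestamps -- so identical runs are byte-identical.
write_pipeline_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  write_bird_table(result$birds, path("birds.csv"))
  for (crit in names(result$clusters)) {
    cl <- result$clusters[[crit]]
    utils::write.table(
      data.frame(id = names(cl$fit$labels), cluster = cl$fit$labels,
                 silhouette = cl$fit$per_point_silhouette),
      path(sprintf("cluster_%s.csv", crit)), sep = ",", row.names = FALSE,
      quote = FALSE)
    utils::write.table(
      data.frame(id = rownames(cl$mds$coordinates),
                 mds1 = cl$mds$coordinates[, 1], mds2 = cl$mds$coordinates[, 2]),
      path(sprintf("mds_%s.csv", crit)), sep = ",", row.names = FALSE,
      quote = FALSE)
  }
  stab <- do.call(rbind, lapply(names(result$clusters), function(crit) {
    cl <- result$clusters[[crit]]
    data.frame(criterion = crit, cluster = seq_along(cl$stability$jaccard),
               jaccard = cl$stability$jaccard, stable = cl$stability$stable,
               estimated_k = cl$estimated_k,
               avg_silhouette = cl$fit$avg_silhouette)
  }))
  utils::write.table(stab, path("stability.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(result$assignments, path("assignments.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(result$patterns, path("patterns.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(criterion = names(result$accuracy),
               accuracy_percent = unname(result$accuracy)),
    path("accuracy.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  for (crit in names(result$dfa)) {
    m <- result$dfa[[crit]]$model
    utils::write.table(
      data.frame(feature = c(m$feature_names, "(constant)"),
                 rbind(m$coefficients, m$constants)),
      path(sprintf("dfa_%s_coefficients.csv", crit)), sep = ",",
      row.names = FALSE, quote = FALSE)
  }
  if (!is.null(result$dataset2))
    utils::write.table(result$dataset2, path("dataset2.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
  utils::write.table(result$varcomp, path("varcomp.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(result$stats$isotope_tests, path("isotope_tests.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  summary <- list(
    seed = result$config$seed,
    n_birds = nrow(result$birds),
    estimated_k = lapply(result$clusters, `[[`, "estimated_k"),
    jaccard = lapply(result$clusters, function(cl) cl$stability$jaccard),
    accuracy = as.list(result$accuracy),
    n_unknown = sum(result$assignments$consensus == "unknown"),
    dfa_loo = lapply(result$dfa, function(d) d$loo$overall),
    dataset2_assigned = if (!is.null(result$dataset2))
      sum(result$dataset2$assigned != "unknown") / nrow(result$dataset2))
  jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
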