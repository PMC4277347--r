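#' Default simulation parameters for a two-shearwater cohort
#'
#' Returns the full parameter set of the synthetic cohort generator. The
#' defaults encode the published study conditions for the Yelkouan (YS) /
#' Balearic (BS) shearwater pair:
#'
#' * per species-by-sex biometric means and SDs (mm) for the six linear
#'   measurements (bill depth at base, bill depth at nostril, bill length,
#'   maximum head length, tarsus length, wing length);
#' * a biometric correlation structure (0.4 within the three bill variables,
#'   0.2 elsewhere) -- correlations are not published, this is a documented
#'   assumption;
#' * per species feather isotope means and SDs (permil) for d15N and d13C of
#'   the first primary (P1) and sixth rectrix (R6), plus an additive
#'   moult-year effect whose SD defaults to one third of the species mean
#'   difference per variable;
#' * mtDNA haplogroup parameters: 293-bp fragment, 2.5% fixed inter-group
#'   divergence (within the reported 2.2--2.9% range), mean one private
#'   substitution per individual, and a 9/13 maternal-introgression fraction
#'   for a designated BS subpopulation (the hybridizing Menorca colony);
#' * a 13-point bill landmark template (10 landmarks + 3 sliding
#'   semilandmarks on the superior unguicorn), a dorso-ventral thickness
#'   offset for BS, isotropic digitizing noise, and log10 centroid-size
#'   distributions per species and sex;
#' * a 10% doubtful-plumage rate;
#' * cohort sizes per species and sex, 10 YS reference birds and one BS
#'   reference bird.
#'
#' @param ... Named overrides of any default element.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(...) {
  bio <- list(
    YS = list(
      male   = list(mean = c(11.39, 8.24, 38.01, 87.74, 48.52, 241.3),
                    sd   = c(0.51, 0.43, 1.13, 1.51, 1.52, 5.6)),
      female = list(mean = c(10.66, 7.59, 36.63, 84.20, 47.07, 237.5),
                    sd   = c(0.47, 0.43, 1.38, 1.86, 1.17, 4.7))),
    BS = list(
      male   = list(mean = c(12.46, 9.15, 39.57, 91.84, 50.65, 252.3),
                    sd   = c(0.40, 0.38, 1.34, 1.73, 1.37, 4.3)),
      female = list(mean = c(11.47, 8.39, 37.47, 87.47, 49.24, 251.9),
                    sd   = c(0.45, 0.44, 1.22, 1.40, 1.24, 5.1))))
  for (sp in names(bio)) for (sx in names(bio[[sp]])) {
    names(bio[[sp]][[sx]]$mean) <- biometric_names()
    names(bio[[sp]][[sx]]$sd) <- biometric_names()
  }

  cor6 <- matrix(0.2, 6, 6, dimnames = list(biometric_names(), biometric_names()))
  cor6[1:3, 1:3] <- 0.4   # the three bill variables covary more tightly
  diag(cor6) <- 1

  iso <- list(
    YS = list(mean = c(11.3, -18.2, 11.8, -17.5), sd = c(0.9, 1.2, 1.4, 1.0)),
    BS = list(mean = c(14.4, -15.7, 14.1, -16.0), sd = c(0.8, 0.6, 1.1, 0.6)))
  for (sp in names(iso)) {
    names(iso[[sp]]$mean) <- isotope_names()
    names(iso[[sp]]$sd) <- isotope_names()
  }
  year_sd <- abs(iso$BS$mean - iso$YS$mean) / 3

  logcs <- list(
    YS = list(male = c(mean = 1.786, sd = 0.012),
              female = c(mean = 1.773, sd = 0.019)),
    BS = list(male = c(mean = 1.821, sd = 0.020),
              female = c(mean = 1.795, sd = 0.019)))

  p <- list(
    biometric = bio,
    biometric_cor = cor6,
    isotope = iso,
    year_sd = year_sd,
    seq_length = 293L,
    divergence = 0.025,
    private_sub_mean = 1,
    introgression_fraction = 9 / 13,
    template = bill_template(),
    depth_landmarks = c(2L, 4L, 6L, 8L),
    species_offset = 0.4,
    landmark_noise_sd = 0.15,
    logcs = logcs,
    doubtful_rate = 0.10,
    cohort = list(ys_male = 13L, ys_female = 28L,
                  bs_male = 30L, bs_female = 32L,
                  refs_ys = 10L, refs_bs = 1L, menorca_n = 1L),
    years = 2002:2007)

  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop_ctx("unknown sim_params field(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$divergence >= 0, p$divergence <= 1,
            p$introgression_fraction >= 0, p$introgression_fraction <= 1,
            p$doubtful_rate >= 0, p$doubtful_rate <= 1)
  structure(p, class = "sim_params")
}

# Hand-digitized 13-point approximation of a shearwater bill in lateral
# view (mm): 10 fixed landmarks plus 3 semilandmarks (11-13) on the curved
# outline of the superior unguicorn between landmarks 1 and 10. Absolute
# geometry is arbitrary; only relative proportions matter.
bill_template <- function() {
  pts <- rbind(
    c(38.0, 6.0),    # 1  start of the superior unguicorn (dorsal)
    c(0.0, 10.0),    # 2  base of culmen (dorsal)
    c(0.0, 0.0),     # 3  base of the lower mandible (ventral)
    c(10.0, 11.0),   # 4  culmen at the nostril (dorsal)
    c(10.0, 0.5),    # 5  ventral outline below the nostril
    c(20.0, 10.5),   # 6  mid-culmen (dorsal)
    c(20.0, 1.0),    # 7  mid ventral outline
    c(30.0, 9.0),    # 8  culmen before the unguicorn (dorsal)
    c(40.0, 0.0),    # 9  tip of the lower mandible
    c(41.5, 2.5),    # 10 tip of the hooked upper mandible
    c(39.5, 5.6),    # 11 semilandmark on the unguicorn curve
    c(40.8, 4.8),    # 12 semilandmark on the unguicorn curve
    c(41.6, 3.8))    # 13 semilandmark on the unguicorn curve
  landmark_config(pts, id = "template")
}

#' Simulate biometric measurements
#'
#' Draws from a multivariate normal whose mean and SD vector come from the
#' species-by-sex defaults and whose correlation matrix is the configured
#' biometric correlation structure.
#'
#' @param species `"YS"` or `"BS"`.
#' @param sex `"male"` or `"female"`.
#' @param n Number of birds.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return An `n x 6` matrix (mm) with the biometric variable names.
#' @export
simulate_biometrics <- function(species, sex, n, params = sim_params(), seed = 1L) {
  stopifnot(is_count(n), n >= 1)
  par <- params$biometric[[match.arg(species, species_levels())]][[
    match.arg(sex, c("male", "female"))]]
  sd <- par$sd
  sigma <- diag(sd, 6) %*% params$biometric_cor %*% diag(sd, 6)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1)))
    stop_ctx("biometric covariance is not positive semi-definite")
  x <- with_seed(seed, MASS::mvrnorm(n, mu = par$mean, Sigma = sigma))
  x <- matrix(x, nrow = n, dimnames = list(NULL, biometric_names()))
  x
}

#' Simulate feather stable-isotope values with moult-year effects
#'
#' Each value is the species-by-feather mean, plus a year effect drawn once
#' per year and variable from `N(0, year_sd^2)` (shared by all birds of that
#' species-year), plus independent individual noise with the configured SD.
#'
#' @param species `"YS"` or `"BS"`.
#' @param years Integer vector of moult years.
#' @param n_per_year Birds per year.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @param year_sd Optional override of the per-variable year-effect SDs.
#' @return A `data.frame` with `year` and the four isotope columns (permil).
#' @export
simulate_isotopes <- function(species, years, n_per_year, params = sim_params(),
                              seed = 1L, year_sd = NULL) {
  stopifnot(is_count(n_per_year), n_per_year >= 1, length(years) >= 1)
  sp <- match.arg(species, species_levels())
  mu <- params$isotope[[sp]]$mean
  sd <- params$isotope[[sp]]$sd
  ysd <- year_sd %||% params$year_sd
  with_seed(seed, {
    eff <- matrix(stats::rnorm(length(years) * 4, 0, rep(ysd, each = length(years))),
                  nrow = length(years), dimnames = list(years, isotope_names()))
    rows <- lapply(seq_along(years), function(i) {
      noise <- matrix(stats::rnorm(n_per_year * 4, 0, rep(sd, each = n_per_year)),
                      nrow = n_per_year)
      vals <- sweep(noise, 2, mu + eff[i, ], "+")
      data.frame(year = years[i], vals)
    })
  })
  out <- do.call(rbind, rows)
  names(out) <- c("year", isotope_names())
  out
}

#' Simulate an aligned mtDNA fragment for two haplogroups
#'
#' Two haplogroup consensus sequences differ at `round(divergence * length)`
#' fixed sites. Each individual receives its group consensus plus a
#' Poisson-distributed number of private substitutions at uniformly chosen
#' sites. A designated subset of BS birds (the hybridizing-colony
#' subpopulation) carries YS-group haplotypes with probability
#' `introgression_fraction`, emulating maternal introgression.
#'
#' @param n_ys,n_bs Number of YS / BS individuals.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @param ids Optional sequence ids (length `n_ys + n_bs`, YS first).
#' @param menorca Indices (within the BS block, 1..n_bs) of the designated
#'   introgression-prone subpopulation; default none.
#' @return A list: `alignment` (class `alignment`), `species`,
#'   `introgressed` (logical), `consensus` (2 x length character matrix).
#' @export
simulate_sequences <- function(n_ys, n_bs, params = sim_params(), seed = 1L,
                               ids = NULL, menorca = integer()) {
  stopifnot(is_count(n_ys), is_count(n_bs), n_ys + n_bs >= 1)
  L <- params$seq_length
  n_div <- round(params$divergence * L)
  if (n_div < 1) warning("divergence x length < 1: haplogroups indistinguishable")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    ys_cons <- sample(bases, L, replace = TRUE)
    div_sites <- sample.int(L, n_div)
    bs_cons <- ys_cons
    for (s in div_sites)
      bs_cons[s] <- sample(setdiff(bases, ys_cons[s]), 1L)
    species <- rep(species_levels(), c(n_ys, n_bs))
    introg <- rep(FALSE, n_ys + n_bs)
    if (length(menorca)) {
      stopifnot(all(menorca >= 1), all(menorca <= n_bs))
      hit <- stats::runif(length(menorca)) < params$introgression_fraction
      introg[n_ys + menorca[hit]] <- TRUE
    }
    seqs <- character(n_ys + n_bs)
    for (i in seq_along(seqs)) {
      s <- if (species[i] == "YS" || introg[i]) ys_cons else bs_cons
      n_priv <- stats::rpois(1L, params$private_sub_mean)
      if (n_priv > 0) {
        sites <- sample.int(L, min(n_priv, L))
        for (j in sites) s[j] <- sample(setdiff(bases, s[j]), 1L)
      }
      seqs[i] <- paste(s, collapse = "")
    }
  })
  if (is.null(ids))
    ids <- sprintf("%s_%03d", species, c(seq_len(n_ys), seq_len(n_bs)))
  names(seqs) <- ids
  list(alignment = as_alignment(seqs), species = species, introgressed = introg,
       consensus = rbind(YS = paste(ys_cons, collapse = ""),
                         BS = paste(bs_cons, collapse = "")))
}

#' Simulate bill landmark configurations
#'
#' Each configuration is the packaged bill template, with the dorsal
#' (depth-related) landmarks of BS displaced outward by the species offset,
#' plus isotropic Gaussian digitizing noise; it is then randomly rotated,
#' translated, and rescaled so that its log10 centroid size follows the
#' configured species-by-sex distribution.
#'
#' @param species `"YS"` or `"BS"`.
#' @param n Number of configurations.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @param sex `"male"` or `"female"` (selects the centroid-size
#'   distribution).
#' @param ids Optional specimen ids.
#' @return A list of [landmark_config()] objects.
#' @export
simulate_landmarks <- function(species, n, params = sim_params(), seed = 1L,
                               sex = "male", ids = NULL) {
  stopifnot(is_count(n), n >= 1)
  sp <- match.arg(species, species_levels())
  sx <- match.arg(sex, c("male", "female"))
  tmpl <- params$template$points
  if (sp == "BS")
    tmpl[params$depth_landmarks, 2] <- tmpl[params$depth_landmarks, 2] +
      params$species_offset
  cs_par <- params$logcs[[sp]][[sx]]
  if (is.null(ids)) ids <- sprintf("%s_%s_%03d", sp, sx, seq_len(n))
  with_seed(seed, {
    out <- lapply(seq_len(n), function(i) {
      pts <- tmpl + matrix(stats::rnorm(26, 0, params$landmark_noise_sd), 13, 2)
      target_cs <- 10^stats::rnorm(1L, cs_par["mean"], cs_par["sd"])
      ctr <- colMeans(pts)
      ctd <- sweep(pts, 2, ctr)
      pts <- ctd * (target_cs / sqrt(sum(ctd^2)))
      th <- stats::runif(1L, 0, 2 * pi)
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      pts <- pts %*% rot
      pts <- sweep(pts, 2, stats::runif(2, -50, 50), "+")
      landmark_config(pts, id = ids[i])
    })
  })
  out
}

#' Simulate plumage calls
#'
#' Returns the true species label for each bird except a configured fraction
#' of `"doubtful"` calls (wet/bloody or whitish-BS plumage that cannot be
#' scored reliably).
#'
#' @param species `"YS"` or `"BS"`.
#' @param n Number of birds.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @param doubtful_rate Optional override of the doubtful-call rate.
#' @return Character vector of calls in `{"YS","BS","doubtful"}`.
#' @export
simulate_plumage <- function(species, n, params = sim_params(), seed = 1L,
                             doubtful_rate = NULL) {
  stopifnot(is_count(n), n >= 1)
  sp <- match.arg(species, species_levels())
  rate <- doubtful_rate %||% params$doubtful_rate
  with_seed(seed, {
    calls <- rep(sp, n)
    calls[stats::runif(n) < rate] <- "doubtful"
  })
  calls
}

#' Simulate a complete cohort
#'
#' Composes the per-criterion generators into one cohort with consistent
#' ids: a bird table (biometrics, isotopes, plumage, sex, moult year,
#' provenance, true species), an aligned mtDNA fragment for every bird, and
#' bill landmark configurations for the bycatch birds (the reference birds
#' from the breeding colony lack photographs, as in the study design). The
#' default cohort holds 41 YS and 62 BS bycatch birds, 10 YS reference birds
#' and one BS bycatch bird of ringed (known) origin used as the BS
#' reference; one BS bird belongs to the introgression-prone subpopulation.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return A list with elements `birds` (bird table), `alignment`,
#'   `landmarks` (list of configurations) and `params`.
#' @export
simulate_cohort <- function(params = sim_params(), seed = 1L) {
  co <- params$cohort
  groups <- list(
    list(species = "YS", sex = "male", n = co$ys_male),
    list(species = "YS", sex = "female", n = co$ys_female),
    list(species = "BS", sex = "male", n = co$bs_male),
    list(species = "BS", sex = "female", n = co$bs_female))
  n_ref <- co$refs_ys
  ref_groups <- list(
    list(species = "YS", sex = "male", n = ceiling(n_ref / 2)),
    list(species = "YS", sex = "female", n = floor(n_ref / 2)))

  rows <- list(); lms <- list(); k <- 0L
  for (g in c(groups, ref_groups)) {
    if (g$n == 0) next
    k <- k + 1L
    is_ref <- k > length(groups)
    bio <- simulate_biometrics(g$species, g$sex, g$n, params,
                               seed = derive_seed(seed, k))
    yrs <- with_seed(derive_seed(seed, 100L + k),
                     sample(params$years, g$n, replace = TRUE))
    rows[[k]] <- data.frame(
      species = g$species, sex = g$sex, moult_year = yrs,
      source = if (is_ref) "reference_ys" else "bycatch", bio,
      stringsAsFactors = FALSE)
  }
  birds <- do.call(rbind, rows)
  if (is.null(birds) || nrow(birds) == 0L)
    return(list(birds = data.frame(), alignment = NULL, landmarks = list(),
                params = params))
  n <- nrow(birds)
  birds$id <- sprintf("B%03d", seq_len(n))
  birds$id[birds$source == "reference_ys"] <-
    sprintf("REF_YS%02d", seq_len(sum(birds$source == "reference_ys")))

  # one ringed BS bycatch bird serves as the BS reference
  if (co$refs_bs > 0 && any(birds$species == "BS")) {
    idx <- which(birds$species == "BS")[seq_len(min(co$refs_bs, sum(birds$species == "BS")))]
    birds$source[idx] <- "reference_bs"
  }

  # isotopes: year effects shared within species-year, then individual noise
  iso <- matrix(NA_real_, n, 4, dimnames = list(NULL, isotope_names()))
  for (sp in species_levels()) {
    eff <- with_seed(derive_seed(seed, 200L + match(sp, species_levels())),
                     matrix(stats::rnorm(length(params$years) * 4, 0,
                                         rep(params$year_sd, each = length(params$years))),
                            nrow = length(params$years),
                            dimnames = list(params$years, isotope_names())))
    sel <- which(birds$species == sp)
    if (!length(sel)) next
    noise <- with_seed(derive_seed(seed, 210L + match(sp, species_levels())),
                       matrix(stats::rnorm(length(sel) * 4, 0,
                                           rep(params$isotope[[sp]]$sd, each = length(sel))),
                              nrow = length(sel)))
    iso[sel, ] <- sweep(noise, 2, params$isotope[[sp]]$mean, "+") +
      eff[as.character(birds$moult_year[sel]), , drop = FALSE]
  }
  birds <- cbind(birds, iso)

  # collection dates consistent with the moult-year assignment rule
  halves <- with_seed(derive_seed(seed, 300L), stats::runif(n) < 0.5)
  birds$collection_date <- ifelse(
    halves, sprintf("%d-10-15", birds$moult_year),
    sprintf("%d-04-15", birds$moult_year + 1L))

  # plumage: references keep their definite species call
  plum <- character(n)
  for (sp in species_levels()) {
    sel <- which(birds$species == sp)
    if (!length(sel)) next
    plum[sel] <- simulate_plumage(sp, length(sel), params,
                                  seed = derive_seed(seed, 400L + match(sp, species_levels())))
  }
  plum[grepl("^reference_", birds$source)] <-
    birds$species[grepl("^reference_", birds$source)]
  birds$plumage_call <- plum

  # sequences: order YS block then BS block, then map back
  ys_idx <- which(birds$species == "YS")
  bs_idx <- which(birds$species == "BS")
  bs_bycatch <- which(birds$species == "BS" & birds$source == "bycatch")
  menorca_global <- utils::tail(bs_bycatch, co$menorca_n)
  menorca_in_bs <- match(menorca_global, bs_idx)
  sim <- simulate_sequences(length(ys_idx), length(bs_idx), params,
                            seed = derive_seed(seed, 500L),
                            ids = birds$id[c(ys_idx, bs_idx)],
                            menorca = menorca_in_bs)
  aln <- sim$alignment[match(birds$id, names(sim$alignment))]
  aln <- as_alignment(aln)
  birds$introgressed <- FALSE
  birds$introgressed[c(ys_idx, bs_idx)[sim$introgressed]] <- TRUE
  birds$menorca <- birds$id %in% birds$id[menorca_global]
  birds$sequence_id <- birds$id

  # landmarks for bycatch (and the ringed BS reference, itself a bycatch bird)
  lm_sel <- which(birds$source != "reference_ys")
  lms <- list()
  for (i in seq_along(lm_sel)) {
    b <- birds[lm_sel[i], ]
    lms[[i]] <- simulate_landmarks(b$species, 1L, params,
                                   seed = derive_seed(seed, 600L + lm_sel[i]),
                                   sex = b$sex, ids = b$id)[[1]]
  }
  birds$landmark_id <- NA_character_
  birds$landmark_id[lm_sel] <- birds$id[lm_sel]

  names(birds)[names(birds) == "species"] <- "true_species"
  birds <- birds[, c("id", "source", "sex", "collection_date", "moult_year",
                     "plumage_call", biometric_names(), isotope_names(),
                     "sequence_id", "landmark_id", "true_species",
                     "introgressed", "menorca")]
  rownames(birds) <- NULL
  list(birds = validate_bird_table(birds), alignment = aln, landmarks = lms,
       params = params)
}
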