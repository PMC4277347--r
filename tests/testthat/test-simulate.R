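test_that("biometric generator matches its configured moments", {
  n <- 10000
  x <- simulate_biometrics("YS", "male", n, seed = 11)
  # sample mean of bill depth at base within 3 SE of the configured 11.39
  se <- 0.51 / sqrt(n)
  expect_lt(abs(mean(x[, "bill_depth_base"]) - 11.39), 3 * se)
  # configured correlation structure shows up
  expect_gt(cor(x[, 1], x[, 2]), 0.25)
  # determinism
  expect_identical(x, simulate_biometrics("YS", "male", n, seed = 11))
})

test_that("zero-noise biometrics collapse to the mean vector", {
  p <- sim_params()
  p$biometric$YS$male$sd <- rep(0, 6)
  x <- simulate_biometrics("YS", "male", 1, p, seed = 1)
  expect_equal(unname(x[1, ]), unname(p$biometric$YS$male$mean))
})

test_that("isotope generator has the configured means and year variance", {
  p <- sim_params()
  # no year effect: BS d15N_P1 mean within 3 SE of 14.4
  iso <- simulate_isotopes("BS", 2006, 10000, p, seed = 3,
                           year_sd = rep(0, 4))
  expect_lt(abs(mean(iso$d15N_P1) - 14.4), 3 * 0.8 / sqrt(10000))
  # fully degenerate: exactly the species mean
  p0 <- p; p0$isotope$BS$sd <- rep(0, 4)
  iso0 <- simulate_isotopes("BS", 2006, 5, p0, seed = 3, year_sd = rep(0, 4))
  expect_true(all(iso0$d15N_P1 == 14.4))
  # law of total variance: between-year variance of year means ~ year_sd^2
  many <- simulate_isotopes("YS", 1:60, 40, p, seed = 5,
                            year_sd = rep(2, 4))
  year_means <- tapply(many$d15N_P1, many$year, mean)
  expect_lt(abs(var(year_means) - (4 + 0.9^2 / 40)) / 4, 0.5)
})

test_that("sequence generator hits the divergence, introgression and noise dials", {
  sim <- simulate_sequences(10, 10, seed = 2)
  cons <- vapply(sim$consensus, function(s) strsplit(s, "")[[1]][1:293],
                 character(293))
  expect_equal(sum(cons[, 1] != cons[, 2]), 7L)  # round(0.025 * 293)
  # private rate 0: all YS sequences identical
  p <- sim_params(private_sub_mean = 0)
  sim0 <- simulate_sequences(5, 5, p, seed = 2)
  ys <- unclass(sim0$alignment)[sim0$species == "YS"]
  expect_length(unique(ys), 1L)
  # introgression fraction 1: every designated bird carries YS haplotype
  p1 <- sim_params(private_sub_mean = 0, introgression_fraction = 1)
  sim1 <- simulate_sequences(3, 6, p1, seed = 4, menorca = 1:6)
  expect_true(all(sim1$introgressed[4:9]))
  expect_equal(unique(unclass(sim1$alignment)[4:9]),
               unique(unclass(sim1$alignment)[1:3]))
  # determinism
  expect_identical(unclass(simulate_sequences(10, 10, seed = 2)$alignment),
                   unclass(sim$alignment))
})

test_that("generated alignments separate haplogroups when divergence dominates", {
  sim <- simulate_sequences(8, 8, seed = 6)
  d <- unclass(identity_distance(sim$alignment))
  ys <- which(sim$species == "YS"); bs <- which(sim$species == "BS")
  within <- c(d[ys, ys][upper.tri(d[ys, ys])], d[bs, bs][upper.tri(d[bs, bs])])
  between <- d[ys, bs]
  expect_gt(mean(between), mean(within))
})

test_that("landmark generator reproduces the size ordering and pose freedom", {
  ys <- simulate_landmarks("YS", 200, seed = 7, sex = "male")
  bs <- simulate_landmarks("BS", 200, seed = 8, sex = "male")
  mean_logcs <- function(l) mean(log10(vapply(l, centroid_size, numeric(1))))
  expect_gt(mean_logcs(bs), mean_logcs(ys))
  expect_lt(abs(mean_logcs(ys) - 1.786), 0.01)
  # zero noise, no offset: all configurations are similarity copies
  p <- sim_params(landmark_noise_sd = 0, species_offset = 0)
  copies <- simulate_landmarks("BS", 10, p, seed = 9)
  gpa <- gpa_align(copies, slide = FALSE)
  flat <- matrix(gpa$aligned, 10, 26)
  expect_lt(max(stats::dist(flat)), 1e-10)
  expect_identical(simulate_landmarks("YS", 3, seed = 1)[[2]]$points,
                   simulate_landmarks("YS", 3, seed = 1)[[2]]$points)
})

test_that("plumage calls follow the doubtful rate", {
  expect_true(all(simulate_plumage("YS", 50, seed = 1, doubtful_rate = 0) == "YS"))
  expect_true(all(simulate_plumage("BS", 50, seed = 1, doubtful_rate = 1) == "doubtful"))
  calls <- simulate_plumage("BS", 10000, seed = 2)
  frac <- mean(calls == "doubtful")
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("cohort generator composes consistent outputs", {
  co <- simulate_cohort(seed = 21)
  b <- co$birds
  expect_equal(sum(b$source == "reference_ys"), 10L)
  expect_equal(sum(b$source == "reference_bs"), 1L)
  expect_true(all(!is.na(b$true_species)))
  expect_setequal(names(co$alignment), b$id)
  expect_setequal(vapply(co$landmarks, `[[`, character(1), "id"),
                  b$id[!is.na(b$landmark_id)])
  # reference birds never doubtful, never introgressed
  refs <- grepl("^reference_", b$source)
  expect_true(all(b$plumage_call[refs] %in% c("YS", "BS")))
  expect_true(all(!b$introgressed[refs]))
  # moult year recoverable from the synthetic collection dates
  expect_equal(assign_moult_year(b$collection_date), b$moult_year)
})

test_that("empty cohort sizes yield empty outputs without crashing", {
  p <- sim_params(cohort = list(ys_male = 0L, ys_female = 0L, bs_male = 0L,
                                bs_female = 0L, refs_ys = 0L, refs_bs = 0L,
                                menorca_n = 0L))
  co <- simulate_cohort(p, seed = 1)
  expect_equal(nrow(co$birds), 0L)
  expect_length(co$landmarks, 0L)
})
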