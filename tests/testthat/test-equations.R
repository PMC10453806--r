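# Frozen expected values for the two fixture athletes (A female, B male),
# each computed with an independent calculator from the published
# coefficients before implementation.
test_that("every density equation matches the hand-computed oracle on the fixture athletes", {
  ath <- fixture_athletes()
  frozen <- list(
    # eq_id, athlete, expected Db (kg/L)
    list("jp3", "A", 1.0554009),
    list("jp3", "B", 1.0755771),
    list("jp7", "A", 1.05621748),
    list("jp7", "B", 1.0773007025),
    list("forsyth", "A", 1.0596),
    list("forsyth", "B", 1.069985),
    list("katch", "A", 1.06687),
    list("katch", "B", 1.07525),
    list("lohman", "A", 1.06545176),
    list("lohman", "B", 1.07298016),
    list("thorland", "A", 1.066021),
    list("thorland", "B", 1.07641361),
    list("dw", "A", 1.042165019),   # female <= 19 stratum
    list("dw", "B", 1.0679745214))  # male 20-29 stratum
  for (case in frozen) {
    got <- estimate_density(ath, case[[1]])
    expect_equal(got$db[got$id == case[[2]]], case[[3]], tolerance = 1e-9,
                 label = paste(case[[1]], case[[2]]))
    expect_equal(got$status, c("ok", "ok"))
  }
})

test_that("direct BF% and FFM equations match the hand-computed oracle", {
  ath <- fixture_athletes()
  bf_frozen <- list(
    list("evans3", "A", 21.326),
    list("evans3", "B", 11.03772),
    list("evans7", "A", 21.67684),
    list("evans7", "B", 11.264825),
    list("slaughter", "A", 23.896),   # triceps+subscapular = 26 <= 35 branch
    list("loftin", "A", 25.0882006920),
    list("devrim", "A", 23.25),
    list("devrim", "B", 10.38))
  for (case in bf_frozen) {
    got <- estimate_bf_direct(ath, case[[1]])
    expect_equal(got$bf_percent[got$id == case[[2]]], case[[3]],
                 tolerance = 1e-9, label = paste(case[[1]], case[[2]]))
  }
  ffm_frozen <- list(
    list("matias_ffm", "A", 45.7812950820),
    list("matias_ffm", "B", 66.4694312500),
    list("stewart_ffm", "B", 58.9571588125),
    list("fornetti_ffm", "A", 49.31))
  for (case in ffm_frozen) {
    got <- estimate_ffm_direct(ath, case[[1]])
    expect_equal(got$ffm[got$id == case[[2]]], case[[3]],
                 tolerance = 1e-9, label = paste(case[[1]], case[[2]]))
  }
  tbw <- estimate_tbw_matias(ath)
  expect_equal(tbw$tbw_l, c(33.3945245902, 48.7111562500), tolerance = 1e-9)
})

test_that("boundary examples: intercepts at zero skinfolds and the D&W log base", {
  zero <- make_athlete(sex = "male", age = 20, sites = 1e-12)
  expect_equal(estimate_density(zero, "katch")$db, 1.09665, tolerance = 1e-7)
  expect_equal(estimate_density(zero, "jp3")$db, 1.104232, tolerance = 1e-7)
  expect_equal(estimate_bf_direct(zero, "evans3")$bf_percent, 2.654,
               tolerance = 1e-7)
  # SS4 = 50 mm, male 18: base-10 log, youngest stratum
  dw <- make_athlete(sex = "male", age = 18,
                     sites = c(subscapular = 12.5, triceps = 12.5,
                               suprailiac = 12.5, biceps = 12.5,
                               chest = 10, midaxillary = 10, abdominal = 10,
                               thigh = 10))
  expect_equal(estimate_density(dw, "dw")$db, 1.0549648897, tolerance = 1e-9)
})

test_that("Slaughter branches at a 35 mm triceps+subscapular sum", {
  low <- make_athlete(sex = "female", sites = c(
    subscapular = 12, triceps = 18, chest = 10, midaxillary = 10,
    suprailiac = 10, abdominal = 10, thigh = 10, biceps = 10))
  high <- make_athlete(sex = "female", sites = c(
    subscapular = 18, triceps = 22, chest = 10, midaxillary = 10,
    suprailiac = 10, abdominal = 10, thigh = 10, biceps = 10))
  expect_equal(estimate_bf_direct(low, "slaughter")$bf_percent,
               0.546 * 30 + 9.7, tolerance = 1e-12)
  expect_equal(estimate_bf_direct(high, "slaughter")$bf_percent, 30.0,
               tolerance = 1e-9)  # 1.33*40 - 0.013*1600 - 2.4
})

test_that("sex and race codings follow each equation's own convention", {
  # coding audit: Evans codes male = 1, Devrim-Lanpir codes female = 1
  coding <- eq_sex_coding <- asNamespace("bodycomp")$eq_sex_coding()
  expect_equal(coding$male[coding$eq_id == "evans3"], 1)
  expect_equal(coding$female[coding$eq_id == "evans3"], 0)
  expect_equal(coding$female[coding$eq_id == "devrim"], 1)
  expect_equal(coding$male[coding$eq_id == "devrim"], 0)

  m <- make_athlete(sex = "male", sites = 10)
  f <- make_athlete(sex = "female", sites = 10)
  expect_equal(estimate_bf_direct(f, "evans3")$bf_percent -
                 estimate_bf_direct(m, "evans3")$bf_percent, 6.343)
  expect_equal(estimate_bf_direct(f, "devrim")$bf_percent -
                 estimate_bf_direct(m, "devrim")$bf_percent, 11.43)
  # race coefficient (Evans: Black = 1 lowers BF% by 1.998)
  mb <- make_athlete(sex = "male", sites = 10, race_black = TRUE)
  expect_equal(estimate_bf_direct(m, "evans3")$bf_percent -
                 estimate_bf_direct(mb, "evans3")$bf_percent, 1.998)
  # Matias sex offset is additive +5.462 kg FFM, +5.086 L TBW for males
  expect_equal(estimate_ffm_direct(m, "matias_ffm")$ffm -
                 estimate_ffm_direct(f, "matias_ffm")$ffm, 5.462)
  expect_equal(estimate_tbw_matias(m)$tbw_l - estimate_tbw_matias(f)$tbw_l,
               5.086)
})

test_that("applicability gating: wrong sex, missing sites, D&W age stratum", {
  m <- make_athlete(sex = "male")
  f <- make_athlete(sex = "female")
  expect_equal(estimate_bf_direct(m, "slaughter")$status, "not_applicable")
  expect_equal(estimate_bf_direct(m, "loftin")$status, "not_applicable")
  expect_equal(estimate_ffm_direct(m, "fornetti_ffm")$status, "not_applicable")
  expect_equal(estimate_ffm_direct(f, "stewart_ffm")$status, "not_applicable")

  old <- make_athlete(sex = "male", age = 31)
  expect_warning(out <- estimate_density(old, "dw"), regexp = NA)
  expect_equal(out$status, "out_of_stratum")
  young <- make_athlete(sex = "female", age = 15)
  expect_warning(estimate_density(young, "dw"), "youngest")

  noimp <- make_athlete(sex = "male", r_ohm = NA_real_)
  expect_equal(estimate_ffm_direct(noimp, "matias_ffm")$status,
               "not_computable")
  expect_equal(estimate_tbw_matias(noimp)$status, "not_computable")
  nosite <- make_athlete(sex = "male")
  nosite$sf_chest_1_mm <- nosite$sf_chest_2_mm <- nosite$sf_chest_3_mm <- NA
  nosite <- reduce_triplicates(nosite)
  expect_equal(estimate_density(nosite, "jp3")$status, "not_computable")
  # female jp3 does not use the chest site
  nosite_f <- nosite; nosite_f$sex <- "female"
  expect_equal(estimate_density(nosite_f, "jp3")$status, "ok")
})

test_that("unknown equation ids raise a catalogued error listing valid ids", {
  ath <- fixture_athletes()
  expect_error(estimate_density(ath, "nope"), "valid ids.*jp3")
  expect_error(estimate_density(ath, "evans3"), "predicts bf_percent")
  expect_error(estimate_bf_direct(ath, "jp3"), "predicts density")
  reg <- equation_registry()
  expect_equal(nrow(reg), 16)
  expect_equal(anyDuplicated(reg$eq_id), 0)
})

test_that("Thorland and Stewart printed variants are exposed and flagged", {
  ath <- fixture_athletes()
  printed <- estimate_density(ath, "thorland", variant = "as_printed")
  expect_equal(printed$db[1], -1.208559, tolerance = 1e-9)
  expect_true(all(printed$nonphysical))
  corrected <- estimate_density(ath, "thorland")
  expect_false(any(corrected$nonphysical))

  st <- estimate_ffm_direct(ath, "stewart_ffm", variant = "as_printed")
  expect_equal(st$ffm[st$id == "B"], 56950.5086588125, tolerance = 1e-9)
  expect_true(st$nonphysical[st$id == "B"])
})

test_that("corrected density equations are non-increasing in each site over (0, 60]", {
  grid <- seq(0.5, 60, by = 0.5)
  eqs <- c("jp3", "jp7", "katch", "lohman", "thorland", "dw", "forsyth")
  for (eq in eqs) {
    for (sex in c("female", "male")) {
      for (site in skinfold_sites()) {
        # forsyth's printed midaxillary coefficient is positive; exempt
        if (eq == "forsyth" && site == "midaxillary") next
        coh <- tibble::tibble(id = as.character(seq_along(grid)), sex = sex,
                              age_y = 18, height_cm = 175, mass_kg = 70,
                              race_black = FALSE)
        for (s in skinfold_sites()) coh[[sprintf("sf_%s_mm", s)]] <- 15
        coh[[sprintf("sf_%s_mm", site)]] <- grid
        db <- suppressWarnings(estimate_density(coh, eq)$db)
        expect_true(all(diff(db) <= 1e-12),
                    label = sprintf("%s/%s/%s monotone", eq, sex, site))
      }
    }
  }
})

test_that("Wilmore residual volume matches hand computation in both variants", {
  expect_equal(residual_volume_wilmore(3, 40, 1, 80, 40), 2.9301277235,
               tolerance = 1e-9)
  expect_equal(residual_volume_wilmore(3, 40, 1, 80, 40,
                                       variant = "dead_space_subtracted"),
               2.855, tolerance = 1e-12)
  expect_equal(residual_volume_wilmore(3, 25, 25, 80, 40), 0)
  expect_error(residual_volume_wilmore(3, 40, 1, 40, 40), "denominator")
  expect_error(residual_volume_wilmore(3, 120, 1, 80, 40), "percentages")
})
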