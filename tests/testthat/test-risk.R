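test_that("ERR reduces to beta at the pivot ages and scales with its modifiers", {
  expect_equal(err("male", e = 40, a = 60, D = 1)$err, 0.32)
  expect_equal(err("female", e = 40, a = 60, D = 1)$err, 1.40)
  # exposure-age modifier below age 30: 0.32 * exp(-0.30 * (20-30)/10)
  expect_equal(err("male", e = 20, a = 60, D = 1)$err, 0.32 * exp(0.3),
               tolerance = 1e-12)
  expect_equal(err("male", e = 20, a = 60, D = 1)$err, 0.4320,
               tolerance = 1e-3)  # printed to 4 decimals
  expect_equal(err("female", e = 50, a = 60, D = 0)$err, 0)
})

test_that("ERR monotonicity, age independence above 30, and the sex ratio", {
  d <- seq(0, 2, by = 0.25)
  e_d <- sapply(d, function(D) err("male", 40, 60, D)$err)
  expect_true(all(diff(e_d) > 0))                 # increasing in dose
  e_e <- sapply(c(30, 45, 60, 80), function(e) err("male", e, 85, 1)$err)
  expect_true(all(e_e == e_e[1]))                 # flat for e >= 30
  e_a <- sapply(c(40, 50, 60, 70, 85), function(a) err("male", 35, a, 1)$err)
  expect_true(all(diff(e_a) < 0))                 # decreasing in attained age
  # beta_female / beta_male at identical (e, a, D)
  expect_equal(err("female", 25, 70, 0.5)$err / err("male", 25, 70, 0.5)$err,
               1.40 / 0.32, tolerance = 1e-12)
  # CI brackets the point estimate
  r <- err("female", 20, 55, 0.8)
  expect_true(r$lo < r$err && r$err < r$hi)
  expect_error(err("male", 40, 60, -0.1), ">= 0")
  expect_error(err("male", 40, 0, 1), "> 0")
  expect_error(err_params(beta_male = c(est = 0.1, lo = 0.2, hi = 0.3)),
               "bracket")
})

test_that("OLS recovers every printed coefficient pair from noiseless tables", {
  cohort <- make_cohort(n = 40, seed = 3)
  tab <- make_dose_table(cohort, noise_sd_frac = 0, seed = 1)
  truth <- study_fit_coefficients()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    rec <- tab[tab$organ == tr$organ & tab$protocol == tr$protocol, ]
    fit <- fit_dose_vs_diameter(rec, cohort)
    expect_equal(fit$intercept_cgy, tr$intercept_cgy, tolerance = 1e-8)
    expect_equal(fit$slope_cgy_per_mm, tr$slope_cgy_per_mm,
                 tolerance = 1e-8)
    expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  }
})

test_that("OLS recovery from noisy synthetic cohorts stays within 3 SE", {
  cohort <- make_cohort(n = 100, seed = 7)
  tab <- make_dose_table(cohort, noise_sd_frac = 0.10, seed = 11)
  truth <- study_fit_coefficients()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    rec <- tab[tab$organ == tr$organ & tab$protocol == tr$protocol, ]
    fit <- fit_dose_vs_diameter(rec, cohort)
    expect_lt(abs(fit$intercept_cgy - tr$intercept_cgy), 3 * fit$se[1])
    expect_lt(abs(fit$slope_cgy_per_mm - tr$slope_cgy_per_mm),
              3 * fit$se[2])
  }
})

test_that("regression guards: duplication invariance, singular designs", {
  cohort <- make_cohort(n = 20, seed = 5)
  tab <- make_dose_table(cohort, noise_sd_frac = 0.05, seed = 2)
  rec <- tab[tab$organ == "lungs" & tab$protocol == "4DCT", ]
  f1 <- fit_dose_vs_diameter(rec, cohort)
  f2 <- fit_dose_vs_diameter(rbind(rec, rec), cohort)
  expect_equal(f2$intercept_cgy, f1$intercept_cgy)
  expect_equal(f2$slope_cgy_per_mm, f1$slope_cgy_per_mm)

  const <- data.frame(patient_id = rec$patient_id, organ = "lungs",
                      protocol = "4DCT", dose_cgy = rec$dose_cgy)
  diam_const <- setNames(rep(300, nrow(rec)), rec$patient_id)
  expect_error(fit_dose_vs_diameter(const, diam_const), "singular")
  expect_error(fit_dose_vs_diameter(tab, cohort), "one organ")
})

test_that("a zero-slope truth is covered by the slope CI at the nominal rate", {
  set.seed(42)
  n_rep <- 200
  covered <- vapply(seq_len(n_rep), function(r) {
    d <- runif(30, 185, 465)
    y <- 5 + rnorm(30, 0, 1)
    rec <- data.frame(patient_id = as.character(seq_len(30)), dose_cgy = y)
    fit <- fit_dose_vs_diameter(rec, setNames(d, rec$patient_id))
    tcrit <- qt(0.975, 28)
    abs(fit$slope_cgy_per_mm) < tcrit * fit$se[2]
  }, logical(1))
  expect_gt(mean(covered), 0.88)
})

test_that("dose prediction is linear with a zero floor", {
  fit <- list(intercept_cgy = 25.90, slope_cgy_per_mm = -0.0491)
  expect_equal(predict_dose(fit, 300), 11.17, tolerance = 1e-6)
  expect_equal(predict_dose(fit, 0), 25.90)
  skin <- list(intercept_cgy = 1.63, slope_cgy_per_mm = -0.003)
  expect_equal(predict_dose(skin, 400), 0.43, tolerance = 1e-6)
  expect_warning(p <- predict_dose(skin, 600), "clamped")
  expect_equal(p, 0)
})

test_that("cohort risk ratios equal lung-dose ratios and average correctly", {
  pats <- data.frame(patient_id = c("A", "B", "C"), age = c(30, 55, 70),
                     sex = c("male", "female", "male"))
  recs <- data.frame(
    patient_id = rep(c("A", "B", "C"), each = 2),
    protocol = rep(c("3DCT", "4DCT"), 3),
    dose_cgy = c(0.8, 0.8 * 12, 0.7, 0.7 * 14, 0.9, 0.9 * 13.9))
  cr <- cohort_risk(recs, pats)
  expect_equal(unname(cr$patient_ratios), c(12, 14, 13.9), tolerance = 1e-12)
  expect_equal(cr$mean_ratio, mean(c(12, 14, 13.9)), tolerance = 1e-12)

  # single-patient cohort: summary ratio is that patient's ratio
  cr1 <- cohort_risk(recs[recs$patient_id == "A", ], pats[1, ])
  expect_equal(cr1$mean_ratio, 12, tolerance = 1e-12)

  # missing arm: skipped with a warning
  expect_warning(cr2 <- cohort_risk(recs[-2, ], pats), "skipped")
  expect_equal(length(cr2$patient_ratios), 2)

  # synthetic cohort with ratios drawn around 13.3: mean tracks the draw
  set.seed(9)
  n <- 60
  ratios <- rnorm(n, 13.3, 1)
  pats_n <- data.frame(patient_id = as.character(seq_len(n)),
                       age = sample(20:80, n, TRUE),
                       sex = sample(c("male", "female"), n, TRUE))
  recs_n <- data.frame(
    patient_id = rep(pats_n$patient_id, each = 2),
    protocol = rep(c("3DCT", "4DCT"), n),
    dose_cgy = as.vector(rbind(rep(0.75, n), 0.75 * ratios)))
  crn <- cohort_risk(recs_n, pats_n)
  expect_equal(crn$mean_ratio, mean(ratios), tolerance = 1e-9)
})
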