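# Structural model, covariate model and derived scalar quantities.

test_that("covariate model reproduces the published fixed-effect arithmetic", {
  ref <- apply_covariates(cov = ref_patient())
  expect_equal(ref$cl20, 5.77)
  expect_equal(ref$cl23, 0.493)
  expect_equal(ref$v_tam, 1120)

  # rifampicin: fractional-change model on cl20, cl23 and v_tam
  rif <- apply_covariates(cov = patient_covariates(2, 65, rif = TRUE))
  expect_equal(rif$cl20, 5.77 * 7.51)
  expect_equal(rif$cl23, 0.493 * 2.18)
  expect_equal(rif$v_tam, 1120 * 1.581)

  # age power model: ~2x elimination at 30 y, 25% lower at 90 y
  y30 <- apply_covariates(cov = patient_covariates(2, 30))
  y90 <- apply_covariates(cov = patient_covariates(2, 90))
  expect_equal(y30$cl20 / 5.77, (30 / 65)^-0.886)
  expect_gt(y30$cl20 / 5.77, 1.9)
  expect_lt(y30$cl20 / 5.77, 2.1)
  expect_equal(1 - y90$cl20 / 5.77, 0.25, tolerance = 0.02)

  # activity-score effects on endoxifen formation only
  as0 <- apply_covariates(cov = patient_covariates(0, 65))
  expect_equal(as0$cl23, 0.493 * 0.278)
  expect_equal(as0$cl20, 5.77)
  ssri <- apply_covariates(cov = patient_covariates(2, 65, ssri = TRUE))
  expect_equal(ssri$cl23, 0.493 * 0.346)
})

test_that("covariate inputs are validated and imputed per the stated rules", {
  expect_error(patient_covariates("2.4", 65), "activity-score")
  expect_error(patient_covariates(2, -5), "age")
  expect_error(apply_covariates(cov = data.frame(activity_score = "7",
                                                 age = 65)),
               "activity-score")
  # imputation: missing AS -> 2, missing age -> median, missing comeds off
  cov <- patient_covariates(c(NA, 0, 1), c(50, NA, 70), rif = NA)
  expect_equal(as.character(cov$activity_score), c("2", "0", "1"))
  expect_equal(cov$age[2], 60)   # median of 50, 70
  expect_false(any(cov$rif))
  # 2.5 and 3 are lumped into one category
  expect_equal(as.character(patient_covariates(c(2.5, 3), 65)$activity_score),
               c("2.5_3", "2.5_3"))
})

test_that("metabolic fraction matches the published values and reductions", {
  ref <- apply_covariates(cov = ref_patient())
  expect_equal(round(metabolic_fraction(ref), 2), 7.87)

  rif <- apply_covariates(cov = patient_covariates(2, 65, rif = TRUE))
  expect_equal(round(metabolic_fraction(rif), 2), 2.42)

  fm_ref <- metabolic_fraction(ref)
  fm_im <- metabolic_fraction(apply_covariates(cov = patient_covariates(0.5, 65)))
  fm_pm <- metabolic_fraction(apply_covariates(cov = patient_covariates(0, 65)))
  # printed 48.9 / 70.5; closed form gives 48.95 / 70.53
  expect_lt(abs(100 * (1 - fm_im / fm_ref) - 48.9), 0.06)
  expect_lt(abs(100 * (1 - fm_pm / fm_ref) - 70.5), 0.06)

  # invariance to joint clearance scaling
  p <- structural_parameters()
  p2 <- structural_parameters(cl20_f = p$cl20_f * 3.7, cl23_f = p$cl23_f * 3.7)
  expect_equal(metabolic_fraction(p), metabolic_fraction(p2))
})

test_that("closed-form profiles agree with the stiff-ODE oracle to 1e-6", {
  skip_if_not_installed("Matrix")
  set.seed(42)
  reg <- dosing_regimen(0, 20)
  tt <- seq(12, 720, by = 36)
  for (i in 1:10) {
    p <- random_params()
    a <- conc_profile(p, reg, tt)
    b <- ode_oracle_profile(p, reg, tt)
    rel <- max(abs(a$tamoxifen - b$tamoxifen) / pmax(b$tamoxifen, 1e-9),
               abs(a$endoxifen - b$endoxifen) / pmax(b$endoxifen, 1e-9))
    expect_lt(rel, 1e-6)
  }
})

test_that("profiles obey superposition, lag and mass balance", {
  p <- apply_covariates(cov = ref_patient())
  tt <- c(5, 10, 30, 60, 100)
  # zero dose
  expect_equal(conc_profile(p, dosing_regimen(0, 0), tt)$endoxifen,
               rep(0, 5))
  # nothing absorbed before the lag time
  early <- conc_profile(p, dosing_regimen(0, 20), c(0, 0.2, 0.38))
  expect_equal(early$tamoxifen, rep(0, 3))
  # two doses = sum of the shifted single-dose solutions
  both <- conc_profile(p, dosing_regimen(0, 20, end = 48), tt)
  d1 <- conc_profile(p, dosing_regimen(0, 20, end = 24), tt)
  d2 <- conc_profile(p, dosing_regimen(24, 20, end = 48), tt)
  expect_equal(both$endoxifen, d1$endoxifen + d2$endoxifen, tolerance = 1e-12)
  expect_equal(both$tamoxifen, d1$tamoxifen + d2$tamoxifen, tolerance = 1e-12)
  # infinite-time tamoxifen AUC of a single dose = dose / (cl20 + cl23)
  f <- function(t) conc_profile(p, dosing_regimen(0, 20, end = 24),
                                t)$tamoxifen
  auc <- stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(auc, 20000 / (p$cl20 + p$cl23), tolerance = 1e-3)
  # long-run average ~ dose rate / total clearance ~ 133 ng/mL
  expect_equal(conc_profile(p, dosing_regimen(0, 20), 5000)$tamoxifen,
               20000 / (24 * (p$cl20 + p$cl23)) , tolerance = 0.07)
  expect_error(conc_profile(p, dosing_regimen(0, 20), c(-1, 5)), "times")
})

test_that("steady-state troughs are linear in dose and consistent with
           long simulation", {
  p <- apply_covariates(cov = ref_patient())
  expect_equal(unlist(css_min(p, 0)), c(tamoxifen = 0, endoxifen = 0))
  expect_equal(css_min(p, 40)$endoxifen, 2 * css_min(p, 20)$endoxifen)
  expect_equal(css_min(p, 40)$tamoxifen, 2 * css_min(p, 20)$tamoxifen)
  # reference patient at 20 mg sits in the ~12 ng/mL region
  tr <- css_min(p, 20)$endoxifen
  expect_gt(tr, 11); expect_lt(tr, 14)
  # asymptote of the finite-dose simulation
  long <- conc_profile(p, dosing_regimen(0, 20), 500 * 24)
  expect_equal(long$endoxifen, tr, tolerance = 1e-3)
  # vectorisation over patients matches row-by-row evaluation
  cov <- patient_covariates(c(0, 1, 2, "2.5_3"), c(40, 55, 65, 80))
  pp <- apply_covariates(cov = cov)
  vec <- css_min(pp, 20)$endoxifen
  for (i in 1:4) {
    expect_equal(vec[i], css_min(pp[i, ], 20)$endoxifen)
  }
})

test_that("troughs are monotone in activity score and age", {
  ages <- c(30, 45, 65, 80, 95)
  tr_age <- css_min(apply_covariates(cov = patient_covariates(2, ages)),
                    20)$tamoxifen
  expect_true(all(diff(tr_age) > 0))
  tr_as <- css_min(apply_covariates(
    cov = patient_covariates(c(0, 0.5, 1, 1.5, 2, "2.5_3"), 65)),
    20)$endoxifen
  expect_true(all(diff(tr_as) > 0))
})

test_that("regimen construction rejects inconsistent segments", {
  expect_error(dosing_regimen(c(10, 5), 20), "increasing")
  expect_error(dosing_regimen(0, -5), "doses")
  expect_error(dosing_regimen(0, 20, interval = 0), "interval")
  expect_error(structural_parameters(ka = -1), "positive")
})
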