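# MAP-Bayesian estimation and dose selection.

trial_spec <- inflate_for_trial(random_effects_spec())

test_that("MAP objective has the stated structure and limits", {
  pat <- ref_patient()
  empty <- tdm_observations(numeric(0), numeric(0))
  expect_equal(map_objective(c(0, 0), empty, pat, trial_spec), 0)
  # prior-only term for nonzero eta without data
  expect_equal(map_objective(c(0.2, -0.1), empty, pat, trial_spec),
               0.2^2 / trial_spec$omega2[["cl20"]] +
                 0.1^2 / trial_spec$omega2[["cl23"]])
  # observations equal to the typical prediction: minimum at eta = 0
  p <- apply_covariates(cov = pat)
  tt <- c(14, 21, 28) * 24
  pred <- conc_profile(p, dosing_regimen(0, 20), tt)$endoxifen
  obs <- tdm_observations(tt, pred, dose = 20)
  expect_equal(map_objective(c(0, 0), obs, pat, trial_spec), 0,
               tolerance = 1e-10)
  for (e in list(c(0.1, 0), c(0, -0.1), c(-0.2, 0.3))) {
    expect_gt(map_objective(e, obs, pat, trial_spec), 0)
  }
  fit <- map_fit(pat, obs, trial_spec)
  expect_equal(unname(fit$eta), c(0, 0), tolerance = 1e-4)
  # sigma -> Inf limit: objective collapses to the prior
  wide <- random_effects_spec(omega2 = trial_spec$omega2,
                              pi2 = c(cl20 = 0, cl23 = 0),
                              phi2 = c(cl20 = 0, cl23 = 0),
                              sigma2 = c(tam = 1e12, endx = 1e12),
                              sigma_cov = 0)
  expect_equal(unname(map_fit(pat, obs, wide)$eta), c(0, 0),
               tolerance = 1e-4)
  expect_error(tdm_observations(336, -1), "positive")
})

test_that("dense noise-free sampling recovers known eta within 0.02", {
  pat <- patient_covariates(2, 55)
  base <- apply_covariates(cov = pat)
  true <- base
  true$cl20 <- base$cl20 * exp(0.3)
  true$cl23 <- base$cl23 * exp(-0.4)
  tt <- c(2, 4, 7, 10, 14, 21, 28) * 24
  prof <- conc_profile(true, dosing_regimen(0, 20), tt)
  # a TDM plasma sample is assayed for both analytes (paired observations)
  obs <- tdm_observations(rep(tt, 2), c(prof$endoxifen, prof$tamoxifen),
                          analyte = rep(c("endoxifen", "tamoxifen"),
                                        each = length(tt)),
                          dose = 20)
  fit <- map_fit(pat, obs, trial_spec, include_tam = TRUE)
  expect_true(fit$converged)
  expect_lt(abs(fit$eta[["cl20"]] - 0.3), 0.02)
  expect_lt(abs(fit$eta[["cl23"]] + 0.4), 0.02)
  # starting-point invariance
  fit2 <- map_fit(pat, obs, trial_spec, include_tam = TRUE,
                  starts = rbind(c(1, -1), c(-1, 1)))
  expect_equal(fit$eta, fit2$eta, tolerance = 1e-6)
  # OFV at the optimum never exceeds the prior-mode OFV
  expect_lte(fit$ofv, map_objective(c(0, 0), obs, pat, trial_spec,
                                    include_tam = TRUE))
})

test_that("no observations return the prior mode", {
  fit <- map_fit(ref_patient(), tdm_observations(numeric(0), numeric(0)),
                 trial_spec)
  expect_equal(unname(fit$eta), c(0, 0))
  expect_true(fit$converged)
  expect_equal(fit$ofv, 0)
})

test_that("more data pull the MAP estimate toward the data-only solution", {
  pat <- patient_covariates(2, 65)
  base <- apply_covariates(cov = pat)
  true <- base
  true$cl23 <- base$cl23 * exp(-0.6)
  errs <- sapply(c(3, 12, 48), function(m) {
    tt <- seq(7, 28, length.out = m) * 24
    prof <- conc_profile(true, dosing_regimen(0, 20), tt)
    obs <- tdm_observations(tt, prof$endoxifen, dose = 20)
    fit <- map_fit(pat, obs, trial_spec)
    abs(fit$eta[["cl23"]] + 0.6)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("dose selection picks the lowest qualifying grid dose", {
  pat <- ref_patient()
  fit <- map_fit(pat, tdm_observations(numeric(0), numeric(0)), trial_spec)
  # reference patient ~12.8 ng/mL at 20 mg -> needs ~9.3 mg -> 10 mg
  sel <- select_dose(fit)
  expect_equal(sel$dose, 10)
  expect_false(sel$capped)
  expect_gte(sel$predicted_trough, 5.97)
  # 5-mg-step grid gives the same answer here (linearity arithmetic)
  expect_equal(select_dose(fit, dose_grid = seq(5, 120, 5))$dose, 10)
  # threshold zero -> lowest grid dose
  expect_equal(select_dose(fit, threshold = 0)$dose, 5)
  # unreachable target -> maximum dose with capped flag
  hi <- select_dose(fit, threshold = 1e5)
  expect_equal(hi$dose, 120)
  expect_true(hi$capped)
  expect_error(select_dose(fit, dose_grid = numeric(0)), "empty")
  # monotone: higher predicted trough never raises the selected dose
  pm <- map_fit(patient_covariates(0, 65),
                tdm_observations(numeric(0), numeric(0)), trial_spec)
  expect_gte(select_dose(pm)$dose, sel$dose)
})

test_that("the trial engine's fast objective equals map_objective", {
  pat <- patient_covariates(1, 58)
  base <- apply_covariates(cov = pat)
  tt_days <- c(14, 21, 28)
  obs_conc <- c(4.2, 5.1, 5.4)
  obs <- tdm_observations(tt_days * 24, obs_conc, dose = 40)
  w_res <- 1 / trial_spec$sigma2[["endx"]]
  fast <- function(e) {
    pred <- tamipd:::.endx_trough_scalar(base$ka, base$tlag, base$v_tam,
                                         base$cl20 * exp(e[1]),
                                         base$cl23 * exp(e[2]),
                                         base$cl30, base$v_endx, 40, tt_days)
    sum((log(obs_conc) - log(pred))^2) * w_res +
      e[1]^2 / trial_spec$omega2[["cl20"]] +
      e[2]^2 / trial_spec$omega2[["cl23"]]
  }
  for (e in list(c(0, 0), c(0.3, -0.2), c(-0.5, 0.4))) {
    expect_equal(fast(e), map_objective(e, obs, pat, trial_spec),
                 tolerance = 1e-10)
  }
})
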