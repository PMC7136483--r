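# Synthetic multi-study database generation and variance decomposition.

test_that("zero-variance trough design reproduces deterministic troughs", {
  zero <- random_effects_spec(omega2 = c(cl20 = 0, cl23 = 0),
                              pi2 = c(cl20 = 0, cl23 = 0),
                              phi2 = c(cl20 = 0, cl23 = 0),
                              sigma2 = c(tam = 0, endx = 0), sigma_cov = 0)
  des <- list(study_design(1, n_patients = 5, n_occasions = 2,
                           style = "trough", age_mean = 65, age_sd = 1e-6,
                           age_bounds = c(64, 66),
                           as_probs = c("0" = 0, "0.5" = 0, "1" = 0,
                                        "1.5" = 0, "2" = 1, "2.5_3" = 0)))
  db <- generate_database(des, spec = zero, seed = 3)
  p <- apply_covariates(cov = patient_covariates(2, 65))
  expected <- css_min(p, 20)
  endx <- db$records$DV[db$records$DVID == 2]
  tam <- db$records$DV[db$records$DVID == 1]
  expect_equal(endx, rep(expected$endoxifen, length(endx)), tolerance = 1e-6)
  expect_equal(tam, rep(expected$tamoxifen, length(tam)), tolerance = 1e-6)
})

test_that("default six-study design has the expected bookkeeping", {
  designs <- default_study_designs()
  expect_length(designs, 6)
  expect_equal(sum(vapply(designs, `[[`, 0, "n_patients")), 468)
  db <- generate_database(designs, seed = 11)
  # two analytes per sample; observation count of the order of the pooled
  # database (3,554), design-dependent
  expect_gt(nrow(db$records), 2500)
  expect_lt(nrow(db$records), 6000)
  expect_equal(sort(unique(db$records$STUDY)), 1:6)
  expect_equal(length(unique(db$records$ID)), 468)
  expect_true(all(db$records$DV > 0))
  # time-ordered within patient
  expect_false(is.unsorted(order(db$records$ID, db$records$TIME)))
  # determinism
  db2 <- generate_database(designs, seed = 11)
  expect_identical(db$records, db2$records)
  # comedication scenarios are occasion-specific
  s4 <- db$latent[db$latent$STUDY == 4, ]
  expect_true(any(s4$RIF == 1) && all(s4$RIF[s4$OCC != 2] == 0))
  s5 <- db$latent[db$latent$STUDY == 5, ]
  expect_true(any(s5$SSRI == 1) && all(s5$SSRI[s5$OCC != 1] == 0))
})

test_that("dataset CSV round-trips exactly and reader validates input", {
  db <- generate_database(default_study_designs(scale = 0.03), seed = 5)
  path <- tempfile(fileext = ".csv")
  write_dataset(db$records, path)
  back <- read_dataset(path)
  expect_equal(back$DV, db$records$DV, tolerance = 1e-12)
  expect_equal(back$TIME, db$records$TIME, tolerance = 1e-12)
  expect_equal(back$AS, as.character(db$records$AS))
  # out-of-order rows are sorted with a warning
  shuffled <- db$records[rev(seq_len(nrow(db$records))), ]
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(shuffled, path2, row.names = FALSE, quote = FALSE)
  expect_warning(sorted <- read_dataset(path2), "sorted")
  expect_equal(sorted$DV, back$DV)
  # missing column and malformed line errors are named
  bad <- db$records[, setdiff(names(db$records), "DV")]
  path3 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path3, row.names = FALSE)
  expect_error(read_dataset(path3), "DV")
  lines <- readLines(path)
  lines[5] <- paste0(lines[5], ",extra,fields")
  path4 <- tempfile(fileext = ".csv")
  writeLines(lines, path4)
  expect_error(read_dataset(path4), "line 5")
})

test_that("hierarchical decomposition recovers the latent variances", {
  designs <- replicate_designs(default_study_designs(scale = 0.5), 4)
  spec <- random_effects_spec()
  db <- generate_database(designs, spec = spec, seed = 21)
  ve <- variance_explained(db)
  mom <- latent_mom(db$latent, "cl23")
  adj <- ve[ve$parameter == "cl23", ]
  # lmer on the latent log clearances agrees with the direct moments of
  # the recorded draws (the two routes are independent implementations)
  expect_equal(adj$var_after[adj$level == "IIV"], mom[["omega2"]],
               tolerance = 0.08)
  expect_equal(adj$var_after[adj$level == "IOV"], mom[["pi2"]],
               tolerance = 0.15)
  expect_equal(adj$var_after[adj$level == "ISV"], mom[["phi2"]],
               tolerance = 0.5)
})

test_that("covariate attribution moves comedication noise out of IOV", {
  # one big SSRI-switch study: without covariate attribution the switch
  # masquerades as interoccasion variability on cl23
  des <- list(study_design(1, n_patients = 150, n_occasions = 3,
                           style = "trough", scenario = "ssri_switch",
                           scenario_frac = 0.8))
  db <- generate_database(des, seed = 8)
  ve <- variance_explained(db, parameters = "cl23")
  iov <- ve[ve$level == "IOV", ]
  pi2 <- random_effects_spec()$pi2[["cl23"]]
  expect_gt(iov$cv_before, variance_to_cv(pi2) * 1.5)
  expect_equal(iov$var_after, pi2, tolerance = 0.35)
  expect_gt(iov$cv_explained_rel, 30)
  # a covariate-free world has nothing to explain
  des0 <- list(study_design(1, n_patients = 40, n_occasions = 2,
                            style = "trough", age_mean = 65, age_sd = 1e-6,
                            age_bounds = c(64, 66),
                            as_probs = c("0" = 0, "0.5" = 0, "1" = 0,
                                         "1.5" = 0, "2" = 1, "2.5_3" = 0)))
  db0 <- generate_database(des0, seed = 9)
  ve0 <- variance_explained(db0, parameters = "cl23")
  expect_true(all(abs(ve0$cv_explained_abs) < 1e-8))
})

test_that("MAP pipeline on rich low-noise patients shows bounded shrinkage", {
  spec <- inflate_for_trial(random_effects_spec())
  low <- random_effects_spec(omega2 = spec$omega2,
                             pi2 = c(cl20 = 0, cl23 = 0),
                             phi2 = c(cl20 = 0, cl23 = 0),
                             sigma2 = spec$sigma2 / 100,
                             sigma_cov = spec$sigma_cov / 100)
  set.seed(14)
  n <- 40
  pop <- patient_covariates(sample(c("1", "2"), n, TRUE), runif(n, 45, 80))
  base <- apply_covariates(cov = pop)
  eta <- sample_effects(spec, n, seed = 14)$eta
  true <- individual_parameters(base, eta)
  tt <- c(1, 2, 3, 5, 7, 10, 14, 21, 28) * 24
  est <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    prof <- conc_profile(true[i, ], dosing_regimen(0, 20), tt)
    eps <- sample_residuals(low, length(tt), seed = 1400 + i)[, "endx"]
    obs <- tdm_observations(tt, prof$endoxifen * exp(eps), dose = 20)
    est[i, ] <- map_fit(pop[i, , drop = FALSE], obs, low)$eta
  }
  for (j in 1:2) {
    slope <- stats::coef(stats::lm(est[, j] ~ eta[, j]))[2]
    expect_gt(slope, 0.8)
    expect_lte(slope, 1.02)  # 1 up to regression noise
  }
})
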