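# Independent oracles used across tests.

# Numerical solution of the linear three-compartment cascade
# (gut -> tamoxifen -> endoxifen) by matrix-exponential event stepping:
# exact for a linear ODE system up to expm() precision, and entirely
# independent of the closed-form superposition code under test.
ode_oracle_profile <- function(p, regimen, times) {
  ka <- p$ka
  k2 <- (p$cl20 + p$cl23) / p$v_tam
  k23f <- p$cl23 / p$v_tam
  k3 <- p$cl30 / p$v_endx
  A <- matrix(c(-ka, 0, 0,
                ka, -k2, 0,
                0, k23f, -k3), 3, 3, byrow = TRUE)
  ev <- NULL
  for (s in seq_len(nrow(regimen))) {
    nd <- if (is.finite(regimen$end[s])) {
      ceiling((regimen$end[s] - regimen$start[s]) / regimen$interval[s])
    } else {
      floor((max(times) - regimen$start[s]) / regimen$interval[s]) + 1L
    }
    if (nd < 1) next
    dt <- regimen$start[s] + (0:(nd - 1)) * regimen$interval[s] + p$tlag
    dt <- dt[dt <= max(times) + 1e-9]
    if (length(dt)) {
      ev <- rbind(ev, cbind(dt, regimen$daily_dose[s] * 1000))
    }
  }
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  pts <- sort(unique(c(times, ev[, 1])))
  x <- c(0, 0, 0)
  tcur <- 0
  out <- matrix(NA_real_, length(times), 2)
  for (tp in pts) {
    if (tp > tcur) {
      x <- as.numeric(Matrix::expm(A * (tp - tcur)) %*% x)
    }
    tcur <- tp
    hit <- which(abs(ev[, 1] - tp) < 1e-12)
    if (length(hit)) x[1] <- x[1] + sum(ev[hit, 2])
    oi <- which(abs(times - tp) < 1e-12)
    if (length(oi)) {
      out[oi, 1] <- x[2] / p$v_tam
      out[oi, 2] <- x[3] / p$v_endx
    }
  }
  data.frame(time = times, tamoxifen = out[, 1], endoxifen = out[, 2])
}

# random but physiologically sane parameter row
random_params <- function() {
  data.frame(ka = runif(1, 0.5, 3), tlag = runif(1, 0.1, 1),
             v_tam = runif(1, 500, 2000), cl20 = runif(1, 1, 15),
             cl23 = runif(1, 0.1, 1.5), cl30 = runif(1, 2, 8),
             v_endx = runif(1, 200, 600))
}

# direct method-of-moments variances of the latent hierarchy draws:
# the generator records the true gamma/eta/kappa realisations, so their
# empirical variances are an lmer-independent recovery oracle
latent_mom <- function(latent, par) {
  g <- latent[[paste0("gamma_", par)]][!duplicated(latent$STUDY)]
  e <- latent[[paste0("eta_", par)]][!duplicated(latent$ID)]
  k <- latent[[paste0("kappa_", par)]]
  c(phi2 = stats::var(g), omega2 = stats::var(e), pi2 = stats::var(k))
}

# reference covariate set (CYP2D6 AS 2, 65 years, no comedication)
ref_patient <- function() patient_covariates(activity_score = 2, age = 65)
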