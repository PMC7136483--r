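#' Dosing regimen with piecewise-constant daily doses
#'
#' An ordered, non-overlapping sequence of dosing segments; within each
#' segment doses of `daily_dose` mg are given every `interval` hours
#' starting at `start`. Dose changes are only allowed at segment boundaries
#' (this is what the precision-dosing switch after the 4-week run-in uses).
#'
#' @param start Segment start times (h), strictly increasing, first >= 0.
#' @param daily_dose Dose per administration (mg), >= 0, recycled.
#' @param interval Dosing interval (h), default 24, recycled.
#' @param end Treatment end (h): no doses are given at or after `end`.
#'   Defaults to `Inf` (dosing continues).
#' @return `data.frame` of class `dosing_regimen` with columns
#'   `start`, `end`, `daily_dose`, `interval`.
#' @export
#' @examples
#' dosing_regimen(0, 20)                      # 20 mg QD from time zero
#' dosing_regimen(c(0, 672), c(40, 25))       # dose switch after 4 weeks
dosing_regimen <- function(start = 0, daily_dose = 20, interval = 24,
                           end = Inf) {
  n <- length(start)
  daily_dose <- rep_len(daily_dose, n)
  interval <- rep_len(interval, n)
  if (n == 0L) stop("regimen needs at least one segment", call. = FALSE)
  if (any(start < 0) || is.unsorted(start, strictly = TRUE)) {
    stop("segment starts must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (any(daily_dose < 0)) stop("doses must be >= 0", call. = FALSE)
  if (any(interval <= 0)) stop("interval must be positive", call. = FALSE)
  seg_end <- c(start[-1L], end)
  if (any(seg_end <= start)) stop("segments must not overlap", call. = FALSE)
  structure(data.frame(start = start, end = seg_end, daily_dose = daily_dose,
                       interval = interval),
            class = c("dosing_regimen", "data.frame"))
}

# Micro-rate constants and superposition coefficients of the linear cascade
# gut -> tamoxifen -> endoxifen. Vectorised over rows of `p`. Doses enter in
# mg and are converted to ug so that ug/L == ng/mL with volumes in L.
# Coincident rate constants (relative gap < 1e-10) are perturbed by 1e-8 so
# the distinct-rate closed form stays valid (documented limiting-case
# convention; error introduced is O(1e-8)).
.pk_terms <- function(p) {
  ka <- p$ka
  k2 <- (p$cl20 + p$cl23) / p$v_tam
  k3 <- p$cl30 / p$v_endx
  nudge <- function(a, b) ifelse(abs(a - b) < 1e-10 * pmax(a, b),
                                 b * (1 + 1e-8), b)
  k2 <- nudge(ka, k2)
  k3 <- nudge(ka, k3)
  k3 <- nudge(k2, k3)
  k23f <- p$cl23 / p$v_tam
  # per-mg-dose coefficients (dose in mg -> 1000 ug)
  a_tam <- 1000 * ka / (p$v_tam * (ka - k2))
  e_pre <- 1000 * ka * k23f / p$v_endx
  list(
    k = list(ka = ka, k2 = k2, k3 = k3),
    tam = list(ka = -a_tam, k2 = a_tam),
    endx = list(ka = e_pre / ((k2 - ka) * (k3 - ka)),
                k2 = e_pre / ((ka - k2) * (k3 - k2)),
                k3 = e_pre / ((ka - k3) * (k2 - k3)))
  )
}

# Stable partial geometric sum over identical doses: for a rate constant k,
# sum over the M most recent doses of exp(-k * tau_m) where the most recent
# active dose has elapsed time tau_min >= 0 and doses are `interval` apart.
# M may be Inf (steady state). Returns 0 where M == 0.
.dose_sum <- function(k, tau_min, interval, m) {
  r <- exp(-k * interval)
  s <- (1 - r^m) / (1 - r)  # r^Inf == 0 gives the steady-state limit
  out <- exp(-k * tau_min) * s
  out[m <= 0] <- 0
  out
}

#' Tamoxifen and endoxifen concentration-time profiles
#'
#' Closed-form concentrations (ng/mL) under a multiple-dose regimen by
#' superposition of the single-dose bi-/tri-exponential solutions of the
#' lagged first-order absorption cascade. Equivalent (to ~1e-10 relative) to
#' numerical integration of the underlying ODE system, but exact and fast.
#'
#' @param params One row of covariate-adjusted (and possibly random-effect
#'   scaled) parameters, as returned by [apply_covariates()] or
#'   [individual_parameters()].
#' @param regimen A [dosing_regimen()].
#' @param times Observation times (h) since first dose, all >= 0.
#' @return `data.frame` with columns `time`, `tamoxifen`, `endoxifen`.
#' @export
#' @examples
#' p <- apply_covariates(cov = patient_covariates(2, 65))
#' conc_profile(p, dosing_regimen(0, 20), times = c(24, 168, 720))
conc_profile <- function(params, regimen, times) {
  if (nrow(params) != 1L) stop("conc_profile expects a single patient row",
                               call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  tm <- .pk_terms(params)
  tam <- numeric(length(times))
  endx <- numeric(length(times))
  for (s in seq_len(nrow(regimen))) {
    n_max <- if (is.finite(regimen$end[s])) {
      ceiling((regimen$end[s] - regimen$start[s]) / regimen$interval[s])
    } else Inf
    u <- times - params$tlag - regimen$start[s]
    m <- pmin(pmax(floor(u / regimen$interval[s]) + 1, 0), n_max)
    tau_min <- u - (m - 1) * regimen$interval[s]
    dose <- regimen$daily_dose[s]
    if (dose == 0) next
    ds_ka <- .dose_sum(tm$k$ka, tau_min, regimen$interval[s], m)
    ds_k2 <- .dose_sum(tm$k$k2, tau_min, regimen$interval[s], m)
    ds_k3 <- .dose_sum(tm$k$k3, tau_min, regimen$interval[s], m)
    tam <- tam + dose * (tm$tam$ka * ds_ka + tm$tam$k2 * ds_k2)
    endx <- endx + dose * (tm$endx$ka * ds_ka + tm$endx$k2 * ds_k2 +
                             tm$endx$k3 * ds_k3)
  }
  data.frame(time = times, tamoxifen = pmax(tam, 0), endoxifen = pmax(endx, 0))
}

#' Steady-state pre-dose trough concentrations
#'
#' Analytic steady-state troughs under once-daily (or `tau`-hourly) dosing,
#' via geometric-series accumulation of each exponential term evaluated at
#' the end of the dosing interval. Linear in dose. Vectorised over patients.
#'
#' @param params `individual_parameters` data frame (any number of rows).
#' @param daily_dose Dose per interval (mg), scalar or per-patient.
#' @param tau Dosing interval (h), default 24.
#' @return `data.frame` with columns `tamoxifen`, `endoxifen` (ng/mL).
#' @export
#' @examples
#' p <- apply_covariates(cov = patient_covariates(2, 65))
#' css_min(p, 20)   # reference patient: endoxifen trough ~ 12 ng/mL
css_min <- function(params, daily_dose, tau = 24) {
  if (any(daily_dose < 0)) stop("daily_dose must be >= 0", call. = FALSE)
  .trough_after(params, daily_dose, n_doses = Inf, tau = tau)
}

# Pre-dose trough after `n_doses` daily doses (observation at t =
# n_doses * tau after the first dose, i.e. just before the next dose).
# n_doses = Inf gives the steady-state trough. Vectorised over patients.
.trough_after <- function(params, daily_dose, n_doses, tau = 24) {
  tm <- .pk_terms(params)
  tau_min <- tau - params$tlag  # time since most recent (absorbed) dose
  f <- function(k, coef) {
    coef * .dose_sum(k, tau_min, tau, n_doses)
  }
  tam <- daily_dose * (f(tm$k$ka, tm$tam$ka) + f(tm$k$k2, tm$tam$k2))
  endx <- daily_dose * (f(tm$k$ka, tm$endx$ka) + f(tm$k$k2, tm$endx$k2) +
                          f(tm$k$k3, tm$endx$k3))
  data.frame(tamoxifen = pmax(as.numeric(tam), 0),
             endoxifen = pmax(as.numeric(endx), 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
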