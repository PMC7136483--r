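#' CYP2D6 allele activity table
#'
#' Maps star-allele names to activity values, following the activity-score
#' convention (fully functional = 1, reduced = 0.5, null = 0). The default
#' is a small seed catalogue of common Caucasian alleles; gene duplication
#' alleles are expressed as extra entries (e.g. `*1x2` with value 2) via
#' `extra`.
#'
#' @param extra Named numeric vector of additional or overriding alleles;
#'   values must lie on the 0-3 grid in steps of 0.5.
#' @return Named numeric vector of class `allele_activity_table`.
#' @export
#' @examples
#' tab <- allele_activity_table(extra = c("*1x2" = 2))
#' genotype_to_as("*1x2", "*1", tab)  # 3
allele_activity_table <- function(extra = NULL) {
  tab <- c("*1" = 1, "*2" = 1, "*35" = 1,
           "*9" = 0.5, "*10" = 0.5, "*17" = 0.5, "*29" = 0.5, "*41" = 0.5,
           "*3" = 0, "*4" = 0, "*5" = 0, "*6" = 0)
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(names(extra) == "")) {
      stop("extra alleles must be named", call. = FALSE)
    }
    tab[names(extra)] <- extra
  }
  if (any(!(tab * 2) %in% 0:6)) {
    stop("allele activity values must lie on the 0-3 grid in steps of 0.5",
         call. = FALSE)
  }
  structure(tab, class = "allele_activity_table")
}

#' Translate a biallelic CYP2D6 genotype to an activity score
#'
#' The activity score is the sum of the two allele activity values,
#' yielding the 0-3 grid in 0.5 steps (e.g. `*1/*41 -> 1.5`). Sums above 3
#' (possible with duplication alleles) are capped at 3, the top of the
#' scored grid.
#'
#' @param allele1,allele2 Star-allele names present in `table`.
#' @param table An [allele_activity_table()].
#' @return Numeric activity score on the 0-3 grid.
#' @export
genotype_to_as <- function(allele1, allele2,
                           table = allele_activity_table()) {
  for (a in c(allele1, allele2)) {
    if (!a %in% names(table)) {
      stop("unknown allele '", a, "'; known alleles: ",
           paste(names(table), collapse = ", "), call. = FALSE)
    }
  }
  min(unname(table[[allele1]] + table[[allele2]]), 3)
}

#' Translate an activity score to the CYP2D6 phenotype category
#'
#' Genotype-predicted phenotypes: poor metabolizer (gPM) at AS 0,
#' intermediate (gIM) at 0.5, normal (gNM) at 1-2 and ultrarapid (gUM) at
#' >= 2.5 (the 2.5 and 3 scores form one high-activity category).
#'
#' @param as_value Activity score(s) on the 0-3 grid in steps of 0.5, or
#'   the category labels used elsewhere in the package.
#' @return Character vector in `c("gPM", "gIM", "gNM", "gUM")`.
#' @export
as_to_phenotype <- function(as_value) {
  lab <- .as_label(as_value)
  if (any(is.na(lab))) stop("activity score must not be missing",
                            call. = FALSE)
  unname(c("0" = "gPM", "0.5" = "gIM", "1" = "gNM", "1.5" = "gNM",
           "2" = "gNM", "2.5_3" = "gUM")[lab])
}

#' Virtual population specification
#'
#' Describes the virtual breast-cancer population for trial simulation:
#' exact phenotype stratum sizes (gNM pools the rare ultrarapid patients,
#' as in the trial summaries), the activity-score split within the gNM
#' stratum, a truncated-normal age distribution and comedication
#' prevalences (zero in the trial: no interacting comedication assumed).
#'
#' @param n Total number of patients.
#' @param phenotype_counts Named counts `c(gNM = , gIM = , gPM = )` summing
#'   to `n`; the gNM stratum includes gUM.
#' @param as_split_gNM Proportions over activity scores
#'   `c("1", "1.5", "2", "2.5_3")` within the gNM stratum, summing to 1.
#'   The published population reports only the marginal phenotype
#'   frequencies; this Caucasian-typical split is the main
#'   reproduction-uncertainty knob and is deliberately configurable.
#' @param age_mean,age_sd Mean/SD (years) of the untruncated normal.
#' @param age_bounds Truncation bounds (years).
#' @param p_rif,p_ssri Comedication prevalences in \[0, 1\].
#' @param seed Integer seed used by [sample_population()].
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n = 10000,
                            phenotype_counts = c(gNM = 8650, gIM = 770,
                                                 gPM = 580),
                            as_split_gNM = c("1" = 0.30, "1.5" = 0.10,
                                             "2" = 0.55, "2.5_3" = 0.05),
                            age_mean = 64, age_sd = 13,
                            age_bounds = c(25, 95),
                            p_rif = 0, p_ssri = 0, seed = 1L) {
  if (!all(c("gNM", "gIM", "gPM") %in% names(phenotype_counts))) {
    stop("phenotype_counts must be named gNM, gIM, gPM", call. = FALSE)
  }
  phenotype_counts <- phenotype_counts[c("gNM", "gIM", "gPM")]
  if (any(phenotype_counts < 0) || sum(phenotype_counts) != n) {
    stop("phenotype counts must be >= 0 and sum to n", call. = FALSE)
  }
  if (!all(c("1", "1.5", "2", "2.5_3") %in% names(as_split_gNM)) ||
      abs(sum(as_split_gNM) - 1) > 1e-8 || any(as_split_gNM < 0)) {
    stop("as_split_gNM must be non-negative proportions over 1, 1.5, 2, ",
         "2.5_3 summing to 1", call. = FALSE)
  }
  if (age_bounds[1] >= age_bounds[2]) stop("age bounds must be ordered",
                                           call. = FALSE)
  if (age_sd <= 0) stop("age_sd must be positive", call. = FALSE)
  if (p_rif < 0 || p_rif > 1 || p_ssri < 0 || p_ssri > 1) {
    stop("comedication prevalences must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n = n, phenotype_counts = phenotype_counts,
                 as_split_gNM = as_split_gNM[c("1", "1.5", "2", "2.5_3")],
                 age_mean = age_mean, age_sd = age_sd,
                 age_bounds = age_bounds, p_rif = p_rif, p_ssri = p_ssri,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# exact integer allocation of n over proportions (largest remainder)
.allocate <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

# inverse-CDF truncated normal draw
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

#' Sample a virtual patient population
#'
#' Stratified (exact-count) sampling of phenotypes and activity scores,
#' i.i.d. truncated-normal ages, and Bernoulli comedication flags.
#' Deterministic given `spec` (which carries the seed).
#'
#' @param spec A [population_spec()].
#' @return A [patient_covariates()] data frame with an extra `phenotype`
#'   column; `nrow == spec$n`.
#' @export
#' @examples
#' pop <- sample_population(population_spec(n = 100))
#' table(pop$phenotype)
sample_population <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  if (spec$n == 0L) {
    out <- patient_covariates(character(0), numeric(0))
    out$phenotype <- character(0)
    return(out)
  }
  n_gnm <- spec$phenotype_counts[["gNM"]]
  as_counts <- c(.allocate(n_gnm, spec$as_split_gNM),
                 "0.5" = spec$phenotype_counts[["gIM"]],
                 "0" = spec$phenotype_counts[["gPM"]])
  as_vec <- rep(names(as_counts), times = as_counts)
  age <- .rtruncnorm(spec$n, spec$age_mean, spec$age_sd,
                     spec$age_bounds[1], spec$age_bounds[2])
  rif <- stats::runif(spec$n) < spec$p_rif
  ssri <- stats::runif(spec$n) < spec$p_ssri
  out <- patient_covariates(as_vec, age, rif = rif, ssri = ssri)
  out$phenotype <- as_to_phenotype(out$activity_score)
  out
}

# theoretical moments of the truncated normal (used as a test oracle and
# reported by summaries)
.truncnorm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  d <- (stats::dnorm(a) - stats::dnorm(b)) / z
  mu <- mean + sd * d
  v <- sd^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z - d^2)
  c(mean = mu, sd = sqrt(v))
}
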