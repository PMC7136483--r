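#' Typical structural PK parameters of the tamoxifen-endoxifen model
#'
#' Constructs the typical (population) parameter vector of the joint
#' parent-metabolite model: a one-compartment tamoxifen model with lagged
#' first-order absorption and first-order elimination, linked to a
#' one-compartment endoxifen model with first-order formation and
#' elimination. All disposition parameters are apparent (scaled by the
#' unknown oral bioavailability F). Defaults are the published estimates for
#' the reference patient (CYP2D6 activity score 2, 65 years, no interacting
#' comedication); `cl30_f` and `v_endx_f` are fixed to literature values
#' from an endoxifen-only study and flagged as non-estimated.
#'
#' @param ka First-order absorption rate constant (1/h).
#' @param tlag Absorption lag time (h).
#' @param v_tam_f Apparent central volume of tamoxifen (L).
#' @param cl20_f Apparent tamoxifen elimination clearance, not via
#'   endoxifen (L/h).
#' @param cl23_f Apparent endoxifen formation clearance (L/h).
#' @param cl30_f Apparent endoxifen elimination clearance (L/h, fixed).
#' @param v_endx_f Apparent endoxifen volume (L, fixed).
#' @return An object of class `structural_parameters` (named list) with an
#'   attribute `fixed` naming the non-estimated fields.
#' @export
#' @examples
#' p <- structural_parameters()
#' metabolic_fraction(p)  # 7.87 % for the reference patient
structural_parameters <- function(ka = 1.78, tlag = 0.389, v_tam_f = 1120,
                                  cl20_f = 5.77, cl23_f = 0.493,
                                  cl30_f = 5.10, v_endx_f = 400) {
  p <- list(ka = ka, tlag = tlag, v_tam_f = v_tam_f, cl20_f = cl20_f,
            cl23_f = cl23_f, cl30_f = cl30_f, v_endx_f = v_endx_f)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("structural parameter '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  structure(p, fixed = c("cl30_f", "v_endx_f"), class = "structural_parameters")
}

#' @export
print.structural_parameters <- function(x, ...) {
  cat("Structural PK parameters (apparent, .../F):\n")
  fixed <- attr(x, "fixed")
  for (nm in names(x)) {
    cat(sprintf("  %-9s %8.4g%s\n", nm, x[[nm]],
                if (nm %in% fixed) "  [fixed]" else ""))
  }
  invisible(x)
}

# canonical six-category activity-score labels (2.5 and 3 lumped)
.as_levels <- c("0", "0.5", "1", "1.5", "2", "2.5_3")

# normalise activity-score input (numeric grid values or labels) to labels
.as_label <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    x <- ifelse(is.na(x), NA_character_, ifelse(x >= 2.5, "2.5_3",
                as.character(x)))
  }
  x <- as.character(x)
  x[x %in% c("2.5", "3")] <- "2.5_3"
  bad <- !is.na(x) & !(x %in% .as_levels)
  if (any(bad)) {
    stop("unknown activity-score category: ", paste(unique(x[bad]),
         collapse = ", "), " (expected one of ",
         paste(.as_levels, collapse = ", "), ")", call. = FALSE)
  }
  x
}

#' Patient covariate records
#'
#' Builds a covariate table (one row per patient) with the stated
#' missing-data rules applied: a missing CYP2D6 activity score is imputed to
#' 2 (the most frequent, reference category), missing age to the population
#' median of the supplied ages (64 years if all are missing), and missing
#' comedication flags to absent.
#'
#' @param activity_score CYP2D6 activity score per patient; numeric on the
#'   0-3 grid in steps of 0.5 (2.5 and 3 are lumped) or character labels
#'   `"0", "0.5", "1", "1.5", "2", "2.5_3"`. `NA` allowed.
#' @param age Age in years, in (0, 120]. `NA` allowed.
#' @param rif,ssri Logical comedication flags (rifampicin; paroxetine or
#'   fluoxetine SSRIs). `NA` allowed, recycled.
#' @param id Optional patient identifiers.
#' @return A `data.frame` of class `patient_covariates` with columns `id`,
#'   `activity_score` (factor), `age`, `rif`, `ssri`.
#' @export
patient_covariates <- function(activity_score, age, rif = FALSE, ssri = FALSE,
                               id = NULL) {
  n <- max(length(activity_score), length(age))
  as_lab <- .as_label(rep_len(activity_score, n))
  as_lab[is.na(as_lab)] <- "2"
  age <- rep_len(as.numeric(age), n)
  if (any(is.na(age))) {
    med <- stats::median(age, na.rm = TRUE)
    if (is.na(med)) med <- 64
    age[is.na(age)] <- med
  }
  if (any(age <= 0 | age > 120)) {
    stop("age must lie in (0, 120] years", call. = FALSE)
  }
  rif <- rep_len(as.logical(rif), n); rif[is.na(rif)] <- FALSE
  ssri <- rep_len(as.logical(ssri), n); ssri[is.na(ssri)] <- FALSE
  out <- data.frame(
    id = if (is.null(id)) seq_len(n) else rep_len(id, n),
    activity_score = factor(as_lab, levels = .as_levels),
    age = age, rif = rif, ssri = ssri,
    stringsAsFactors = FALSE
  )
  class(out) <- c("patient_covariates", "data.frame")
  out
}

#' Covariate effect coefficients
#'
#' Fractional-change and power-model covariate coefficients acting on the
#' structural parameters. Categorical effects enter as proportional changes
#' `(1 + theta)`; age enters CL20/F as a power model centred at the
#' 65-year-old reference, `(age/65)^theta`. Defaults are the published
#' estimates.
#'
#' @param age_exponent Power exponent of age on CL20/F.
#' @param age_reference Reference age (years).
#' @param rif_cl20,rif_cl23,rif_vtam Fractional changes under rifampicin on
#'   CL20/F, CL23/F and V_TAM/F.
#' @param ssri_cl23 Fractional change on CL23/F under paroxetine/fluoxetine.
#' @param as_cl23 Named vector of fractional changes on CL23/F per CYP2D6
#'   activity-score category; must be 0 at the reference category `"2"`.
#' @return Object of class `covariate_effects`.
#' @export
covariate_effects <- function(age_exponent = -0.886, age_reference = 65,
                              rif_cl20 = 6.51, rif_cl23 = 1.18,
                              rif_vtam = 0.581, ssri_cl23 = -0.654,
                              as_cl23 = c("0" = -0.722, "0.5" = -0.510,
                                          "1" = -0.323, "1.5" = -0.211,
                                          "2" = 0, "2.5_3" = 0.533)) {
  if (!setequal(names(as_cl23), .as_levels)) {
    stop("as_cl23 must be named with all categories: ",
         paste(.as_levels, collapse = ", "), call. = FALSE)
  }
  as_cl23 <- as_cl23[.as_levels]
  frac <- c(rif_cl20 = rif_cl20, rif_cl23 = rif_cl23, rif_vtam = rif_vtam,
            ssri_cl23 = ssri_cl23, as_cl23)
  if (any(frac <= -1)) {
    stop("fractional-change effects must exceed -1 to keep parameters positive",
         call. = FALSE)
  }
  if (as_cl23[["2"]] != 0) {
    stop("as_cl23 must be exactly 0 at the reference category '2'",
         call. = FALSE)
  }
  structure(list(age_exponent = age_exponent, age_reference = age_reference,
                 rif_cl20 = rif_cl20, rif_cl23 = rif_cl23,
                 rif_vtam = rif_vtam, ssri_cl23 = ssri_cl23,
                 as_cl23 = as_cl23),
            class = "covariate_effects")
}

#' Apply the covariate model to the typical parameters
#'
#' Computes covariate-adjusted individual structural parameters:
#' \deqn{CL20/F = CL20_{ref} (age/65)^{-0.886} (1 + 6.51\, rif)}
#' \deqn{CL23/F = CL23_{ref} (1 + \theta_{AS}) (1 - 0.654\, ssri)
#'   (1 + 1.18\, rif)}
#' \deqn{V_{TAM}/F = V_{ref} (1 + 0.581\, rif)}
#' Absorption and endoxifen disposition are covariate-free.
#'
#' @param typical A [structural_parameters()] object.
#' @param cov A [patient_covariates()] table (or anything it accepts).
#' @param eff A [covariate_effects()] object.
#' @return A `data.frame` of class `individual_parameters`, one row per
#'   patient, columns `ka, tlag, v_tam, cl20, cl23, cl30, v_endx`.
#' @export
#' @examples
#' ref <- patient_covariates(activity_score = 2, age = 65)
#' apply_covariates(structural_parameters(), ref, covariate_effects())
apply_covariates <- function(typical = structural_parameters(),
                             cov, eff = covariate_effects()) {
  if (!inherits(cov, "patient_covariates")) {
    cov <- patient_covariates(cov$activity_score, cov$age,
                              rif = if (is.null(cov$rif)) FALSE else cov$rif,
                              ssri = if (is.null(cov$ssri)) FALSE else cov$ssri,
                              id = cov$id)
  }
  if (any(cov$age <= 0)) stop("age must be positive", call. = FALSE)
  as_eff <- eff$as_cl23[as.character(cov$activity_score)]
  cl20 <- typical$cl20_f * (cov$age / eff$age_reference)^eff$age_exponent *
    (1 + eff$rif_cl20 * cov$rif)
  cl23 <- typical$cl23_f * (1 + as_eff) * (1 + eff$ssri_cl23 * cov$ssri) *
    (1 + eff$rif_cl23 * cov$rif)
  v_tam <- typical$v_tam_f * (1 + eff$rif_vtam * cov$rif)
  out <- data.frame(
    id = cov$id,
    ka = typical$ka, tlag = typical$tlag, v_tam = v_tam,
    cl20 = as.numeric(cl20), cl23 = as.numeric(cl23),
    cl30 = typical$cl30_f, v_endx = typical$v_endx_f,
    row.names = NULL
  )
  stopifnot(all(unlist(out[-1]) > 0))
  class(out) <- c("individual_parameters", "data.frame")
  out
}

#' Metabolic fraction of tamoxifen converted to endoxifen
#'
#' `FM = 100 * CL23 / (CL23 + CL20)` in percent: the fraction of apparent
#' tamoxifen clearance routed through endoxifen formation. 7.87 % for the
#' reference patient.
#'
#' @param params A [structural_parameters()] object or an
#'   `individual_parameters` data frame (vectorised over rows).
#' @return Percent value(s) in (0, 100).
#' @export
metabolic_fraction <- function(params) {
  if (inherits(params, "structural_parameters")) {
    cl20 <- params$cl20_f; cl23 <- params$cl23_f
  } else {
    cl20 <- params$cl20; cl23 <- params$cl23
  }
  stopifnot(all(cl20 > 0), all(cl23 > 0))
  100 * cl23 / (cl23 + cl20)
}
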