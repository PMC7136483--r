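#' Write / read a long-format PK dataset
#'
#' Comma-separated, header required; documented dialect with columns
#' `STUDY, ID, OCC, TIME, AMT, DVID, DV, AS, AGE, RIF, SSRI`. The reader
#' validates the header, checks field counts per line (naming the first
#' malformed line), sorts records within patient by time (with a warning if
#' reordering was needed), and round-trips [write_dataset()] output
#' exactly.
#'
#' @param records Records `data.frame` (e.g. `generate_database(...)$records`).
#' @param path File path.
#' @return `write_dataset`: the path, invisibly. `read_dataset`: the
#'   records `data.frame`.
#' @export
write_dataset <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.required_cols <- c("STUDY", "ID", "OCC", "TIME", "AMT", "DVID", "DV",
                    "AS", "AGE", "RIF", "SSRI")

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (any(is.na(nf)) || length(unique(nf)) > 1L) {
    bad <- which(is.na(nf) | nf != nf[1])[1]
    stop("malformed CSV in ", path, ": line ", bad,
         " has an inconsistent field count", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.required_cols, names(df))
  if (length(missing) > 0) {
    stop("dataset is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$AS <- as.character(df$AS)  # activity-score labels, not numbers
  ord <- order(df$ID, df$TIME, df$DVID)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning("records were not time-ordered within patient; sorted",
            call. = FALSE)
    df <- df[ord, ]
    rownames(df) <- NULL
  }
  df
}

#' Write a trial result in the comparison-table layout
#'
#' One row per subgroup (gNM incl. gUM, gIM, gPM, All) with patient count,
#' dose summary, trough median/IQR/CV and risk percent, prefixed by the
#' strategy name -- mirroring the published strategy-comparison table.
#'
#' @param result A [run_trial()] result (or a list of them).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_results <- function(result, path) {
  results <- if (inherits(result, "trial_result")) list(result) else result
  tab <- do.call(rbind, lapply(results, function(r) {
    cbind(strategy = r$strategy, seed = r$seed, r$summary)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#' @param path CSV path.
#' @return `data.frame` of per-strategy, per-subgroup summaries.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# ---- configuration ---------------------------------------------------------

.config_schema <- list(
  parameters = c("ka", "tlag", "v_tam_f", "cl20_f", "cl23_f", "cl30_f",
                 "v_endx_f"),
  covariate_effects = c("age_exponent", "age_reference", "rif_cl20",
                        "rif_cl23", "rif_vtam", "ssri_cl23", "as_cl23"),
  random_effects = c("omega2", "pi2", "phi2", "sigma2", "sigma_cov"),
  population = c("n", "phenotype_counts", "as_split_gNM", "age_mean",
                 "age_sd", "age_bounds", "p_rif", "p_ssri", "seed"),
  strategy = c("name", "standard_dose", "guided_doses", "runin_weeks",
               "tdm_days", "dose_grid", "threshold", "horizon_months", "cv"),
  top = c("parameters", "covariate_effects", "random_effects", "population",
          "strategies", "seed")
)

.check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown) > 0) {
    stop("unknown key(s) in config block '", where, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration holding the model parameter values as data
#' (so the published estimates are configuration, not code), the
#' random-effects block, the virtual-population spec and dosing-strategy
#' definitions. Every block is schema-validated: unknown keys are rejected
#' by name, numeric fields are range-checked by the respective
#' constructors, and omitted fields fall back to the package defaults (the
#' published estimates). The shipped default configuration is at
#' `system.file("extdata", "default_config.json", package = "tamipd")`.
#'
#' @param path Path to a JSON config file.
#' @param verbose Echo each block's provenance (default vs user) via
#'   [message()].
#' @return Object of class `tamipd_config`: list with `parameters`,
#'   `effects`, `random_effects`, `population`, `strategies` (named list),
#'   `seed`.
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "default_config.json",
#'                                package = "tamipd"))
#' cfg$parameters$cl20_f  # 5.77
load_config <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("config schema violation: ", path,
                         " is not valid JSON (", conditionMessage(e), ")",
                         call. = FALSE)
                  })
  if (!is.list(raw) || length(raw) == 0) {
    stop("config schema violation: ", path, " holds no configuration blocks",
         call. = FALSE)
  }
  .check_keys(raw, .config_schema$top, "<top level>")
  note <- function(block) {
    if (verbose) {
      message("config block '", block, "': ",
              if (block %in% names(raw)) "user-supplied" else
                "package default")
    }
  }
  note("parameters")
  parameters <- if (is.null(raw$parameters)) structural_parameters() else {
    .check_keys(raw$parameters, .config_schema$parameters, "parameters")
    do.call(structural_parameters, raw$parameters)
  }
  note("covariate_effects")
  effects <- if (is.null(raw$covariate_effects)) covariate_effects() else {
    b <- raw$covariate_effects
    .check_keys(b, .config_schema$covariate_effects, "covariate_effects")
    if (!is.null(b$as_cl23)) b$as_cl23 <- unlist(b$as_cl23)
    do.call(covariate_effects, b)
  }
  note("random_effects")
  random_effects <- if (is.null(raw$random_effects)) {
    random_effects_spec()
  } else {
    b <- raw$random_effects
    .check_keys(b, .config_schema$random_effects, "random_effects")
    for (k in c("omega2", "pi2", "phi2", "sigma2")) {
      if (!is.null(b[[k]])) b[[k]] <- unlist(b[[k]])
    }
    tryCatch(do.call(random_effects_spec, b),
             error = function(e) stop("config block 'random_effects': ",
                                      conditionMessage(e), call. = FALSE))
  }
  note("population")
  population <- if (is.null(raw$population)) population_spec() else {
    b <- raw$population
    .check_keys(b, .config_schema$population, "population")
    for (k in c("phenotype_counts", "as_split_gNM")) {
      if (!is.null(b[[k]])) b[[k]] <- unlist(b[[k]])
    }
    do.call(population_spec, b)
  }
  note("strategies")
  strategies <- if (is.null(raw$strategies)) {
    list(standard = strategy_config("standard"),
         cyp2d6_guided = strategy_config("cyp2d6_guided"),
         mipd = strategy_config("mipd"))
  } else {
    out <- lapply(raw$strategies, function(b) {
      .check_keys(b, .config_schema$strategy, "strategies")
      if (!is.null(b$guided_doses)) b$guided_doses <- unlist(b$guided_doses)
      do.call(strategy_config, b)
    })
    stats::setNames(out, vapply(out, `[[`, "", "name"))
  }
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  structure(list(parameters = parameters, effects = effects,
                 random_effects = random_effects, population = population,
                 strategies = strategies, seed = seed),
            class = "tamipd_config")
}
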