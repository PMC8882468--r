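#' Screen configuration
#'
#' Bundles the design parameters of a 384-well organoid viability screen:
#' an eight-point serial dilution from `top_dose_uM`, technical
#' quadruplicates within each of three biological replicates, sixteen day-0
#' seeding-control wells on a parallel plate, and a 96-hour drug exposure.
#' The noise parameters feed the synthetic-data generators only; scoring
#' functions ignore them.
#'
#' @param n_doses Number of doses in the dilution series (>= 2).
#' @param dilution_factor Fold-change between adjacent doses (> 1).
#'   Defaults to a half-log (3.162-fold) series.
#' @param top_dose_uM Highest tested concentration, in micromolar.
#' @param n_tech_rep Technical replicate wells per dose within a biological
#'   replicate.
#' @param n_bio_rep Biological replicates (independent screen runs).
#' @param exposure_h Drug exposure, hours, between dosing and endpoint read.
#' @param n_day0_wells Day-0 seeding-control wells per biological replicate.
#' @param n_vehicle_wells DMSO vehicle wells per biological replicate.
#' @param cv_tech Technical (per-well) coefficient of variation of the
#'   luminescence readout, applied as multiplicative lognormal noise.
#' @param cv_bio Standard deviation of the per-biological-replicate
#'   lognormal scale factor.
#' @param cv_day0 Per-well coefficient of variation of day-0 control wells.
#' @param rng_seed Integer seed recorded with the configuration; generators
#'   use it when no explicit seed is passed.
#'
#' @return A list of class `"screen_config"`.
#' @export
#' @examples
#' cfg <- screen_config(top_dose_uM = 10)
#' dose_series(cfg)
screen_config <- function(n_doses = 8,
                          dilution_factor = 10^0.5,
                          top_dose_uM = 10,
                          n_tech_rep = 4,
                          n_bio_rep = 3,
                          exposure_h = 96,
                          n_day0_wells = 16,
                          n_vehicle_wells = 16,
                          cv_tech = 0.05,
                          cv_bio = 0.10,
                          cv_day0 = 0.05,
                          rng_seed = 1L) {
  cfg <- list(
    n_doses = as.integer(n_doses),
    dilution_factor = dilution_factor,
    top_dose_uM = top_dose_uM,
    n_tech_rep = as.integer(n_tech_rep),
    n_bio_rep = as.integer(n_bio_rep),
    exposure_h = exposure_h,
    n_day0_wells = as.integer(n_day0_wells),
    n_vehicle_wells = as.integer(n_vehicle_wells),
    cv_tech = cv_tech,
    cv_bio = cv_bio,
    cv_day0 = cv_day0,
    rng_seed = as.integer(rng_seed)
  )
  validate_screen_config(cfg)
  structure(cfg, class = "screen_config")
}

validate_screen_config <- function(cfg) {
  if (cfg$n_doses < 2) abort("`n_doses` must be >= 2.")
  if (cfg$dilution_factor <= 1) abort("`dilution_factor` must be > 1.")
  if (cfg$top_dose_uM <= 0) abort("`top_dose_uM` must be positive.")
  counts <- c(cfg$n_tech_rep, cfg$n_bio_rep, cfg$n_day0_wells,
              cfg$n_vehicle_wells)
  if (any(counts < 1)) abort("replicate and control-well counts must be >= 1.")
  if (cfg$exposure_h <= 0) abort("`exposure_h` must be positive.")
  if (any(c(cfg$cv_tech, cfg$cv_bio, cfg$cv_day0) < 0)) {
    abort("noise coefficients must be nonnegative.")
  }
  invisible(cfg)
}

#' Dose series implied by a screen configuration
#'
#' @param config A [screen_config()].
#' @return Ascending numeric vector of `n_doses` concentrations (uM) ending
#'   at `top_dose_uM`.
#' @export
dose_series <- function(config) {
  config$top_dose_uM / config$dilution_factor^((config$n_doses - 1):0)
}

#' Read a screen configuration from JSON or YAML
#'
#' Accepts a file whose top-level keys mirror the [screen_config()]
#' arguments; unknown keys are rejected, missing keys take the defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `screen_config` object.
#' @export
read_screen_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    abort("config file must be .json, .yaml or .yml")
  }
  known <- names(formals(screen_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  }
  do.call(screen_config, raw)
}

#' Write a screen configuration
#'
#' @param config A `screen_config`.
#' @param path Destination `.json`, `.yaml` or `.yml` path.
#' @return `path`, invisibly.
#' @export
write_screen_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    abort("config file must be .json, .yaml or .yml")
  }
  invisible(path)
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  cat(sprintf("  %d-point dilution (x%.3g) from %g uM; %d tech x %d bio reps\n",
              x$n_doses, x$dilution_factor, x$top_dose_uM,
              x$n_tech_rep, x$n_bio_rep))
  cat(sprintf("  exposure %g h; %d day-0 wells; %d vehicle wells\n",
              x$exposure_h, x$n_day0_wells, x$n_vehicle_wells))
  cat(sprintf("  noise cv: tech %.3g, bio %.3g, day0 %.3g; seed %d\n",
              x$cv_tech, x$cv_bio, x$cv_day0, x$rng_seed))
  invisible(x)
}
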