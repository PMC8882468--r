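#' Normalize screen records to day-0 seeding controls
#'
#' For each model line and biological replicate, the day-0 baseline `T0` is
#' the mean of that replicate's day-0 control wells (seeded on a parallel
#' plate and read at dosing time) and the untreated endpoint `C` is the
#' mean of its DMSO vehicle wells. Every treated well is then expressed as
#' a fold-change over `T0` and converted to the GR, relative-growth and
#' endpoint-viability scales. A biological replicate that lacks day-0
#' wells falls back to the model's pooled day-0 mean with a warning.
#'
#' @param records Validated plate records (see [read_screen()]).
#' @return A tibble with one row per treated well: `model_id, drug_id,
#'   dose_uM, bio_rep, tech_rep, luminescence, t0, c0, fold_change`
#'   (= `T/T0`), `vehicle_fold` (= `C/T0`), `gr` ([gr_value()]), `rv`
#'   ([rv_value()]) and `tc` (endpoint viability `T/C`).
#' @export
normalize_screen <- function(records) {
  records <- validate_plate_records(records)
  if (!any(records$role == "day0")) abort("no day-0 control wells present")
  if (!any(records$role == "vehicle")) abort("no vehicle wells present")

  day0 <- records |>
    filter(.data$role == "day0") |>
    group_by(.data$model_id, .data$bio_rep) |>
    summarise(t0 = mean(.data$luminescence), .groups = "drop")
  day0_pooled <- records |>
    filter(.data$role == "day0") |>
    group_by(.data$model_id) |>
    summarise(t0_pooled = mean(.data$luminescence), .groups = "drop")
  vehicle <- records |>
    filter(.data$role == "vehicle") |>
    group_by(.data$model_id, .data$bio_rep) |>
    summarise(c0 = mean(.data$luminescence), .groups = "drop")

  treated <- records |>
    filter(.data$role == "treated") |>
    left_join(day0, by = c("model_id", "bio_rep")) |>
    left_join(day0_pooled, by = "model_id") |>
    left_join(vehicle, by = c("model_id", "bio_rep"))

  if (anyNA(treated$t0)) {
    missing_reps <- treated |> filter(is.na(.data$t0)) |>
      distinct(.data$model_id, .data$bio_rep)
    warn(paste0("no day-0 wells for ",
                paste0(missing_reps$model_id, "/bio_rep ",
                       missing_reps$bio_rep, collapse = ", "),
                "; using the model's pooled day-0 mean"))
    treated <- treated |>
      mutate(t0 = ifelse(is.na(.data$t0), .data$t0_pooled, .data$t0))
  }
  if (anyNA(treated$t0)) abort("day-0 baseline unavailable for some wells")
  if (anyNA(treated$c0)) abort("missing vehicle wells for some replicates")
  if (any(treated$t0 <= 0)) abort("day-0 baseline T0 must be positive")
  if (any(treated$c0 <= treated$t0)) {
    bad <- treated |> filter(.data$c0 <= .data$t0) |>
      distinct(.data$model_id, .data$bio_rep)
    abort(paste0("control did not grow (C <= T0) for ",
                 paste0(bad$model_id, "/bio_rep ", bad$bio_rep,
                        collapse = ", ")))
  }

  treated |>
    mutate(fold_change = .data$luminescence / .data$t0,
           vehicle_fold = .data$c0 / .data$t0,
           gr = gr_value(.data$luminescence, .data$t0, .data$c0),
           rv = rv_value(.data$luminescence, .data$t0, .data$c0),
           tc = .data$luminescence / .data$c0) |>
    select("model_id", "drug_id", "dose_uM", "bio_rep", "tech_rep",
           "luminescence", "t0", "c0", "fold_change", "vehicle_fold",
           "gr", "rv", "tc") |>
    arrange(.data$model_id, .data$drug_id, .data$dose_uM, .data$bio_rep,
            .data$tech_rep)
}

score_one_profile <- function(profile, extrapolation_factor, flat_alpha) {
  doses <- profile$dose_uM
  fit_gr <- fit_dose_response(doses, profile$gr, scale = "GR",
                              flat_alpha = flat_alpha)
  fit_rv <- fit_dose_response(doses, profile$rv, scale = "RV",
                              flat_alpha = flat_alpha)
  fit_tc <- fit_dose_response(doses, profile$tc, scale = "TC",
                              flat_alpha = flat_alpha)
  sig_gr <- fit_gr$fit_type == "sigmoid"
  tibble(
    GR50 = gr50(fit_gr, extrapolation_factor = extrapolation_factor),
    GEC50 = if (sig_gr) fit_gr$midpoint else NA_real_,
    GR_inf = if (sig_gr) fit_gr$plateau else NA_real_,
    hill = if (sig_gr) fit_gr$hill else NA_real_,
    GR_aoc = gr_aoc(fit_gr, doses),
    cytostatic_uM = cytostatic_dose(fit_gr,
                                    extrapolation_factor = extrapolation_factor),
    EC50 = if (fit_rv$fit_type == "sigmoid") fit_rv$midpoint else NA_real_,
    IC50 = solve_dose(fit_tc, 0.5,
                      extrapolation_factor = extrapolation_factor),
    GI50 = solve_dose(fit_rv, 50,
                      extrapolation_factor = extrapolation_factor),
    fit_type_gr = fit_gr$fit_type,
    fit_type_rv = fit_rv$fit_type,
    n_points = as.integer(length(doses))
  )
}

#' Score a screen: per-(model, drug) dose-response metrics
#'
#' Runs the full scoring pipeline: day-0 normalization
#' ([normalize_screen()]), pooled sigmoidal fits on the GR,
#' relative-growth and endpoint-viability scales, and extraction of all
#' response metrics. Threshold metrics (GR50, cytostatic dose, GI50,
#' IC50) are `NA` whenever the fitted curve never crosses the threshold
#' inside the reporting window or the fit is flat; `GR_aoc` is always
#' defined.
#'
#' @param records Validated plate records, or a list with `plate_map` and
#'   `readings` tibbles (as returned by [simulate_screen()]).
#' @param per_bio_rep If `TRUE`, fit each biological replicate separately
#'   (4 points per dose) and add a `bio_rep` column; used for
#'   reproducibility analyses. Default pools all 12 replicates per dose
#'   into one fit.
#' @param extrapolation_factor Reporting window for threshold metrics
#'   (see [solve_dose()]).
#' @param flat_alpha Sigmoid-vs-flat F-test level (see
#'   [fit_dose_response()]).
#' @return A metrics tibble with columns `model_id, drug_id, GR50, GEC50,
#'   GR_inf, hill, GR_aoc, cytostatic_uM, EC50, IC50, GI50, fit_type_gr,
#'   fit_type_rv, n_points` (plus `bio_rep` when `per_bio_rep = TRUE`).
#' @export
#' @examples
#' lines <- tibble::tibble(model_id = "L1", doubling_days = 4,
#'                         subtype = "TNBC")
#' truth <- tibble::tibble(model_id = "L1", drug_id = "d1",
#'                         gr_inf = -0.8, gec50_uM = 0.1, hill = 1.5)
#' sim <- simulate_screen(lines, truth, screen_config(), seed = 7)
#' score_screen(sim)
score_screen <- function(records, per_bio_rep = FALSE,
                         extrapolation_factor = 10, flat_alpha = 0.05) {
  if (is.list(records) && !is.data.frame(records) &&
      all(c("plate_map", "readings") %in% names(records))) {
    records <- inner_join(records$plate_map, records$readings,
                          by = c("plate_id", "well"))
  }
  profiles <- normalize_screen(records)
  keys <- if (per_bio_rep) c("model_id", "drug_id", "bio_rep") else
    c("model_id", "drug_id")
  profiles |>
    group_by(across(all_of(keys))) |>
    group_modify(~ score_one_profile(.x, extrapolation_factor, flat_alpha)) |>
    ungroup()
}
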