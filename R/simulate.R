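#' Random ground-truth drug responses for a panel of lines
#'
#' Draws a per-(line, drug) dose-response truth for the synthetic screen.
#' A fraction of pairs is inert (the drug has no effect; GR stays at 1).
#' Responsive pairs get a Hill truth with asymptote `gr_inf` spanning
#' strong cytotoxicity to weak partial response (uniform on
#' `[-1, 0.5]`), a midpoint drawn log-uniformly from the central part of
#' the tested dose range (screens are designed so that potency falls
#' inside the dilution series), and a Hill slope uniform on `[0.5, 3]`.
#'
#' @param lines Tibble `model_id, doubling_days, subtype`.
#' @param drugs Character vector of drug ids, or tibble with a `drug_id`
#'   column.
#' @param config A [screen_config()] (supplies the dose range).
#' @param seed Integer seed.
#' @param inert_fraction Fraction of (line, drug) pairs with no effect.
#' @return Truth tibble `model_id, drug_id, inert, gr_inf, gec50_uM,
#'   hill` (parameters `NA` for inert pairs).
#' @export
simulate_line_truths <- function(lines, drugs, config = screen_config(),
                                 seed = config$rng_seed,
                                 inert_fraction = 0.3) {
  if (is.data.frame(drugs)) drugs <- drugs$drug_id
  set.seed(seed)
  doses <- dose_series(config)
  lo <- log10(min(doses) * 3)
  hi <- log10(max(doses) / 3)
  truth <- tidyr::expand_grid(model_id = lines$model_id, drug_id = drugs)
  n <- nrow(truth)
  truth |>
    mutate(inert = runif(n) < inert_fraction,
           gr_inf = ifelse(.data$inert, NA_real_, runif(n, -1, 0.5)),
           gec50_uM = ifelse(.data$inert, NA_real_, 10^runif(n, lo, hi)),
           hill = ifelse(.data$inert, NA_real_, runif(n, 0.5, 3)))
}

true_gr <- function(dose, gr_inf, gec50, hill) {
  gr_inf + (1 - gr_inf) / (1 + (dose / gec50)^hill)
}

well_label <- function(i) {
  sprintf("%s%02d", LETTERS[(i - 1) %/% 24 + 1], (i - 1) %% 24 + 1)
}

#' Simulate a full organoid viability screen with known ground truth
#'
#' Emulates the screen design end to end: for every line, biological
#' replicate and drug, an `n_doses`-point serial dilution in technical
#' replicate wells, plus DMSO vehicle wells on the screening plates and
#' day-0 seeding-control wells on a parallel plate per biological
#' replicate. Growth over the exposure window is exponential: the vehicle
#' fold-change is `C/T0 = 2^(exposure_h / (24 * doubling_days))` and a
#' treated well's expected endpoint is
#' `T = T0 * (C/T0)^r(c)` with `r(c) = log2(GR*(c) + 1)`, the exact
#' inverse of the GR transform, so in the noiseless limit the scoring
#' pipeline recovers the truth exactly. Noise is multiplicative
#' lognormal per well (`cv_tech`, `cv_day0`) plus a lognormal scale
#' factor shared by all wells of a biological replicate (`cv_bio`).
#' Output is bit-reproducible given `(lines, truth, config, seed)`.
#'
#' @param lines Tibble `model_id, doubling_days, subtype`.
#' @param truth Truth tibble from [simulate_line_truths()] (or built by
#'   hand with the same columns; an `inert` column is optional).
#' @param config A [screen_config()].
#' @param seed Integer seed (defaults to the config's `rng_seed`).
#' @return List with tibbles `plate_map`, `readings` (the schemas read by
#'   [read_screen()]), `truth` (with the per-line expected vehicle
#'   fold-change attached) and `lines`, plus `config`.
#' @export
simulate_screen <- function(lines, truth, config = screen_config(),
                            seed = config$rng_seed) {
  validate_screen_config(config)
  if (any(lines$doubling_days <= 0)) abort("doubling_days must be positive")
  if (!"inert" %in% names(truth)) truth$inert <- FALSE
  bad <- truth |> filter(!.data$inert) |>
    filter(.data$gr_inf < -1 | .data$gr_inf > 1 | .data$gec50_uM <= 0 |
             .data$hill <= 0)
  if (nrow(bad)) {
    abort("responsive truths need gr_inf in [-1, 1], gec50_uM > 0, hill > 0")
  }
  set.seed(seed)
  doses <- dose_series(config)
  t0_base <- 1e6
  wells_per_plate <- 384L

  lines <- lines |>
    mutate(vehicle_fold = 2^(config$exposure_h / (24 * .data$doubling_days)))

  bio <- tidyr::expand_grid(model_id = lines$model_id,
                            bio_rep = seq_len(config$n_bio_rep)) |>
    arrange(.data$model_id, .data$bio_rep) |>
    mutate(bio_scale = rlnorm(dplyr::n(), 0, config$cv_bio))

  day0 <- bio |>
    tidyr::expand_grid(well_idx = seq_len(config$n_day0_wells)) |>
    mutate(plate_id = sprintf("%s-B%d-D0", .data$model_id, .data$bio_rep),
           well = well_label(.data$well_idx),
           model_id = .data$model_id, drug_id = "", dose_uM = 0,
           role = "day0", tech_rep = .data$well_idx,
           luminescence = t0_base * .data$bio_scale *
             rlnorm(dplyr::n(), 0, config$cv_day0))

  vehicle <- bio |>
    left_join(select(lines, "model_id", "vehicle_fold"), by = "model_id") |>
    tidyr::expand_grid(well_idx = seq_len(config$n_vehicle_wells)) |>
    mutate(plate_id = sprintf("%s-B%d-P1", .data$model_id, .data$bio_rep),
           well = well_label(.data$well_idx),
           drug_id = "", dose_uM = 0, role = "vehicle",
           tech_rep = .data$well_idx,
           luminescence = t0_base * .data$vehicle_fold * .data$bio_scale *
             rlnorm(dplyr::n(), 0, config$cv_tech))

  treated <- bio |>
    left_join(select(lines, "model_id", "vehicle_fold"), by = "model_id") |>
    tidyr::expand_grid(drug_id = unique(truth$drug_id),
                       dose_uM = doses,
                       tech_rep = seq_len(config$n_tech_rep)) |>
    left_join(truth, by = c("model_id", "drug_id")) |>
    arrange(.data$model_id, .data$bio_rep, .data$drug_id, .data$dose_uM,
            .data$tech_rep) |>
    mutate(gr_true = ifelse(.data$inert, 1,
                            true_gr(.data$dose_uM, .data$gr_inf,
                                    .data$gec50_uM, .data$hill)))
  if (any(treated$gr_true <= -1)) {
    warn("true GR at or below -1 clipped to -1 + 1e-9")
    treated$gr_true <- pmax(treated$gr_true, -1 + 1e-9)
  }
  treated <- treated |>
    mutate(growth_exponent = log2(.data$gr_true + 1),
           luminescence = t0_base *
             .data$vehicle_fold^.data$growth_exponent * .data$bio_scale *
             rlnorm(dplyr::n(), 0, config$cv_tech)) |>
    group_by(.data$model_id, .data$bio_rep) |>
    mutate(pos = config$n_vehicle_wells + row_number(),
           plate_no = (.data$pos - 1L) %/% wells_per_plate + 1L,
           well_idx = (.data$pos - 1L) %% wells_per_plate + 1L,
           plate_id = sprintf("%s-B%d-P%d", .data$model_id, .data$bio_rep,
                              .data$plate_no),
           well = well_label(.data$well_idx),
           role = "treated") |>
    ungroup()

  cols <- c("plate_id", "well", "model_id", "drug_id", "dose_uM", "role",
            "bio_rep", "tech_rep")
  plate_map <- bind_rows(day0[c(cols)], vehicle[cols], treated[cols])
  readings <- bind_rows(day0[c("plate_id", "well", "luminescence")],
                        vehicle[c("plate_id", "well", "luminescence")],
                        treated[c("plate_id", "well", "luminescence")])
  truth_out <- truth |>
    left_join(select(lines, "model_id", "doubling_days", "vehicle_fold"),
              by = "model_id")
  list(plate_map = plate_map, readings = readings, truth = truth_out,
       lines = lines, config = config)
}

viability_truth_params <- function(truth) {
  list(flat = FALSE, plateau = truth$e_inf, midpoint = truth$ec50_uM,
       hill = truth$hill, top = 100)
}

#' Simulate a two-drug combination dose matrix
#'
#' Builds the observed response surface of a two-drug grid from known
#' single-agent viability truths: each cell's expected response is the
#' Loewe-additive value computed from the true curves, minus a synergy
#' `bonus` (so `bonus = 0` gives an exactly additive grid and a positive
#' bonus simulates synergistic extra kill). Replicates get multiplicative
#' lognormal technical noise and a per-biological-replicate scale factor.
#'
#' @param truth_a,truth_b Lists `list(ec50_uM =, hill =, e_inf =)`
#'   describing each single agent on the percent-viability scale (top
#'   fixed at 100).
#' @param config A [screen_config()] (replicate counts and noise).
#' @param seed Integer seed.
#' @param doses_a,doses_b Dose vectors including 0; default `0` plus the
#'   config's dilution series.
#' @param bonus Synergy offset: a scalar, or a function of
#'   `(dose_a, dose_b)` returning the offset in percent viability,
#'   applied only where both doses are nonzero.
#' @return List: `grid` (tibble `dose_a_uM, dose_b_uM, bio_rep, tech_rep,
#'   response_pct`) and `truth` (per-cell tibble with the additive
#'   expectation and applied bonus).
#' @export
simulate_synergy_grid <- function(truth_a, truth_b,
                                  config = screen_config(),
                                  seed = config$rng_seed,
                                  doses_a = c(0, dose_series(config)),
                                  doses_b = c(0, dose_series(config)),
                                  bonus = 0) {
  set.seed(seed)
  pa <- viability_truth_params(truth_a)
  pb <- viability_truth_params(truth_b)
  bonus_fun <- if (is.function(bonus)) bonus else function(da, db) bonus
  cells <- tidyr::expand_grid(dose_a_uM = sort(doses_a),
                              dose_b_uM = sort(doses_b)) |>
    rowwise() |>
    mutate(expected_additive = loewe_solve_curves(pa, pb, .data$dose_a_uM,
                                                  .data$dose_b_uM)$expected,
           bonus = ifelse(.data$dose_a_uM > 0 & .data$dose_b_uM > 0,
                          bonus_fun(.data$dose_a_uM, .data$dose_b_uM), 0),
           true_response = .data$expected_additive - .data$bonus) |>
    ungroup()
  reps <- tidyr::expand_grid(bio_rep = seq_len(config$n_bio_rep),
                             tech_rep = seq_len(config$n_tech_rep))
  bio_scale <- rlnorm(config$n_bio_rep, 0, config$cv_bio)
  grid <- tidyr::expand_grid(cells, reps) |>
    arrange(.data$dose_a_uM, .data$dose_b_uM, .data$bio_rep,
            .data$tech_rep) |>
    mutate(raw = .data$true_response * bio_scale[.data$bio_rep] *
             rlnorm(dplyr::n(), 0, config$cv_tech)) |>
    # percent-of-control: renormalize each biological replicate to its own
    # untreated (0, 0) wells, as plate-level combination data are scaled in
    # practice; the replicate-level factor cancels here by construction
    group_by(.data$bio_rep) |>
    mutate(response_pct = .data$raw /
             mean(.data$raw[.data$dose_a_uM == 0 & .data$dose_b_uM == 0]) *
             100) |>
    ungroup() |>
    select("dose_a_uM", "dose_b_uM", "bio_rep", "tech_rep", "response_pct")
  list(grid = grid, truth = cells)
}

#' Simulate in vivo tumor-volume trajectories coupled to screen truth
#'
#' Exponential tumor growth per mouse with multiplicative measurement
#' noise, sampled on a twice-weekly schedule. Each line gets a vehicle
#' arm growing at `vehicle_rate` per day and a treated arm growing at
#' `vehicle_rate * multiplier`, where the per-line `multiplier` maps the
#' line's latent drug sensitivity (shared with the screen truth) onto an
#' in vivo effect: 1 = no effect, 0 = complete stasis, negative =
#' regression. Recurrence times after treatment cessation are exponential
#' with a hazard proportional to each treated mouse's residual relative
#' volume, censored at `follow_up` days.
#'
#' @param lines Tibble `model_id` (other columns ignored).
#' @param effects Tibble `model_id, multiplier`.
#' @param n_mice Mice per arm.
#' @param seed Integer seed.
#' @param days Measurement days (must start at 0).
#' @param v0_mm3 Implant volume at treatment start.
#' @param vehicle_rate Vehicle-arm growth rate, per day.
#' @param noise_cv Multiplicative measurement noise (lognormal sd).
#' @param hazard0 Baseline recurrence hazard per day (scaled by residual
#'   relative volume).
#' @param follow_up Censoring time for recurrence, days.
#' @return List: `volumes` (`mouse_id, model_id, arm, day, volume_mm3`),
#'   `recurrence` (`mouse_id, model_id, arm, day, event`), `truth`
#'   (per-line rates).
#' @export
simulate_invivo <- function(lines, effects, n_mice = 5, seed = 1,
                            days = c(0, 3, 7, 10, 14, 17, 21),
                            v0_mm3 = 150, vehicle_rate = 0.08,
                            noise_cv = 0.10, hazard0 = 0.02,
                            follow_up = 120) {
  stopifnot(days[1] == 0, n_mice >= 1)
  set.seed(seed)
  arms <- tidyr::expand_grid(model_id = lines$model_id,
                             arm = c("vehicle", "treated")) |>
    left_join(effects, by = "model_id") |>
    mutate(rate = ifelse(.data$arm == "vehicle", vehicle_rate,
                         vehicle_rate * .data$multiplier))
  mice <- tidyr::expand_grid(arms, mouse = seq_len(n_mice)) |>
    mutate(mouse_id = sprintf("%s-%s-m%d", .data$model_id,
                              .data$arm, .data$mouse))
  volumes <- tidyr::expand_grid(mice, day = days) |>
    arrange(.data$mouse_id, .data$day) |>
    mutate(volume_mm3 = v0_mm3 * exp(.data$rate * .data$day) *
             rlnorm(dplyr::n(), 0, noise_cv)) |>
    select("mouse_id", "model_id", "arm", "day", "volume_mm3")
  t_end <- max(days)
  rec <- mice |>
    filter(.data$arm == "treated") |>
    mutate(residual = exp(.data$rate * t_end),
           t_recur = rexp(dplyr::n(), rate = hazard0 * .data$residual),
           event = .data$t_recur <= follow_up,
           day = pmin(.data$t_recur, follow_up)) |>
    select("mouse_id", "model_id", "arm", "day", "event")
  list(volumes = volumes, recurrence = rec,
       truth = arms |> select("model_id", "arm", "rate"))
}

#' Simulate recurrence times under per-arm exponential hazards
#'
#' @param arms Tibble `arm, n, hazard_per_day`.
#' @param follow_up Censoring time (days).
#' @param seed Integer seed.
#' @return Tibble `mouse_id, arm, day, event` suitable for
#'   [logrank_recurrence()].
#' @export
simulate_recurrence <- function(arms, follow_up = 120, seed = 1) {
  set.seed(seed)
  purrr::pmap_dfr(arms, function(arm, n, hazard_per_day) {
    t <- rexp(n, hazard_per_day)
    tibble(mouse_id = sprintf("%s-m%d", arm, seq_len(n)), arm = arm,
           day = pmin(t, follow_up), event = t <= follow_up)
  })
}

#' Simulate clinical therapy durations
#'
#' Draws progression-free survival (PFS) from an exponential distribution
#' with the stated per-therapy median; the time to next systemic therapy
#' (TTNT) adds an exponential gap. `deterministic = TRUE` returns the
#' medians themselves (and is exact: `PFS = median_pfs_days`).
#'
#' @param courses Tibble `therapy, median_pfs_days, median_gap_days`.
#' @param n Draws per therapy.
#' @param seed Integer seed.
#' @param deterministic If `TRUE`, no randomness: PFS equals the median
#'   and the gap its median.
#' @return Tibble `therapy, draw, pfs_days, ttnt_days`.
#' @export
simulate_clinical <- function(courses, n = 1, seed = 1,
                              deterministic = FALSE) {
  if (any(courses$median_pfs_days <= 0)) {
    abort("median_pfs_days must be positive")
  }
  if (any(courses$median_gap_days < 0)) {
    abort("median_gap_days must be nonnegative")
  }
  set.seed(seed)
  purrr::pmap_dfr(courses, function(therapy, median_pfs_days,
                                    median_gap_days) {
    if (deterministic) {
      pfs <- rep(median_pfs_days, n)
      gap <- rep(median_gap_days, n)
    } else {
      pfs <- rexp(n, log(2) / median_pfs_days)
      gap <- if (median_gap_days > 0) {
        rexp(n, log(2) / median_gap_days)
      } else {
        rep(0, n)
      }
    }
    tibble(therapy = therapy, draw = seq_len(n), pfs_days = pfs,
           ttnt_days = pfs + gap)
  })
}
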