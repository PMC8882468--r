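#' Read and validate a plate map joined to plate-reader readings
#'
#' The plate map annotates each well of a screen (model line, drug, dose,
#' role, replicate indices); the readings file carries the raw endpoint
#' luminescence. `read_screen()` joins the two on `(plate_id, well)` and
#' validates the combined records.
#'
#' Expected columns:
#' * `plate_map.csv`: `plate_id, well, model_id, drug_id, dose_uM, role,
#'   bio_rep, tech_rep`. An optional `dose_unit` column (`uM`, `nM` or `mM`)
#'   is converted to micromolar on read. `role` is one of `treated`,
#'   `vehicle`, `day0`; control rows must have an empty `drug_id` and dose 0,
#'   treated rows a nonempty `drug_id` and dose > 0.
#' * `readings.csv`: `plate_id, well, luminescence` (nonnegative).
#'
#' Well labels are case-insensitive and normalized to the row-letter plus
#' two-digit-column form (`"a1"` becomes `"A01"`).
#'
#' @param plate_map_path,readings_path CSV paths.
#' @return A tibble of validated plate records, one row per well, with
#'   columns `plate_id, well, model_id, drug_id, dose_uM, role, bio_rep,
#'   tech_rep, luminescence`.
#' @export
read_screen <- function(plate_map_path, readings_path) {
  map <- read_plate_map(plate_map_path)
  readings <- read_readings(readings_path)
  dup <- readings |> count(.data$plate_id, .data$well) |> filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("duplicate (plate, well) in readings: ",
                 dup$plate_id[1], "/", dup$well[1]))
  }
  unmatched <- anti_join(readings, map, by = c("plate_id", "well"))
  if (nrow(unmatched)) {
    abort(paste0("unmatched well in readings: ", unmatched$plate_id[1],
                 "/", unmatched$well[1], " not present in plate map"))
  }
  records <- inner_join(map, readings, by = c("plate_id", "well"))
  missing_read <- anti_join(map, readings, by = c("plate_id", "well"))
  if (nrow(missing_read)) {
    abort(paste0("plate-map well without a reading: ",
                 missing_read$plate_id[1], "/", missing_read$well[1]))
  }
  validate_plate_records(records)
}

#' @rdname read_screen
#' @export
read_plate_map <- function(plate_map_path) {
  if (!file.exists(plate_map_path)) {
    abort(paste0("plate map not found: ", plate_map_path))
  }
  map <- readr::read_csv(plate_map_path, show_col_types = FALSE,
                         progress = FALSE)
  need <- c("plate_id", "well", "model_id", "drug_id", "dose_uM", "role",
            "bio_rep", "tech_rep")
  have <- names(map)
  if ("dose_unit" %in% have && !("dose_uM" %in% have) && "dose" %in% have) {
    map <- map |>
      mutate(dose_uM = .data$dose * dose_unit_factor(.data$dose_unit)) |>
      select(-"dose", -"dose_unit")
  } else if (all(c("dose_uM", "dose_unit") %in% have)) {
    map <- map |>
      mutate(dose_uM = .data$dose_uM * dose_unit_factor(.data$dose_unit)) |>
      select(-"dose_unit")
  }
  miss <- setdiff(need, names(map))
  if (length(miss)) {
    abort(paste0("plate map is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  map |>
    mutate(well = normalize_well(.data$well),
           drug_id = ifelse(is.na(.data$drug_id), "", .data$drug_id),
           role = tolower(.data$role)) |>
    select(all_of(need))
}

#' @rdname read_screen
#' @export
read_readings <- function(readings_path) {
  if (!file.exists(readings_path)) {
    abort(paste0("readings file not found: ", readings_path))
  }
  readings <- readr::read_csv(readings_path, show_col_types = FALSE,
                              progress = FALSE)
  need <- c("plate_id", "well", "luminescence")
  miss <- setdiff(need, names(readings))
  if (length(miss)) {
    abort(paste0("readings file is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  readings |> mutate(well = normalize_well(.data$well)) |> select(all_of(need))
}

dose_unit_factor <- function(unit) {
  u <- tolower(unit)
  fac <- c(um = 1, nm = 1e-3, mm = 1e3)
  out <- unname(fac[u])
  if (anyNA(out)) {
    abort(paste0("unsupported dose unit: ",
                 paste(unique(unit[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Normalize well labels to row-letter + two-digit column
#'
#' @param well Character vector like `"a1"`, `"A01"`, `"P24"`.
#' @return Normalized labels (`"A01"`).
#' @export
normalize_well <- function(well) {
  m <- regmatches(well, regexec("^([A-Za-z]+)0*([0-9]+)$", well))
  bad <- lengths(m) != 3
  if (any(bad)) {
    abort(paste0("malformed well label: ", well[bad][1]))
  }
  vapply(m, function(p) sprintf("%s%02d", toupper(p[2]), as.integer(p[3])),
         character(1))
}

#' Validate plate records
#'
#' Enforces the record invariants: unique `(plate_id, well)`, nonnegative
#' luminescence, control wells (day-0 and vehicle) with no drug and dose 0,
#' treated wells with a drug and dose > 0, positive replicate indices.
#'
#' @param records Tibble of plate records as returned by [read_screen()].
#' @return The validated records, invisibly usable in pipelines.
#' @export
validate_plate_records <- function(records) {
  records <- as_tibble(records)
  dup <- records |> count(.data$plate_id, .data$well) |> filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("duplicate (plate, well): ", dup$plate_id[1], "/",
                 dup$well[1]))
  }
  if (any(!records$role %in% c("treated", "vehicle", "day0"))) {
    abort("role must be one of treated/vehicle/day0")
  }
  if (any(is.na(records$luminescence) | records$luminescence < 0)) {
    abort("luminescence must be nonnegative and present for every well")
  }
  ctrl <- records |> filter(.data$role != "treated")
  if (any(ctrl$dose_uM != 0) || any(nzchar(ctrl$drug_id))) {
    abort("vehicle/day0 records must have empty drug_id and dose 0")
  }
  trt <- records |> filter(.data$role == "treated")
  if (any(trt$dose_uM <= 0) || any(!nzchar(trt$drug_id))) {
    abort("treated records must have dose > 0 and a nonempty drug_id")
  }
  if (any(records$bio_rep < 1) || any(records$tech_rep < 1)) {
    abort("bio_rep and tech_rep must be positive integers")
  }
  records
}

metrics_columns <- c("model_id", "drug_id", "GR50", "GEC50", "GR_inf",
                     "hill", "GR_aoc", "cytostatic_uM", "EC50", "IC50",
                     "GI50", "fit_type_gr", "fit_type_rv", "n_points")

#' Write and read the per-(model, drug) metrics table
#'
#' Metrics tables use the literal string `NA` as the missing-value sentinel
#' so that undefined metrics (for example a GR50 on a curve that never
#' reaches 0.5) are never conflated with 0. `read_metrics(write_metrics(x))`
#' round-trips the table exactly, including the NA pattern.
#'
#' @param metrics Tibble with columns `model_id, drug_id, GR50, GEC50,
#'   GR_inf, hill, GR_aoc, cytostatic_uM, EC50, IC50, GI50, fit_type_gr,
#'   fit_type_rv, n_points`.
#' @param path CSV path.
#' @return `write_metrics()` returns `path` invisibly; `read_metrics()`
#'   returns the metrics tibble.
#' @export
write_metrics <- function(metrics, path) {
  miss <- setdiff(metrics_columns, names(metrics))
  if (length(miss)) {
    abort(paste0("metrics table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  dup <- metrics |> count(.data$model_id, .data$drug_id) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("metrics table has duplicate (model, drug): ",
                 dup$model_id[1], "/", dup$drug_id[1]))
  }
  readr::write_csv(metrics[metrics_columns], path, na = "NA",
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) abort(paste0("metrics file not found: ", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    model_id = readr::col_character(),
                    drug_id = readr::col_character(),
                    fit_type_gr = readr::col_character(),
                    fit_type_rv = readr::col_character(),
                    n_points = readr::col_integer(),
                    .default = readr::col_double()
                  ))
}

#' Write a simulated screen to disk
#'
#' Writes `plate_map.csv`, `readings.csv` and `truth.csv` (plus
#' `lines.csv`) in the schemas accepted by [read_screen()].
#'
#' @param sim Result of [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(sim$plate_map, file.path(dir, "plate_map.csv"),
                   na = "NA", progress = FALSE)
  readr::write_csv(sim$readings, file.path(dir, "readings.csv"),
                   na = "NA", progress = FALSE)
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), na = "NA",
                   progress = FALSE)
  readr::write_csv(sim$lines, file.path(dir, "lines.csv"), na = "NA",
                   progress = FALSE)
  invisible(dir)
}
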