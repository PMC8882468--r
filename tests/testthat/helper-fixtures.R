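# Small in-code fixtures shared across tests.

two_line_panel <- function(dts = c(3, 8)) {
  tibble::tibble(model_id = paste0("L", seq_along(dts)),
                 doubling_days = dts,
                 subtype = rep(c("TNBC", "HR+"), length.out = length(dts)))
}

# one clearly cytotoxic drug and one inert drug for every line
basic_truth <- function(lines, gr_inf = -0.8, gec50 = 0.1, hill = 1.5) {
  dplyr::bind_rows(
    tibble::tibble(model_id = lines$model_id, drug_id = "cytotox",
                   inert = FALSE, gr_inf = gr_inf, gec50_uM = gec50,
                   hill = hill),
    tibble::tibble(model_id = lines$model_id, drug_id = "inert",
                   inert = TRUE, gr_inf = NA_real_, gec50_uM = NA_real_,
                   hill = NA_real_)
  )
}

quiet_config <- function(...) {
  screen_config(cv_tech = 0, cv_bio = 0, cv_day0 = 0, ...)
}

# write a simulated screen's map/readings to a temp dir, return paths
sim_to_csv <- function(sim) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  readr::write_csv(sim$plate_map, file.path(dir, "plate_map.csv"))
  readr::write_csv(sim$readings, file.path(dir, "readings.csv"))
  list(map = file.path(dir, "plate_map.csv"),
       readings = file.path(dir, "readings.csv"))
}

trapz_ref <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# per-model mean AUC of relative volume (treated arm), tibble model_id,
# endpoint
auc_by_model <- function(volumes) {
  t_max <- min(dplyr::summarise(dplyr::group_by(volumes, mouse_id),
                                last = max(day))$last)
  relative_volume(volumes) |>
    dplyr::group_by(model_id, mouse_id) |>
    dplyr::arrange(day, .by_group = TRUE) |>
    dplyr::summarise(auc = trapz_ref(day[day <= t_max],
                                     relative_volume[day <= t_max]),
                     .groups = "drop") |>
    dplyr::group_by(model_id) |>
    dplyr::summarise(endpoint = mean(auc), .groups = "drop")
}

well_labels16 <- function() {
  sprintf("%s%02d", rep(LETTERS[1:2], each = 8), rep(1:8, 2))
}

# minimal hand-written four-well screen fragment
tiny_records <- function() {
  tibble::tibble(
    plate_id = c("P1", "P1", "P1", "D0"),
    well = c("A01", "A02", "A03", "A01"),
    model_id = "L1",
    drug_id = c("d1", "d1", "", ""),
    dose_uM = c(1, 10, 0, 0),
    role = c("treated", "treated", "vehicle", "day0"),
    bio_rep = 1L,
    tech_rep = c(1L, 1L, 1L, 1L),
    luminescence = c(1.5e6, 0.8e6, 4e6, 1e6)
  )
}
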