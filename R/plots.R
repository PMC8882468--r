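#' Clustered GR_aoc heat map of a screen
#'
#' Tile map of the model x drug GR_aoc matrix with rows and columns in
#' dendrogram order from [cluster_screen()]: darker tiles = more
#' cytotoxic response.
#'
#' @param metrics Metrics tibble or a `screen_clustering` object.
#' @return A ggplot.
#' @export
plot_screen_heatmap <- function(metrics) {
  cl <- if (inherits(metrics, "screen_clustering")) metrics else
    cluster_screen(metrics)
  df <- as_tibble(cl$matrix, rownames = "model_id") |>
    tidyr::pivot_longer(-"model_id", names_to = "drug_id",
                        values_to = "GR_aoc") |>
    mutate(model_id = factor(.data$model_id, levels = cl$row_order),
           drug_id = factor(.data$drug_id, levels = cl$col_order))
  ggplot(df, aes(x = .data$drug_id, y = .data$model_id,
                 fill = .data$GR_aoc)) +
    geom_tile() +
    scale_fill_viridis_c(direction = -1) +
    labs(x = NULL, y = NULL, fill = "GR_aoc") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Dose-response points and fitted curves for one (model, drug)
#'
#' @param profiles Normalized profiles from [normalize_screen()].
#' @param model_id,drug_id Pair to plot.
#' @param scale `"GR"`, `"RV"` or `"TC"`.
#' @return A ggplot of replicate points with the pooled fitted curve.
#' @export
plot_dose_response <- function(profiles, model_id, drug_id,
                               scale = c("GR", "RV", "TC")) {
  scale <- match.arg(scale)
  col <- c(GR = "gr", RV = "rv", TC = "tc")[[scale]]
  sub <- profiles |>
    filter(.data$model_id == .env$model_id,
           .data$drug_id == .env$drug_id)
  if (!nrow(sub)) abort("no data for that (model, drug) pair")
  fit <- fit_dose_response(sub$dose_uM, sub[[col]], scale = scale)
  autoplot(fit, data = tibble(dose_uM = sub$dose_uM, value = sub[[col]])) +
    ggtitle(paste0(model_id, " / ", drug_id))
}

#' Relative tumor volume curves by arm
#'
#' @param volumes Volume tibble; `relative_volume` computed if absent.
#' @return A ggplot of per-mouse trajectories with arm means.
#' @export
plot_tumor_volumes <- function(volumes) {
  if (!"relative_volume" %in% names(volumes)) {
    volumes <- relative_volume(volumes)
  }
  means <- volumes |>
    group_by(.data$arm, .data$day) |>
    summarise(relative_volume = mean(.data$relative_volume),
              .groups = "drop")
  ggplot(volumes, aes(x = .data$day, y = .data$relative_volume,
                      colour = .data$arm)) +
    geom_line(aes(group = .data$mouse_id), alpha = 0.3) +
    geom_line(data = means, linewidth = 1.2) +
    labs(x = "days from treatment start", y = "relative tumor volume") +
    theme_minimal()
}
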