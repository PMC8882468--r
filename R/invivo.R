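#' Relative tumor volume trajectories
#'
#' Divides each mouse's tumor volumes by its volume at treatment start
#' (day 0), the standard normalization for comparing treatment arms.
#'
#' @param volumes Tibble `mouse_id, arm, day, volume_mm3`; every mouse
#'   must have a day-0 measurement with positive volume.
#' @return The input with a `relative_volume` column, sorted by mouse and
#'   day.
#' @export
relative_volume <- function(volumes) {
  need <- c("mouse_id", "arm", "day", "volume_mm3")
  miss <- setdiff(need, names(volumes))
  if (length(miss)) {
    abort(paste0("volumes is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(volumes$volume_mm3 <= 0)) abort("volumes must be positive")
  out <- volumes |>
    group_by(.data$mouse_id) |>
    arrange(.data$day, .by_group = TRUE) |>
    mutate(baseline = .data$volume_mm3[.data$day == 0][1]) |>
    ungroup()
  if (anyNA(out$baseline)) {
    abort("every mouse needs a day-0 baseline measurement")
  }
  out |>
    mutate(relative_volume = .data$volume_mm3 / .data$baseline) |>
    select(-"baseline")
}

auc_one_mouse <- function(day, rel, t_max) {
  if (max(day) < t_max) {
    abort(paste0("trajectory ends at day ", max(day), " before t_max = ",
                 t_max, "; extrapolation is refused"))
  }
  keep <- day <= t_max
  d <- day[keep]
  r <- rel[keep]
  if (max(d) < t_max) {
    # interpolate the trajectory to t_max from the bracketing measurements
    at <- approx(day, rel, xout = t_max)$y
    d <- c(d, t_max)
    r <- c(r, at)
  }
  trapz(d, r)
}

#' Per-mouse growth-curve AUC with a two-arm t-test
#'
#' Trapezoidal area under each mouse's relative-volume curve on
#' `[0, t_max]` (trajectories measured on differing days are linearly
#' interpolated to `t_max`; extrapolation beyond the last measurement is
#' refused), followed by a two-sided t-test between the two arms.
#' A flat trajectory at relative volume 1 has AUC exactly `t_max`.
#'
#' @param volumes Volume tibble (see [relative_volume()]); the
#'   `relative_volume` column is computed if absent.
#' @param arm_a,arm_b Arm labels to compare.
#' @param t_max Upper integration limit, days.
#' @param var_equal Pooled-variance Student t-test by default; set `FALSE`
#'   for Welch.
#' @return List: `auc` (tibble `mouse_id, arm, auc`), `t`, `df`,
#'   `p_value`, `mean_a`, `mean_b`.
#' @export
auc_compare <- function(volumes, arm_a, arm_b, t_max, var_equal = TRUE) {
  if (!"relative_volume" %in% names(volumes)) {
    volumes <- relative_volume(volumes)
  }
  volumes <- volumes |> filter(.data$arm %in% c(arm_a, arm_b))
  if (n_distinct(volumes$arm) != 2) abort("both arms must be present")
  auc <- volumes |>
    group_by(.data$mouse_id, .data$arm) |>
    arrange(.data$day, .by_group = TRUE) |>
    summarise(auc = auc_one_mouse(.data$day, .data$relative_volume,
                                  .env$t_max),
              .groups = "drop")
  if (any(table(auc$arm) < 2)) abort("need >= 2 mice per arm")
  a <- auc$auc[auc$arm == arm_a]
  b <- auc$auc[auc$arm == arm_b]
  if (sd(c(a - mean(a), b - mean(b))) == 0) {
    # no within-arm variability at all: identical arms are a clean null
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(auc = auc, t = if (equal) 0 else Inf,
                df = length(a) + length(b) - 2,
                p_value = as.numeric(equal), mean_a = mean(a),
                mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  list(auc = auc, t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Per-mouse exponential tumor growth rate
#'
#' Slope of the least-squares fit of `log(relative volume)` against time,
#' in units of per day; a tumor doubling every 7 days grows at
#' `log(2)/7 ~ 0.099` per day.
#'
#' @param volumes Volume tibble; `relative_volume` computed if absent.
#' @return Tibble `mouse_id, arm, growth_rate`.
#' @export
growth_rate <- function(volumes) {
  if (!"relative_volume" %in% names(volumes)) {
    volumes <- relative_volume(volumes)
  }
  volumes |>
    group_by(.data$mouse_id, .data$arm) |>
    summarise(growth_rate = {
      if (dplyr::n() < 2) abort("need >= 2 time points per mouse")
      unname(coef(lm(log(.data$relative_volume) ~ .data$day))[2])
    }, .groups = "drop")
}

#' Log-rank (Mantel-Cox) test of time to recurrence between arms
#'
#' Standard k-group log-rank statistic with right censoring, compared to
#' a chi-square distribution with k - 1 degrees of freedom. Identical
#' event-time distributions give chi-square 0 and p = 1.
#'
#' @param records Tibble `mouse_id, arm, day, event` (`event` logical or
#'   0/1; `FALSE`/0 = censored).
#' @return Tibble `chisq, df, p_value, n_arms, n_events`.
#' @export
logrank_recurrence <- function(records) {
  need <- c("arm", "day", "event")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort(paste0("records missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(records$day <= 0)) abort("times must be positive")
  records$event <- as.integer(records$event)
  if (n_distinct(records$arm) < 2) abort("need >= 2 arms")
  if (sum(records$event) < 1) abort("need at least one event")
  sd_fit <- survival::survdiff(survival::Surv(day, event) ~ arm,
                               data = records)
  df <- length(sd_fit$n) - 1
  tibble(chisq = sd_fit$chisq, df = df,
         p_value = pchisq(sd_fit$chisq, df, lower.tail = FALSE),
         n_arms = length(sd_fit$n), n_events = sum(records$event))
}

#' Concordance between organoid GR_aoc and in vivo response
#'
#' Spearman correlation between the organoid screen's GR_aoc and an in
#' vivo response endpoint per model (by default the AUC of relative tumor
#' volume in the treated arm, where smaller means a better response).
#' The sign convention makes perfect concordance -- the most cytotoxic
#' organoid response matching the smallest in vivo endpoint -- equal
#' rho = +1. Being rank-based, the measure is invariant to monotone
#' transformations of either endpoint.
#'
#' @param graoc Tibble `model_id, GR_aoc` for one drug.
#' @param endpoint Tibble `model_id, endpoint` (smaller = better
#'   response).
#' @return Tibble `rho, p_value, n_models`.
#' @export
pdxo_pdx_concordance <- function(graoc, endpoint) {
  merged <- inner_join(graoc, endpoint, by = "model_id")
  if (nrow(merged) < 3) abort("need >= 3 models with both measurements")
  ct <- suppressWarnings(cor.test(merged$GR_aoc, merged$endpoint,
                                  method = "spearman"))
  tibble(rho = -unname(ct$estimate), p_value = ct$p.value,
         n_models = nrow(merged))
}
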