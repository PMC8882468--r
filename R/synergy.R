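curve_params <- function(fit) {
  if (fit$fit_type == "flat") {
    list(flat = TRUE, level = fit$flat_level)
  } else {
    list(flat = FALSE, plateau = fit$plateau, midpoint = fit$midpoint,
         hill = fit$hill, top = fit$top)
  }
}

curve_value <- function(p, dose) {
  if (p$flat) return(rep(p$level, length(dose)))
  p$plateau + (p$top - p$plateau) / (1 + (dose / p$midpoint)^p$hill)
}

# dose needed for a single agent to reach effect level E; Inf when the
# curve cannot reach E alone (E at or below its plateau, or a flat curve)
curve_inverse <- function(p, e, top = 100) {
  if (p$flat || e <= p$plateau) return(Inf)
  if (e >= p$top) return(0)
  p$midpoint * ((p$top - p$plateau) / (e - p$plateau) - 1)^(1 / p$hill)
}

loewe_solve_curves <- function(pa, pb, dose_a, dose_b, top = 100) {
  if (dose_a == 0 && dose_b == 0) {
    return(list(expected = top, flag = "control"))
  }
  if (dose_b == 0) {
    return(list(expected = curve_value(pa, dose_a)[1], flag = "margin"))
  }
  if (dose_a == 0) {
    return(list(expected = curve_value(pb, dose_b)[1], flag = "margin"))
  }
  if (pa$flat && pb$flat) {
    # neither agent has a dose-dependent effect; additivity is vacuous
    return(list(expected = min(pa$level, pb$level), flag = "degenerate"))
  }
  floors <- c(if (!pa$flat) pa$plateau, if (!pb$flat) pb$plateau)
  lo <- min(floors)
  hi <- top
  g <- function(e) {
    dose_a / curve_inverse(pa, e, top) + dose_b / curve_inverse(pb, e, top) - 1
  }
  eps <- (hi - lo) * 1e-12
  if (g(lo + eps) >= 0) {
    # the combined dose pushes the expected effect below every attainable
    # single-agent plateau; clip to the deepest plateau
    return(list(expected = lo, flag = "extrapolated"))
  }
  a <- lo + eps
  b <- hi - eps
  for (i in 1:80) {
    m <- (a + b) / 2
    if (g(m) < 0) a <- m else b <- m
  }
  list(expected = (a + b) / 2, flag = "interior")
}

#' Fit the single-agent margins of a combination dose matrix
#'
#' Fits Hill curves (viability as percent of vehicle control, top fixed at
#' 100) to the zero-dose margins of a two-drug grid: the `dose_b = 0` rows
#' give drug A's single-agent curve and vice versa.
#'
#' @param grid Tibble with columns `dose_a_uM, dose_b_uM, response_pct`
#'   (replicate rows allowed; `bio_rep`/`tech_rep` columns are ignored
#'   here).
#' @return List with elements `fit_a` and `fit_b` (`gr_fit` objects on the
#'   RV scale).
#' @export
fit_single_agents <- function(grid) {
  ma <- grid |> filter(.data$dose_b_uM == 0, .data$dose_a_uM > 0)
  mb <- grid |> filter(.data$dose_a_uM == 0, .data$dose_b_uM > 0)
  if (length(unique(ma$dose_a_uM)) < 4 || length(unique(mb$dose_b_uM)) < 4) {
    abort("each single-agent margin needs >= 4 distinct nonzero doses")
  }
  list(fit_a = fit_dose_response(ma$dose_a_uM, ma$response_pct, scale = "RV"),
       fit_b = fit_dose_response(mb$dose_b_uM, mb$response_pct, scale = "RV"))
}

#' Loewe-additive expected response of a dose combination
#'
#' Under Loewe additivity the expected effect `E` of the pair
#' `(dose_a, dose_b)` is the unique solution of
#' \deqn{\frac{dose_a}{A(E)} + \frac{dose_b}{B(E)} = 1}
#' where `A(E)` and `B(E)` invert the single-agent curves (the dose at
#' which each drug alone produces effect `E`). The defining property is
#' that a drug is exactly additive with itself. The equation is solved by
#' bisection on `E` over the attainable response range; when one drug
#' cannot reach `E` alone its dose term vanishes (inverse treated as
#' infinite), and when the pair's expected effect falls below both
#' single-agent plateaus the deepest plateau is returned with the
#' `"extrapolated"` flag.
#'
#' @param fit_a,fit_b Single-agent fits from [fit_single_agents()].
#' @param dose_a,dose_b Doses (uM, >= 0), scalars.
#' @return List: `expected` (percent viability) and `flag`
#'   (`"interior"`, `"margin"`, `"control"`, `"extrapolated"` or
#'   `"degenerate"`).
#' @export
loewe_expected <- function(fit_a, fit_b, dose_a, dose_b) {
  stopifnot(inherits(fit_a, "gr_fit"), inherits(fit_b, "gr_fit"))
  loewe_solve_curves(curve_params(fit_a), curve_params(fit_b),
                     dose_a, dose_b, top = 100)
}

#' Loewe synergy matrix for a two-drug dose grid
#'
#' Computes, for every dose pair, the Loewe-additive expected response
#' from the single-agent margin fits and the synergy score
#' `expected - observed` on the percent-of-control viability scale, so a
#' positive score means the observed kill exceeds the additive
#' expectation (synergy) and a negative score antagonism. Replicate wells
#' are averaged per cell before scoring; their spread is retained as a
#' per-cell standard error. `mean_synergy` averages the score over all
#' cells where both doses are nonzero.
#'
#' @param grid Tibble `dose_a_uM, dose_b_uM, bio_rep, tech_rep,
#'   response_pct` (replicate columns optional).
#' @param drug_a,drug_b Optional drug labels carried into the result.
#' @return Object of class `synergy_grid`: `doses_a`, `doses_b`
#'   (ascending, including 0), matrices `observed`, `expected`, `synergy`,
#'   `se` (rows = doses of drug A), `flags`, `mean_synergy`,
#'   `mean_synergy_se`, and the margin `fits`.
#' @export
synergy_matrix <- function(grid, drug_a = "drug_a", drug_b = "drug_b") {
  fits <- fit_single_agents(grid)
  pa <- curve_params(fits$fit_a)
  pb <- curve_params(fits$fit_b)
  cells <- grid |>
    group_by(.data$dose_a_uM, .data$dose_b_uM) |>
    summarise(observed = mean(.data$response_pct),
              se = sd(.data$response_pct) / sqrt(dplyr::n()),
              n = dplyr::n(), .groups = "drop")
  doses_a <- sort(unique(cells$dose_a_uM))
  doses_b <- sort(unique(cells$dose_b_uM))
  dims <- list(paste0(drug_a, "_", doses_a), paste0(drug_b, "_", doses_b))
  shape <- function(col) {
    m <- matrix(NA_real_, length(doses_a), length(doses_b), dimnames = dims)
    m[cbind(match(cells$dose_a_uM, doses_a),
            match(cells$dose_b_uM, doses_b))] <- cells[[col]]
    m
  }
  observed <- shape("observed")
  se <- shape("se")
  expected <- matrix(NA_real_, length(doses_a), length(doses_b),
                     dimnames = dims)
  flags <- matrix(NA_character_, length(doses_a), length(doses_b),
                  dimnames = dims)
  for (i in seq_along(doses_a)) {
    for (j in seq_along(doses_b)) {
      sol <- loewe_solve_curves(pa, pb, doses_a[i], doses_b[j])
      expected[i, j] <- sol$expected
      flags[i, j] <- sol$flag
    }
  }
  synergy <- expected - observed
  interior <- outer(doses_a > 0, doses_b > 0, "&")
  mean_synergy <- mean(synergy[interior], na.rm = TRUE)
  n_int <- sum(interior & !is.na(synergy))
  se_cells <- sqrt(sum(se[interior]^2, na.rm = TRUE)) / n_int
  # replicate standard error of the mean synergy: re-run the analysis per
  # biological replicate (own margin fits), so error shared across cells
  # through the fitted margins is counted, then add the within-cell term
  se_rep <- NA_real_
  if ("bio_rep" %in% names(grid) && dplyr::n_distinct(grid$bio_rep) >= 2) {
    ms_rep <- tryCatch(
      vapply(sort(unique(grid$bio_rep)), function(b) {
        sub <- grid[grid$bio_rep == b, ]
        f <- fit_single_agents(sub)
        qa <- curve_params(f$fit_a)
        qb <- curve_params(f$fit_b)
        cc <- sub |>
          group_by(.data$dose_a_uM, .data$dose_b_uM) |>
          summarise(obs = mean(.data$response_pct), .groups = "drop") |>
          filter(.data$dose_a_uM > 0, .data$dose_b_uM > 0)
        exp_b <- vapply(seq_len(nrow(cc)), function(k) {
          loewe_solve_curves(qa, qb, cc$dose_a_uM[k], cc$dose_b_uM[k])$expected
        }, numeric(1))
        mean(exp_b - cc$obs)
      }, numeric(1)),
      error = function(e) NULL
    )
    if (!is.null(ms_rep)) {
      se_rep <- sd(ms_rep) / sqrt(length(ms_rep))
    }
  }
  mean_synergy_se <- if (is.finite(se_rep)) {
    sqrt(se_rep^2 + se_cells^2)
  } else {
    se_cells
  }
  structure(list(drug_a = drug_a, drug_b = drug_b,
                 doses_a = doses_a, doses_b = doses_b,
                 observed = observed, expected = expected,
                 synergy = synergy, se = se, flags = flags,
                 mean_synergy = mean_synergy,
                 mean_synergy_se = mean_synergy_se,
                 fits = fits),
            class = "synergy_grid")
}

#' @export
print.synergy_grid <- function(x, ...) {
  cat(sprintf("<synergy_grid: %s x %s, %d x %d doses>\n", x$drug_a,
              x$drug_b, length(x$doses_a), length(x$doses_b)))
  cat(sprintf("  mean synergy (interior cells): %.3f +/- %.3f\n",
              x$mean_synergy, x$mean_synergy_se))
  invisible(x)
}

#' Tidy a synergy grid into long form
#'
#' @param x A `synergy_grid`.
#' @param ... Unused.
#' @return Long tibble: `dose_a_uM, dose_b_uM, observed, expected,
#'   synergy, se, flag`.
#' @exportS3Method generics::tidy
tidy.synergy_grid <- function(x, ...) {
  idx <- expand.grid(i = seq_along(x$doses_a), j = seq_along(x$doses_b))
  tibble(dose_a_uM = x$doses_a[idx$i],
         dose_b_uM = x$doses_b[idx$j],
         observed = x$observed[cbind(idx$i, idx$j)],
         expected = x$expected[cbind(idx$i, idx$j)],
         synergy = x$synergy[cbind(idx$i, idx$j)],
         se = x$se[cbind(idx$i, idx$j)],
         flag = x$flags[cbind(idx$i, idx$j)])
}

#' @exportS3Method generics::glance
glance.synergy_grid <- function(x, ...) {
  tibble(drug_a = x$drug_a, drug_b = x$drug_b,
         n_cells = length(x$doses_a) * length(x$doses_b),
         mean_synergy = x$mean_synergy,
         mean_synergy_se = x$mean_synergy_se)
}

#' Heat-map of a Loewe synergy matrix
#'
#' @param object A `synergy_grid`.
#' @param ... Unused.
#' @return A ggplot tile map of the synergy scores (positive = synergy).
#' @exportS3Method ggplot2::autoplot
autoplot.synergy_grid <- function(object, ...) {
  df <- tidy(object) |>
    filter(.data$dose_a_uM > 0, .data$dose_b_uM > 0)
  ggplot(df, aes(x = factor(.data$dose_a_uM), y = factor(.data$dose_b_uM),
                 fill = .data$synergy)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0) +
    labs(x = paste0(object$drug_a, " (uM)"),
         y = paste0(object$drug_b, " (uM)"),
         fill = "Loewe\nsynergy") +
    theme_minimal()
}
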