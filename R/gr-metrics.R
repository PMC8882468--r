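#' Growth-rate-corrected (GR) response value
#'
#' The GR transform re-expresses an endpoint viability reading as the ratio
#' of the treated to the untreated growth rate over the assay window,
#' assuming exponential growth:
#' \deqn{GR = 2^{\log_2(T/T_0)/\log_2(C/T_0)} - 1}
#' where `T` is the treated endpoint reading, `T0` the day-0 baseline and
#' `C` the vehicle-control endpoint reading. GR = 1 means uninhibited
#' growth (`T = C`), GR = 0 cytostasis (`T = T0`) and GR approaches -1 for
#' a complete kill (`T -> 0`). The value depends only on the fold-changes
#' `T/T0` and `C/T0`, so it is invariant to the absolute scale of the
#' readout and, crucially, to the line's doubling time.
#'
#' @param t Treated endpoint reading(s), nonnegative.
#' @param t0 Day-0 baseline reading (> 0).
#' @param c0 Vehicle-control endpoint reading; must exceed `t0` (the
#'   control population must grow).
#' @return GR value(s) in `[-1, Inf)`; `-1` exactly when `t == 0`.
#' @seealso [rv_value()] for the traditional relative-growth transform.
#' @export
#' @examples
#' gr_value(4, 1, 4)  # uninhibited growth -> 1
#' gr_value(1, 1, 4)  # cytostasis -> 0
#' gr_value(2, 1, 4)  # partial inhibition -> sqrt(2) - 1
gr_value <- function(t, t0, c0) {
  if (any(t0 <= 0)) abort("`t0` must be positive")
  if (any(c0 <= t0)) abort("control did not grow: C must exceed T0")
  if (any(t < 0)) abort("`t` must be nonnegative")
  ifelse(t == 0, -1, 2^(log2(t / t0) / log2(c0 / t0)) - 1)
}

#' Relative-growth (percent) response value
#'
#' The traditional growth-inhibition transform: net growth of the treated
#' wells as a percentage of net control growth,
#' \deqn{RV = (T - T_0)/(C - T_0) \times 100.}
#' 100 means uninhibited growth, 0 cytostasis; values below 0 indicate net
#' cell loss. GI50 is the dose at which this value crosses 50. Unlike the
#' GR transform, this scale is sensitive to how many doublings the control
#' undergoes, which penalizes slow-growing lines.
#'
#' @inheritParams gr_value
#' @return Percent relative growth (may be negative).
#' @export
rv_value <- function(t, t0, c0) {
  if (any(c0 == t0)) abort("degenerate control: C equals T0")
  (t - t0) / (c0 - t0) * 100
}

#' Closed-form threshold crossing of a fitted dose-response curve
#'
#' Solves `f(c) = level` for the fitted sigmoid
#' `f(c) = plateau + (top - plateau)/(1 + (c/midpoint)^hill)`. The root is
#' `midpoint * ((top - plateau)/(level - plateau) - 1)^(1/hill)`, defined
#' only when `level` lies strictly between the plateau and the top. Roots
#' outside the tested dose range extended by the reporting window are
#' censored to `NA`: by default doses above `10 * max(dose_range)` or below
#' `0.1 * min(dose_range)` are not reported, to avoid meaningless
#' extrapolation beyond the dilution series.
#'
#' @param fit A `gr_fit` from [fit_dose_response()].
#' @param level Response level to solve for (e.g. 0.5 on the GR scale).
#' @param dose_range Tested dose range used for censoring; defaults to the
#'   range seen at fit time. `NULL` disables censoring.
#' @param extrapolation_factor Allowed extrapolation beyond the tested
#'   range (default 10).
#' @return Dose in uM, or `NA` if the curve never crosses `level`, the fit
#'   is flat, or the root falls outside the reporting window.
#' @export
solve_dose <- function(fit, level, dose_range = fit$dose_range,
                       extrapolation_factor = 10) {
  stopifnot(inherits(fit, "gr_fit"))
  if (fit$fit_type == "flat") return(NA_real_)
  top <- fit$top
  p <- fit$plateau
  if (!((level - p) * (top - level) > 0)) return(NA_real_)
  x <- (top - p) / (level - p) - 1
  root <- fit$midpoint * x^(1 / fit$hill)
  if (!is.finite(root) || root <= 0) return(NA_real_)
  if (!is.null(dose_range)) {
    lo <- min(dose_range) / extrapolation_factor
    hi <- max(dose_range) * extrapolation_factor
    if (root < lo || root > hi) return(NA_real_)
  }
  root
}

#' GR50: dose at which the fitted GR curve crosses 0.5
#'
#' Defined only when the asymptotic response `GR_inf` lies below 0.5 and
#' the crossing falls inside the reporting window; flat fits and
#' never-crossing curves yield `NA`. With `GR_inf = 0` the GR50 equals the
#' curve midpoint GEC50.
#'
#' @inheritParams solve_dose
#' @return Dose in uM or `NA`.
#' @export
gr50 <- function(fit, dose_range = fit$dose_range,
                 extrapolation_factor = 10) {
  stopifnot(fit$scale == "GR")
  solve_dose(fit, 0.5, dose_range, extrapolation_factor)
}

#' Cytostatic dose: GR curve crossing of 0
#'
#' The concentration at which the model neither grows nor shrinks
#' (GR = 0); requires `GR_inf < 0`, i.e. the drug is cytotoxic at high
#' dose. For the GR sigmoid this is
#' `GEC50 * (-1/GR_inf)^(1/hill)`; with `GR_inf = -1` it coincides with
#' the GEC50.
#'
#' @inheritParams solve_dose
#' @return Dose in uM or `NA`.
#' @export
cytostatic_dose <- function(fit, dose_range = fit$dose_range,
                            extrapolation_factor = 10) {
  stopifnot(fit$scale == "GR")
  solve_dose(fit, 0, dose_range, extrapolation_factor)
}

#' GR_aoc: normalized area over the GR dose-response curve
#'
#' \deqn{GR_{aoc} = \frac{1}{\log_{10} c_{max} - \log_{10} c_{min}}
#'   \int (1 - GR(c))\, d\log_{10} c}
#' evaluated by the trapezoid rule. Normalizing by the log10 dose span
#' makes screens with different dilution ranges comparable. A constant
#' GR = 1 (no effect) gives 0; a constant GR = -1 (complete kill at every
#' dose) gives 2. Unlike the threshold metrics, the area is defined for
#' every curve -- including flat fits -- so it is never missing, which is
#' why it is the workhorse summary for ranking and clustering.
#'
#' @param object Either a `gr_fit` on the GR scale (the curve is evaluated
#'   at `n_grid` log-spaced points across `doses`) or a numeric vector of
#'   pointwise GR values observed at `doses`.
#' @param doses Tested doses (ascending, > 0); at least 2.
#' @param n_grid Evaluation grid size for fitted curves.
#' @return The area over the curve (scalar).
#' @export
#' @examples
#' gr_aoc(c(1, 1, 1, 1), doses = 10^(0:3))   # no effect -> 0
#' gr_aoc(c(-1, -1, -1, -1), doses = 10^(0:3)) # full kill -> 2
gr_aoc <- function(object, doses, n_grid = 50) {
  doses <- sort(unique(doses))
  if (length(doses) < 2) abort("GR_aoc needs at least 2 distinct doses")
  if (any(doses <= 0)) abort("doses must be positive")
  if (inherits(object, "gr_fit")) {
    grid <- 10^seq(log10(min(doses)), log10(max(doses)), length.out = n_grid)
    gr <- predict_fit(object, grid)
    lx <- log10(grid)
  } else {
    gr <- as.numeric(object)
    if (length(gr) != length(doses)) {
      abort("pointwise GR values must match `doses` in length")
    }
    lx <- log10(doses)
  }
  trapz(lx, 1 - gr) / (max(lx) - min(lx))
}

trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Doubling time from a growth time course
#'
#' Least-squares fit of `log(measure)` against time; the doubling time is
#' `log(2) / slope`. Returns `NA` with a warning when the fitted slope is
#' not positive (no net growth).
#'
#' @param days Time points in days (>= 2).
#' @param measures Positive viability measurements (cell counts, ATP
#'   luminescence, occupied area...).
#' @return Doubling time in days, or `NA`.
#' @export
#' @examples
#' estimate_doubling_time(c(0, 4, 8, 12), c(1, 2, 4, 8)) # 4 days
estimate_doubling_time <- function(days, measures) {
  if (length(days) < 2 || length(measures) != length(days)) {
    abort("need >= 2 matching time points")
  }
  if (any(measures <= 0)) abort("measures must be positive")
  slope <- unname(coef(lm(log(measures) ~ days))[2])
  if (!is.finite(slope) || slope <= 0) {
    warn("no net growth: nonpositive fitted slope; doubling time is NA")
    return(NA_real_)
  }
  log(2) / slope
}
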