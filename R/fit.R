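fit_scale_top <- c(GR = 1, RV = 100, TC = 1)

fit_scale_plateau_bounds <- list(
  GR = c(-1, 1),
  RV = c(-200, 100),
  TC = c(0, 1)
)

#' Fit a sigmoidal dose-response curve
#'
#' Fits
#' \deqn{f(c) = plateau + \frac{top - plateau}{1 + (c/midpoint)^{hill}}}
#' by bounded least squares, with the top asymptote fixed by the response
#' scale: 1 on the GR scale, 100 on the relative-growth (percent) scale,
#' 1 on the endpoint-viability (`T/C`) scale. All replicate points enter
#' one pooled fit (12 points per dose in the default screen design).
#'
#' The sigmoid is accepted over the flat alternative (the mean response)
#' only if an F-test on the residual sums of squares rejects flatness at
#' `flat_alpha`; otherwise `fit_type = "flat"` and the sigmoid parameters
#' are `NA`. This reproduces the behaviour of GR-style scoring tools,
#' which report missing potency metrics for non-responders. Optimization
#' uses `optim(method = "L-BFGS-B")` from three deterministic starts
#' (midpoint at the geometric mean and the first/third log-quartiles of
#' the tested doses), so the fit is reproducible for fixed input.
#'
#' Default parameter bounds: `hill` in `[0.1, 5]`, `midpoint` in
#' `[min(dose)/100, max(dose) * 100]`, `plateau` in `[-1, 1]` (GR),
#' `[-200, 100]` (RV) or `[0, 1]` (TC).
#'
#' @param doses Dose vector (uM, > 0), one entry per observation; at least
#'   4 distinct doses.
#' @param values Observed responses, same length as `doses`.
#' @param scale `"GR"`, `"RV"` (percent relative growth) or `"TC"`
#'   (endpoint viability as fraction of control).
#' @param hill_bounds,plateau_bounds,midpoint_bounds Optional 2-vectors
#'   overriding the default box constraints.
#' @param flat_alpha Significance level of the sigmoid-vs-flat F-test.
#' @return An object of class `gr_fit`: a list with `scale`, `top`,
#'   `plateau`, `midpoint`, `hill`, `fit_type` (`"sigmoid"`/`"flat"`),
#'   `flat_level`, `rss`, `n_points`, `dose_range`.
#' @export
#' @examples
#' d <- rep(10^seq(-3, 0.5, length.out = 8), each = 3)
#' y <- -0.5 + (1 + 0.5) / (1 + (d / 0.1)^2)
#' f <- fit_dose_response(d, y, scale = "GR")
#' tidy(f)
fit_dose_response <- function(doses, values,
                              scale = c("GR", "RV", "TC"),
                              hill_bounds = c(0.1, 5),
                              plateau_bounds = NULL,
                              midpoint_bounds = NULL,
                              flat_alpha = 0.05) {
  scale <- match.arg(scale)
  keep <- is.finite(doses) & is.finite(values)
  doses <- doses[keep]
  values <- values[keep]
  if (length(unique(doses)) < 4) {
    abort("need at least 4 distinct doses to fit a sigmoid")
  }
  if (any(doses <= 0)) abort("doses must be positive")
  top <- fit_scale_top[[scale]]
  if (is.null(plateau_bounds)) plateau_bounds <- fit_scale_plateau_bounds[[scale]]
  if (is.null(midpoint_bounds)) {
    midpoint_bounds <- c(min(doses) / 100, max(doses) * 100)
  }

  n <- length(values)
  flat_level <- mean(values)
  rss_flat <- sum((values - flat_level)^2)

  lx <- log10(doses)
  starts_mid <- 10^c(mean(lx), quantile(lx, c(0.25, 0.75), names = FALSE))
  start_plateau <- min(max(min(values), plateau_bounds[1]), plateau_bounds[2])

  obj <- function(par) {
    pred <- par[1] + (top - par[1]) / (1 + (doses / 10^par[2])^par[3])
    sum((values - pred)^2)
  }
  lower <- c(plateau_bounds[1], log10(midpoint_bounds[1]), hill_bounds[1])
  upper <- c(plateau_bounds[2], log10(midpoint_bounds[2]), hill_bounds[2])

  best <- NULL
  for (m in starts_mid) {
    par0 <- pmin(pmax(c(start_plateau, log10(m), 1), lower), upper)
    res <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }

  make_flat <- function(msg = NULL) {
    if (!is.null(msg)) warn(msg)
    structure(list(scale = scale, top = top, plateau = NA_real_,
                   midpoint = NA_real_, hill = NA_real_,
                   fit_type = "flat", flat_level = flat_level,
                   rss = rss_flat, n_points = n,
                   dose_range = range(doses)),
              class = "gr_fit")
  }
  if (is.null(best)) return(make_flat("sigmoid optimizer failed; flat fit"))

  rss_sig <- best$value
  # F-test: flat (1 parameter) vs sigmoid (3 parameters)
  df2 <- n - 3
  accept <- FALSE
  if (df2 > 0 && rss_sig < rss_flat && rss_sig > 0) {
    fstat <- ((rss_flat - rss_sig) / 2) / (rss_sig / df2)
    accept <- pf(fstat, 2, df2, lower.tail = FALSE) < flat_alpha
  } else if (df2 > 0 && rss_sig == 0 && rss_flat > 0) {
    accept <- TRUE  # perfect sigmoid fit of non-constant data
  }
  if (!accept) return(make_flat())

  structure(list(scale = scale, top = top, plateau = best$par[1],
                 midpoint = 10^best$par[2], hill = best$par[3],
                 fit_type = "sigmoid", flat_level = flat_level,
                 rss = rss_sig, n_points = n,
                 dose_range = range(doses)),
            class = "gr_fit")
}

#' Evaluate a fitted dose-response curve
#'
#' @param fit A `gr_fit`.
#' @param doses Doses at which to evaluate.
#' @return Predicted response; flat fits return their constant level.
#' @export
predict_fit <- function(fit, doses) {
  stopifnot(inherits(fit, "gr_fit"))
  if (fit$fit_type == "flat") {
    return(rep(fit$flat_level, length(doses)))
  }
  fit$plateau + (fit$top - fit$plateau) /
    (1 + (doses / fit$midpoint)^fit$hill)
}

#' @export
print.gr_fit <- function(x, ...) {
  cat(sprintf("<gr_fit: %s scale, %s>\n", x$scale, x$fit_type))
  if (x$fit_type == "sigmoid") {
    cat(sprintf("  plateau %.4g, midpoint %.4g uM, hill %.3g\n",
                x$plateau, x$midpoint, x$hill))
  } else {
    cat(sprintf("  flat level %.4g\n", x$flat_level))
  }
  cat(sprintf("  rss %.4g on %d points\n", x$rss, x$n_points))
  invisible(x)
}

#' Tidy a fitted dose-response curve
#'
#' @param x A `gr_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @exportS3Method generics::tidy
tidy.gr_fit <- function(x, ...) {
  if (x$fit_type == "sigmoid") {
    tibble(term = c("plateau", "midpoint", "hill"),
           estimate = c(x$plateau, x$midpoint, x$hill))
  } else {
    tibble(term = "flat_level", estimate = x$flat_level)
  }
}

#' @rdname tidy.gr_fit
#' @return `glance()`: a one-row summary with scale, fit type, rss and
#'   point count.
#' @exportS3Method generics::glance
glance.gr_fit <- function(x, ...) {
  tibble(scale = x$scale, fit_type = x$fit_type, rss = x$rss,
         n_points = x$n_points,
         plateau = ifelse(x$fit_type == "sigmoid", x$plateau, NA_real_),
         midpoint = ifelse(x$fit_type == "sigmoid", x$midpoint, NA_real_),
         hill = ifelse(x$fit_type == "sigmoid", x$hill, NA_real_),
         flat_level = x$flat_level)
}

#' Plot a fitted dose-response curve
#'
#' @param object A `gr_fit`.
#' @param data Optional tibble with `dose_uM` and `value` columns of the
#'   underlying observations, drawn as points.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gr_fit <- function(object, data = NULL, ...) {
  rng <- object$dose_range
  grid <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = 100)
  curve_df <- tibble(dose_uM = grid, value = predict_fit(object, grid))
  p <- ggplot(curve_df, aes(x = .data$dose_uM, y = .data$value)) +
    geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    scale_x_log10() +
    labs(x = "dose (uM)",
         y = switch(object$scale, GR = "GR value",
                    RV = "relative growth (%)", TC = "viability (T/C)")) +
    theme_minimal()
  if (!is.null(data)) {
    p <- p + geom_point(data = data, alpha = 0.5, size = 1)
  }
  if (object$scale == "GR") {
    p <- p + geom_hline(yintercept = c(0, 0.5), linetype = "dotted",
                        colour = "grey50")
  }
  p
}
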