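test_that("GR and relative-growth transforms hit their anchor points", {
  # uninhibited growth, cytostasis, and the forced intermediate value
  expect_equal(gr_value(4, 1, 4), 1)
  expect_equal(gr_value(1, 1, 4), 0)
  expect_equal(gr_value(2, 1, 4), sqrt(2) - 1)
  expect_equal(gr_value(0, 1, 4), -1)  # complete kill limit
  expect_equal(gr_value(1e-12, 1, 4), 2^(log2(1e-12) / 2) - 1,
               tolerance = 1e-12)

  expect_equal(rv_value(4, 1, 4), 100)
  expect_equal(rv_value(1, 1, 4), 0)
  expect_equal(rv_value(2, 1, 4), 100 / 3)
  expect_lt(rv_value(0.5, 1, 4), 0)  # net cell loss goes negative

  expect_error(gr_value(2, 1, 0.9), "control did not grow")
  expect_error(gr_value(2, 0, 4), "positive")
  expect_error(rv_value(2, 1, 1), "degenerate")
})

test_that("gr_value is invariant to rescaling the readout", {
  set.seed(21)
  for (i in 1:50) {
    t0 <- runif(1, 0.5, 2e6)
    c0 <- t0 * runif(1, 1.2, 8)
    t <- runif(1, 0, c0 * 1.5)
    k <- 10^runif(1, -3, 3)
    expect_equal(gr_value(k * t, k * t0, k * c0), gr_value(t, t0, c0),
                 tolerance = 1e-9)
  }
})

test_that("closed-form threshold doses agree with bisection on the curve", {
  set.seed(31)
  for (i in 1:200) {
    plateau <- runif(1, -1, 0.45)
    midpoint <- 10^runif(1, -2, 1)
    hill <- runif(1, 0.3, 4)
    fit <- structure(list(scale = "GR", top = 1, plateau = plateau,
                          midpoint = midpoint, hill = hill,
                          fit_type = "sigmoid", flat_level = NA_real_,
                          rss = 0, n_points = 8,
                          dose_range = c(1e-4, 1e3)),
                     class = "gr_fit")
    f <- hill_curve(1, plateau, midpoint, hill)
    g50 <- gr50(fit, dose_range = NULL)
    expect_equal(g50, bisect_root(f, 0.5), tolerance = 1e-6)
    if (plateau < 0) {
      expect_equal(cytostatic_dose(fit, dose_range = NULL),
                   bisect_root(f, 0), tolerance = 1e-6)
    } else {
      expect_true(is.na(cytostatic_dose(fit, dose_range = NULL)))
    }
  }
})

test_that("gr50 and cytostatic closed forms match their special cases", {
  mk <- function(plateau, midpoint, hill) {
    structure(list(scale = "GR", top = 1, plateau = plateau,
                   midpoint = midpoint, hill = hill, fit_type = "sigmoid",
                   flat_level = NA_real_, rss = 0, n_points = 8,
                   dose_range = NULL),
              class = "gr_fit")
  }
  # GR_inf = 0: GR50 coincides with the midpoint, any hill
  expect_equal(gr50(mk(0, 0.37, 2.3)), 0.37)
  # curve never reaches 0.5
  expect_true(is.na(gr50(mk(0.8, 0.1, 1))))
  # GR_inf = -1, hill = 1: GR50 = GEC50 / 3
  expect_equal(gr50(mk(-1, 0.1, 1)), 0.1 * (2 / 1.5 - 1), tolerance = 1e-12)
  # GR_inf = -1: cytostatic dose equals the midpoint for any hill
  expect_equal(cytostatic_dose(mk(-1, 0.25, 3.7)), 0.25)
  # growing asymptote: no cytostatic dose
  expect_true(is.na(cytostatic_dose(mk(0.2, 0.1, 1))))
  # GR_inf = -0.5, hill = 2, midpoint 1 -> sqrt(2)
  expect_equal(cytostatic_dose(mk(-0.5, 1, 2)), sqrt(2), tolerance = 1e-12)
})

test_that("threshold doses outside the reporting window are censored", {
  fit <- structure(list(scale = "GR", top = 1, plateau = -1,
                        midpoint = 1e-4, hill = 1, fit_type = "sigmoid",
                        flat_level = NA_real_, rss = 0, n_points = 8,
                        dose_range = c(0.01, 10)),
                   class = "gr_fit")
  expect_true(is.na(gr50(fit)))            # crossing far below tested range
  expect_false(is.na(gr50(fit, dose_range = NULL)))
})

test_that("GI50 closed form matches the relative-growth curve", {
  mk_rv <- function(plateau, midpoint, hill) {
    structure(list(scale = "RV", top = 100, plateau = plateau,
                   midpoint = midpoint, hill = hill, fit_type = "sigmoid",
                   flat_level = NA_real_, rss = 0, n_points = 8,
                   dose_range = NULL),
              class = "gr_fit")
  }
  expect_equal(solve_dose(mk_rv(0, 0.2, 1.4), 50), 0.2)  # RV_inf = 0
  expect_true(is.na(solve_dose(mk_rv(80, 0.2, 1), 50)))  # never reaches 50
  expect_equal(solve_dose(mk_rv(-100, 0.5, 1), 50), 0.5 * (200 / 150 - 1),
               tolerance = 1e-12)
  f <- hill_curve(100, -60, 0.3, 2.2)
  expect_equal(solve_dose(mk_rv(-60, 0.3, 2.2), 50), bisect_root(f, 50),
               tolerance = 1e-6)
})

test_that("GR_aoc integrates the area over the curve on the log scale", {
  doses <- 10^seq(-3, 0.5, length.out = 8)
  expect_equal(gr_aoc(rep(1, 8), doses), 0)
  expect_equal(gr_aoc(rep(-1, 8), doses), 2)
  expect_equal(gr_aoc(rep(0.25, 8), doses), 0.75)

  # step curve: GR = 1 on the lower half of the log range, -1 above
  d <- 10^seq(0, 4, length.out = 64)
  step <- ifelse(log10(d) < 2, 1, -1)
  expect_equal(gr_aoc(step, d), 1, tolerance = 0.05)

  # fitted flat curve integrates to 1 - flat level
  flat <- structure(list(scale = "GR", top = 1, plateau = NA_real_,
                         midpoint = NA_real_, hill = NA_real_,
                         fit_type = "flat", flat_level = 0.6, rss = 0,
                         n_points = 8, dose_range = range(doses)),
                    class = "gr_fit")
  expect_equal(gr_aoc(flat, doses), 0.4)
  expect_error(gr_aoc(1, 0.5), "2 distinct doses")
})

test_that("doubling-time estimation inverts exponential growth", {
  expect_equal(estimate_doubling_time(c(0, 4, 8, 12), c(1, 2, 4, 8)), 4)
  expect_warning(dt0 <- estimate_doubling_time(0:3, rep(2, 4)),
                 "no net growth")
  expect_true(is.na(dt0))
  set.seed(41)
  days <- seq(0, 30, by = 6)
  meas <- 2^(days / 6) * exp(rnorm(length(days), 0, 0.05))
  expect_equal(estimate_doubling_time(days, meas), 6, tolerance = 0.5 / 6)
})
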