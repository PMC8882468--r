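mk_volumes <- function(days, vols, mouse = "m1", arm = "a") {
  tibble::tibble(mouse_id = mouse, arm = arm, day = days, volume_mm3 = vols)
}

test_that("relative volume divides by the treatment-start baseline", {
  rv <- relative_volume(mk_volumes(c(0, 7, 14), c(100, 200, 400)))
  expect_equal(rv$relative_volume, c(1, 2, 4))
  flat <- relative_volume(mk_volumes(c(0, 7, 14), c(150, 150, 150)))
  expect_equal(flat$relative_volume, c(1, 1, 1))
  expect_error(relative_volume(mk_volumes(c(3, 7), c(100, 200))),
               "day-0 baseline")
  expect_error(relative_volume(mk_volumes(c(0, 7), c(0, 200))), "positive")
  # exponential growth reproduces e^{rt}
  r <- 0.11
  days <- c(0, 3, 7, 10)
  rv <- relative_volume(mk_volumes(days, 120 * exp(r * days)))
  expect_equal(rv$relative_volume, exp(r * days), tolerance = 1e-12)
})

test_that("growth-curve AUC matches hand trapezoids and arm t-test", {
  flat <- dplyr::bind_rows(
    mk_volumes(c(0, 10, 19), c(100, 100, 100), "m1", "veh"),
    mk_volumes(c(0, 10, 19), c(120, 120, 120), "m2", "veh"),
    mk_volumes(c(0, 10, 19), c(100, 100, 100), "m3", "drg"),
    mk_volumes(c(0, 10, 19), c(120, 120, 120), "m4", "drg")
  )
  res <- auc_compare(flat, "veh", "drg", t_max = 19)
  expect_equal(res$auc$auc, rep(19, 4))  # constant-1 trajectory
  expect_equal(res$p_value, 1)           # identical arms: no separation

  lin <- dplyr::bind_rows(
    mk_volumes(c(0, 19), c(100, 300), "m1", "veh"),      # 1 -> 3 linear
    mk_volumes(c(0, 19), c(100, 300.1), "m2", "veh"),
    mk_volumes(c(0, 19), c(100, 100), "m3", "drg"),
    mk_volumes(c(0, 19), c(100, 100.1), "m4", "drg")
  )
  res2 <- auc_compare(lin, "veh", "drg", t_max = 19)
  expect_equal(res2$auc$auc[res2$auc$arm == "veh"][1], 38, tolerance = 1e-3)
  expect_lt(res2$p_value, 0.01)

  ident <- dplyr::bind_rows(
    mk_volumes(c(0, 19), c(100, 200), "m1", "a"),
    mk_volumes(c(0, 19), c(100, 300), "m2", "a"),
    mk_volumes(c(0, 19), c(100, 200), "m3", "b"),
    mk_volumes(c(0, 19), c(100, 300), "m4", "b")
  )
  expect_equal(auc_compare(ident, "a", "b", t_max = 19)$p_value, 1,
               tolerance = 1e-9)
})

test_that("AUC interpolates to t_max but refuses extrapolation", {
  traj <- dplyr::bind_rows(
    mk_volumes(c(0, 10, 21), c(100, 200, 310), "m1", "a"),
    mk_volumes(c(0, 12, 20), c(100, 220, 300), "m2", "a"),
    mk_volumes(c(0, 9, 19), c(100, 150, 200), "m3", "b"),
    mk_volumes(c(0, 11, 19), c(100, 160, 210), "m4", "b")
  )
  res <- auc_compare(traj, "a", "b", t_max = 19)
  # m1: measured at 10 and 21, value at 19 interpolated linearly
  m1 <- traj |> dplyr::filter(mouse_id == "m1")
  rel <- m1$volume_mm3 / 100
  v19 <- approx(m1$day, rel, xout = 19)$y
  expect_equal(res$auc$auc[res$auc$mouse_id == "m1"],
               trapz_ref(c(0, 10, 19), c(rel[1:2], v19)))
  short <- mk_volumes(c(0, 10), c(100, 200), "m9", "a")
  expect_error(auc_compare(dplyr::bind_rows(traj, short), "a", "b", 19),
               "extrapolation")
})

test_that("growth rate recovers the exponential slope", {
  days <- c(0, 7, 14, 21)
  gr <- growth_rate(mk_volumes(days, 100 * 2^(days / 7)))
  expect_equal(gr$growth_rate, log(2) / 7, tolerance = 1e-9)
  expect_equal(growth_rate(mk_volumes(days, rep(100, 4)))$growth_rate, 0)
  set.seed(121)
  noisy <- mk_volumes(days, 100 * exp(0.05 * days + rnorm(4, 0, 0.05)))
  expect_equal(growth_rate(noisy)$growth_rate, 0.05, tolerance = 0.01)
})

test_that("log-rank matches the hand-computed Mantel-Cox table", {
  rec <- tibble::tibble(mouse_id = paste0("m", 1:6),
                        arm = rep(c("A", "B"), each = 3),
                        day = c(1, 2, 3, 10, 11, 12),
                        event = TRUE)
  res <- logrank_recurrence(rec)
  expect_equal(res$chisq,
               logrank_table_chisq(rec$day, as.integer(rec$event), rec$arm),
               tolerance = 1e-9)
  expect_lt(res$p_value, 0.05)

  # censoring handled: censored mouse stays in the risk set until day 5
  rec2 <- tibble::tibble(mouse_id = paste0("m", 1:6),
                         arm = rep(c("A", "B"), each = 3),
                         day = c(2, 4, 9, 3, 5, 7),
                         event = c(1, 1, 1, 1, 0, 1))
  res2 <- logrank_recurrence(rec2)
  expect_equal(res2$chisq,
               logrank_table_chisq(rec2$day, rec2$event, rec2$arm),
               tolerance = 1e-9)

  same <- tibble::tibble(mouse_id = paste0("m", 1:6),
                         arm = rep(c("A", "B"), each = 3),
                         day = rep(c(3, 6, 9), 2), event = TRUE)
  res3 <- logrank_recurrence(same)
  expect_equal(res3$chisq, 0, tolerance = 1e-9)
  expect_equal(res3$p_value, 1, tolerance = 1e-9)

  expect_error(logrank_recurrence(same[same$arm == "A", ]), "2 arms")
  expect_error(logrank_recurrence(same |> dplyr::mutate(event = FALSE)),
               "one event")
})

test_that("log-rank is enriched under a hazard ratio of 3, calibrated under the null", {
  detect <- function(hr, seeds) {
    vapply(seeds, function(s) {
      rec <- simulate_recurrence(
        tibble::tibble(arm = c("ctl", "trt"), n = 5,
                       hazard_per_day = c(0.03, 0.03 * hr)),
        follow_up = 365, seed = 1000 + s)
      logrank_recurrence(rec)$p_value < 0.05
    }, logical(1))
  }
  power <- mean(detect(3, 1:200))
  null_rate <- mean(detect(1, 1:200))
  # 10 events at HR 3 gives modest asymptotic power (~0.4); the test must
  # still clearly separate signal from the calibrated null
  expect_gt(power, 0.3)
  expect_gt(power, null_rate + 0.2)
  expect_lt(null_rate, 0.1)
})

test_that("concordance is a signed Spearman with rho = +1 when perfect", {
  graoc <- tibble::tibble(model_id = paste0("M", 1:5),
                          GR_aoc = c(1.8, 1.2, 0.9, 0.4, 0.1))
  endp <- tibble::tibble(model_id = paste0("M", 1:5),
                         endpoint = c(5, 9, 14, 20, 31))
  expect_equal(pdxo_pdx_concordance(graoc, endp)$rho, 1)
  rev_endp <- endp |> dplyr::mutate(endpoint = rev(endpoint))
  expect_equal(pdxo_pdx_concordance(graoc, rev_endp)$rho, -1)
  # invariant to monotone transformation of the endpoint
  expect_equal(pdxo_pdx_concordance(graoc,
                                    endp |> dplyr::mutate(endpoint = log(endpoint)))$rho,
               1)
  expect_error(pdxo_pdx_concordance(graoc[1:2, ], endp), "3 models")
})

test_that("coupled screen and xenograft simulations are concordant", {
  lines <- tibble::tibble(model_id = paste0("M", 1:8))
  set.seed(131)
  latent <- runif(8, 0, 1)  # latent sensitivity: 1 = most sensitive
  effects <- tibble::tibble(model_id = lines$model_id,
                            multiplier = 1 - latent)
  rhos <- vapply(1:20, function(s) {
    sim <- simulate_invivo(lines, effects, n_mice = 4, seed = 200 + s)
    endp <- sim$volumes |>
      dplyr::filter(arm == "treated") |>
      auc_by_model()
    graoc <- tibble::tibble(model_id = lines$model_id,
                            GR_aoc = 2 * latent + rnorm(8, 0, 0.05))
    pdxo_pdx_concordance(graoc, endp)$rho
  }, numeric(1))
  expect_gt(mean(rhos > 0.8), 0.85)
})
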