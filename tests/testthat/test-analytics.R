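test_that("Mann-Whitney matches its textbook example and degenerate case", {
  res <- mw_test(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(res$p_value, 2 / 70, tolerance = 1e-12)
  expect_equal(res$hl_shift, -4)
  expect_true(res$conf_low <= res$hl_shift & res$hl_shift <= res$conf_high)

  same <- mw_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$hl_shift, 0, tolerance = 1e-6)

  const <- mw_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const$p_value, 1)
  expect_equal(const$hl_shift, 0)
  expect_error(mw_test(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney agrees with exhaustive enumeration", {
  set.seed(91)
  sizes <- list(c(3, 3), c(4, 4), c(3, 5), c(5, 5), c(4, 6), c(6, 6))
  for (s in sizes) {
    for (rep in 1:3) {
      x <- rnorm(s[1])
      y <- rnorm(s[2], mean = runif(1, -2, 2))
      got <- mw_test(x, y)
      expect_equal(got$p_value, mw_enum_p(x, y), tolerance = 1e-12)
      expect_equal(got$hl_shift, hl_brute(x, y), tolerance = 1e-12)
    }
  }
})

test_that("model ranking is a stable descending GR_aoc permutation", {
  m <- tibble::tibble(model_id = c("A", "B", "C"), drug_id = "nav",
                      GR_aoc = c(1.5, 0.2, 0.9))
  r <- rank_models_by_drug(m, "nav")
  expect_equal(r$model_id, c("A", "C", "B"))
  expect_equal(r$rank, 1:3)
  tie <- m |> dplyr::mutate(GR_aoc = 1)
  expect_equal(rank_models_by_drug(tie, "nav")$model_id, c("A", "B", "C"))
  expect_error(rank_models_by_drug(m, "nope"), "unknown drug")
  # a permutation regardless of input order
  shuf <- m[c(3, 1, 2), ]
  expect_equal(rank_models_by_drug(shuf, "nav"), r)
})

test_that("within-model drug ranks average over ties", {
  m <- tibble::tibble(model_id = "M", drug_id = c("d1", "d2", "d3"),
                      GR_aoc = c(2, 1, 0))
  r <- rank_drugs_within_model(m, "M")
  expect_equal(r$rank[match(c("d1", "d2", "d3"), r$drug_id)], c(1, 2, 3))
  tie <- tibble::tibble(model_id = "M", drug_id = c("d1", "d2"),
                        GR_aoc = c(1, 1))
  expect_equal(rank_drugs_within_model(tie)$rank, c(1.5, 1.5))
})

test_that("group GR_aoc comparison pools per-(model,drug) values", {
  m <- tidyr::expand_grid(model_id = paste0("M", 1:4),
                          drug_id = paste0("d", 1:2)) |>
    dplyr::mutate(GR_aoc = c(1, 2, 3, 4, 5, 6, 7, 8))
  grp <- tibble::tibble(model_id = paste0("M", 1:4),
                        group = c("TNBC", "TNBC", "other", "other"))
  res <- group_compare_graoc(m, grp)
  expect_equal(res$n_x, 4)
  expect_equal(res$p_value, mw_enum_p(c(1, 2, 3, 4), c(5, 6, 7, 8)),
               tolerance = 1e-12)
  expect_error(group_compare_graoc(m, grp, drug_ids = "zzz"), "not in")
  expect_error(group_compare_graoc(m, grp[1, ] |>
                                     dplyr::mutate(group = "x")),
               "exactly 2")
})

test_that("class rank comparison reports shifts in rank units", {
  # 12 drugs; the class occupies ranks 1-3 in group A, 10-12 in group B
  drugs <- sprintf("d%02d", 1:12)
  mk <- function(model, top_class) {
    graoc <- if (top_class) c(12:10, 9:1) else c(3:1, 12:4)
    tibble::tibble(model_id = model, drug_id = drugs, GR_aoc = graoc)
  }
  m <- dplyr::bind_rows(mk("A1", TRUE), mk("A2", TRUE),
                        mk("B1", FALSE), mk("B2", FALSE))
  classes <- tibble::tibble(drug_id = drugs,
                            class = c(rep("PI3K", 3), rep("other", 9)))
  grp <- tibble::tibble(model_id = c("A1", "A2", "B1", "B2"),
                        group = c("HR+", "HR+", "TNBC", "TNBC"))
  res <- class_rank_compare(m, grp, classes, "PI3K")
  expect_equal(res$hl_shift, -9)
  expect_lt(res$p_value, 0.01)
  expect_error(class_rank_compare(m, grp, classes, "none"), "no drugs")

  ident <- class_rank_compare(dplyr::bind_rows(mk("A1", TRUE),
                                               mk("B1", TRUE)),
                              tibble::tibble(model_id = c("A1", "B1"),
                                             group = c("g1", "g2")),
                              classes, "PI3K")
  expect_equal(ident$p_value, 1)
})

test_that("GR50-GI50 concordance is exact for identical metrics", {
  m <- tibble::tibble(model_id = rep(c("M1", "M2"), each = 3),
                      drug_id = rep(paste0("d", 1:3), 2),
                      GR50 = 10^c(-2, -1, 0, -1.5, -0.5, 0.5)) |>
    dplyr::mutate(GI50 = GR50)
  dt <- tibble::tibble(model_id = c("M1", "M2"), doubling_days = c(3, 8))
  cc <- gr_gi_concordance(m, dt)
  expect_equal(cc$pearson_r, 1)
  expect_equal(cc$slope, 1, tolerance = 1e-9)
  expect_equal(max(abs(cc$pairs$residual)), 0, tolerance = 1e-12)
  expect_error(gr_gi_concordance(m[1:2, ], dt), "at least 3")
})

test_that("clustering separates block structure and ignores row order", {
  mat <- rbind(A1 = c(2, 2, 0, 0), A2 = c(2, 2, 0, 0),
               B1 = c(0, 0, 2, 2), B2 = c(0, 0, 2, 2))
  colnames(mat) <- paste0("d", 1:4)
  noise <- matrix(seq(-0.05, 0.05, length.out = 16), 4, 4)
  cl <- cluster_screen(mat + noise)
  grp <- substr(cl$row_order, 1, 1)
  expect_true(all(grp == c("A", "A", "B", "B")) ||
                all(grp == c("B", "B", "A", "A")))
  # permuting the input rows leaves the topology unchanged
  perm <- (mat + noise)[c(3, 1, 4, 2), ]
  cl2 <- cluster_screen(perm)
  coph <- function(x) as.matrix(stats::cophenetic(x))
  expect_equal(coph(cl$row_hclust)[cl$row_order, cl$row_order],
               coph(cl2$row_hclust)[cl$row_order, cl$row_order])
  # single-row matrix: trivial row tree
  cl1 <- cluster_screen(mat[1, , drop = FALSE])
  expect_null(cl1$row_hclust)
  expect_equal(cl1$row_order, "A1")
  mat_na <- mat
  mat_na[1, 1] <- NA
  expect_error(cluster_screen(mat_na), "NA")
})

test_that("identical replicates give correlation 1 and zero CV", {
  one <- tidyr::expand_grid(model_id = c("M1", "M2"),
                            drug_id = paste0("d", 1:4)) |>
    dplyr::mutate(GR_aoc = c(0.1, 0.5, 1.2, 1.9, 0.3, 0.8, 1.5, 0.2))
  reps <- dplyr::bind_rows(
    one |> dplyr::mutate(bio_rep = 1L),
    one |> dplyr::mutate(bio_rep = 2L),
    one |> dplyr::mutate(bio_rep = 3L)
  )
  rr <- replicate_reproducibility(reps)
  expect_equal(rr$pairwise$correlation, rep(1, 3))
  expect_equal(max(rr$cv$cv), 0)
  expect_error(replicate_reproducibility(one |> dplyr::mutate(bio_rep = 1L)),
               "2 biological replicates")
  expect_error(replicate_reproducibility(one), "bio_rep")
})

test_that("pure-noise replicates are uncorrelated on average", {
  set.seed(101)
  cors <- replicate(40, {
    base <- tidyr::expand_grid(model_id = paste0("M", 1:4),
                               drug_id = paste0("d", 1:5))
    reps <- dplyr::bind_rows(
      base |> dplyr::mutate(bio_rep = 1L, GR_aoc = rnorm(20, 0, 0.1)),
      base |> dplyr::mutate(bio_rep = 2L, GR_aoc = rnorm(20, 0, 0.1))
    )
    replicate_reproducibility(reps)$pairwise$correlation
  })
  expect_lt(abs(mean(cors)), 0.15)
})

test_that("clinical benefit ratios reproduce the case-study arithmetic", {
  res <- clinical_benefit_ratio(list(pfs_days = 138, ttnt_days = 197),
                                list(pfs_days = 41, ttnt_days = 41))
  expect_equal(res$ttnt_ratio, 4.8)   # 197/41
  expect_equal(res$pfs_ratio, 3.4)    # 138/41, computed not transcribed
  expect_true(res$meets_benchmark)    # exceeds the 1.3 benchmark

  same <- clinical_benefit_ratio(list(pfs_days = 41, ttnt_days = 41),
                                 list(pfs_days = 41, ttnt_days = 41))
  expect_equal(same$pfs_ratio, 1.0)
  expect_false(same$meets_benchmark)

  expect_error(clinical_benefit_ratio(list(pfs_days = -1),
                                      list(pfs_days = 41)), "positive")
  expect_error(clinical_benefit_ratio(list(pfs_days = 50, ttnt_days = 40),
                                      list(pfs_days = 41)), ">= pfs")
})
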