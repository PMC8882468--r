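#' Two-sample Mann-Whitney test with Hodges-Lehmann shift
#'
#' Two-sided Mann-Whitney U test, exact (by inversion of the U
#' distribution) when `length(x) * length(y) <= exact_max` and the pooled
#' sample has no ties, otherwise a normal approximation with continuity
#' and tie correction. The Hodges-Lehmann estimate is the median of the
#' pairwise differences `x - y`, with a 95% confidence interval obtained
#' by inverting the test.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param conf_level Confidence level for the shift interval.
#' @param exact_max Largest `n * m` for which the exact distribution is
#'   used.
#' @return One-row tibble: `statistic` (U for the first sample),
#'   `p_value`, `hl_shift`, `conf_low`, `conf_high`, `n_x`, `n_y`.
#' @export
#' @examples
#' mw_test(c(1, 2, 3, 4), c(5, 6, 7, 8))  # exact p = 0.0286, shift -4
mw_test <- function(x, y, conf_level = 0.95, exact_max = 10000) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (!length(x) || !length(y)) abort("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) * length(y) <= exact_max
  wt <- tryCatch(
    suppressWarnings(wilcox.test(x, y, conf.int = TRUE, exact = exact,
                                 correct = TRUE, conf.level = conf_level)),
    error = function(e) NULL
  )
  if (is.null(wt)) {
    # degenerate input (e.g. every observation identical): test carries no
    # information; report the brute-force shift with a vacuous interval
    wt0 <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    diffs <- as.numeric(outer(x, y, "-"))
    return(tibble(statistic = unname(wt0$statistic),
                  p_value = min(ifelse(is.nan(wt0$p.value), 1, wt0$p.value), 1),
                  hl_shift = median(diffs),
                  conf_low = min(diffs), conf_high = max(diffs),
                  n_x = length(x), n_y = length(y)))
  }
  p <- wt$p.value
  if (is.nan(p)) p <- 1
  tibble(statistic = unname(wt$statistic),
         p_value = min(p, 1),
         hl_shift = unname(wt$estimate),
         conf_low = unname(wt$conf.int[1]),
         conf_high = unname(wt$conf.int[2]),
         n_x = length(x), n_y = length(y))
}

#' Order model lines by sensitivity to one drug
#'
#' Models sorted by `GR_aoc` descending -- most cytotoxic response first --
#' with ties broken lexicographically by `model_id` (stable).
#'
#' @param metrics Metrics tibble from [score_screen()].
#' @param drug_id Drug to rank by.
#' @return Tibble `model_id, GR_aoc, rank`.
#' @export
rank_models_by_drug <- function(metrics, drug_id) {
  sub <- metrics |> filter(.data$drug_id == .env$drug_id)
  if (!nrow(sub)) abort(paste0("unknown drug: ", drug_id))
  sub |>
    arrange(desc(.data$GR_aoc), .data$model_id) |>
    mutate(rank = row_number()) |>
    select("model_id", "GR_aoc", "rank")
}

#' Rank drugs within each model line
#'
#' Rank 1 is the drug with the highest `GR_aoc` (most cytotoxic) in that
#' model; tied drugs share the average rank.
#'
#' @param metrics Metrics tibble.
#' @param model_id Optional single model; default ranks every model.
#' @return Tibble `model_id, drug_id, GR_aoc, rank`.
#' @export
rank_drugs_within_model <- function(metrics, model_id = NULL) {
  if (!is.null(model_id)) {
    metrics <- metrics |> filter(.data$model_id == .env$model_id)
    if (!nrow(metrics)) abort(paste0("unknown model: ", model_id))
  }
  metrics |>
    group_by(.data$model_id) |>
    mutate(rank = rank(-.data$GR_aoc, ties.method = "average")) |>
    ungroup() |>
    select("model_id", "drug_id", "GR_aoc", "rank") |>
    arrange(.data$model_id, .data$rank)
}

check_two_groups <- function(groups) {
  if (!all(c("model_id", "group") %in% names(groups))) {
    abort("`groups` needs columns model_id and group")
  }
  lev <- unique(groups$group)
  if (length(lev) != 2) abort("`groups` must define exactly 2 groups")
  lev
}

#' Compare pooled GR_aoc between two groups of models
#'
#' Pools the per-(model, drug) `GR_aoc` values of each model group over
#' the chosen drug set (e.g. cytotoxic chemotherapies in TNBC vs non-TNBC
#' lines) and compares the two pools by a two-sided Mann-Whitney test with
#' a Hodges-Lehmann shift estimate.
#'
#' @param metrics Metrics tibble.
#' @param groups Tibble `model_id, group` with exactly two group labels;
#'   the first label in order of appearance is the first sample.
#' @param drug_ids Optional drug subset (default: all drugs present).
#' @return The [mw_test()] row plus `group_1`, `group_2`.
#' @export
group_compare_graoc <- function(metrics, groups, drug_ids = NULL) {
  lev <- check_two_groups(groups)
  if (!is.null(drug_ids)) {
    missing_drugs <- setdiff(drug_ids, metrics$drug_id)
    if (length(missing_drugs)) {
      abort(paste0("drug(s) not in metrics: ",
                   paste(missing_drugs, collapse = ", ")))
    }
    metrics <- metrics |> filter(.data$drug_id %in% drug_ids)
  }
  pooled <- metrics |> inner_join(groups, by = "model_id")
  x <- pooled$GR_aoc[pooled$group == lev[1]]
  y <- pooled$GR_aoc[pooled$group == lev[2]]
  if (!length(x) || !length(y)) abort("both groups must be nonempty")
  mw_test(x, y) |> mutate(group_1 = lev[1], group_2 = lev[2])
}

#' Compare the rank positions of a drug class between model groups
#'
#' Ranks all drugs within each model ([rank_drugs_within_model()]),
#' collects the rank positions occupied by the drugs of one class, and
#' compares those positions between two model groups by a two-sided
#' Mann-Whitney test. The Hodges-Lehmann shift is in rank units: a
#' negative shift means the class ranks better (closer to 1) in the first
#' group.
#'
#' @param metrics Metrics tibble.
#' @param groups Tibble `model_id, group` (two labels).
#' @param drug_classes Tibble `drug_id, class`.
#' @param class Drug class to test.
#' @return The [mw_test()] row plus `class`, `group_1`, `group_2`.
#' @export
class_rank_compare <- function(metrics, groups, drug_classes, class) {
  lev <- check_two_groups(groups)
  class_drugs <- drug_classes$drug_id[drug_classes$class == class]
  if (!length(class_drugs)) abort(paste0("no drugs in class: ", class))
  ranks <- rank_drugs_within_model(metrics) |>
    filter(.data$drug_id %in% class_drugs) |>
    inner_join(groups, by = "model_id")
  x <- ranks$rank[ranks$group == lev[1]]
  y <- ranks$rank[ranks$group == lev[2]]
  if (!length(x) || !length(y)) abort("both groups must be nonempty")
  mw_test(x, y) |>
    mutate(class = .env$class, group_1 = lev[1], group_2 = lev[2])
}

#' Concordance between GR50 and GI50 across a screen
#'
#' Pearson correlation between `log10(GR50)` and `log10(GI50)` over all
#' (model, drug) pairs where both metrics are defined (complete-case), the
#' least-squares regression line, per-pair residuals, and a two-sided
#' Mann-Whitney comparison of the residuals between slower- and
#' faster-growing lines (split at the median doubling time). Under the
#' growth-rate-corrected scoring, slow growers should not be
#' systematically displaced from the regression line.
#'
#' @param metrics Metrics tibble.
#' @param doubling_times Tibble `model_id, doubling_days`.
#' @return List of class `gr_gi_concordance`: `pearson_r`, `intercept`,
#'   `slope`, `n_pairs`, `pairs` (tibble with `residual` and
#'   `growth_group`), and `residual_test` (the [mw_test()] row comparing
#'   fast vs slow residuals, `NA` if only one group).
#' @export
gr_gi_concordance <- function(metrics, doubling_times) {
  pairs <- metrics |>
    filter(!is.na(.data$GR50), !is.na(.data$GI50),
           .data$GR50 > 0, .data$GI50 > 0) |>
    inner_join(doubling_times, by = "model_id") |>
    mutate(log_gr50 = log10(.data$GR50), log_gi50 = log10(.data$GI50))
  if (nrow(pairs) < 3) {
    abort("need at least 3 (model, drug) pairs with both GR50 and GI50")
  }
  r <- cor(pairs$log_gr50, pairs$log_gi50)
  ols <- lm(log_gi50 ~ log_gr50, data = pairs)
  med_dt <- median(doubling_times$doubling_days)
  pairs <- pairs |>
    mutate(residual = unname(ols$residuals),
           growth_group = ifelse(.data$doubling_days <= med_dt,
                                 "faster", "slower"))
  res_test <- if (n_distinct(pairs$growth_group) == 2) {
    mw_test(pairs$residual[pairs$growth_group == "faster"],
            pairs$residual[pairs$growth_group == "slower"])
  } else {
    NULL
  }
  structure(list(pearson_r = r,
                 intercept = unname(coef(ols)[1]),
                 slope = unname(coef(ols)[2]),
                 n_pairs = nrow(pairs),
                 pairs = pairs |>
                   select("model_id", "drug_id", "doubling_days",
                          "log_gr50", "log_gi50", "residual",
                          "growth_group"),
                 residual_test = res_test),
            class = "gr_gi_concordance")
}

#' @export
print.gr_gi_concordance <- function(x, ...) {
  cat(sprintf("<gr_gi_concordance: r = %.4f over %d pairs>\n",
              x$pearson_r, x$n_pairs))
  cat(sprintf("  log10(GI50) = %.3f + %.3f log10(GR50)\n",
              x$intercept, x$slope))
  if (!is.null(x$residual_test)) {
    cat(sprintf("  faster vs slower residuals: p = %.4g, shift = %.4g\n",
                x$residual_test$p_value, x$residual_test$hl_shift))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.gr_gi_concordance <- function(x, ...) {
  tibble(pearson_r = x$pearson_r, intercept = x$intercept,
         slope = x$slope, n_pairs = x$n_pairs,
         residual_p = if (is.null(x$residual_test)) NA_real_ else
           x$residual_test$p_value)
}

#' Unsupervised clustering of a screen's GR_aoc matrix
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average
#' linkage, no scaling) of both the model rows and the drug columns of
#' the GR_aoc matrix. Deterministic for fixed input, and the dendrogram
#' topology does not depend on the input row order.
#'
#' @param metrics Metrics tibble (long) or a numeric model x drug matrix.
#' @return List of class `screen_clustering`: `matrix` (models x drugs),
#'   `row_hclust`, `col_hclust` (`NULL` for a single row/column),
#'   `row_order`, `col_order` (character vectors of ids, dendrogram order).
#' @export
cluster_screen <- function(metrics) {
  if (is.matrix(metrics)) {
    mat <- metrics
  } else {
    mat <- metrics |>
      select("model_id", "drug_id", "GR_aoc") |>
      tidyr::pivot_wider(names_from = "drug_id", values_from = "GR_aoc") |>
      tibble::column_to_rownames("model_id") |>
      as.matrix()
  }
  if (anyNA(mat)) {
    abort("GR_aoc matrix contains NA; impute or drop incomplete pairs first")
  }
  cluster_axis <- function(m) {
    if (nrow(m) < 2) {
      return(list(hc = NULL, order = rownames(m)))
    }
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "average")
    list(hc = hc, order = rownames(m)[hc$order])
  }
  rows <- cluster_axis(mat)
  cols <- cluster_axis(t(mat))
  structure(list(matrix = mat,
                 row_hclust = rows$hc, col_hclust = cols$hc,
                 row_order = rows$order, col_order = cols$order),
            class = "screen_clustering")
}

#' @export
print.screen_clustering <- function(x, ...) {
  cat(sprintf("<screen_clustering: %d models x %d drugs>\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("  row order:", paste(head(x$row_order, 8), collapse = ", "),
      if (length(x$row_order) > 8) "..." else "", "\n")
  invisible(x)
}

#' Replicate reproducibility of GR_aoc across biological replicates
#'
#' Given per-replicate metrics (from `score_screen(per_bio_rep = TRUE)`),
#' computes the pairwise Pearson correlation of the GR_aoc vectors between
#' replicates and a per-(model, drug) coefficient of variation.
#'
#' @param rep_metrics Metrics tibble with a `bio_rep` column.
#' @return List: `pairwise` (tibble `rep_a, rep_b, correlation`),
#'   `median_correlation`, `cv` (tibble `model_id, drug_id, mean_graoc,
#'   sd_graoc, cv`).
#' @export
replicate_reproducibility <- function(rep_metrics) {
  if (!"bio_rep" %in% names(rep_metrics)) {
    abort("`rep_metrics` needs a bio_rep column; run score_screen(per_bio_rep = TRUE)")
  }
  reps <- sort(unique(rep_metrics$bio_rep))
  if (length(reps) < 2) abort("need at least 2 biological replicates")
  wide <- rep_metrics |>
    select("model_id", "drug_id", "bio_rep", "GR_aoc") |>
    tidyr::pivot_wider(names_from = "bio_rep", values_from = "GR_aoc",
                       names_prefix = "rep_")
  combos <- utils::combn(reps, 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    a <- wide[[paste0("rep_", combos[1, k])]]
    b <- wide[[paste0("rep_", combos[2, k])]]
    ok <- complete.cases(a, b)
    tibble(rep_a = combos[1, k], rep_b = combos[2, k],
           correlation = if (sum(ok) >= 3) cor(a[ok], b[ok]) else NA_real_)
  })
  cv <- rep_metrics |>
    group_by(.data$model_id, .data$drug_id) |>
    summarise(mean_graoc = mean(.data$GR_aoc),
              sd_graoc = sd(.data$GR_aoc),
              cv = ifelse(.data$mean_graoc == 0, NA_real_,
                          .data$sd_graoc / abs(.data$mean_graoc)),
              .groups = "drop")
  list(pairwise = pairwise,
       median_correlation = median(pairwise$correlation, na.rm = TRUE),
       cv = cv)
}

#' Clinical benefit ratios for a model-informed therapy
#'
#' Ratios of progression-free survival (PFS) and time to next systemic
#' therapy (TTNT) achieved on a new therapy versus the immediately prior
#' therapy, reported to one decimal. The default benchmark follows the
#' convention used by genomics-guided precision-oncology trials that a
#' matched-therapy:prior-therapy PFS ratio of at least 1.3 indicates
#' clinical benefit.
#'
#' @param new,prior One-row data frames (or named lists) with `pfs_days`
#'   and `ttnt_days` (`ttnt_days` may be `NA`; when present it must be
#'   at least `pfs_days`).
#' @param benchmark PFS-ratio benchmark (default 1.3).
#' @return One-row tibble: `pfs_ratio`, `ttnt_ratio` (one decimal),
#'   `benchmark`, `meets_benchmark`.
#' @export
#' @examples
#' clinical_benefit_ratio(list(pfs_days = 138, ttnt_days = 197),
#'                        list(pfs_days = 41, ttnt_days = 41))
clinical_benefit_ratio <- function(new, prior, benchmark = 1.3) {
  get_course <- function(x, who) {
    pfs <- as.numeric(x[["pfs_days"]])
    ttnt <- if (!is.null(x[["ttnt_days"]])) as.numeric(x[["ttnt_days"]])
            else NA_real_
    if (!is.finite(pfs) || pfs <= 0) {
      abort(paste0(who, " pfs_days must be a positive duration"))
    }
    if (is.finite(ttnt)) {
      if (ttnt <= 0) abort(paste0(who, " ttnt_days must be positive"))
      if (ttnt < pfs) abort(paste0(who, " ttnt_days must be >= pfs_days"))
    }
    list(pfs = pfs, ttnt = ttnt)
  }
  a <- get_course(new, "new")
  b <- get_course(prior, "prior")
  pfs_ratio <- round(a$pfs / b$pfs, 1)
  ttnt_ratio <- if (is.finite(a$ttnt) && is.finite(b$ttnt)) {
    round(a$ttnt / b$ttnt, 1)
  } else {
    NA_real_
  }
  tibble(pfs_ratio = pfs_ratio, ttnt_ratio = ttnt_ratio,
         benchmark = benchmark,
         meets_benchmark = pfs_ratio >= benchmark)
}
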