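# Independent oracles used across the suite.

# brute-force two-sided Mann-Whitney p by enumerating every assignment of
# the pooled (tie-free) sample into groups of the observed sizes
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - n * (n + 1) / 2
  }
  u_obs <- u_of(seq_len(n))
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2, u_of)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Hodges-Lehmann shift as the median of the explicit pairwise-difference
# multiset
hl_brute <- function(x, y) {
  stats::median(as.numeric(outer(x, y, "-")))
}

# two-group Mantel-Cox chi-square from the explicit risk table
logrank_table_chisq <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- unique(group)[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d_t <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + (d1 - d_t * n1 / n_t)
    if (n_t > 1) {
      v <- v + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  o_minus_e^2 / v
}

# root of hill_curve(c) = level by bisection on log10 dose, independent of
# the closed-form solver
bisect_root <- function(f, level, lo = 1e-9, hi = 1e9, iter = 200) {
  g <- function(c) f(c) - level
  a <- log10(lo)
  b <- log10(hi)
  ga <- g(10^a)
  gb <- g(10^b)
  if (sign(ga) == sign(gb)) return(NA_real_)
  for (i in seq_len(iter)) {
    m <- (a + b) / 2
    if (sign(g(10^m)) == sign(ga)) a <- m else b <- m
  }
  10^((a + b) / 2)
}

hill_curve <- function(top, plateau, midpoint, hill) {
  function(c) plateau + (top - plateau) / (1 + (c / midpoint)^hill)
}
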