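# Shared fixtures and independent oracles used across test files.

subsyn_names <- names(npiq_subsyndromes())

# A reduced cohort (6 per sex-by-dx cell, n = 60) for cheap structural tests.
small_spec <- function(seed = 1, ...) {
  gs <- matrix(6L, 5, 2, dimnames = list(c("ADMCI", "ALS", "FTD", "PD", "CVD"),
                                         c("F", "M")))
  cohort_spec(group_sizes = gs, seed = seed, ...)
}

# Full-size cohort (N = 490), scored and normalized, ready for modelling.
analysis_cohort <- function(seed = 1, effects = NULL) {
  spec <- cohort_spec(seed = seed)
  if (!is.null(effects)) spec$effect_spec <- effects
  normalize_wmh(score_npiq(generate_cohort(spec)))
}

subs_matrix <- function(cohort) {
  as.matrix(cohort[paste0("sub_", subsyn_names)])
}

# Independent oracle: closed-form chi-square for a 2x2 table,
# (ad - bc)^2 N / (r1 r2 c1 c2).
chi2_2x2_closed <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c2 <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  (a * d - b * c2)^2 * n /
    (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
}

# Independent oracle: two-sided Fisher p by exhaustive enumeration of the
# hypergeometric support (probability-mass method, ties within rel. 1e-7).
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent oracle: largest-remainder apportionment of a train fraction.
largest_remainder <- function(sizes, frac) {
  target <- round(frac * sum(sizes))
  ideal <- frac * sizes
  base <- floor(ideal)
  extra <- target - sum(base)
  give <- rep(0, length(sizes))
  if (extra > 0) give[order(-(ideal - base))[seq_len(extra)]] <- 1
  base + give
}

skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
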