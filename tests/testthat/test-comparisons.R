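test_that("denominators are recovered from printed count/percent pairs", {
  expect_equal(reconstruct_denominator(33, 28.2), 117L)
  expect_equal(reconstruct_denominator(10, 50.0), 20L)
  expect_equal(reconstruct_denominator(73, 52.9), 138L)
  expect_error(reconstruct_denominator(10, 0), "percent")
  expect_warning(reconstruct_denominator(7, 23.0), "0.05")
})

test_that("every bundled printed percentage is reproduced within 0.05 points", {
  freq <- nps_frequencies()
  den <- reconstruct_denominator(freq$count, freq$percent)
  expect_true(all(abs(100 * freq$count / den - freq$percent) <= 0.05))
})

test_that("chi-square matches the 2x2 closed form on random tables", {
  set.seed(21)
  for (i in 1:1000) {
    tab <- matrix(sample(1:60, 4, replace = TRUE), 2)
    expect_equal(pearson_chi2(tab)$statistic, chi2_2x2_closed(tab),
                 tolerance = 1e-10)
  }
  expect_equal(pearson_chi2(matrix(c(10, 20, 20, 10), 2))$statistic,
               6.666667, tolerance = 1e-6)
})

test_that("chi-square is zero iff row proportions are equal; guards hold", {
  expect_equal(pearson_chi2(rbind(c(10, 30), c(5, 15)))$statistic, 0)
  r <- pearson_chi2(rbind(c(30, 87), c(7, 33), c(24, 27), c(30, 108),
                          c(22, 123)))
  expect_equal(r$df, 4)
  expect_gt(r$statistic, 0)
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "zero margin")
  expect_error(pearson_chi2(matrix(1:3, 1)), "at least 2 x 2")
})

test_that("fisher p agrees with exhaustive hypergeometric enumeration", {
  set.seed(31)
  for (i in 1:300) {
    n <- sample(8:60, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    c2 <- sample(0:(n - a - b), 1); d <- n - a - b - c2
    tab <- matrix(c(a, b, c2, d), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p.value, fisher_enum(tab),
                 tolerance = 1e-7)
  }
  expect_equal(fisher_exact(matrix(c(3, 0, 0, 3), 2))$p.value, 0.1,
               tolerance = 1e-10)
  expect_equal(fisher_exact(matrix(c(0, 10, 0, 10), 2))$p.value, 1)
})

test_that("frequency report reproduces the published group chi-squares", {
  rep <- chi2_frequency_report()
  get <- function(s) rep$chi2[rep$symptom == s]
  expect_equal(get("anxiety"), 22.94, tolerance = 0.05)
  expect_equal(get("apathy"), 26.43, tolerance = 0.05)
  expect_equal(get("agitation"), 10.54, tolerance = 0.05)
  expect_true(all(rep$df == 4))
})

test_that("pairwise fisher flags the known non-reproducible printed rows", {
  fl <- fisher_flag_discrepancies()
  ok <- function(s, g1, g2) fl$matches_printed[fl$symptom == s &
                                                 fl$group1 == g1 &
                                                 fl$group2 == g2]
  expect_true(ok("agitation", "FTD", "PD"))
  expect_true(ok("anxiety", "FTD", "PD"))
  expect_true(ok("anxiety", "FTD", "ALS"))
  # rows whose printed p is inconsistent with the reconstructed tables
  expect_false(ok("apathy", "FTD", "ALS"))
  expect_false(ok("euphoria", "FTD", "PD"))
})

test_that("identity fit gives standardized beta 1 with zero-width CI", {
  d <- data.frame(y = rnorm(60)); d$x <- d$y
  # lm warns about the (intentionally) perfect fit
  r <- suppressWarnings(adjusted_linear_association(d, "y", "x", character()))
  expect_equal(r$beta, 1, tolerance = 1e-10)
  expect_equal(r$ci_high - r$ci_low, 0, tolerance = 1e-10)
  expect_true(r$ci_low <= r$beta && r$beta <= r$ci_high)
})

test_that("adjusted association recovers planted and null exposure effects", {
  recover <- vapply(1:100, function(s) {
    set.seed(8000 + s)
    n <- 490
    d <- data.frame(x = rnorm(n), age = rnorm(n, 69, 7),
                    sex = factor(sample(c("F", "M"), n, TRUE)))
    d$y <- 0.3 * d$x + sqrt(1 - 0.3^2) * rnorm(n)
    abs(adjusted_linear_association(d, "y", "x")$beta - 0.3) <= 0.1
  }, logical(1))
  expect_gte(mean(recover), 0.9)
  nulls <- vapply(1:100, function(s) {
    set.seed(9000 + s)
    n <- 490
    d <- data.frame(x = rnorm(n), y = rnorm(n), age = rnorm(n, 69, 7),
                    sex = factor(sample(c("F", "M"), n, TRUE)))
    abs(adjusted_linear_association(d, "y", "x")$beta) < 0.1
  }, logical(1))
  expect_gte(mean(nulls), 0.9)
})

test_that("vascular burden vs total WMH load runs on a scored cohort", {
  co <- analysis_cohort(seed = 17)
  r <- adjusted_linear_association(co, "wmhlog_total", "vasc_burden",
                                   c("age", "sex"))
  expect_true(r$ci_low <= r$beta && r$beta <= r$ci_high)
  expect_equal(r$n, 490)
})

test_that("collinear designs fail naming the offending column", {
  d <- data.frame(y = rnorm(60), x = rnorm(60))
  d$x2 <- d$x
  expect_error(adjusted_linear_association(d, "y", "x", "x2"),
               "collinear")
})
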