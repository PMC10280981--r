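test_that("design matrix has the documented shape and stratification", {
  co <- analysis_cohort(seed = 1)
  d <- build_design(co, "psychotic")
  expect_equal(nrow(d$x), 490)
  expect_equal(ncol(d$x), 82) # 2 sex + age + moca + 68 thickness + 10 WMH
  expect_equal(nlevels(d$strata), 10)
  expect_identical(colnames(d$x)[1:4],
                   c("sex_female", "sex_male", "age", "moca"))
  expect_error(build_design(co, "mood"), "unknown subsyndrome")
  # a missing MoCA drops exactly that row
  co$moca[5] <- NA
  expect_message(d2 <- build_design(co, "psychotic"), "dropped")
  expect_equal(nrow(d2$x), 489)
  expect_equal(d2$n_dropped, 1)
})

test_that("stratified split follows largest-remainder arithmetic", {
  co <- analysis_cohort(seed = 2)
  d <- build_design(co, "apathy")
  sp <- stratified_split(d$strata, 0.75, seed = 9)
  expect_equal(length(sp$train), 368) # round(0.75 * 490)
  expect_equal(sort(c(sp$train, sp$test)), 1:490) # disjoint, exhaustive
  got <- as.vector(table(d$strata[sp$train]))
  want <- largest_remainder(as.vector(table(d$strata)), 0.75)
  expect_equal(got, want)
  # different seeds: different partitions, identical per-stratum counts
  sp2 <- stratified_split(d$strata, 0.75, seed = 10)
  expect_false(identical(sp$train, sp2$train))
  expect_equal(table(d$strata[sp2$train]), table(d$strata[sp$train]))
})

test_that("split guards reject degenerate fractions and tiny strata", {
  s <- factor(rep(c("a", "b"), c(8, 12)))
  expect_error(stratified_split(s, 1.0), "train_fraction")
  expect_error(stratified_split(s, 0), "train_fraction")
  expect_error(stratified_split(factor(c("a", "b", "b")), 0.75), ">= 2")
})

test_that("cross-validated selection picks the sentinel on pure noise and
           leaves it for a real effect", {
  sent <- 0; eff <- 0
  for (s in 1:15) {
    set.seed(s)
    x <- matrix(rnorm(150 * 20), 150, 20)
    colnames(x) <- paste0("v", 1:20)
    strata <- factor(rep(1:5, 30))
    # strong penalty grid: all values at/above the data's lambda_max
    strong <- sort(unique(c(1000, seq(250, 750, length.out = 20))),
                   decreasing = TRUE)
    r <- cv_lambda_select(x, rnorm(150), strata, enet_config(), seed = s,
                          lambda = strong)
    sent <- sent + (r$lambda == 1000)
    y <- 0.5 * x[, 1] + rnorm(150)
    r2 <- cv_lambda_select(x, y, strata, enet_config(), seed = s)
    eff <- eff + (r2$lambda < 1000)
  }
  expect_gte(sent / 15, 0.8)
  expect_gte(eff / 15, 0.95)
  x <- matrix(rnorm(40), 20, 2); colnames(x) <- c("a", "b")
  expect_error(cv_lambda_select(x, rnorm(20), factor(rep(1:2, 10)),
                                enet_config(k_folds = 30)), "k_folds")
  expect_error(cv_lambda_select(x, rep(1, 20), factor(rep(1:2, 10)),
                                enet_config()), "zero variance")
})

test_that("lambda-zero fit on an overdetermined design matches least squares", {
  set.seed(9)
  x <- matrix(rnorm(120 * 8), 120, 8); colnames(x) <- paste0("v", 1:8)
  y <- drop(x %*% rnorm(8) + rnorm(120))
  b_enet <- enet_fit(x, y, 0, thresh = 1e-12)
  b_ols <- coef(lm(y ~ x))
  expect_equal(unname(drop(b_enet)), unname(b_ols), tolerance = 1e-6)
})

test_that("aggregate shrinkage is monotone along the penalty path", {
  co <- analysis_cohort(seed = 20)
  d <- build_design(co, "apathy")
  grid <- npsmap:::lambda_grid(d$x, d$y, enet_config())
  cf <- enet_fit(d$x, d$y, grid)
  l1 <- colSums(abs(cf[-1, ])) # grid is decreasing: sum|coef| must not drop
  expect_true(all(diff(l1) >= -1e-8))
})

test_that("consensus accounting is exact and sentinel refit is intercept-only", {
  co <- analysis_cohort(seed = 3)
  d <- build_design(co, "hyperactivity")
  cfg <- enet_config(repeats = 40, seed = 3)
  fit <- consensus_enet(d, cfg)
  expect_equal(sum(fit$freq$count), 40)
  expect_true(all(fit$lambda_per_repeat %in% fit$grid))
  expect_true(all(fit$retained %in% fit$grid))
  expect_true(all(fit$freq$count[match(fit$retained, fit$freq$lambda)] >=
                    fit$retention_threshold))
  if (1000 %in% fit$retained) {
    sent_col <- match(1000, fit$retained)
    cf <- coef(fit)
    expect_equal(unname(cf[1, sent_col]), mean(d$y), tolerance = 1e-8)
    expect_true(all(cf[-1, sent_col] == 0))
  }
  # sentinel full fit checked directly too
  b <- enet_fit(d$x, d$y, 1000)
  expect_equal(unname(b[1, 1]), mean(d$y), tolerance = 1e-8)
  expect_true(all(b[-1, 1] == 0))
})

test_that("null outcomes keep the consensus at the sentinel and exclude
           irrelevant predictors", {
  co <- analysis_cohort(seed = 4) # no planted effects
  d <- build_design(co, "affective")
  fit <- consensus_enet(d, enet_config(repeats = 100, seed = 4))
  expect_true(1000 %in% fit$retained)
  sent_count <- fit$freq$count[fit$freq$lambda == 1000]
  expect_gte(sent_count, max(fit$freq$count[fit$freq$lambda < 1000]))
})

test_that("a planted thickness effect is selected at non-sentinel lambdas
           with a consistently signed coefficient", {
  hits <- 0; sign_ok <- TRUE
  for (s in 1:8) {
    spec <- plant_effect(cohort_spec(seed = 300 + s),
                         "thk_rh_parstriangularis", "hyperactivity", 0.5)
    co <- normalize_wmh(score_npiq(generate_cohort(spec)))
    fit <- consensus_enet(build_design(co, "hyperactivity"),
                          enet_config(repeats = 40, seed = s))
    nonsent <- setdiff(fit$retained, 1000)
    cf <- coef(fit)[, match(nonsent, fit$retained), drop = FALSE]
    vals <- cf["thk_rh_parstriangularis", ]
    hits <- hits + (length(nonsent) > 0 && all(vals != 0))
    sign_ok <- sign_ok && all(vals >= 0)
  }
  expect_gte(hits / 8, 0.85)
  expect_true(sign_ok)
})

test_that("coefficients are reported on both scales consistently", {
  co <- analysis_cohort(seed = 6)
  d <- build_design(co, "apathy")
  fit <- consensus_enet(d, enet_config(repeats = 20, seed = 6))
  raw <- coef(fit); std <- coef(fit, standardized = TRUE)
  sds <- apply(d$x, 2, sd)
  expect_equal(std[-1, 1], raw[-1, 1] * sds, tolerance = 1e-10)
  expect_equal(std[1, ], raw[1, ]) # intercept untouched
})
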