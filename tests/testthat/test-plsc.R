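test_that("symmetric case: singular values equal correlation eigenvalues", {
  set.seed(41)
  x <- matrix(rnorm(200 * 4), 200, 4)
  colnames(x) <- paste0("v", 1:4)
  fit <- plsc(x, x)
  # with both blocks z-scored, R is the correlation matrix of x
  expect_equal(fit$d, eigen(cor(x), symmetric = TRUE)$values,
               tolerance = 1e-8)
  expect_equal(abs(fit$u), abs(fit$v), tolerance = 1e-8)
})

test_that("noise-free rank-1 coupling loads 100% on the first component", {
  set.seed(42)
  x <- matrix(rnorm(100 * 6), 100, 6)
  y <- (x %*% rnorm(6)) %*% t(rnorm(3)) # rank-1 map into 3 outcomes
  fit <- plsc(x, y)
  expect_equal(fit$varexp[1], 100, tolerance = 1e-6)
})

test_that("saliences are orthonormal, variance sums to 100, scores covary
           with the singular values", {
  co <- analysis_cohort(seed = 8)
  d <- build_design(co, "apathy")
  fit <- plsc(d$x, subs_matrix(co))
  expect_equal(fit$k, 4)
  expect_equal(crossprod(fit$u), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(fit$v), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(fit$varexp), 100, tolerance = 1e-6)
  expect_true(all(diff(fit$varexp) <= 1e-12))
  for (i in 1:4)
    expect_equal(cov(fit$scores_x[, i], fit$scores_y[, i]), fit$d[i],
                 tolerance = 1e-8)
  # deterministic sign convention: refitting reproduces identical saliences
  expect_identical(fit$u, plsc(d$x, subs_matrix(co))$u)
})

test_that("squared singular values match an independent eigendecomposition", {
  set.seed(43)
  for (i in 1:100) {
    n <- sample(20:60, 1); p <- sample(5:20, 1); q <- sample(2:4, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- matrix(rnorm(n * q), n, q) + x[, 1] %o% rnorm(q) * runif(1)
    fit <- plsc(x, y)
    r <- crossprod(fit$xz, fit$yz) / (n - 1)
    ev <- sort(eigen(crossprod(r), symmetric = TRUE)$values,
               decreasing = TRUE)[seq_len(fit$k)]
    expect_equal(fit$d^2, pmax(ev, 0), tolerance = 1e-8)
  }
})

test_that("zero-variance columns are rejected by name", {
  x <- matrix(rnorm(60), 20, 3); colnames(x) <- c("a", "flat", "c")
  x[, "flat"] <- 5
  expect_error(plsc(x, matrix(rnorm(40), 20, 2)), "flat")
})

test_that("permutation p-values respect the add-one bounds and attain the
           minimum under strong planted coupling", {
  spec <- plant_effect(cohort_spec(seed = 55), "thk_lh_superiorfrontal",
                       "apathy", 0.8)
  co <- normalize_wmh(score_npiq(generate_cohort(spec)))
  d <- build_design(co, "apathy")
  fit <- plsc(d$x, subs_matrix(co))
  perm <- plsc_permutation(fit, d$strata, n_perm = 200, seed = 5)
  expect_true(all(perm$p > 0 & perm$p <= 1))
  expect_equal(perm$p[1], 1 / 201, tolerance = 1e-12)
  # determinism and the add-one formula against the stored null samples
  perm2 <- plsc_permutation(fit, d$strata, n_perm = 200, seed = 5)
  expect_identical(perm$p, perm2$p)
  expect_equal(perm$p[2],
               (1 + sum(perm$null_d[, 2] >= fit$d[2])) / 201)
  expect_error(plsc_permutation(fit, d$strata, n_perm = 5), "19")
  expect_error(plsc_permutation(fit, factor(seq_len(fit$n)), n_perm = 50),
               ">= 2")
})

test_that("permutation rejection is near-nominal on small null cohorts", {
  # 40 null cohorts (n = 60) x 300 permutations; super-uniformity within
  # binomial Monte-Carlo error at each level.
  pvals <- vapply(1:40, function(s) {
    co <- normalize_wmh(score_npiq(generate_cohort(small_spec(seed = 500 + s))))
    d <- build_design(co, "apathy")
    fit <- plsc(d$x, subs_matrix(co))
    plsc_permutation(fit, d$strata, n_perm = 300, seed = s)$p[1]
  }, numeric(1))
  for (alpha in c(0.01, 0.05, 0.10)) {
    se <- sqrt(alpha * (1 - alpha) / 40)
    expect_lte(mean(pvals <= alpha), alpha + 3 * se + 1 / 40)
  }
})

test_that("bootstrap ratios are sign-equivariant in the predictors", {
  co <- analysis_cohort(seed = 9)
  d <- build_design(co, "apathy")
  fit <- plsc(d$x, subs_matrix(co))
  bt <- plsc_bootstrap(fit, d$strata, n_boot = 120, seed = 2)
  xf <- d$x; xf[, "age"] <- -xf[, "age"]
  fitf <- plsc(xf, subs_matrix(co))
  btf <- plsc_bootstrap(fitf, d$strata, n_boot = 120, seed = 2)
  expect_equal(btf$bsr_x["age", ], -bt$bsr_x["age", ], tolerance = 1e-6)
  expect_equal(abs(btf$bsr_x), abs(bt$bsr_x), tolerance = 1e-6)
  expect_error(plsc_bootstrap(fit, d$strata, n_boot = 10), "100")
})

test_that("a planted contributor is stable; contributor lists honour the
           threshold", {
  spec <- plant_effect(cohort_spec(seed = 66), "thk_lh_precuneus",
                       "psychotic", -0.6)
  co <- normalize_wmh(score_npiq(generate_cohort(spec)))
  d <- build_design(co, "psychotic")
  fit <- plsc(d$x, subs_matrix(co))
  bt <- plsc_bootstrap(fit, d$strata, n_boot = 300, seed = 3)
  expect_gte(abs(bt$bsr_x["thk_lh_precuneus", 1]), 2)
  top <- stable_contributors(bt, 1, 2, "x")
  expect_true("thk_lh_precuneus" %in% names(top))
  expect_true(all(diff(abs(top)) <= 1e-12)) # sorted by |BSR| descending
  expect_length(stable_contributors(bt, 1, Inf, "x"), 0)
  expect_length(stable_contributors(bt, 1, 0, "x"), nrow(fit$u))
  expect_error(stable_contributors(bt, 9), "range")
})

test_that("latent-score projection of the training data matches predict", {
  co <- analysis_cohort(seed = 10)
  d <- build_design(co, "apathy")
  fit <- plsc(d$x, subs_matrix(co))
  expect_equal(predict(fit), fit$scores_x)
  expect_equal(predict(fit, d$x[1:5, ]), fit$scores_x[1:5, ],
               tolerance = 1e-10, ignore_attr = TRUE)
})
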