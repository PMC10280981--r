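#' Configuration for the consensus elastic-net procedure
#'
#' @param alpha Elastic-net mixing parameter in `[0, 1]`; `1` (default) is
#'   the pure LASSO penalty.
#' @param nlambda Number of data-driven grid points.
#' @param lambda_min_ratio Smallest grid lambda as a fraction of
#'   `lambda_max` (the smallest lambda that zeroes every coefficient).
#' @param sentinel Explicit large lambda appended to the grid (default 1000)
#'   so an intercept-only consensus is representable.
#' @param k_folds Folds of the internal cross-validation (default 10).
#' @param train_fraction Fraction of each sex-by-dx stratum assigned to the
#'   training split (default 0.75).
#' @param repeats Number of stratified train/test repeats (default 500).
#' @param retention_fraction A lambda is retained when it wins at least
#'   `ceil(retention_fraction * repeats)` repeats (default 0.05).
#' @param selection How a repeat's lambda is chosen: `"test"` (default)
#'   takes the grid value minimizing mean squared error on the held-out 25%;
#'   `"cv"` takes the internal 10-fold cross-validation winner on the
#'   training 75%.
#' @param thresh Convergence threshold passed to the coordinate-descent
#'   solver.
#' @param seed Master seed; per-repeat split and fold seeds are derived from
#'   it.
#' @return List of class `enet_config`.
#' @export
enet_config <- function(alpha = 1, nlambda = 100, lambda_min_ratio = 1e-4,
                        sentinel = 1000, k_folds = 10, train_fraction = 0.75,
                        repeats = 500, retention_fraction = 0.05,
                        selection = c("test", "cv"), thresh = 1e-9,
                        seed = 1L) {
  selection <- match.arg(selection)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop_cfg("alpha", "must be in [0, 1]")
  check_scalar_prob(train_fraction, "train_fraction", open = TRUE)
  if (!is.numeric(repeats) || repeats < 1)
    stop_cfg("repeats", "must be >= 1")
  check_scalar_prob(retention_fraction, "retention_fraction")
  if (!is.numeric(k_folds) || k_folds < 2) stop_cfg("k_folds", "must be >= 2")
  structure(list(alpha = alpha, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio, sentinel = sentinel,
                 k_folds = as.integer(k_folds),
                 train_fraction = train_fraction,
                 repeats = as.integer(repeats),
                 retention_fraction = retention_fraction,
                 selection = selection, thresh = thresh,
                 seed = as.integer(seed)),
            class = "enet_config")
}

#' Build the regression design for one subsyndrome
#'
#' Assembles the 82-column predictor matrix used by both the elastic-net and
#' PLSc analyses — two sex indicators (female, male), age, MoCA, the 68
#' cortical-thickness columns and the 10 normalized WMH columns — together
#' with the chosen subsyndrome outcome and the sex-by-dx stratum labels.
#' Rows with any missing value among the used columns are dropped (and
#' counted).
#'
#' @param cohort A scored ([score_npiq()]) and normalized
#'   ([normalize_wmh()]) cohort.
#' @param subsyndrome One of `"hyperactivity"`, `"psychotic"`,
#'   `"affective"`, `"apathy"`.
#' @return Object of class `nps_design`: list with `x` (n x 82 matrix),
#'   `y`, `strata` (factor), `subsyndrome`, `n_dropped`.
#' @export
#' @examples
#' cohort <- normalize_wmh(score_npiq(generate_cohort(cohort_spec(seed = 5))))
#' d <- build_design(cohort, "apathy")
#' dim(d$x)
build_design <- function(cohort, subsyndrome) {
  if (!subsyndrome %in% names(subsyndrome_items))
    stop("unknown subsyndrome '", subsyndrome, "'; must be one of ",
         paste(names(subsyndrome_items), collapse = ", "), call. = FALSE)
  ycol <- paste0("sub_", subsyndrome)
  need <- c("dx", "sex", "age", "moca", ycol, thickness_cols(), wmhlog_cols())
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks column(s) (score and normalize it first): ",
         paste(head(missing_cols, 5), collapse = ", "),
         if (length(missing_cols) > 5) ", ...", call. = FALSE)
  keep <- complete.cases(cohort[need])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " row(s) dropped as incomplete cases")
  d <- cohort[keep, , drop = FALSE]
  x <- cbind(
    sex_female = as.numeric(d$sex == "F"),
    sex_male = as.numeric(d$sex == "M"),
    age = d$age,
    moca = as.numeric(d$moca),
    as.matrix(d[thickness_cols()]),
    as.matrix(d[wmhlog_cols()])
  )
  structure(list(x = x, y = as.numeric(d[[ycol]]),
                 strata = droplevels(interaction(d$sex, d$dx, sep = ":")),
                 subsyndrome = subsyndrome, n_dropped = n_dropped),
            class = "nps_design")
}

#' Stratified train/test split with largest-remainder rounding
#'
#' Assigns `round(train_fraction * stratum size)` participants of each
#' sex-by-dx stratum to the training set, using largest-remainder rounding
#' across strata so the overall training size equals
#' `round(train_fraction * n)` exactly (remainder ties broken by stratum
#' order). The split is disjoint and exhaustive and preserves the sex-by-dx
#' distribution of the whole sample.
#'
#' @param strata Factor of stratum labels, one per row.
#' @param train_fraction Fraction in `(0, 1)`.
#' @param seed Integer seed for the within-stratum shuffles.
#' @return List with integer index vectors `train` and `test`.
#' @export
#' @examples
#' s <- factor(rep(c("a", "b"), c(8, 12)))
#' lengths(stratified_split(s, 0.75, seed = 1))
stratified_split <- function(strata, train_fraction, seed = 1L) {
  check_scalar_prob(train_fraction, "train_fraction", open = TRUE)
  strata <- droplevels(as.factor(strata))
  sizes <- table(strata)
  if (any(sizes < 2))
    stop("every stratum needs >= 2 members; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  n <- length(strata)
  target <- round(train_fraction * n)
  ideal <- train_fraction * as.numeric(sizes)
  base <- floor(ideal)
  extra <- target - sum(base)
  # Largest remainders get the leftover slots; ties by stratum order.
  give <- rep(0L, length(sizes))
  if (extra > 0) give[order(-(ideal - base))[seq_len(extra)]] <- 1L
  n_train <- base + give
  set.seed(seed)
  train <- integer(0)
  idx_by <- split(seq_len(n), strata)
  for (j in seq_along(idx_by)) {
    idx <- idx_by[[j]]
    take <- if (n_train[j] > 0) sample(idx, n_train[j]) else integer(0)
    train <- c(train, take)
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

# Shared penalty grid: glmnet-style lambda_max from the standardized
# predictors, nlambda log-spaced values down to lambda_min_ratio * lambda_max,
# plus the explicit sentinel, sorted decreasing.
lambda_grid <- function(x, y, cfg) {
  n <- nrow(x)
  xs <- scale(x, center = TRUE, scale = apply(x, 2, function(v) {
    s <- sqrt(sum((v - mean(v))^2) / n) # glmnet uses 1/n standardization
    if (s == 0) 1 else s
  }))
  lam_max <- max(abs(crossprod(xs, y - mean(y)))) / (n * max(cfg$alpha, 1e-3))
  grid <- exp(seq(log(lam_max), log(lam_max * cfg$lambda_min_ratio),
                  length.out = cfg$nlambda))
  sort(unique(c(cfg$sentinel, grid)), decreasing = TRUE)
}

#' Internal cross-validated lambda selection
#'
#' For each grid lambda, the mean held-out squared error over `k_folds`
#' sex-by-dx-stratified folds of the training data; the winner is the grid
#' value minimizing it, with ties broken toward the larger (more
#' parsimonious) lambda.
#'
#' @param x,y Training predictor matrix and outcome.
#' @param strata Stratum factor aligned with the rows of `x`.
#' @param cfg An [enet_config()].
#' @param seed Seed for the fold assignment.
#' @param lambda Optional shared penalty grid (decreasing); computed from
#'   `x`, `y` when omitted.
#' @return List with `lambda` (the winner), `cvm` (mean CV error per grid
#'   value) and `grid`.
#' @export
cv_lambda_select <- function(x, y, strata, cfg = enet_config(), seed = 1L,
                             lambda = NULL) {
  if (var(y) == 0)
    stop("outcome has zero variance; cross-validation is degenerate",
         call. = FALSE)
  if (cfg$k_folds > nrow(x))
    stop("k_folds exceeds the number of training rows", call. = FALSE)
  if (is.null(lambda)) lambda <- lambda_grid(x, y, cfg)
  set.seed(seed)
  strata <- droplevels(as.factor(strata))
  foldid <- integer(length(y))
  for (idx in split(seq_along(y), strata)) {
    foldid[sample(idx)] <- rep_len(seq_len(cfg$k_folds), length(idx))
  }
  sse <- matrix(0, cfg$k_folds, length(lambda))
  nheld <- integer(cfg$k_folds)
  for (f in seq_len(cfg$k_folds)) {
    held <- foldid == f
    fit <- glmnet::glmnet(x[!held, , drop = FALSE], y[!held],
                          alpha = cfg$alpha, lambda = lambda,
                          thresh = cfg$thresh, standardize = TRUE)
    pred <- predict(fit, x[held, , drop = FALSE], s = lambda, exact = FALSE)
    sse[f, ] <- colSums((y[held] - pred)^2)
    nheld[f] <- sum(held)
  }
  cvm <- colSums(sse) / sum(nheld) # mean held-out squared error per lambda
  best <- which(cvm <= min(cvm) + 1e-12)[1] # grid decreasing: tie -> larger
  list(lambda = lambda[best], cvm = cvm, grid = lambda)
}

#' Consensus elastic net over repeated stratified train/test splits
#'
#' The study's variable-selection procedure. Each of `repeats` iterations
#' draws a stratified 75/25 train/test split ([stratified_split()]), fits
#' the LASSO path on the training split over a shared penalty grid, and
#' records the lambda that minimizes held-out mean squared error on the test
#' split (or, with `selection = "cv"`, the internal 10-fold
#' cross-validation winner). Lambdas winning at least
#' `ceil(retention_fraction * repeats)` repeats are retained and refit on
#' the full sample; the result is a coefficient table whose columns are the
#' retained lambdas headed by their occurrence counts. The grid always
#' contains a large sentinel lambda (default 1000) whose full-sample fit is
#' the intercept-only model (intercept = outcome mean, all coefficients
#' exactly zero), so a null consensus is representable.
#'
#' @param design An [build_design()] result, or a list with elements `x`,
#'   `y` and `strata`.
#' @param cfg An [enet_config()].
#' @return Object of class `consensus_enet`: list with
#'   \describe{
#'     \item{lambda_per_repeat, mse_per_repeat}{the winning lambda and its
#'       test MSE for every repeat}
#'     \item{freq}{data frame of lambda occurrence counts over repeats}
#'     \item{retained}{the retained lambda values (decreasing)}
#'     \item{coefficients}{(p+1) x n_retained matrix of full-sample
#'       original-scale coefficients, columns headed
#'       `"lambda (count/repeats)"`}
#'     \item{coefficients_std}{the same coefficients on the
#'       standardized-predictor scale}
#'     \item{selected}{union of predictors with a nonzero coefficient in any
#'       retained model}
#'   }
#' @export
#' @examples
#' \donttest{
#' cohort <- normalize_wmh(score_npiq(generate_cohort(cohort_spec(seed = 5))))
#' fit <- consensus_enet(build_design(cohort, "apathy"),
#'                       enet_config(repeats = 25, seed = 5))
#' fit
#' }
consensus_enet <- function(design, cfg = enet_config()) {
  x <- design$x; y <- design$y; strata <- design$strata
  if (is.null(x) || is.null(y) || is.null(strata))
    stop("design must provide x, y and strata", call. = FALSE)
  if (var(y) == 0) stop("outcome has zero variance", call. = FALSE)
  grid <- lambda_grid(x, y, cfg)
  lambda_sel <- numeric(cfg$repeats)
  mse_sel <- numeric(cfg$repeats)
  for (r in seq_len(cfg$repeats)) {
    sp <- stratified_split(strata, cfg$train_fraction,
                           seed = derive_seed(cfg$seed, "split", r))
    fit <- glmnet::glmnet(x[sp$train, , drop = FALSE], y[sp$train],
                          alpha = cfg$alpha, lambda = grid,
                          thresh = cfg$thresh, standardize = TRUE)
    pred <- predict(fit, x[sp$test, , drop = FALSE], s = grid, exact = FALSE)
    mse <- colMeans((y[sp$test] - pred)^2)
    if (cfg$selection == "cv") {
      cvs <- cv_lambda_select(x[sp$train, , drop = FALSE], y[sp$train],
                              strata[sp$train], cfg,
                              seed = derive_seed(cfg$seed, "folds", r),
                              lambda = grid)
      k <- match(cvs$lambda, grid)
    } else {
      k <- which(mse <= min(mse) + 1e-12)[1] # ties toward larger lambda
    }
    lambda_sel[r] <- grid[k]
    mse_sel[r] <- mse[k]
  }
  counts <- tabulate(match(lambda_sel, grid), nbins = length(grid))
  stopifnot(sum(counts) == cfg$repeats)
  freq <- data.frame(lambda = grid, count = as.integer(counts))
  freq <- freq[freq$count > 0, ]
  freq <- freq[order(-freq$lambda), ]
  rownames(freq) <- NULL
  threshold <- ceiling(cfg$retention_fraction * cfg$repeats)
  retained <- freq$lambda[freq$count >= threshold]
  if (length(retained) == 0) {
    warning("no lambda reached the retention threshold (", threshold,
            "/", cfg$repeats, "); reporting the top 5 by frequency",
            call. = FALSE)
    retained <- freq$lambda[order(-freq$count)][seq_len(min(5, nrow(freq)))]
    retained <- sort(retained, decreasing = TRUE)
  }
  full <- glmnet::glmnet(x, y, alpha = cfg$alpha, lambda = grid,
                         thresh = cfg$thresh, standardize = TRUE)
  coefs <- as.matrix(coef(full, s = retained, exact = FALSE))
  counts_ret <- freq$count[match(retained, freq$lambda)]
  colnames(coefs) <- sprintf("%.4g (%d/%d)", retained, counts_ret, cfg$repeats)
  sds <- apply(x, 2, sd)
  coefs_std <- coefs
  coefs_std[-1, ] <- coefs[-1, , drop = FALSE] * sds
  nz <- rownames(coefs)[-1][rowSums(coefs[-1, , drop = FALSE] != 0) > 0]
  structure(list(lambda_per_repeat = lambda_sel, mse_per_repeat = mse_sel,
                 freq = freq, retained = retained,
                 retention_threshold = threshold,
                 coefficients = coefs, coefficients_std = coefs_std,
                 selected = nz, grid = grid, config = cfg,
                 subsyndrome = design$subsyndrome %||% NA_character_,
                 n = nrow(x)),
            class = "consensus_enet")
}

#' @export
print.consensus_enet <- function(x, ...) {
  cat("Consensus elastic net")
  if (!is.na(x$subsyndrome)) cat(" for subsyndrome:", x$subsyndrome)
  cat("\n")
  cat(sprintf("  n = %d, repeats = %d, alpha = %g, selection = %s\n",
              x$n, x$config$repeats, x$config$alpha, x$config$selection))
  cat(sprintf("  retained lambdas (>= %d wins): %s\n", x$retention_threshold,
              paste(sprintf("%.4g", x$retained), collapse = ", ")))
  cat(sprintf("  selected variables (%d): %s\n", length(x$selected),
              paste(head(x$selected, 8), collapse = ", ")))
  if (length(x$selected) > 8) cat("    ...\n")
  invisible(x)
}

#' @export
summary.consensus_enet <- function(object, ...) {
  sel <- c("(Intercept)", object$selected)
  out <- object$coefficients[rownames(object$coefficients) %in% sel, ,
                             drop = FALSE]
  cat("Full-sample coefficients at the retained lambdas",
      "(rows: selected variables; columns: lambda (count/repeats)):\n")
  print(round(out, 4))
  invisible(out)
}

#' @export
coef.consensus_enet <- function(object, standardized = FALSE, ...) {
  if (standardized) object$coefficients_std else object$coefficients
}

#' Penalized fit at fixed lambda values
#'
#' Elastic-net coefficients at the requested penalty strengths from a single
#' full-data coordinate-descent path (predictors standardized internally,
#' coefficients returned on the original scale). `lambda = 0` on a
#' full-rank overdetermined design recovers ordinary least squares.
#'
#' @param x,y Predictor matrix and outcome.
#' @param lambda Penalty value(s).
#' @param alpha Mixing parameter (1 = LASSO).
#' @param thresh Coordinate-descent convergence threshold.
#' @return (p+1) x length(lambda) coefficient matrix (intercept first).
#' @export
enet_fit <- function(x, y, lambda, alpha = 1, thresh = 1e-9) {
  lam_max <- max(lambda_grid(x, y, enet_config(alpha = alpha)))
  path <- sort(unique(c(lam_max, exp(seq(log(lam_max), log(lam_max * 1e-4),
                                         length.out = 50)), lambda)),
               decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = path, thresh = thresh,
                        standardize = TRUE)
  # requested lambdas are members of the fitted path, so no refit is needed
  as.matrix(coef(fit, s = lambda, exact = FALSE))
}

#' Write a consensus coefficient table as delimited text
#'
#' @param fit A [consensus_enet()] result.
#' @param path Output file.
#' @param selected_only Restrict rows to the intercept plus the selected
#'   variables.
#' @export
write_consensus_table <- function(fit, path, selected_only = TRUE) {
  m <- fit$coefficients
  if (selected_only)
    m <- m[rownames(m) %in% c("(Intercept)", fit$selected), , drop = FALSE]
  df <- data.frame(variable = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
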