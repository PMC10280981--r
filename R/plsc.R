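#' Partial least squares correlation (PLSc) between two blocks
#'
#' Behavioural-PLS analysis of the relationship between an outcome block
#' `Y` (here the four neuropsychiatric subsyndrome scores) and a predictor
#' block `X` (sex indicators, age, MoCA, 68 cortical thickness regions, 10
#' normalized WMH volumes). Both blocks are column-wise z-scored, the
#' cross-block matrix `R = X'Y / (n - 1)` is formed, and its singular value
#' decomposition `R = U S V'` yields paired saliences (weight vectors) `U`
#' (predictor side) and `V` (outcome side) with singular values
#' `s_1 >= ... >= s_k`, `k = min(p, q)`. Component `i` explains
#' `100 * s_i^2 / sum_j s_j^2` percent of the cross-block covariance (or
#' `s_i / sum_j s_j` with `var_base = "raw"`). Latent scores are the block
#' projections `Lx = X U`, `Ly = Y V`, whose per-component covariance equals
#' `s_i`. Salience signs are fixed so each outcome salience's
#' largest-magnitude entry is non-negative, making the fit deterministic.
#'
#' Exactly collinear predictor columns (e.g. complementary female/male
#' indicators) are permitted: this is an SVD of a covariance matrix, not a
#' regression.
#'
#' @param x Numeric predictor matrix (n x p).
#' @param y Numeric outcome matrix (n x q), `q <= p`.
#' @param var_base `"squared"` (default) bases variance-explained on squared
#'   singular values; `"raw"` on the singular values themselves.
#' @return Object of class `plsc`: list with `u` (p x k), `v` (q x k), `d`
#'   (singular values), `varexp` (percent), `scores_x`, `scores_y`, the
#'   z-scored blocks `xz`, `yz`, the raw blocks, and `n`.
#' @seealso [plsc_permutation()], [plsc_bootstrap()], [stable_contributors()]
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4)
#' fit <- plsc(x, x)  # symmetric case: d equal eigenvalues of cor(x)
#' fit$d
plsc <- function(x, y, var_base = c("squared", "raw")) {
  var_base <- match.arg(var_base)
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 rows", call. = FALSE)
  if (nrow(y) != n) stop("x and y must have the same number of rows", call. = FALSE)
  xz <- zscore_block(x, "x")
  yz <- zscore_block(y, "y")
  r <- crossprod(xz, yz) / (n - 1)
  sv <- svd(r)
  k <- min(ncol(x), ncol(y))
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  # Deterministic signs: largest-|entry| of each outcome salience >= 0.
  for (j in seq_len(k)) {
    s <- sign(v[which.max(abs(v[, j])), j])
    if (s < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  rownames(u) <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  rownames(v) <- colnames(y) %||% paste0("y", seq_len(ncol(y)))
  varexp <- if (var_base == "squared") 100 * d^2 / sum(d^2) else 100 * d / sum(d)
  structure(list(u = u, v = v, d = d, varexp = varexp,
                 scores_x = xz %*% u, scores_y = yz %*% v,
                 xz = xz, yz = yz, x = x, y = y, n = n, k = k,
                 var_base = var_base,
                 center_x = attr(xz, "scaled:center"),
                 scale_x = attr(xz, "scaled:scale")),
            class = "plsc")
}

zscore_block <- function(m, what) {
  if (anyNA(m)) stop("block '", what, "' contains missing values", call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    nm <- (colnames(m) %||% as.character(seq_len(ncol(m))))[sds == 0]
    stop("zero-variance column(s) in block '", what, "': ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  scale(m, center = TRUE, scale = sds)
}

#' @export
print.plsc <- function(x, ...) {
  cat(sprintf("PLSc fit: n = %d, p = %d, q = %d, %d components\n",
              x$n, nrow(x$u), nrow(x$v), x$k))
  tab <- data.frame(singular_value = round(x$d, 4),
                    pct_variance = round(x$varexp, 2))
  print(tab)
  invisible(x)
}

#' @export
summary.plsc <- function(object, ...) {
  data.frame(component = seq_len(object$k),
             singular_value = object$d,
             pct_variance = object$varexp,
             cum_pct_variance = cumsum(object$varexp))
}

#' @export
coef.plsc <- function(object, block = c("x", "y"), ...) {
  block <- match.arg(block)
  if (block == "x") object$u else object$v
}

#' Project new observations onto the fitted predictor saliences
#'
#' @param object A [plsc()] fit.
#' @param newdata Matrix with the same predictor columns as the fitted `x`
#'   block; when omitted the training latent scores are returned.
#' @param ... Unused.
#' @return Matrix of latent predictor scores (n x k).
#' @export
predict.plsc <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores_x)
  newdata <- as.matrix(newdata)
  z <- scale(newdata, center = object$center_x, scale = object$scale_x)
  z %*% object$u
}

#' Latent-score plot of a PLSc fit
#'
#' Scatter of the predictor-block against outcome-block latent scores for
#' one component, optionally coloured by a grouping factor (e.g. dx).
#'
#' @param x A [plsc()] fit.
#' @param component Component to display.
#' @param groups Optional factor for colouring points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.plsc <- function(x, component = 1, groups = NULL, ...) {
  lx <- x$scores_x[, component]
  ly <- x$scores_y[, component]
  col <- if (is.null(groups)) "black" else as.integer(as.factor(groups))
  graphics::plot(lx, ly, col = col, pch = 19,
                 xlab = sprintf("Predictor latent score (component %d)", component),
                 ylab = sprintf("Outcome latent score (component %d)", component),
                 ...)
  if (!is.null(groups))
    graphics::legend("topleft", legend = levels(as.factor(groups)),
                     col = seq_along(levels(as.factor(groups))), pch = 19,
                     cex = 0.8)
  invisible(x)
}

# Permutation of row indices within strata (counts per cell preserved).
permute_within <- function(idx_by_stratum) {
  out <- integer(sum(lengths(idx_by_stratum)))
  for (idx in idx_by_stratum) out[idx] <- idx[sample.int(length(idx))]
  out
}

#' Stratified permutation test for PLSc components
#'
#' Assesses which components to interpret: the rows of the outcome block are
#' permuted within sex-by-dx strata (preserving every cell's composition),
#' the PLSc is refit, and each observed singular value is compared with the
#' same-index null singular values. P-values use the add-one formula
#' `p_i = (1 + #\{null s_i >= observed s_i\}) / (1 + n_perm)`, so every p lies
#' in `(0, 1]` with minimum `1/(n_perm + 1)`. No Procrustes rotation is
#' applied to the null samples.
#'
#' @param fit A [plsc()] fit.
#' @param strata Factor of stratum labels (one per row); every stratum needs
#'   at least 2 rows.
#' @param n_perm Number of permutations (>= 19; default 5000).
#' @param seed Integer seed.
#' @return Object of class `plsc_perm`: list with `p` (per component),
#'   `null_d` (n_perm x k matrix), `n_perm`.
#' @export
plsc_permutation <- function(fit, strata, n_perm = 5000, seed = 1L) {
  stopifnot(inherits(fit, "plsc"))
  if (n_perm < 19) stop("n_perm must be >= 19", call. = FALSE)
  strata <- droplevels(as.factor(strata))
  if (length(strata) != fit$n)
    stop("strata length must match the number of rows", call. = FALSE)
  sizes <- table(strata)
  if (any(sizes < 2))
    stop("every stratum needs >= 2 rows for permutation; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  idx_by <- split(seq_len(fit$n), strata)
  set.seed(seed)
  nm1 <- fit$n - 1
  null_d <- matrix(0, n_perm, fit$k)
  for (b in seq_len(n_perm)) {
    perm <- permute_within(idx_by)
    # z-scores are permutation-invariant column-wise, so permuting rows of
    # the z-scored block is a full refit.
    r <- crossprod(fit$xz, fit$yz[perm, , drop = FALSE]) / nm1
    null_d[b, ] <- svd(r, nu = 0, nv = 0)$d[seq_len(fit$k)]
  }
  p <- vapply(seq_len(fit$k), function(i) {
    (1 + sum(null_d[, i] >= fit$d[i])) / (1 + n_perm)
  }, numeric(1))
  structure(list(p = p, null_d = null_d, n_perm = n_perm,
                 observed_d = fit$d),
            class = "plsc_perm")
}

#' @export
print.plsc_perm <- function(x, ...) {
  cat(sprintf("PLSc permutation test (%d permutations, stratified):\n",
              x$n_perm))
  print(data.frame(component = seq_along(x$p),
                   singular_value = round(x$observed_d, 4),
                   p = signif(x$p, 4)))
  invisible(x)
}

# Align a replicate's saliences to the original fit: greedy matching of
# components by maximal |correlation| of the stacked [U; V] columns, with
# sign flips.
align_saliences <- function(u0, v0, ub, vb) {
  m0 <- rbind(u0, v0); mb <- rbind(ub, vb)
  k <- ncol(m0)
  cc <- suppressWarnings(cor(mb, m0))
  cc[!is.finite(cc)] <- 0
  map <- integer(k); sgn <- numeric(k)
  free <- rep(TRUE, k)
  for (j in seq_len(k)) {
    i <- which.max(ifelse(free, abs(cc[, j]), -Inf))
    map[j] <- i
    sgn[j] <- if (cc[i, j] < 0) -1 else 1
    free[i] <- FALSE
  }
  list(u = sweep(ub[, map, drop = FALSE], 2, sgn, `*`),
       v = sweep(vb[, map, drop = FALSE], 2, sgn, `*`))
}

#' Stratified bootstrap ratios for PLSc saliences
#'
#' Identifies the most stable contributors to each component. Rows are
#' resampled with replacement within sex-by-dx strata (per-cell counts
#' preserved), the PLSc is refit per replicate (including re-z-scoring), and
#' the replicate saliences are sign/order-aligned to the original fit by
#' maximal absolute correlation of the stacked salience columns. The
#' bootstrap ratio (BSR) of a variable on a component is the
#' original-sample salience divided by the standard deviation of the aligned
#' replicate saliences. Replicates in which a column becomes constant (so
#' z-scoring is undefined) are dropped; more than 10% dropped is an error.
#'
#' @inheritParams plsc_permutation
#' @param n_boot Number of bootstrap replicates (>= 100; default 1000).
#' @param threshold |BSR| at or above which a variable is flagged stable
#'   (default 2).
#' @return Object of class `plsc_boot`: list with `bsr_x` (p x k), `bsr_y`
#'   (q x k), `se_x`, `se_y`, `stable_x`, `stable_y` (logical), `n_boot`
#'   (effective), `n_dropped`.
#' @export
plsc_bootstrap <- function(fit, strata, n_boot = 1000, seed = 1L,
                           threshold = 2) {
  stopifnot(inherits(fit, "plsc"))
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  strata <- droplevels(as.factor(strata))
  if (length(strata) != fit$n)
    stop("strata length must match the number of rows", call. = FALSE)
  idx_by <- split(seq_len(fit$n), strata)
  set.seed(seed)
  k <- fit$k
  sum_u <- matrix(0, nrow(fit$u), k); sumsq_u <- sum_u
  sum_v <- matrix(0, nrow(fit$v), k); sumsq_v <- sum_v
  kept <- 0L; dropped <- 0L
  nm1 <- fit$n - 1
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(idx_by, function(i) i[sample.int(length(i),
                                                          replace = TRUE)]),
                  use.names = FALSE)
    xb <- fit$x[idx, , drop = FALSE]
    yb <- fit$y[idx, , drop = FALSE]
    sx <- apply(xb, 2, sd); sy <- apply(yb, 2, sd)
    if (any(sx == 0) || any(sy == 0)) { dropped <- dropped + 1L; next }
    r <- crossprod(scale(xb, scale = sx), scale(yb, scale = sy)) / nm1
    sv <- svd(r)
    al <- align_saliences(fit$u, fit$v, sv$u[, seq_len(k), drop = FALSE],
                          sv$v[, seq_len(k), drop = FALSE])
    sum_u <- sum_u + al$u; sumsq_u <- sumsq_u + al$u^2
    sum_v <- sum_v + al$v; sumsq_v <- sumsq_v + al$v^2
    kept <- kept + 1L
  }
  if (dropped > 0.1 * n_boot)
    stop("more than 10% of bootstrap replicates dropped (", dropped, "/",
         n_boot, ") due to zero-variance columns", call. = FALSE)
  if (dropped > 0)
    message(dropped, " bootstrap replicate(s) dropped (zero-variance column)")
  boot_sd <- function(s, ss) sqrt(pmax((ss - s^2 / kept) / (kept - 1), 0))
  se_u <- boot_sd(sum_u, sumsq_u)
  se_v <- boot_sd(sum_v, sumsq_v)
  bsr_x <- fit$u / se_u
  bsr_y <- fit$v / se_v
  dimnames(bsr_x) <- dimnames(fit$u); dimnames(se_u) <- dimnames(fit$u)
  dimnames(bsr_y) <- dimnames(fit$v); dimnames(se_v) <- dimnames(fit$v)
  structure(list(bsr_x = bsr_x, bsr_y = bsr_y, se_x = se_u, se_y = se_v,
                 stable_x = abs(bsr_x) >= threshold,
                 stable_y = abs(bsr_y) >= threshold,
                 threshold = threshold, n_boot = kept, n_dropped = dropped),
            class = "plsc_boot")
}

#' @export
print.plsc_boot <- function(x, ...) {
  cat(sprintf(
    "PLSc bootstrap ratios (%d replicates, stratified; stability |BSR| >= %g):\n",
    x$n_boot, x$threshold))
  cat(sprintf("  stable predictor-block variables on component 1: %d of %d\n",
              sum(x$stable_x[, 1]), nrow(x$bsr_x)))
  cat(sprintf("  stable outcome-block variables on component 1: %d of %d\n",
              sum(x$stable_y[, 1]), nrow(x$bsr_y)))
  invisible(x)
}

#' Stable contributors to a PLSc component
#'
#' Variables whose bootstrap ratio magnitude meets the stability threshold,
#' sorted by |BSR| descending.
#'
#' @param boot A [plsc_bootstrap()] result.
#' @param component Component index.
#' @param threshold Minimum |BSR| (default 2).
#' @param block `"x"` (predictors) or `"y"` (outcomes).
#' @return Named numeric vector of bootstrap ratios.
#' @export
stable_contributors <- function(boot, component = 1, threshold = 2,
                                block = c("x", "y")) {
  block <- match.arg(block)
  bsr <- if (block == "x") boot$bsr_x else boot$bsr_y
  if (component < 1 || component > ncol(bsr))
    stop("component out of fitted range", call. = FALSE)
  b <- bsr[, component]
  b <- b[!is.na(b) & abs(b) >= threshold]
  b[order(-abs(b))]
}
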