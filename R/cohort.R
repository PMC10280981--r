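#' Specification of a synthetic five-cohort study population
#'
#' Builds a validated specification for [generate_cohort()]. The defaults
#' emulate the published study population: exact sex-by-diagnosis cell counts
#' (AD/MCI 52F/65M, ALS 16F/23M, FTD 19F/32M, PD 31F/107M, CVD 46F/99M;
#' N = 490), per-cohort age and MoCA distributions, plausible Desikan-Killiany
#' cortical thickness values with mild global atrophy in the AD/MCI and FTD
#' groups, right-skewed (log-normal) regional WMH volumes highest in the CVD
#' group, and per-cohort vascular-risk prevalences. NPI-Q item severities are
#' driven by four latent subsyndrome propensities that can be coupled to any
#' numeric predictor through `effect_spec`, enabling parameter-recovery
#' experiments; with an empty `effect_spec` (the default) all
#' predictor-outcome associations are chance-level.
#'
#' @param group_sizes 5 x 2 numeric matrix of female/male counts per
#'   diagnostic cohort (rows `ADMCI, ALS, FTD, PD, CVD`; columns `F, M`).
#' @param age_params,education_params,moca_params 5 x 2 matrices of per-cohort
#'   mean and SD (columns `mean, sd`). Ages in years; MoCA on its 0-30 scale
#'   (values are rounded and clamped).
#' @param thickness_params List with `region_mean` (named vector of 34
#'   baseline mean thicknesses, mm), `sd` (within-region SD, mm) and
#'   `dx_offset` (named additive offset per cohort, mm).
#' @param wmh_params List with `meanlog` (named per-region log-scale location
#'   of the per-hemisphere raw volume, mm^3), `sdlog` (log-scale SD) and
#'   `dx_offset` (additive per-cohort shift of `meanlog`).
#' @param sttiv_params Numeric `c(mean, sd)` of supratentorial total
#'   intracranial volume (mm^3).
#' @param vascular_params 4 x 5 matrix of per-cohort prevalences of the four
#'   vascular-risk flags (rows hypertension, diabetes, high_cholesterol,
#'   smoked_3mo).
#' @param latent_mean Named numeric: baseline of the four latent subsyndrome
#'   propensities (on the summed-severity scale).
#' @param effect_spec Data frame with columns `predictor`, `subsyndrome`,
#'   `beta`: planted linear effects of z-scored predictors on the latent
#'   propensities. Betas are on the standardized-predictor scale.
#' @param noise_sd Residual SD of the latent subsyndrome propensity.
#' @param item_noise_sd SD of the per-item noise added before discretizing
#'   severities to 0-3.
#' @param missing_rate Optional probability that a participant's MoCA is
#'   missing (the generator otherwise emits complete data).
#' @param seed Integer seed; generation is fully deterministic given the spec.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [null_cohort()]
#' @export
#' @examples
#' spec <- cohort_spec(seed = 7)
#' rowSums(spec$group_sizes)
cohort_spec <- function(group_sizes = default_group_sizes(),
                        age_params = default_dist_params("age"),
                        education_params = default_dist_params("education"),
                        moca_params = default_dist_params("moca"),
                        thickness_params = default_thickness_params(),
                        wmh_params = default_wmh_params(),
                        sttiv_params = c(mean = 1.45e6, sd = 1.4e5),
                        vascular_params = default_vascular_params(),
                        latent_mean = c(hyperactivity = 1.5, psychotic = 0.8,
                                        affective = 0.9, apathy = 1.0),
                        effect_spec = empty_effect_spec(),
                        noise_sd = 1,
                        item_noise_sd = 0.5,
                        missing_rate = 0,
                        seed = 1L) {
  spec <- list(
    group_sizes = as.matrix(group_sizes),
    age_params = as.matrix(age_params),
    education_params = as.matrix(education_params),
    moca_params = as.matrix(moca_params),
    thickness_params = thickness_params,
    wmh_params = wmh_params,
    sttiv_params = sttiv_params,
    vascular_params = as.matrix(vascular_params),
    latent_mean = latent_mean,
    effect_spec = as.data.frame(effect_spec),
    noise_sd = noise_sd,
    item_noise_sd = item_noise_sd,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

# Sex-by-diagnosis cell counts of the modelling sample (N = 490).
default_group_sizes <- function() {
  m <- rbind(ADMCI = c(52, 65), ALS = c(16, 23), FTD = c(19, 32),
             PD = c(31, 107), CVD = c(46, 99))
  colnames(m) <- c("F", "M")
  m
}

default_dist_params <- function(which = c("age", "education", "moca")) {
  which <- match.arg(which)
  m <- switch(which,
    age = rbind(ADMCI = c(71.03, 8.16), ALS = c(61.98, 8.74),
                FTD = c(67.81, 7.12), PD = c(67.94, 6.34),
                CVD = c(69.35, 7.36)),
    education = rbind(ADMCI = c(15.23, 3.08), ALS = c(13.83, 2.88),
                      FTD = c(13.89, 2.73), PD = c(15.49, 2.73),
                      CVD = c(14.69, 2.88)),
    moca = rbind(ADMCI = c(22.67, 2.99), ALS = c(25.46, 2.83),
                 FTD = c(21.48, 3.96), PD = c(25.84, 2.57),
                 CVD = c(25.29, 2.99))
  )
  colnames(m) <- c("mean", "sd")
  m
}

default_thickness_params <- function() {
  rm <- rep(2.5, length(dk_regions))
  names(rm) <- dk_regions
  # Override parcels with distinctly thin/thick cortex for realism.
  rm[c("pericalcarine", "cuneus", "lingual", "postcentral",
       "superiorparietal", "lateraloccipital", "paracentral")] <-
    c(1.65, 1.95, 2.0, 2.05, 2.15, 2.2, 2.4)
  rm[c("entorhinal", "temporalpole", "insula", "superiortemporal",
       "middletemporal", "rostralanteriorcingulate", "superiorfrontal")] <-
    c(3.35, 3.7, 3.0, 2.8, 2.85, 2.85, 2.7)
  list(
    region_mean = rm,
    sd = 0.15,
    dx_offset = c(ADMCI = -0.15, ALS = 0, FTD = -0.15, PD = 0, CVD = -0.05)
  )
}

default_wmh_params <- function() {
  list(
    meanlog = c(frontal = log(700), parietal = log(550), temporal = log(260),
                occipital = log(320), bgt = log(45)),
    sdlog = 1.1,
    dx_offset = c(ADMCI = 0, ALS = 0.05, FTD = 0.1, PD = 0.2, CVD = 0.9)
  )
}

default_vascular_params <- function() {
  m <- rbind(
    hypertension     = c(0.642, 0.714, 0.704, 0.691, 0.837),
    diabetes         = c(0.342, 0.105, 0.276, 0.191, 0.262),
    high_cholesterol = c(0.795, 0.632, 0.931, 0.838, 0.931),
    smoked_3mo       = c(0.532, 0.550, 0.538, 0.414, 0.542)
  )
  colnames(m) <- dx_levels
  m
}

#' @rdname cohort_spec
#' @export
empty_effect_spec <- function() {
  data.frame(predictor = character(), subsyndrome = character(),
             beta = numeric(), stringsAsFactors = FALSE)
}

#' Add a planted effect to a cohort specification
#'
#' Convenience helper that appends one (predictor, subsyndrome, beta) row to
#' the specification's `effect_spec`.
#'
#' @param spec A [cohort_spec()].
#' @param predictor Name of a numeric cohort column (e.g.
#'   `"thk_lh_precuneus"`, `"age"`, `"moca"`, `"wmh_frontal_l"`).
#' @param subsyndrome One of `"hyperactivity"`, `"psychotic"`, `"affective"`,
#'   `"apathy"`.
#' @param beta Standardized-scale coefficient of the effect on the latent
#'   propensity.
#' @return The modified `cohort_spec`.
#' @export
#' @examples
#' spec <- plant_effect(cohort_spec(seed = 3), "thk_lh_precuneus",
#'                      "psychotic", -0.5)
plant_effect <- function(spec, predictor, subsyndrome, beta) {
  stopifnot(inherits(spec, "cohort_spec"))
  spec$effect_spec <- rbind(
    spec$effect_spec,
    data.frame(predictor = predictor, subsyndrome = subsyndrome, beta = beta,
               stringsAsFactors = FALSE)
  )
  validate_cohort_spec(unclass(spec))
  spec
}

validate_cohort_spec <- function(spec) {
  gs <- spec$group_sizes
  if (!is.numeric(gs) || nrow(gs) != 5 || ncol(gs) != 2 ||
      any(is.na(gs)) || any(gs < 0) || any(gs != round(gs)))
    stop_cfg("group_sizes", "must be a 5 x 2 matrix of non-negative integer counts")
  for (fld in c("age_params", "education_params", "moca_params")) {
    p <- spec[[fld]]
    if (!is.numeric(p) || nrow(p) != 5 || ncol(p) != 2 || any(is.na(p)))
      stop_cfg(fld, "must be a 5 x 2 numeric matrix (mean, sd)")
    if (any(p[, 2] <= 0)) stop_cfg(fld, "SDs must be > 0")
  }
  tp <- spec$thickness_params
  if (!setequal(names(tp$region_mean), dk_regions))
    stop_cfg("thickness_params$region_mean", "must name all 34 cortical regions")
  if (any(tp$region_mean <= 0)) stop_cfg("thickness_params$region_mean", "must be > 0")
  if (!is.numeric(tp$sd) || tp$sd <= 0) stop_cfg("thickness_params$sd", "must be > 0")
  wp <- spec$wmh_params
  if (!setequal(names(wp$meanlog), wmh_regions))
    stop_cfg("wmh_params$meanlog", "must name the 5 WMH regions")
  if (!is.numeric(wp$sdlog) || wp$sdlog <= 0) stop_cfg("wmh_params$sdlog", "must be > 0")
  if (spec$sttiv_params[["sd"]] <= 0 || spec$sttiv_params[["mean"]] <= 0)
    stop_cfg("sttiv_params", "mean and sd must be > 0")
  vp <- spec$vascular_params
  if (any(vp < 0) || any(vp > 1))
    stop_cfg("vascular_params", "prevalences must be in [0, 1]")
  if (!setequal(names(spec$latent_mean), names(subsyndrome_items)))
    stop_cfg("latent_mean", "must name the four subsyndromes")
  es <- spec$effect_spec
  if (!all(c("predictor", "subsyndrome", "beta") %in% names(es)))
    stop_cfg("effect_spec", "must have columns predictor, subsyndrome, beta")
  if (nrow(es) && !all(es$subsyndrome %in% names(subsyndrome_items)))
    stop_cfg("effect_spec", "subsyndrome names must be one of hyperactivity/psychotic/affective/apathy")
  if (!is.numeric(spec$noise_sd) || spec$noise_sd <= 0)
    stop_cfg("noise_sd", "must be > 0")
  if (!is.numeric(spec$item_noise_sd) || spec$item_noise_sd < 0)
    stop_cfg("item_noise_sd", "must be >= 0")
  check_scalar_prob(spec$missing_rate, "missing_rate")
  if (is.na(spec$seed)) stop_cfg("seed", "must be an integer")
  invisible(spec)
}

#' Generate a synthetic cohort
#'
#' Draws one complete per-participant table from a [cohort_spec()]:
#' demographics with the exact sex-by-diagnosis margins of the specification
#' (cell counts are fixed, never sampled), 68 Desikan-Killiany cortical
#' thickness values, 10 raw regional WMH volumes (log-normal, right-skewed),
#' supratentorial total intracranial volume, vascular-risk flags, and 12
#' NPI-Q severity/distress item pairs.
#'
#' Item severities arise from a latent-propensity model: for each subsyndrome
#' `s` with `k_s` items, a latent propensity
#' `L_s = latent_mean_s + sum_j beta_j * z(x_j) + N(0, noise_sd)` is computed
#' from the planted effects, then each member item's severity is
#' `clip(round(L_s / k_s + N(0, item_noise_sd)), 0, 3)`, so the summed item
#' severities track the latent propensity. Predictors named `wmh_*` are
#' z-scored on the head-size-corrected log scale (see [wmh_log_correct()]);
#' all other predictors are z-scored as-is. Study-partner distress is
#' generated conditional on severity and is positive only when the symptom is
#' present. Generation is bitwise-reproducible given the spec (a fixed
#' sub-seed is derived per generation block).
#'
#' @param spec A [cohort_spec()].
#' @return A data frame of class `nps_cohort`, one row per participant, with
#'   attributes `effect_spec` and `seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 11))
#' table(cohort$dx, cohort$sex)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    stop("spec must be a 'cohort_spec' object", call. = FALSE)
  validate_cohort_spec(spec)

  gs <- spec$group_sizes
  dx <- rep(rep(dx_levels, 2L), times = c(gs[, 1], gs[, 2]))
  sex <- rep(c("F", "M"), times = c(sum(gs[, 1]), sum(gs[, 2])))
  ord <- order(match(dx, dx_levels), sex) # rows grouped by dx, F before M
  dx <- factor(dx[ord], levels = dx_levels)
  sex <- factor(sex[ord], levels = c("F", "M"))
  n <- length(dx)
  if (n == 0) stop_cfg("group_sizes", "must yield at least one participant")
  gi <- as.integer(dx)

  set.seed(derive_seed(spec$seed, "demographics"))
  age <- rnorm(n, spec$age_params[gi, 1], spec$age_params[gi, 2])
  education <- pmax(0, round(rnorm(n, spec$education_params[gi, 1],
                                   spec$education_params[gi, 2])))
  moca <- pmin(30, pmax(0, round(rnorm(n, spec$moca_params[gi, 1],
                                       spec$moca_params[gi, 2]))))

  set.seed(derive_seed(spec$seed, "anatomy"))
  sttiv <- pmax(0.5 * spec$sttiv_params[["mean"]],
                rnorm(n, spec$sttiv_params[["mean"]], spec$sttiv_params[["sd"]]))
  tp <- spec$thickness_params
  thk <- matrix(0, n, 68, dimnames = list(NULL, thickness_cols()))
  for (h in c("lh", "rh")) {
    for (r in dk_regions) {
      mu <- tp$region_mean[[r]] + tp$dx_offset[dx_levels][gi]
      thk[, paste("thk", h, r, sep = "_")] <- pmax(0.5, rnorm(n, mu, tp$sd))
    }
  }

  set.seed(derive_seed(spec$seed, "wmh"))
  wp <- spec$wmh_params
  wmh <- matrix(0, n, 10, dimnames = list(NULL, wmh_cols()))
  for (r in wmh_regions) {
    for (h in c("l", "r")) {
      ml <- wp$meanlog[[r]] + wp$dx_offset[dx_levels][gi]
      wmh[, paste("wmh", r, h, sep = "_")] <- rlnorm(n, ml, wp$sdlog)
    }
  }

  set.seed(derive_seed(spec$seed, "vascular"))
  vasc <- sapply(vascular_flags, function(f) {
    rbinom(n, 1, spec$vascular_params[f, dx_levels][gi]) == 1
  })
  colnames(vasc) <- paste0("vasc_", vascular_flags)

  cohort <- data.frame(id = sprintf("S%04d", seq_len(n)), dx = dx, sex = sex,
                       age = age, education = education, moca = moca,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(thk), as.data.frame(wmh),
                  sttiv = sttiv, as.data.frame(vasc))

  # Latent subsyndrome propensities -> item severities and distress.
  set.seed(derive_seed(spec$seed, "npiq"))
  latent <- matrix(rnorm(n * 4, 0, spec$noise_sd), n, 4,
                   dimnames = list(NULL, names(subsyndrome_items)))
  latent <- sweep(latent, 2, spec$latent_mean[colnames(latent)], `+`)
  es <- spec$effect_spec
  for (i in seq_len(nrow(es))) {
    z <- zscore_predictor(cohort, es$predictor[i])
    latent[, es$subsyndrome[i]] <- latent[, es$subsyndrome[i]] + es$beta[i] * z
  }
  sev <- matrix(0L, n, 12, dimnames = list(NULL, paste0("npiq_", npiq_symptoms, "_sev")))
  dis <- matrix(0L, n, 12, dimnames = list(NULL, paste0("npiq_", npiq_symptoms, "_distress")))
  for (s in names(subsyndrome_items)) {
    items <- subsyndrome_items[[s]]
    k <- length(items)
    for (it in items) {
      raw <- latent[, s] / k + rnorm(n, 0, spec$item_noise_sd)
      v <- pmin(3L, pmax(0L, as.integer(round(raw))))
      sev[, paste0("npiq_", it, "_sev")] <- v
      d <- as.integer(pmin(5, pmax(0, round(v + rnorm(n, 0.5, 0.8)))))
      d[v == 0L] <- 0L
      dis[, paste0("npiq_", it, "_distress")] <- d
    }
  }
  cohort <- cbind(cohort, as.data.frame(sev), as.data.frame(dis))

  if (spec$missing_rate > 0) {
    set.seed(derive_seed(spec$seed, "missingness"))
    cohort$moca[runif(n) < spec$missing_rate] <- NA_integer_
  }

  rownames(cohort) <- NULL
  attr(cohort, "effect_spec") <- es
  attr(cohort, "seed") <- spec$seed
  class(cohort) <- c("nps_cohort", "data.frame")
  cohort
}

# z-score a predictor column for the latent-effect model; WMH volumes are
# taken on the head-size-corrected log scale, everything else as-is.
zscore_predictor <- function(cohort, name) {
  if (!name %in% names(cohort))
    stop_cfg("effect_spec", sprintf("names unknown predictor '%s'", name))
  x <- cohort[[name]]
  if (!is.numeric(x))
    stop_cfg("effect_spec", sprintf("predictor '%s' is not numeric", name))
  if (startsWith(name, "wmh_")) x <- wmh_log_correct(x, cohort$sttiv)
  s <- sd(x)
  if (s == 0) stop_cfg("effect_spec", sprintf("predictor '%s' has zero variance", name))
  (x - mean(x)) / s
}

#' Generate a null cohort with equal strata
#'
#' A cohort with `n_per_stratum` participants in each of the 10 sex-by-dx
#' cells and no planted effects, so every predictor-outcome association is
#' chance-level. Used to calibrate permutation tests and selection
#' procedures.
#'
#' @param n_per_stratum Participants per sex-by-dx cell (>= 2, so stratified
#'   resampling remains possible).
#' @param seed Integer seed.
#' @return An `nps_cohort` with `10 * n_per_stratum` rows and an empty
#'   `effect_spec` attribute.
#' @export
#' @examples
#' nrow(null_cohort(10, seed = 2))
null_cohort <- function(n_per_stratum, seed = 1L) {
  if (!is.numeric(n_per_stratum) || n_per_stratum < 2)
    stop("n_per_stratum must be >= 2: stratified resampling is impossible otherwise",
         call. = FALSE)
  gs <- matrix(as.integer(n_per_stratum), 5, 2,
               dimnames = list(dx_levels, c("F", "M")))
  generate_cohort(cohort_spec(group_sizes = gs,
                              effect_spec = empty_effect_spec(),
                              seed = seed))
}

#' Read/write a cohort as a delimited text table
#'
#' `write_cohort()` writes one header row plus one row per participant as
#' tab-separated text; `read_cohort()` restores the table (re-establishing
#' factor levels for `dx` and `sex`).
#'
#' @param cohort An `nps_cohort` or plain data frame.
#' @param path File path.
#' @return `read_cohort()` returns an `nps_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  if ("dx" %in% names(cohort)) cohort$dx <- factor(cohort$dx, levels = dx_levels)
  if ("sex" %in% names(cohort)) cohort$sex <- factor(cohort$sex, levels = c("F", "M"))
  class(cohort) <- c("nps_cohort", "data.frame")
  cohort
}

#' Read a cohort specification from a YAML or JSON config file
#'
#' Scalar fields override the defaults of [cohort_spec()]; matrix-valued
#' fields are given as named lists of rows. An `effect_spec` entry is a list
#' of `(predictor, subsyndrome, beta)` mappings.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `cohort_spec`.
#' @export
cohort_spec_from_file <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(cfg$group_sizes)) {
    m <- do.call(rbind, cfg$group_sizes)
    colnames(m) <- c("F", "M")
    args$group_sizes <- m[dx_levels, , drop = FALSE]
  }
  for (fld in c("noise_sd", "item_noise_sd", "missing_rate", "seed"))
    if (!is.null(cfg[[fld]])) args[[fld]] <- cfg[[fld]]
  if (!is.null(cfg$effect_spec)) {
    args$effect_spec <- do.call(rbind, lapply(cfg$effect_spec, function(e) {
      data.frame(predictor = e$predictor, subsyndrome = e$subsyndrome,
                 beta = as.numeric(e$beta), stringsAsFactors = FALSE)
    }))
  }
  do.call(cohort_spec, args)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  participants: %d (F %d / M %d)\n", sum(x$group_sizes),
              sum(x$group_sizes[, 1]), sum(x$group_sizes[, 2])))
  cat("  per-dx (F/M):",
      paste(sprintf("%s %d/%d", rownames(x$group_sizes),
                    x$group_sizes[, 1], x$group_sizes[, 2]), collapse = ", "),
      "\n")
  if (nrow(x$effect_spec)) {
    cat("  planted effects:\n")
    for (i in seq_len(nrow(x$effect_spec)))
      cat(sprintf("    %s -> %s (beta = %.3g)\n", x$effect_spec$predictor[i],
                  x$effect_spec$subsyndrome[i], x$effect_spec$beta[i]))
  } else cat("  planted effects: none (null cohort)\n")
  cat(sprintf("  noise_sd = %g, item_noise_sd = %g, seed = %d\n",
              x$noise_sd, x$item_noise_sd, x$seed))
  invisible(x)
}
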