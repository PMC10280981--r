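#' Head-size correction and log transform of WMH volumes
#'
#' Applies the regional white matter hyperintensity correction
#' `log((x / sttiv) + c)` with `c = 0.0001`: the raw regional volume is
#' expressed as a fraction of supratentorial total intracranial volume
#' (ST-TIV), a small constant is added so zero-lesion regions stay finite,
#' and the natural log is taken to tame the right skew. The output is
#' bounded below by `log(c)` (attained exactly when `x = 0`), strictly
#' increasing in `x` for fixed `sttiv`, and invariant to rescaling `x` and
#' `sttiv` by a common factor.
#'
#' @param x Raw regional WMH volume(s), mm^3, `>= 0`.
#' @param sttiv Supratentorial total intracranial volume(s), mm^3, `> 0`.
#' @param const Additive constant applied to the volume fraction
#'   (default `1e-4`).
#' @param base Logarithm base: `"e"` (natural log, default) or `"10"`.
#'   Downstream analyses are invariant to this up to a constant factor.
#' @return Corrected, log-transformed volume(s) (dimensionless log units).
#' @export
#' @examples
#' wmh_log_correct(0, 1.5e6)        # log(1e-4) floor
#' wmh_log_correct(1500, 1.5e6)     # log(0.0011)
wmh_log_correct <- function(x, sttiv, const = 1e-4, base = c("e", "10")) {
  base <- match.arg(base)
  if (any(is.na(x)) || any(x < 0))
    stop("raw WMH volumes must be non-negative and non-missing", call. = FALSE)
  if (any(is.na(sttiv)) || any(sttiv <= 0))
    stop("sttiv must be > 0", call. = FALSE)
  v <- log((x / sttiv) + const)
  if (base == "10") v <- v / log(10)
  v
}

#' Combine periventricular and deep WMH parcels into regional volumes
#'
#' Regional WMH volumes are the sums of all periventricular (pWMH) and deep
#' (dWMH) lesion parcels that map to each of the five regions (frontal,
#' parietal, temporal, occipital, basal ganglia/thalamus) in each
#' hemisphere. Regions with no contributing parcel get volume 0.
#'
#' @param parcels Data frame with columns `region` (one of
#'   `frontal, parietal, temporal, occipital, bgt`), `hemisphere`
#'   (`l`/`r`), `class` (`pWMH`/`dWMH`) and `volume` (mm^3, `>= 0`).
#' @return Named numeric vector of the 10 region-by-hemisphere volumes
#'   (names `wmh_<region>_<hemi>`).
#' @export
#' @examples
#' p <- data.frame(region = "frontal", hemisphere = "l",
#'                 class = c("pWMH", "dWMH"), volume = c(100, 50))
#' combine_pwmh_dwmh(p)[["wmh_frontal_l"]]
combine_pwmh_dwmh <- function(parcels) {
  req <- c("region", "hemisphere", "class", "volume")
  if (!all(req %in% names(parcels)))
    stop("parcels must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  region <- tolower(as.character(parcels$region))
  hemi <- tolower(substr(as.character(parcels$hemisphere), 1, 1))
  bad <- unique(region[!region %in% wmh_regions])
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "),
         "; valid labels are: ", paste(wmh_regions, collapse = ", "),
         call. = FALSE)
  if (!all(hemi %in% c("l", "r")))
    stop("hemisphere must be 'l' or 'r'", call. = FALSE)
  if (!all(parcels$class %in% c("pWMH", "dWMH")))
    stop("class must be 'pWMH' or 'dWMH'", call. = FALSE)
  if (any(is.na(parcels$volume)) || any(parcels$volume < 0))
    stop("parcel volumes must be non-negative", call. = FALSE)
  out <- setNames(numeric(10), wmh_cols())
  key <- paste("wmh", region, hemi, sep = "_")
  agg <- tapply(parcels$volume, key, sum)
  out[names(agg)] <- agg
  out
}

#' Normalize the WMH columns of a cohort table
#'
#' Applies [wmh_log_correct()] to each of the 10 `wmh_<region>_<hemi>`
#' columns against the `sttiv` column, appending `wmhlog_<region>_<hemi>`
#' columns. Also appends hemisphere-summed regional values
#' (`wmhlog_<region>`) and the corrected total lesion load `wmhlog_total`
#' (sum of all 10 raw volumes, corrected the same way), used for the
#' vascular-burden association.
#'
#' @param cohort Cohort data frame with raw `wmh_*` columns and `sttiv`.
#' @inheritParams wmh_log_correct
#' @return The cohort with normalized columns appended; the log base is
#'   recorded in attribute `wmh_log_base`.
#' @export
#' @examples
#' cohort <- normalize_wmh(generate_cohort(cohort_spec(seed = 5)))
#' range(cohort$wmhlog_frontal_l)
normalize_wmh <- function(cohort, const = 1e-4, base = c("e", "10")) {
  base <- match.arg(base)
  missing_cols <- setdiff(c(wmh_cols(), "sttiv"), names(cohort))
  if (length(missing_cols))
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (cl in wmh_cols()) {
    cohort[[sub("^wmh_", "wmhlog_", cl)]] <-
      wmh_log_correct(cohort[[cl]], cohort$sttiv, const, base)
  }
  for (r in wmh_regions) {
    both <- cohort[[paste0("wmh_", r, "_l")]] + cohort[[paste0("wmh_", r, "_r")]]
    cohort[[paste0("wmhlog_", r)]] <- wmh_log_correct(both, cohort$sttiv, const, base)
  }
  total <- rowSums(as.matrix(cohort[wmh_cols()]))
  cohort$wmhlog_total <- wmh_log_correct(total, cohort$sttiv, const, base)
  attr(cohort, "wmh_log_base") <- base
  cohort
}
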