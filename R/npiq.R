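#' Score NPI-Q items into the four neuropsychiatric subsyndromes
#'
#' Sums the 12 NPI-Q item severities (0-3) into the four EADC subsyndrome
#' composites: hyperactivity (agitation + euphoria + irritability +
#' disinhibition + aberrant motor), psychotic (hallucinations + delusions +
#' night-time behaviours), affective (depression + anxiety) and apathy
#' (apathy + appetite), plus the total severity and study-partner distress
#' scores. A symptom that is absent simply carries severity 0; the NPI-Q
#' "presence" flag is implicit in severity > 0.
#'
#' @param severities Named numeric vector (or single-row list/data frame) of
#'   the 12 item severities; names must cover
#'   `delusions, hallucinations, agitation, depression, anxiety, euphoria,
#'   apathy, disinhibition, irritability, aberrant_motor, nighttime,
#'   appetite`. Values must be integers in 0-3.
#' @param distress Optional named vector of the matching study-partner
#'   distress ratings (integers 0-5, positive only when the corresponding
#'   severity is positive).
#' @return Named list with `hyperactivity`, `psychotic`, `affective`,
#'   `apathy`, `total_severity` and (when distress is supplied)
#'   `total_distress`. The four subsyndromes always sum to `total_severity`.
#' @export
#' @examples
#' sev <- setNames(rep(0, 12), unlist(npiq_subsyndromes()))
#' sev[c("agitation", "nighttime", "anxiety", "appetite")] <- c(2, 1, 3, 1)
#' subsyndrome_scores(sev)
subsyndrome_scores <- function(severities, distress = NULL) {
  severities <- unlist(severities)
  missing_items <- setdiff(npiq_symptoms, names(severities))
  if (length(missing_items))
    stop("missing NPI-Q item(s): ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  severities <- severities[npiq_symptoms]
  bad <- names(severities)[is.na(severities) | severities < 0 |
                             severities > 3 | severities != round(severities)]
  if (length(bad))
    stop("severity out of range 0-3 for symptom(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- lapply(subsyndrome_items, function(items) sum(severities[items]))
  out$total_severity <- sum(severities)
  if (!is.null(distress)) {
    distress <- unlist(distress)[npiq_symptoms]
    badd <- npiq_symptoms[is.na(distress) | distress < 0 | distress > 5 |
                            (distress > 0 & severities == 0)]
    if (length(badd))
      stop("invalid distress (range 0-5, positive only with severity > 0) for: ",
           paste(badd, collapse = ", "), call. = FALSE)
    out$total_distress <- sum(distress)
  }
  out
}

#' Vascular risk factor burden
#'
#' Counts how many of the four vascular-risk diagnoses/history flags are
#' present: hypertension, diabetes, high cholesterol, and having ever smoked
#' for three or more months.
#'
#' @param hypertension,diabetes,high_cholesterol,smoked_3mo Logical flags
#'   (vectorized).
#' @return List with `count` (integer 0-4 per observation) and `flags`.
#' @export
#' @examples
#' vascular_burden(TRUE, FALSE, FALSE, TRUE)$count
vascular_burden <- function(hypertension, diabetes, high_cholesterol,
                            smoked_3mo) {
  flags <- cbind(hypertension = as.logical(hypertension),
                 diabetes = as.logical(diabetes),
                 high_cholesterol = as.logical(high_cholesterol),
                 smoked_3mo = as.logical(smoked_3mo))
  if (any(is.na(flags)))
    stop("vascular risk flags must be non-missing logicals", call. = FALSE)
  list(count = as.integer(rowSums(flags)), flags = flags)
}

#' Score a whole cohort table
#'
#' Vectorized scoring over the cohort columns `npiq_<symptom>_sev` /
#' `npiq_<symptom>_distress` and `vasc_*` flags. Appends the columns
#' `sub_hyperactivity`, `sub_psychotic`, `sub_affective`, `sub_apathy`,
#' `npiq_total_sev`, `npiq_total_distress` and `vasc_burden`.
#'
#' Records with missing NPI-Q items are rejected unless `skip_missing = TRUE`,
#' in which case missing item severities/distress are treated as 0 in the
#' sums (documented behaviour for incomplete questionnaires).
#'
#' @param cohort A cohort data frame (see [generate_cohort()]).
#' @param skip_missing Treat missing NPI-Q items as 0 instead of failing.
#' @return The cohort with scoring columns appended.
#' @export
#' @examples
#' cohort <- score_npiq(generate_cohort(cohort_spec(seed = 5)))
#' summary(cohort$sub_apathy)
score_npiq <- function(cohort, skip_missing = FALSE) {
  sev_cols <- paste0("npiq_", npiq_symptoms, "_sev")
  dis_cols <- paste0("npiq_", npiq_symptoms, "_distress")
  missing_cols <- setdiff(sev_cols, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks NPI-Q severity column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sev <- as.matrix(cohort[sev_cols])
  if (anyNA(sev)) {
    if (!skip_missing)
      stop("missing NPI-Q item severities in ", sum(!complete.cases(sev)),
           " record(s); use skip_missing = TRUE to score them as 0",
           call. = FALSE)
    sev[is.na(sev)] <- 0
  }
  if (any(sev < 0 | sev > 3 | sev != round(sev))) {
    bad <- sev_cols[colSums(sev < 0 | sev > 3 | sev != round(sev)) > 0]
    stop("severity out of range 0-3 in column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (s in names(subsyndrome_items)) {
    cols <- paste0("npiq_", subsyndrome_items[[s]], "_sev")
    cohort[[paste0("sub_", s)]] <- as.integer(rowSums(sev[, cols, drop = FALSE]))
  }
  cohort$npiq_total_sev <- as.integer(rowSums(sev))
  if (all(dis_cols %in% names(cohort))) {
    dis <- as.matrix(cohort[dis_cols])
    if (anyNA(dis)) {
      if (!skip_missing)
        stop("missing NPI-Q distress values; use skip_missing = TRUE",
             call. = FALSE)
      dis[is.na(dis)] <- 0
    }
    cohort$npiq_total_distress <- as.integer(rowSums(dis))
  }
  vcols <- paste0("vasc_", vascular_flags)
  if (all(vcols %in% names(cohort))) {
    cohort$vasc_burden <- vascular_burden(
      cohort[[vcols[1]]], cohort[[vcols[2]]], cohort[[vcols[3]]],
      cohort[[vcols[4]]]
    )$count
  }
  cohort
}
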