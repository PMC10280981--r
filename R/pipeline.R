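pipeline_stages <- c("synth", "score", "normalize", "compare", "enet", "plsc")

# Which earlier stages each stage needs.
stage_deps <- list(
  synth = character(), score = character(), normalize = character(),
  compare = c("score", "normalize"),
  enet = c("score", "normalize"),
  plsc = c("score", "normalize")
)

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the full chain on one seeded run: generate (or ingest) a
#' cohort, score the NPI-Q subsyndromes, normalize the WMH volumes, run the
#' cohort comparisons (per-symptom chi-square of endorsement frequencies
#' across dx groups, plus the age/sex-adjusted association of vascular
#' burden with total WMH load), fit the consensus elastic net for each of
#' the four subsyndromes, and fit the PLSc with permutation and bootstrap
#' inference. All stage outputs are written as tab-delimited text under
#' `outdir`; a JSON manifest records the seeds, a configuration fingerprint
#' and row counts, and per-stage timings go to `timings.json`. Re-running
#' with the same configuration and seed reproduces the manifest and every
#' output bitwise.
#'
#' Per-stage seeds are derived deterministically from the master seed and
#' the stage name (plus repeat index where applicable), so adding or
#' removing stages never perturbs the randomness of the others.
#'
#' @param config Either a list or a path to a YAML/JSON file. Recognized
#'   entries: `seed` (master seed), `stages` (subset of
#'   `synth, score, normalize, compare, enet, plsc`), `input` (path to a
#'   cohort table, replacing the synth stage), `cohort` (overrides passed to
#'   [cohort_spec()]: currently `effect_spec`, `noise_sd`, `missing_rate`),
#'   `enet` (overrides for [enet_config()]), `plsc` (`n_perm`, `n_boot`,
#'   `bsr_threshold`).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(list(seed = 1, enet = list(repeats = 20),
#'                          plsc = list(n_perm = 100, n_boot = 100)),
#'                     outdir = tempfile("npsmap-run-"))
#' names(res)
#' }
run_pipeline <- function(config = list(), outdir) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stages <- pipeline_stages[pipeline_stages %in% stages] # fixed order
  for (st in stages) {
    need <- setdiff(stage_deps[[st]], stages)
    if (length(need) && is.null(config$input))
      stop("stage '", st, "' requires stage(s): ",
           paste(need, collapse = ", "), call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(master_seed = seed,
                   config_hash = fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE)),
                   stages = stages, seeds = list())
  timings <- list()
  results <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  # --- cohort: synthesize or ingest -------------------------------------
  if (!is.null(config$input)) {
    cohort <- timed("ingest", read_cohort(config$input))
  } else if ("synth" %in% stages) {
    synth_seed <- derive_seed(seed, "synth")
    manifest$seeds$synth <- synth_seed
    spec_args <- list(seed = synth_seed)
    cc <- config$cohort %||% list()
    for (fld in c("noise_sd", "missing_rate", "item_noise_sd"))
      if (!is.null(cc[[fld]])) spec_args[[fld]] <- cc[[fld]]
    if (!is.null(cc$effect_spec)) spec_args$effect_spec <- as.data.frame(cc$effect_spec)
    cohort <- timed("synth", generate_cohort(do.call(cohort_spec, spec_args)))
    write_cohort(cohort, file.path(outdir, "cohort.tsv"))
  } else {
    stop("no cohort source: provide config$input or include the 'synth' stage",
         call. = FALSE)
  }
  manifest$n_cohort <- nrow(cohort)
  results$cohort <- cohort

  if ("score" %in% stages) {
    cohort <- timed("score", score_npiq(cohort, skip_missing = TRUE))
  }
  if ("normalize" %in% stages) {
    cohort <- timed("normalize", normalize_wmh(cohort))
    write_cohort(cohort, file.path(outdir, "cohort_processed.tsv"))
  }
  results$processed <- cohort

  if ("compare" %in% stages) {
    results$compare <- timed("compare", {
      present <- sapply(npiq_symptoms, function(s) {
        tapply(cohort[[paste0("npiq_", s, "_sev")]] > 0, cohort$dx, sum)
      })
      totals <- as.vector(table(cohort$dx))
      rep_df <- do.call(rbind, lapply(npiq_symptoms, function(s) {
        ct <- pearson_chi2(cbind(present[, s], totals - present[, s]))
        data.frame(symptom = s, chi2 = ct$statistic, df = ct$df,
                   p = ct$p.value, stringsAsFactors = FALSE)
      }))
      assoc <- adjusted_linear_association(cohort, "wmhlog_total",
                                           "vasc_burden", c("age", "sex"))
      utils::write.table(rep_df, file.path(outdir, "compare_chi2.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(chi2 = rep_df, vascular = assoc)
    })
  }

  if ("enet" %in% stages) {
    en_cfg <- config$enet %||% list()
    results$enet <- timed("enet", {
      lapply(setNames(nm = names(subsyndrome_items)), function(s) {
        cfg_args <- en_cfg
        cfg_args$seed <- derive_seed(seed, paste0("enet_", s))
        manifest$seeds[[paste0("enet_", s)]] <<- cfg_args$seed
        fit <- consensus_enet(build_design(cohort, s),
                              do.call(enet_config, cfg_args))
        write_consensus_table(fit, file.path(outdir, paste0("enet_", s, ".tsv")))
        fit
      })
    })
    manifest$n_design <- results$enet[[1]]$n
  }

  if ("plsc" %in% stages) {
    pl_cfg <- config$plsc %||% list()
    results$plsc <- timed("plsc", {
      d <- build_design(cohort, "hyperactivity")
      ymat <- as.matrix(score_cols(cohort)[complete_rows(cohort), , drop = FALSE])
      fit <- plsc(d$x, ymat)
      perm_seed <- derive_seed(seed, "plsc_perm")
      boot_seed <- derive_seed(seed, "plsc_boot")
      manifest$seeds$plsc_perm <- perm_seed
      manifest$seeds$plsc_boot <- boot_seed
      perm <- plsc_permutation(fit, d$strata,
                               n_perm = pl_cfg$n_perm %||% 5000,
                               seed = perm_seed)
      boot <- plsc_bootstrap(fit, d$strata,
                             n_boot = pl_cfg$n_boot %||% 1000,
                             seed = boot_seed,
                             threshold = pl_cfg$bsr_threshold %||% 2)
      comp <- data.frame(component = seq_len(fit$k),
                         singular_value = fit$d, pct_variance = fit$varexp,
                         perm_p = perm$p)
      utils::write.table(comp, file.path(outdir, "plsc_components.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      wr <- function(m, f) utils::write.table(
        data.frame(variable = rownames(m), m, check.names = FALSE),
        file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
      wr(boot$bsr_y, "plsc_bsr_outcomes.tsv")
      wr(boot$bsr_x, "plsc_bsr_predictors.tsv")
      scores <- data.frame(dx = cohort$dx[complete_rows(cohort)],
                           fit$scores_x[, 1:2], fit$scores_y[, 1:2])
      names(scores) <- c("dx", "lx1", "lx2", "ly1", "ly2")
      utils::write.table(scores, file.path(outdir, "plsc_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(fit = fit, permutation = perm, bootstrap = boot)
    })
    manifest$n_design <- manifest$n_design %||% results$plsc$fit$n
  }

  # The manifest is fully deterministic given config + seed; wall-clock
  # timings go to a separate file so re-runs compare bitwise.
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(timings, file.path(outdir, "timings.json"),
                       auto_unbox = TRUE)
  results$manifest <- manifest
  invisible(results)
}

score_cols <- function(cohort) {
  cohort[paste0("sub_", names(subsyndrome_items))]
}

# Complete-case filter over the modelling columns (mirrors build_design).
complete_rows <- function(cohort) {
  need <- c("dx", "sex", "age", "moca", paste0("sub_", names(subsyndrome_items)),
            thickness_cols(), wmhlog_cols())
  complete.cases(cohort[intersect(need, names(cohort))])
}
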